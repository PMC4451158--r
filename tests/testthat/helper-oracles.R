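# Independent oracles used by the unit and acceptance tests. These stay
# deliberately naive: enumeration and closed forms, no shared code with the
# package internals.

random_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# score a fixed (gapped) alignment under the package's affine convention:
# a run of k gaps costs gap_open + (k - 1) * gap_extend
score_alignment_rows <- function(ra, rb, p) {
  a <- strsplit(ra, "", fixed = TRUE)[[1]]
  b <- strsplit(rb, "", fixed = TRUE)[[1]]
  sc <- 0
  state <- "M"
  for (i in seq_along(a)) {
    if (a[i] == "-" || b[i] == "-") {
      this <- if (a[i] == "-") "Y" else "X"
      sc <- sc + if (state == this) p$gap_extend else p$gap_open
      state <- this
    } else {
      sc <- sc + if (a[i] == b[i]) p$match else p$mismatch
      state <- "M"
    }
  }
  sc
}

# exhaustive global-alignment optimum by enumerating all monotone paths
brute_force_align_score <- function(a, b, p) {
  ac <- strsplit(a, "", fixed = TRUE)[[1]]
  bc <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(ac); m <- length(bc)
  best <- -Inf
  recurse <- function(i, j, sc, state) {
    if (i == n && j == m) {
      if (sc > best) best <<- sc
      return(invisible())
    }
    if (i < n && j < m) {
      s <- if (ac[i + 1] == bc[j + 1]) p$match else p$mismatch
      recurse(i + 1, j + 1, sc + s, "M")
    }
    if (i < n) {
      g <- if (state == "X") p$gap_extend else p$gap_open
      recurse(i + 1, j, sc + g, "X")
    }
    if (j < m) {
      g <- if (state == "Y") p$gap_extend else p$gap_open
      recurse(i, j + 1, sc + g, "Y")
    }
  }
  recurse(0, 0, 0, "M")
  best
}

# brute-force minimum-Hamming primer location (for trim oracle)
brute_force_primer_pos <- function(seq, primer) {
  sc <- strsplit(seq, "", fixed = TRUE)[[1]]
  pc <- strsplit(primer, "", fixed = TRUE)[[1]]
  k <- length(pc)
  mism <- vapply(seq_len(length(sc) - k + 1), function(i) {
    sum(sc[i:(i + k - 1)] != pc)
  }, numeric(1))
  list(start = which.min(mism), mismatches = min(mism))
}

# small random unrooted tree with strictly positive branch lengths, and its
# (additive) tip-to-tip distance matrix
random_additive_case <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE)
  tr$edge.length <- runif(length(tr$edge.length), 0.05, 1)
  list(tree = tr, dm = cophenetic(tr))
}
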