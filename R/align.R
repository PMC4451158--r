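#' Alignment scoring parameters
#'
#' Affine-gap scoring: a run of `k` gap characters costs
#' `gap_open + k * gap_extend`. Defaults are conservative about opening gaps,
#' which suits near-identical barcode amplicons.
#'
#' @param match match score (> mismatch).
#' @param mismatch mismatch score.
#' @param gap_open gap-opening penalty (non-positive).
#' @param gap_extend per-character gap-extension penalty (non-positive).
#' @return an `align_params` list.
#' @export
align_params <- function(match = 1, mismatch = -1,
                         gap_open = -4, gap_extend = -1) {
  stopifnot(match > mismatch, gap_open <= 0, gap_extend <= 0)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "align_params")
}

#' Global pairwise alignment (Needleman-Wunsch, affine gaps)
#'
#' Deterministic optimal global alignment; traceback ties are resolved
#' diagonal > up > left so results are bit-reproducible. Any two identical
#' symbols (including identical ambiguity codes) score `match`; differing
#' symbols score `mismatch`.
#'
#' @param a,b non-empty DNA strings.
#' @param params an [align_params()] object.
#' @return list with `row_a`, `row_b` (gapped strings of equal length) and
#'   `score`.
#' @examples
#' global_align("ACGT", "ACT")
#' @export
global_align <- function(a, b, params = align_params()) {
  if (!nzchar(a) || !nzchar(b)) stop("empty input sequence")
  res <- nw_align_cpp(toupper(a), toupper(b), params$match, params$mismatch,
                      params$gap_open, params$gap_extend)
  structure(res, class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(x$row_a, "\n", x$row_b, "\nscore: ", x$score, "\n", sep = "")
  invisible(x)
}

#' Construct a multiple-alignment object
#'
#' A `dna_msa` holds the gapped rows of a multiple alignment as a character
#' matrix (rows = samples, columns = 1-based alignment sites) together with
#' the species label of each row. All site numbers reported by the variation
#' and phylogeny functions refer to this object's columns.
#'
#' @param rows named character vector of equal-length gapped strings
#'   (names = sample ids).
#' @param species named character vector mapping sample id to species.
#' @return an object of class `dna_msa` with elements `matrix` and `species`.
#' @export
as_msa <- function(rows, species) {
  stopifnot(length(rows) >= 1, !is.null(names(rows)))
  lens <- nchar(rows)
  if (length(unique(lens)) != 1) stop("rows differ in length")
  m <- do.call(rbind, strsplit(toupper(rows), "", fixed = TRUE))
  rownames(m) <- names(rows)
  if (ncol(m) > 0 && any(colSums(m != "-") == 0)) stop("all-gap column")
  species <- species[rownames(m)]
  if (anyNA(species)) stop("species label missing for some rows")
  structure(list(matrix = m, species = species), class = "dna_msa")
}

#' @export
print.dna_msa <- function(x, ...) {
  cat("dna_msa: ", nrow(x$matrix), " sequences x ", ncol(x$matrix),
      " columns, ", length(unique(x$species)), " species\n", sep = "")
  invisible(x)
}

#' Number of alignment columns
#' @param msa a `dna_msa`.
#' @return integer column count.
#' @export
n_cols <- function(msa) ncol(msa$matrix)

#' Gapped row strings of an alignment
#' @param msa a `dna_msa`.
#' @return named character vector of gapped strings.
#' @export
msa_strings <- function(msa) {
  setNames(apply(msa$matrix, 1, paste, collapse = ""), rownames(msa$matrix))
}

#' Extract one alignment column
#'
#' @param msa a `dna_msa`.
#' @param site 1-based column index.
#' @return named character vector of the symbols at that site.
#' @export
msa_column <- function(msa, site) {
  if (length(site) != 1 || site < 1 || site > n_cols(msa) ||
      site != as.integer(site)) {
    stop("site out of range [1, ", n_cols(msa), "]: ", site)
  }
  setNames(msa$matrix[, site], rownames(msa$matrix))
}

# encode an MSA character matrix: A=1 C=2 G=3 T=4, gap=0, ambiguity=-1
.msa_codes <- function(msa) {
  m <- msa$matrix
  codes <- match(m, .DNA_BASES)
  codes[is.na(codes) & m == "-"] <- 0L
  codes[is.na(codes)] <- -1L
  matrix(as.integer(codes), nrow = nrow(m), dimnames = dimnames(m))
}

# 6 x L count profile (A,C,G,T,gap,other) from a character sub-matrix
.profile_of <- function(mat) {
  L <- ncol(mat)
  prof <- matrix(0, nrow = 6, ncol = L)
  for (r in seq_len(nrow(mat))) {
    code <- match(mat[r, ], c(.DNA_BASES, "-"))
    code[is.na(code)] <- 6L
    prof[cbind(code, seq_len(L))] <- prof[cbind(code, seq_len(L))] + 1
  }
  prof
}

#' Progressive multiple sequence alignment
#'
#' Sequences identical at the string level are grouped first (they trivially
#' co-align), then a guide tree is built by neighbor joining on pairwise K2P
#' distances between the distinct sequences (p-distance fallback where K2P is
#' saturated; equal guide distances resolved by lexicographic sample id), and
#' profiles are merged bottom-up by affine-gap global profile alignment under
#' "once a gap, always a gap". Row order in the result follows the input.
#'
#' @param records barcode record `data.frame` with at least 2 rows.
#' @param params an [align_params()] object.
#' @return a `dna_msa`.
#' @export
progressive_msa <- function(records, params = align_params()) {
  n <- nrow(records)
  if (n < 2) stop("need at least 2 records")
  seqs <- setNames(toupper(records$sequence), records$sample_id)
  species <- species_labels(records)

  uniq <- !duplicated(seqs)
  useqs <- seqs[uniq]
  rep_of <- names(useqs)[match(seqs, useqs)] # representative id per record
  k <- length(useqs)

  if (k == 1) {
    return(as_msa(seqs, species))
  }

  aligned <- .align_unique(useqs, params)

  rows <- setNames(aligned[rep_of], names(seqs))
  as_msa(rows, species)
}

# progressive alignment of distinct sequences; returns named gapped strings
.align_unique <- function(useqs, params) {
  k <- length(useqs)
  ids <- sort(names(useqs)) # lexicographic order for reproducible guide trees
  useqs <- useqs[ids]
  if (k == 2) {
    pa <- global_align(useqs[[1]], useqs[[2]], params)
    return(setNames(c(pa$row_a, pa$row_b), ids))
  }

  d <- matrix(0, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      pa <- global_align(useqs[[i]], useqs[[j]], params)
      cnt <- count_site_patterns(pa$row_a, pa$row_b)
      dij <- tryCatch(k2p_distance(cnt$P, cnt$Q),
                      its2barcode_saturated = function(e) cnt$P + cnt$Q)
      d[i, j] <- d[j, i] <- dij
    }
  }
  guide <- stats::reorder(ape::nj(as.dist(d)), "postorder")

  # post-order profile merge over the guide tree
  node_mat <- vector("list", guide$Nnode + k)
  tip_ids <- vector("list", guide$Nnode + k)
  for (i in seq_len(k)) {
    node_mat[[i]] <- matrix(
      strsplit(useqs[[guide$tip.label[i]]], "", fixed = TRUE)[[1]], nrow = 1)
    tip_ids[[i]] <- guide$tip.label[i]
  }

  edge <- guide$edge
  for (e in seq_len(nrow(edge))) {
    parent <- edge[e, 1]; child <- edge[e, 2]
    if (is.null(node_mat[[parent]])) {
      node_mat[[parent]] <- node_mat[[child]]
      tip_ids[[parent]] <- tip_ids[[child]]
    } else {
      merged <- .merge_profiles(node_mat[[parent]], node_mat[[child]], params)
      node_mat[[parent]] <- rbind(merged$a, merged$b)
      tip_ids[[parent]] <- c(tip_ids[[parent]], tip_ids[[child]])
    }
  }
  root <- edge[nrow(edge), 1]
  out <- apply(node_mat[[root]], 1, paste, collapse = "")
  setNames(out, tip_ids[[root]])[ids]
}

.merge_profiles <- function(ma, mb, params) {
  res <- profile_align_cpp(.profile_of(ma), .profile_of(mb),
                           params$match, params$mismatch,
                           params$gap_open, params$gap_extend)
  L <- length(res$use_a)
  expand <- function(mat, use) {
    out <- matrix("-", nrow = nrow(mat), ncol = L)
    out[, use == 1L] <- mat
    out
  }
  list(a = expand(ma, res$use_a), b = expand(mb, res$use_b))
}

#' Read an aligned FASTA file into a `dna_msa`
#'
#' @param path aligned FASTA path (gap character `-`).
#' @param delim header field delimiter (`sample_id<delim>species`).
#' @return a `dna_msa`.
#' @export
read_aligned_fasta <- function(path, delim = "|") {
  set <- Biostrings::readBStringSet(path)
  headers <- strsplit(names(set), delim, fixed = TRUE)
  ids <- vapply(headers, `[[`, character(1), 1L)
  spp <- vapply(headers, `[[`, character(1), 2L)
  as_msa(setNames(toupper(as.character(set)), ids), setNames(spp, ids))
}

#' Write a `dna_msa` as aligned FASTA
#'
#' @param msa a `dna_msa`.
#' @param path output path.
#' @param delim header field delimiter.
#' @return `path`, invisibly.
#' @export
write_aligned_fasta <- function(msa, path, delim = "|") {
  rows <- msa_strings(msa)
  set <- Biostrings::BStringSet(setNames(
    rows, paste(names(rows), msa$species[names(rows)], sep = delim)
  ))
  Biostrings::writeXStringSet(set, path, width = 70)
  invisible(path)
}
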