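#' Classify alignment columns as monomorphic, substitution, or indel
#'
#' Every column is assigned exactly one kind: columns containing any gap
#' symbol are `indel` (even if they also vary in their bases, so substitution
#' and indel counts partition the variable sites); gap-free columns with two
#' or more distinct symbols are `substitution`; the rest are `monomorphic`.
#' Ambiguity codes count as distinct symbols and are flagged.
#'
#' @param msa a `dna_msa`.
#' @return `data.frame` with columns `site` (1-based), `kind`, `states`
#'   (sorted distinct symbols joined by `/`, gap written `-`), `has_ambiguity`.
#' @export
classify_sites <- function(msa) {
  m <- msa$matrix
  res <- lapply(seq_len(ncol(m)), function(j) {
    syms <- unique(m[, j])
    has_gap <- "-" %in% syms
    kind <- if (has_gap) "indel"
            else if (length(syms) >= 2) "substitution"
            else "monomorphic"
    data.frame(
      site = j,
      kind = kind,
      states = paste(sort(syms), collapse = "/"),
      has_ambiguity = any(!syms %in% c(.DNA_BASES, "-")),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, res)
}

#' Tally substitution columns by their unordered base set
#'
#' Each substitution column contributes one count to the bucket of its
#' distinct-state set, e.g. `C/T` or `A/C/T`; two-state and three-state
#' buckets coexist. Non-substitution rows in the input are ignored.
#'
#' @param sites output of [classify_sites()].
#' @return named integer vector of counts, names are sorted state sets.
#' @export
tally_substitutions <- function(sites) {
  sub <- sites[sites$kind == "substitution", , drop = FALSE]
  if (nrow(sub) == 0) return(setNames(integer(0), character(0)))
  tab <- table(sub$states)
  setNames(as.integer(tab), names(tab))
}

#' Collapse aligned rows into haplotypes per species
#'
#' Within each species, rows are grouped by exact identity of their aligned
#' (gapped) sequence.
#'
#' @param msa a `dna_msa`.
#' @return `data.frame` with columns `species`, `haplotype` (1-based index
#'   within species), `n_members`, `members` (sample ids joined by `,`),
#'   `sequence` (gapped).
#' @export
collapse_haplotypes <- function(msa) {
  rows <- msa_strings(msa)
  sp <- msa$species[names(rows)]
  out <- lapply(unique(sp), function(x) {
    rx <- rows[sp == x]
    groups <- split(names(rx), factor(rx, levels = unique(rx)))
    data.frame(
      species = x,
      haplotype = seq_along(groups),
      n_members = vapply(groups, length, integer(1)),
      members = vapply(groups, paste, character(1), collapse = ","),
      sequence = names(groups),
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
  do.call(rbind, out)
}

#' Detect species-diagnostic (distinctive) alignment sites
#'
#' A (species, site) pair is diagnostic when every sample of the species
#' carries one identical symbol at that site (a gap is allowed as the shared
#' symbol) and no sample of any other species carries that symbol. One such
#' character is enough to authenticate the species at that site.
#'
#' @param msa a `dna_msa` with at least 2 species.
#' @return `data.frame` sorted by `site` then `species`, with columns
#'   `species`, `site`, `state`, `background` (sorted symbols seen in the
#'   other species, joined by `/`).
#' @export
find_diagnostic_sites <- function(msa) {
  m <- msa$matrix
  sp <- msa$species[rownames(m)]
  if (length(unique(sp)) < 2) stop("need at least 2 species")
  hits <- list()
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    for (x in unique(sp)) {
      inside <- col[sp == x]
      if (length(unique(inside)) != 1) next
      state <- inside[[1]]
      background <- unique(col[sp != x])
      if (!state %in% background) {
        hits[[length(hits) + 1]] <- data.frame(
          species = x, site = j, state = state,
          background = paste(sort(background), collapse = "/"),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(species = character(0), site = integer(0),
                      state = character(0), background = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$site, out$species), , drop = FALSE]
  rownames(out) <- NULL
  out
}
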