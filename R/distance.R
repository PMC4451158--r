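#' Pairwise site-pattern counts under pairwise deletion
#'
#' Counts the sites compared between two gapped rows after excluding every
#' column in which either row carries a gap or an IUPAC ambiguity code
#' (pairwise deletion), and splits the differing sites into transitions
#' (A<->G, C<->T) and transversions (all other base pairs).
#'
#' @param row_a,row_b gapped strings of equal length.
#' @return list with `n` (compared sites), `s` (transitions), `v`
#'   (transversions), `P = s/n`, `Q = v/n`.
#' @examples
#' count_site_patterns("AC-T", "ACGT")
#' @export
count_site_patterns <- function(row_a, row_b) {
  a <- strsplit(toupper(row_a), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(row_b), "", fixed = TRUE)[[1]]
  if (length(a) != length(b)) stop("rows differ in length")
  ca <- match(a, .DNA_BASES)
  cb <- match(b, .DNA_BASES)
  keep <- !is.na(ca) & !is.na(cb)
  n <- sum(keep)
  if (n == 0) {
    stop(structure(class = c("its2barcode_no_overlap", "error", "condition"),
                   list(message = "no comparable sites after pairwise deletion",
                        call = sys.call(-1))))
  }
  ca <- ca[keep]; cb <- cb[keep]
  diff <- ca != cb
  purine_a <- ca == 1L | ca == 3L
  purine_b <- cb == 1L | cb == 3L
  s <- sum(diff & (purine_a == purine_b))
  v <- sum(diff & (purine_a != purine_b))
  list(n = n, s = s, v = v, P = s / n, Q = v / n)
}

#' Kimura 2-parameter distance
#'
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` where `P` and `Q` are the
#' proportions of sites differing by a transition and a transversion. Inputs
#' at or beyond the model's saturation boundary (`1 - 2P - Q <= 0` or
#' `1 - 2Q <= 0`) raise a typed condition of class
#' `its2barcode_saturated`.
#'
#' @param P transition proportion, or the list returned by
#'   [count_site_patterns()] (in which case `Q` is taken from it).
#' @param Q transversion proportion.
#' @return the K2P distance in expected substitutions per site.
#' @examples
#' k2p_distance(0.1, 0)
#' @export
k2p_distance <- function(P, Q = NULL) {
  if (is.list(P)) { Q <- P$Q; P <- P$P }
  stopifnot(length(P) == length(Q), all(P >= 0), all(Q >= 0))
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  if (any(a1 <= 0) || any(a2 <= 0)) {
    cond <- structure(
      class = c("its2barcode_saturated", "error", "condition"),
      list(message = sprintf(
        "saturated K2P distance (P = %s, Q = %s)",
        paste(signif(P[a1 <= 0 | a2 <= 0], 4), collapse = ","),
        paste(signif(Q[a1 <= 0 | a2 <= 0], 4), collapse = ",")),
        call = sys.call(-1), P = P, Q = Q))
    stop(cond)
  }
  -0.5 * log(a1) - 0.25 * log(a2)
}

#' Pairwise K2P distance matrix of an alignment
#'
#' All pairwise K2P distances under pairwise deletion of gap/ambiguous
#' columns. Indels contribute nothing to the distance; they are reported by
#' the variation functions instead.
#'
#' @param msa a `dna_msa` with at least 2 rows.
#' @param on_saturation `"error"` to fail listing the saturated pairs
#'   (default), `"inf"` to flag them as `Inf`.
#' @return symmetric numeric matrix (substitutions/site) with zero diagonal,
#'   dimnames = sample ids.
#' @export
distance_matrix <- function(msa, on_saturation = c("error", "inf")) {
  on_saturation <- match.arg(on_saturation)
  codes <- .msa_codes(msa)
  n <- nrow(codes)
  if (n < 2) stop("need at least 2 aligned rows")
  cnt <- pair_counts_cpp(codes)
  N <- cnt$n; S <- cnt$s; V <- cnt$v
  off <- upper.tri(N)
  if (any(N[off] == 0)) {
    bad <- which(N == 0 & off, arr.ind = TRUE)
    stop("no comparable sites for pair(s): ",
         paste(rownames(codes)[bad[, 1]], rownames(codes)[bad[, 2]],
               sep = "/", collapse = ", "))
  }
  P <- S / N; Q <- V / N
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  sat <- (a1 <= 0 | a2 <= 0) & off
  D <- matrix(0, n, n, dimnames = list(rownames(codes), rownames(codes)))
  ok <- !sat & off
  D[ok] <- -0.5 * log(a1[ok]) - 0.25 * log(a2[ok])
  if (any(sat)) {
    if (on_saturation == "error") {
      bad <- which(sat, arr.ind = TRUE)
      stop(structure(
        class = c("its2barcode_saturated", "error", "condition"),
        list(message = paste0(
          "saturated K2P distance for pair(s): ",
          paste(rownames(codes)[bad[, 1]], rownames(codes)[bad[, 2]],
                sep = "/", collapse = ", ")),
          call = sys.call())))
    }
    D[sat] <- Inf
  }
  D[lower.tri(D)] <- t(D)[lower.tri(D)]
  D
}

#' Per-species intra- and interspecific distance summaries
#'
#' For each species: the minimum, maximum and arithmetic mean of the K2P
#' distances over all unordered within-species sample pairs (intraspecific;
#' `NA` when the species has a single sample) and over all pairs of one
#' sample of the species with any sample of a different species
#' (interspecific). Means are unweighted over pairs.
#'
#' @param dm distance matrix from [distance_matrix()].
#' @param labels named character vector mapping sample id to species.
#' @return `data.frame` with columns `species`, `n_samples`, `intra_min`,
#'   `intra_max`, `intra_mean`, `inter_min`, `inter_max`, `inter_mean`.
#' @export
species_summaries <- function(dm, labels) {
  ids <- rownames(dm)
  if (any(!ids %in% names(labels))) stop("unlabelled sample id(s)")
  sp <- labels[ids]
  out <- lapply(unique(sp), function(x) {
    inside <- which(sp == x)
    outside <- which(sp != x)
    intra <- if (length(inside) >= 2) {
      dm[inside, inside][upper.tri(diag(length(inside)))]
    } else numeric(0)
    inter <- as.vector(dm[inside, outside, drop = FALSE])
    data.frame(
      species = x,
      n_samples = length(inside),
      intra_min = if (length(intra)) min(intra) else NA_real_,
      intra_max = if (length(intra)) max(intra) else NA_real_,
      intra_mean = if (length(intra)) mean(intra) else NA_real_,
      inter_min = if (length(inter)) min(inter) else NA_real_,
      inter_max = if (length(inter)) max(inter) else NA_real_,
      inter_mean = if (length(inter)) mean(inter) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
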