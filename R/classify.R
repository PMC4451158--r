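#' Default BLAST1-surrogate local-alignment scoring
#'
#' Smith-Waterman scoring approximating megablast-like behaviour
#' (match 2, mismatch -3, gap open -5, gap extend -2).
#'
#' @return an [align_params()] object.
#' @export
blast1_params <- function() {
  align_params(match = 2, mismatch = -3, gap_open = -5, gap_extend = -2)
}

#' Assign a species by nearest genetic distance
#'
#' The query is assigned the species of its minimum-distance reference. When
#' several references tie at the minimum the prediction is their common
#' species if unique, otherwise `"AMBIGUOUS"`. The margin is the minimum
#' distance to any other species minus the minimum distance to the predicted
#' species.
#'
#' @param query_id sample id present in `dm`; all other rows serve as
#'   references.
#' @param dm K2P distance matrix (see [distance_matrix()]).
#' @param labels named character vector mapping sample id to species.
#' @return one-row `data.frame`: `query_id`, `true_species`, `predicted`,
#'   `method`, `margin`.
#' @export
nearest_distance_assign <- function(query_id, dm, labels) {
  if (!query_id %in% rownames(dm)) stop("query not in distance matrix")
  d <- dm[query_id, setdiff(colnames(dm), query_id)]
  if (all(!is.finite(d))) stop("query has no finite distances")
  d <- d[is.finite(d)]
  .top_hit_result(query_id, scores = -d, labels = labels,
                  method = "nearest_distance")
}

#' Assign a species by local-alignment top hit (BLAST1 style)
#'
#' Full Smith-Waterman local alignment of the query against every reference;
#' the query is assigned the species of the top-scoring reference, with the
#' same tie rule as [nearest_distance_assign()]. The margin is the top score
#' minus the best score achieved by any other species.
#'
#' @param query one-row barcode record `data.frame` (or a row subset).
#' @param refs barcode record `data.frame` of references (query excluded).
#' @param params scoring parameters, default [blast1_params()].
#' @return one-row `data.frame` as in [nearest_distance_assign()].
#' @export
blast1_assign <- function(query, refs, params = blast1_params()) {
  if (nrow(refs) == 0) stop("empty reference set")
  scores <- vapply(refs$sequence, function(r) {
    sw_score_cpp(query$sequence, r, params$match, params$mismatch,
                 params$gap_open, params$gap_extend)
  }, numeric(1), USE.NAMES = FALSE)
  names(scores) <- refs$sample_id
  labels <- c(species_labels(refs),
              setNames(query$species, query$sample_id))
  .top_hit_result(query$sample_id, scores = scores, labels = labels,
                  method = "blast1")
}

# shared top-hit logic: scores named by reference id, higher is better
.top_hit_result <- function(query_id, scores, labels, method) {
  top <- max(scores)
  tied <- names(scores)[scores == top]
  tied_species <- unique(labels[tied])
  predicted <- if (length(tied_species) == 1) unname(tied_species) else "AMBIGUOUS"
  margin <- if (predicted == "AMBIGUOUS") {
    0
  } else {
    other <- scores[labels[names(scores)] != predicted]
    if (length(other) == 0) NA_real_ else top - max(other)
  }
  data.frame(
    query_id = query_id,
    true_species = unname(labels[query_id]),
    predicted = predicted,
    method = method,
    margin = margin,
    stringsAsFactors = FALSE
  )
}

#' Leave-one-out identification evaluation
#'
#' Each sample in turn is treated as the query against all remaining samples
#' and classified by the chosen method; ambiguous predictions count as
#' incorrect. For the nearest-distance method the alignment and K2P matrix
#' are computed once and reused across folds (removing a row does not change
#' the other pairwise distances under pairwise deletion). A species
#' represented by a single sample cannot be identified once held out; by
#' default such queries are evaluated (and fail), or they can be excluded
#' and listed.
#'
#' @param records barcode record `data.frame`.
#' @param method `"nearest_distance"` or `"blast1"`.
#' @param params alignment parameters: for `nearest_distance`, the
#'   [align_params()] used to build the MSA; for `blast1`, the local-alignment
#'   scoring (default [blast1_params()]).
#' @param msa optional precomputed `dna_msa` (nearest-distance only).
#' @param include_singletons evaluate singleton-species queries (default
#'   `TRUE`)?
#' @return list of class `loo_eval`: `method`, `n_queries`, `n_correct`,
#'   `success_rate` (percent), `per_species` breakdown, `results` per-query
#'   `data.frame`, `excluded` sample ids.
#' @export
leave_one_out_eval <- function(records,
                               method = c("nearest_distance", "blast1"),
                               params = NULL, msa = NULL,
                               include_singletons = TRUE) {
  method <- match.arg(method)
  labels <- species_labels(records)
  counts <- table(labels)
  singles <- names(labels)[counts[labels] == 1]
  excluded <- if (include_singletons) character(0) else singles
  queries <- setdiff(records$sample_id, excluded)
  if (length(queries) == 0) stop("no queries to evaluate")

  if (method == "nearest_distance") {
    if (is.null(msa)) {
      msa <- progressive_msa(records, params %||% align_params())
    }
    dm <- distance_matrix(msa)
    results <- do.call(rbind, lapply(queries, nearest_distance_assign,
                                     dm = dm, labels = labels))
  } else {
    params <- params %||% blast1_params()
    sm <- sw_score_matrix_cpp(records$sequence, params$match, params$mismatch,
                              params$gap_open, params$gap_extend)
    dimnames(sm) <- list(records$sample_id, records$sample_id)
    results <- do.call(rbind, lapply(queries, function(q) {
      sc <- sm[q, setdiff(colnames(sm), q)]
      .top_hit_result(q, scores = sc, labels = labels, method = "blast1")
    }))
  }

  correct <- results$predicted == results$true_species
  per_species <- do.call(rbind, lapply(sort(unique(results$true_species)),
    function(x) {
      idx <- results$true_species == x
      data.frame(species = x, n_queries = sum(idx),
                 n_correct = sum(correct[idx]),
                 success_rate = 100 * sum(correct[idx]) / sum(idx),
                 stringsAsFactors = FALSE)
    }))
  structure(list(
    method = method,
    n_queries = nrow(results),
    n_correct = sum(correct),
    success_rate = 100 * sum(correct) / nrow(results),
    per_species = per_species,
    results = results,
    excluded = excluded
  ), class = "loo_eval")
}

#' @export
print.loo_eval <- function(x, ...) {
  cat("Leave-one-out evaluation (", x$method, ")\n",
      "  queries: ", x$n_queries, ", correct: ", x$n_correct,
      ", success rate: ", sprintf("%.1f%%", x$success_rate), "\n", sep = "")
  if (length(x$excluded)) {
    cat("  excluded singleton-species queries:",
        paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
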