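#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining (via `ape::nj`) on a symmetric
#' distance matrix; negative branch lengths, which NJ can produce on
#' non-additive input, are clamped to zero by default (the usual convention
#' in barcoding toolchains) with the total clamped deficit recorded in the
#' `"clamped_deficit"` attribute.
#'
#' @param dm symmetric numeric distance matrix with >= 3 taxa, finite
#'   entries, zero diagonal.
#' @param clamp_negative clamp negative branch lengths to 0 (default `TRUE`).
#' @return an unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(dm, clamp_negative = TRUE) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3) stop("need at least 3 taxa")
  if (any(!is.finite(dm))) stop("non-finite distance(s)")
  tree <- ape::nj(as.dist(dm))
  deficit <- 0
  if (clamp_negative && any(tree$edge.length < 0)) {
    deficit <- -sum(tree$edge.length[tree$edge.length < 0])
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  attr(tree, "clamped_deficit") <- deficit
  tree
}

#' Column-bootstrap support values for an NJ tree
#'
#' Felsenstein bootstrap: alignment columns are resampled with replacement
#' (seeded), the K2P + NJ tree is rebuilt for each replicate, and each
#' internal bipartition of the reference tree is scored by the percentage of
#' replicates in which it recurs. Replicates in which a distance saturates
#' are dropped and counted. Supports below `display_threshold` are retained
#' in the returned tree but suppressed by the renderer convention (the
#' threshold is carried in the result).
#'
#' @param msa a `dna_msa` with >= 4 rows.
#' @param replicates number of bootstrap replicates (default 1000).
#' @param seed integer seed; identical seeds give identical supports.
#' @param display_threshold percent threshold for display (default 50).
#' @return list of class `bootstrap_tree`: `tree` (reference NJ tree with
#'   node labels = rounded percent supports; root label empty), `support`
#'   (numeric per internal node), `n_valid`, `n_dropped`,
#'   `display_threshold`.
#' @export
bootstrap_support <- function(msa, replicates = 1000, seed = NULL,
                              display_threshold = 50) {
  stopifnot(replicates >= 1)
  if (nrow(msa$matrix) < 4) stop("need at least 4 rows for supports")
  if (!is.null(seed)) set.seed(seed)
  ref <- neighbor_joining(distance_matrix(msa))
  L <- n_cols(msa)
  trees <- vector("list", replicates)
  dropped <- 0L
  for (r in seq_len(replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    sub <- structure(list(matrix = msa$matrix[, cols, drop = FALSE],
                          species = msa$species), class = "dna_msa")
    trees[[r]] <- tryCatch(neighbor_joining(distance_matrix(sub)),
                           error = function(e) NULL)
    if (is.null(trees[[r]])) dropped <- dropped + 1L
  }
  trees <- Filter(Negate(is.null), trees)
  n_valid <- length(trees)
  if (n_valid == 0) stop("all bootstrap replicates failed")
  counts <- ape::prop.clades(ref, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- 100 * counts / n_valid
  lab <- sprintf("%.0f", support)
  lab[1] <- "" # basal node: trivial bipartition
  ref$node.label <- lab
  structure(list(tree = ref, support = support, n_valid = n_valid,
                 n_dropped = dropped, display_threshold = display_threshold),
            class = "bootstrap_tree")
}

#' @export
print.bootstrap_tree <- function(x, ...) {
  cat("NJ tree with bootstrap supports (", x$n_valid, " valid replicates",
      if (x$n_dropped) paste0(", ", x$n_dropped, " dropped"), ")\n", sep = "")
  shown <- sum(x$support[-1] >= x$display_threshold)
  cat("  internal branches with support >= ", x$display_threshold, "%: ",
      shown, "/", length(x$support) - 1, "\n", sep = "")
  invisible(x)
}

#' Bootstrap support of a tip-set bipartition
#'
#' Looks up the support of the internal branch that separates exactly `tips`
#' from all other leaves of the reference tree, matching either orientation
#' of the bipartition.
#'
#' @param bst a `bootstrap_tree` from [bootstrap_support()].
#' @param tips character vector of tip labels on one side of the bipartition.
#' @return percent support, or `NA` if no branch of the reference tree
#'   induces that bipartition.
#' @export
bipartition_support <- function(bst, tips) {
  tree <- bst$tree
  node <- .bipartition_node(tree, tips)
  if (is.na(node)) return(NA_real_)
  ntip <- length(tree$tip.label)
  bst$support[node - ntip]
}

# internal node whose clade equals `tips` or their complement; NA if none
.bipartition_node <- function(tree, tips) {
  ntip <- length(tree$tip.label)
  if (any(!tips %in% tree$tip.label)) stop("tips missing from tree")
  pp <- ape::prop.part(tree)
  target <- sort(match(tips, tree$tip.label))
  comp <- sort(setdiff(seq_len(ntip), target))
  for (i in seq_along(pp)) {
    clade <- sort(pp[[i]])
    if (identical(clade, target) || identical(clade, comp)) return(ntip + i)
  }
  NA_integer_
}

#' Bootstrap support of each species' clade
#'
#' @param bst a `bootstrap_tree` from [bootstrap_support()].
#' @param labels named character vector mapping sample id to species.
#' @return named numeric vector of percent supports; `NA` when a species with
#'   more than one sample is not monophyletic on the reference tree, and 100
#'   by convention for singleton species (a leaf is trivially exclusive).
#' @export
species_clade_support <- function(bst, labels) {
  ntip <- length(bst$tree$tip.label)
  vapply(sort(unique(labels)), function(x) {
    tips <- names(labels)[labels == x]
    if (length(tips) < 2 || length(tips) == ntip) return(100)
    bipartition_support(bst, tips)
  }, numeric(1))
}

#' Test whether a species is monophyletic on an unrooted tree
#'
#' TRUE when some branch bipartition separates exactly the species' leaves
#' from all others; a single-leaf species (or a species covering every leaf)
#' is monophyletic by definition.
#'
#' @param tree an `ape::phylo`.
#' @param labels named character vector mapping tip label to species.
#' @param species species name to test.
#' @return logical.
#' @export
is_monophyletic <- function(tree, labels, species) {
  tips <- names(labels)[labels == species]
  if (length(tips) == 0) stop("unknown species: ", species)
  if (any(!tips %in% tree$tip.label)) stop("species tips missing from tree")
  if (length(tips) < 2 || length(tips) == length(tree$tip.label)) return(TRUE)
  !is.na(.bipartition_node(tree, tips))
}

#' Serialize / parse trees in Newick format
#'
#' Thin wrappers over `ape` preserving topology, branch lengths (6 decimal
#' digits) and internal-node support labels.
#'
#' @param tree an `ape::phylo` or `bootstrap_tree`.
#' @param path optional file path; when `NULL` the Newick string is returned.
#' @return `write_newick`: the Newick string (invisibly if written to file);
#'   `read_newick`: an `ape::phylo`.
#' @export
write_newick <- function(tree, path = NULL) {
  if (inherits(tree, "bootstrap_tree")) tree <- tree$tree
  s <- ape::write.tree(tree, digits = 6)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' @param text Newick string (used when `path` is `NULL`).
#' @rdname write_newick
#' @export
read_newick <- function(text = NULL, path = NULL) {
  tree <- tryCatch(
    if (is.null(path)) ape::read.tree(text = text) else ape::read.tree(path),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(tree)) stop("malformed Newick input")
  tree
}
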