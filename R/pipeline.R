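# atomic TSV writing: temp file in the target directory, then rename
.write_tsv <- function(df, path, meta = character(0)) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  con <- file(tmp, open = "wt")
  on.exit(tryCatch(close(con), error = function(e) NULL), add = TRUE)
  if (length(meta)) writeLines(paste0("# ", meta), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  file.rename(tmp, path)
  invisible(path)
}

.write_matrix_tsv <- function(m, path, meta = character(0)) {
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path, meta)
}

#' Run the full barcoding analysis pipeline
#'
#' Chains the package end-to-end on one set of labelled amplicons: optional
#' primer trimming, region annotation and per-region statistics, progressive
#' multiple alignment, K2P distance matrix and per-species summaries,
#' variable/diagnostic-site reports, haplotype collapsing, leave-one-out
#' identification by nearest distance and BLAST1-style top hit, and an NJ
#' tree with bootstrap supports plus per-species monophyly. All artifacts are
#' written atomically to `out_dir` as TSV / aligned FASTA / Newick, with a
#' run manifest listing inputs, parameters, seed and outputs.
#'
#' @param input path to a labelled FASTA file, or a barcode record
#'   `data.frame`.
#' @param out_dir output directory (created if missing).
#' @param header_delim FASTA header delimiter.
#' @param params [align_params()] for the multiple alignment.
#' @param fwd_primer,rev_primer optional universal primers; when both are
#'   given, amplicons are trimmed before analysis.
#' @param max_mismatch primer mismatch tolerance.
#' @param bootstrap_replicates bootstrap replicates for the NJ tree.
#' @param seed seed for the bootstrap resampling.
#' @param methods identification methods to evaluate.
#' @return invisibly, a list with the in-memory results (`records`, `msa`,
#'   `dm`, `species_summary`, `sites`, `tally`, `haplotypes`, `diagnostics`,
#'   `evaluations`, `tree`, `monophyly`, `paths`).
#' @export
run_full_pipeline <- function(input, out_dir,
                              header_delim = "|",
                              params = align_params(),
                              fwd_primer = NULL, rev_primer = NULL,
                              max_mismatch = 0,
                              bootstrap_replicates = 1000,
                              seed = NULL,
                              methods = c("nearest_distance", "blast1")) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  records <- stage("read", {
    if (is.character(input)) read_fasta(input, delim = header_delim)
    else input
  })
  if (nrow(records) == 0) stop("no input records")

  if (!is.null(fwd_primer) && !is.null(rev_primer)) {
    records <- stage("trim",
                     trim_primers(records, fwd_primer, rev_primer,
                                  max_mismatch))
  }

  stats_df <- stage("region_stats", {
    ann <- if (all(nchar(records$sequence) >= 451)) {
      annotate_regions(records)
    } else NULL
    region_stats(records, ann)
  })
  paths$region_stats <- .write_tsv(
    stats_df, file.path(out_dir, "region_stats.tsv"),
    meta = "per-record, per-region length and GC content")

  notes <- character(0)
  if (nrow(records) < 2) {
    notes <- c(notes, "fewer than 2 records: alignment stages skipped")
    msa <- NULL; dm <- NULL
  } else {
    msa <- stage("align", progressive_msa(records, params))
    paths$alignment <- write_aligned_fasta(
      msa, file.path(out_dir, "aligned.fasta"), delim = header_delim)
    dm <- stage("distance", distance_matrix(msa))
    paths$distance_matrix <- .write_matrix_tsv(
      round(dm, 6), file.path(out_dir, "distance_matrix.tsv"),
      meta = "pairwise K2P distances (substitutions/site), pairwise deletion")
  }

  species_summary <- NULL; sites <- NULL; tally <- NULL
  haplotypes <- NULL; diagnostics <- NULL
  if (!is.null(msa)) {
    labels <- species_labels(msa)
    species_summary <- stage("summaries", species_summaries(dm, labels))
    paths$species_summary <- .write_tsv(
      species_summary, file.path(out_dir, "species_summary.tsv"),
      meta = "per-species intra/interspecific K2P distance summaries")
    sites <- stage("variation", classify_sites(msa))
    tally <- tally_substitutions(sites)
    paths$variable_sites <- .write_tsv(
      sites[sites$kind != "monomorphic", , drop = FALSE],
      file.path(out_dir, "variable_sites.tsv"),
      meta = c("variable alignment columns (1-based MSA coordinates)",
               paste0("substitution tally: ",
                      paste(names(tally), tally, sep = "=", collapse = ", "))))
    haplotypes <- collapse_haplotypes(msa)
    paths$haplotypes <- .write_tsv(
      haplotypes[, c("species", "haplotype", "n_members", "members")],
      file.path(out_dir, "haplotypes.tsv"),
      meta = "haplotypes per species (exact aligned-sequence identity)")
    if (length(unique(labels)) >= 2) {
      diagnostics <- stage("diagnostics", find_diagnostic_sites(msa))
      paths$diagnostic_sites <- .write_tsv(
        diagnostics, file.path(out_dir, "diagnostic_sites.tsv"),
        meta = "species-diagnostic sites (state private to the species)")
    }
  }

  evaluations <- list()
  if (!is.null(msa)) {
    for (m in methods) {
      ev <- stage(paste0("classify_", m),
                  leave_one_out_eval(records, method = m, msa = msa))
      evaluations[[m]] <- ev
      paths[[paste0("classification_", m)]] <- .write_tsv(
        ev$results, file.path(out_dir, paste0("classification_", m, ".tsv")),
        meta = sprintf("leave-one-out %s: %d/%d correct (%.1f%%)",
                       m, ev$n_correct, ev$n_queries, ev$success_rate))
    }
  }

  tree <- NULL; monophyly <- NULL
  if (!is.null(msa) && nrow(records) >= 4) {
    tree <- stage("tree", bootstrap_support(msa,
                                            replicates = bootstrap_replicates,
                                            seed = seed))
    paths$tree <- file.path(out_dir, "nj_tree.nwk")
    write_newick(tree, paths$tree)
    labels <- species_labels(msa)
    monophyly <- vapply(sort(unique(labels)), function(x) {
      is_monophyletic(tree$tree, labels, x)
    }, logical(1))
    paths$monophyly <- .write_tsv(
      data.frame(species = names(monophyly), monophyletic = monophyly,
                 row.names = NULL, stringsAsFactors = FALSE),
      file.path(out_dir, "monophyly.tsv"),
      meta = "per-species monophyly on the NJ tree")
  } else if (!is.null(msa)) {
    notes <- c(notes, "fewer than 4 records: tree stage skipped")
  }

  manifest <- data.frame(
    key = c("package_version", "n_records", "n_species", "seed",
            "bootstrap_replicates",
            "align_match", "align_mismatch", "align_gap_open",
            "align_gap_extend",
            paste0("artifact_", names(paths)),
            if (length(notes)) paste0("note_", seq_along(notes))),
    value = c(as.character(packageVersion("its2barcode")),
              nrow(records), length(unique(records$species)),
              if (is.null(seed)) "none" else seed,
              bootstrap_replicates,
              params$match, params$mismatch, params$gap_open,
              params$gap_extend,
              basename(unlist(paths)),
              notes),
    stringsAsFactors = FALSE
  )
  paths$manifest <- .write_tsv(manifest, file.path(out_dir, "manifest.tsv"),
                               meta = "pipeline run manifest")

  invisible(list(records = records, msa = msa, dm = dm,
                 species_summary = species_summary, sites = sites,
                 tally = tally, haplotypes = haplotypes,
                 diagnostics = diagnostics, evaluations = evaluations,
                 tree = tree, monophyly = monophyly, paths = paths))
}
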