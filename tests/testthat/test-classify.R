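test_that("nearest-distance assignment picks the closest species", {
  dm <- matrix(c(0, 0, 0.05, 0.06,
                 0, 0, 0.05, 0.06,
                 0.05, 0.05, 0, 0.02,
                 0.06, 0.06, 0.02, 0), 4, 4,
               dimnames = list(c("x1", "x2", "y1", "z1"),
                               c("x1", "x2", "y1", "z1")))
  labels <- c(x1 = "X", x2 = "X", y1 = "Y", z1 = "Z")
  res <- nearest_distance_assign("x1", dm, labels)
  expect_equal(res$predicted, "X")
  expect_equal(res$margin, 0.05) # distance to nearest non-X minus 0
})

test_that("ties across species are ambiguous; ties within are not", {
  dm <- matrix(0.1, 3, 3); diag(dm) <- 0
  dimnames(dm) <- list(c("q", "y1", "z1"), c("q", "y1", "z1"))
  labels <- c(q = "X", y1 = "Y", z1 = "Z")
  res <- nearest_distance_assign("q", dm, labels)
  expect_equal(res$predicted, "AMBIGUOUS")

  labels2 <- c(q = "X", y1 = "Y", z1 = "Y") # same species: tie resolves
  res2 <- nearest_distance_assign("q", dm, labels2)
  expect_equal(res2$predicted, "Y")
})

test_that("blast1 assignment returns the top local-alignment hit", {
  refs <- barcode_records(
    c("r1", "r2", "r3"),
    c("X", "Y", "Y"),
    c("ACGTACGTACGTACGT", "ACGTACGTACGTTTTT", "ACGTACGTACGTTTTA")
  )
  q <- barcode_records("q", "X", "ACGTACGTACGTACGT", "sampled")
  res <- blast1_assign(q, refs)
  expect_equal(res$predicted, "X")
  expect_gt(res$margin, 0)

  # query equidistant from two references of one species -> that species
  q2 <- barcode_records("q2", "Y", "ACGTACGTACGTTTTC", "sampled")
  res2 <- blast1_assign(q2, refs[refs$sample_id != "r1", ])
  expect_equal(res2$predicted, "Y")
  expect_error(blast1_assign(q, refs[0, ]), "empty")
})

test_that("blast1 ranking matches negated Hamming distance on gapless refs", {
  set.seed(31)
  q_seq <- random_dna(60)
  refs_seq <- vapply(1:6, function(i) {
    s <- strsplit(q_seq, "")[[1]]
    pos <- sample(60, i) # i substitutions
    for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
    paste(s, collapse = "")
  }, character(1))
  refs <- barcode_records(paste0("r", 1:6), paste0("S", 1:6), refs_seq)
  p <- blast1_params()
  scores <- vapply(refs_seq, function(r) {
    its2barcode:::sw_score_cpp(q_seq, r, p$match, p$mismatch,
                               p$gap_open, p$gap_extend)
  }, numeric(1))
  hamming <- vapply(refs_seq, function(r) {
    sum(strsplit(q_seq, "")[[1]] != strsplit(r, "")[[1]])
  }, numeric(1))
  expect_equal(order(scores, decreasing = TRUE), order(hamming))
})

test_that("local alignment scores agree with an independent implementation", {
  skip_if_not_installed("Biostrings")
  set.seed(17)
  p <- blast1_params()
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  for (i in 1:10) {
    a <- random_dna(sample(20:60, 1))
    b <- random_dna(sample(20:60, 1))
    ours <- its2barcode:::sw_score_cpp(a, b, p$match, p$mismatch,
                                       p$gap_open, p$gap_extend)
    ref <- Biostrings::pairwiseAlignment(
      a, b, type = "local", substitutionMatrix = mat,
      gapOpening = 3, gapExtension = 2)@score
    expect_equal(ours, ref, info = paste(a, b))
  }
})

test_that("assignment is invariant to reference ordering", {
  sim <- simulate_dataset(simulation_config(
    n_species = 4, samples_per_species = rep(3, 4), seed = 19))
  recs <- sim$records
  msa <- progressive_msa(recs)
  dm <- distance_matrix(msa)
  labels <- species_labels(recs)
  q <- recs$sample_id[1]
  base <- nearest_distance_assign(q, dm, labels)
  ids <- sample(rownames(dm))
  expect_equal(nearest_distance_assign(q, dm[ids, ids], labels), base)
})

test_that("leave-one-out on trivially separable data is perfect", {
  recs <- barcode_records(paste0("s", 1:3), "OnlySpecies",
                          rep(paste(rep("ACGT", 10), collapse = ""), 3))
  ev <- leave_one_out_eval(recs, "nearest_distance")
  expect_equal(ev$success_rate, 100)
  expect_equal(ev$n_queries, 3)
})

test_that("cross-species identical samples cannot be identified", {
  seqs <- rep(paste(rep("ACGT", 10), collapse = ""), 4)
  recs <- barcode_records(paste0("s", 1:4), rep(c("X", "Y"), 2), seqs)
  ev <- leave_one_out_eval(recs, "nearest_distance")
  expect_equal(ev$success_rate, 0)
  expect_true(all(ev$results$predicted == "AMBIGUOUS"))
})

test_that("a strict barcoding gap guarantees 100% nearest-distance success", {
  for (seed in c(5, 23, 77)) {
    sim <- simulate_dataset(simulation_config(
      n_species = 6, samples_per_species = rep(2, 6), seed = seed))
    msa <- progressive_msa(sim$records)
    dm <- distance_matrix(msa)
    labels <- species_labels(msa)
    ss <- species_summaries(dm, labels)
    # generator guarantees intra = 0 < min inter
    expect_true(all(ss$inter_min > max(ss$intra_max)))
    ev <- leave_one_out_eval(sim$records, "nearest_distance", msa = msa)
    expect_equal(ev$success_rate, 100)
  }
})

test_that("singleton species fail when included and are listed when excluded", {
  sim <- simulate_dataset(simulation_config(
    n_species = 3, samples_per_species = c(3, 3, 1), seed = 10))
  ev_inc <- leave_one_out_eval(sim$records, "nearest_distance")
  singleton <- ev_inc$results[ev_inc$results$true_species == "Species_03", ]
  expect_false(singleton$predicted == "Species_03")
  expect_lt(ev_inc$success_rate, 100)

  ev_exc <- leave_one_out_eval(sim$records, "nearest_distance",
                               include_singletons = FALSE)
  expect_equal(ev_exc$excluded, singleton$query_id)
  expect_equal(ev_exc$success_rate, 100)
})

test_that("both identification methods concur on well-separated data", {
  sim <- simulate_dataset(simulation_config(
    n_species = 5, samples_per_species = rep(3, 5), seed = 26))
  ev_n <- leave_one_out_eval(sim$records, "nearest_distance")
  ev_b <- leave_one_out_eval(sim$records, "blast1")
  expect_equal(ev_b$results$predicted, ev_n$results$predicted)
  expect_equal(ev_n$success_rate, 100)
  expect_equal(ev_b$success_rate, 100)
})
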