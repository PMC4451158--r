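test_that("site-pattern counting applies pairwise deletion and ts/tv split", {
  expect_equal(count_site_patterns("ACGT", "ACGT")[c("n", "s", "v")],
               list(n = 4L, s = 0L, v = 0L))
  expect_equal(count_site_patterns("AAAA", "GAAA")[c("n", "s", "v")],
               list(n = 4L, s = 1L, v = 0L)) # A<->G is a transition
  expect_equal(count_site_patterns("AC-T", "ACGT")[c("n", "s", "v")],
               list(n = 3L, s = 0L, v = 0L)) # gap column dropped
  expect_equal(count_site_patterns("ANGT", "AAGA")[c("n", "s", "v")],
               list(n = 3L, s = 0L, v = 1L)) # ambiguity column dropped
  expect_error(count_site_patterns("--", "AC"), "no comparable")
})

test_that("K2P distance matches its closed form and flags saturation", {
  expect_equal(k2p_distance(0, 0), 0)
  expect_equal(k2p_distance(0.1, 0), -0.5 * log(0.8), tolerance = 1e-12)
  expect_error(k2p_distance(0.3, 0.4), class = "its2barcode_saturated")
  expect_error(k2p_distance(0, 0.5), class = "its2barcode_saturated")
  # accepts the counts list directly
  cnt <- count_site_patterns("AAAA", "GAAA")
  expect_equal(k2p_distance(cnt), -0.5 * log(1 - 0.5) - 0.25 * log(1))
})

test_that("K2P distance dominates the p-distance", {
  set.seed(2)
  for (i in 1:200) {
    Q <- runif(1, 0, 0.45)
    P <- runif(1, 0, (1 - Q) / 2 - 0.01)
    expect_gte(k2p_distance(P, Q), P + Q)
  }
  expect_equal(k2p_distance(0, 0), 0)
})

test_that("distance matrix equals per-pair closed-form values", {
  msa <- as_msa(
    c(a = "AAAAAAAAAA", b = "GAAAAAAAAA", c = "GCAAAAAAAA"),
    c(a = "X", b = "Y", c = "Z")
  )
  dm <- distance_matrix(msa)
  expect_equal(dm["a", "a"], 0)
  expect_equal(dm, t(dm))
  expect_equal(dm["a", "b"], k2p_distance(0.1, 0))     # one transition
  expect_equal(dm["a", "c"], k2p_distance(0.1, 0.1))   # + one transversion
  expect_equal(dm["b", "c"], k2p_distance(0, 0.1))
})

test_that("identical rows are at distance zero", {
  msa <- as_msa(c(a = "ACGTAC", b = "ACGTAC"), c(a = "X", b = "X"))
  expect_equal(unname(distance_matrix(msa)), matrix(0, 2, 2))
})

test_that("distance matrix is invariant to row permutation", {
  sim <- simulate_dataset(simulation_config(
    n_species = 5, samples_per_species = rep(2, 5), seed = 8))
  msa <- progressive_msa(sim$records)
  dm <- distance_matrix(msa)
  ids <- sample(rownames(dm))
  msa_perm <- as_msa(msa_strings(msa)[ids], msa$species)
  expect_equal(distance_matrix(msa_perm), dm[ids, ids])
})

test_that("saturated pairs error by default and can be flagged as Inf", {
  msa <- as_msa(c(a = "ACACACAC", b = "CACACACA"), c(a = "X", b = "Y"))
  expect_error(distance_matrix(msa), class = "its2barcode_saturated")
  dm <- distance_matrix(msa, on_saturation = "inf")
  expect_equal(dm["a", "b"], Inf)
})

test_that("species summaries reproduce brute-force pair statistics", {
  # two singletons at a known distance
  msa2 <- as_msa(c(a = "AAAAAAAAAA", b = "GAAAAAAAAA"), c(a = "X", b = "Y"))
  ss2 <- species_summaries(distance_matrix(msa2), c(a = "X", b = "Y"))
  d <- k2p_distance(0.1, 0)
  expect_equal(ss2$inter_min, c(d, d))
  expect_equal(ss2$inter_mean, c(d, d))
  expect_true(all(is.na(ss2$intra_mean))) # singletons: intra empty, not zero

  # synthetic multi-species set vs. brute-force enumeration over all pairs
  sim <- simulate_dataset(simulation_config(
    n_species = 3, samples_per_species = c(3, 2, 4), seed = 15))
  msa <- progressive_msa(sim$records)
  dm <- distance_matrix(msa)
  labels <- species_labels(msa)
  ss <- species_summaries(dm, labels)
  for (x in unique(labels)) {
    ids_in <- names(labels)[labels == x]
    ids_out <- setdiff(names(labels), ids_in)
    intra <- combn(ids_in, 2, function(p) dm[p[1], p[2]])
    inter <- as.vector(outer(ids_in, ids_out,
                             Vectorize(function(i, j) dm[i, j])))
    row <- ss[ss$species == x, ]
    expect_equal(row$intra_mean, mean(intra))
    expect_equal(c(row$inter_min, row$inter_max, row$inter_mean),
                 c(min(inter), max(inter), mean(inter)))
    expect_true(row$intra_min <= row$intra_mean &&
                  row$intra_mean <= row$intra_max)
  }
})

test_that("species sharing one haplotype have intraspecific distance zero", {
  sim <- simulate_dataset(simulation_config(seed = 4))
  msa <- progressive_msa(sim$records)
  ss <- species_summaries(distance_matrix(msa), species_labels(msa))
  multi <- ss[ss$n_samples >= 2, ]
  expect_equal(multi$intra_min, rep(0, nrow(multi)))
  expect_equal(multi$intra_max, rep(0, nrow(multi)))
  expect_equal(multi$intra_mean, rep(0, nrow(multi)))
})
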