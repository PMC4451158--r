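test_that("FASTA round-trip preserves records, labels and order", {
  recs <- barcode_records(
    sample_id = c("S1", "S2", "S3"),
    species = c("Ferula_sinkiangensis", "Ferula_fukangensis",
                "Ferula_sinkiangensis"),
    sequence = c("ACGTACGT", "acgtt", "NNACGT")
  )
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, f)
  back <- read_fasta(f)
  expect_equal(back$sample_id, recs$sample_id)
  expect_equal(back$species, recs$species)
  expect_equal(back$sequence, recs$sequence) # already uppercased on input
})

test_that("single-entry and empty FASTA files parse as expected", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">S1|Ferula_sinkiangensis", "ACGT"), f)
  one <- read_fasta(f)
  expect_equal(nrow(one), 1)
  expect_equal(one$sample_id, "S1")
  expect_equal(one$species, "Ferula_sinkiangensis")
  expect_equal(one$sequence, "ACGT")

  empty <- withr::local_tempfile(fileext = ".fasta")
  file.create(empty)
  expect_equal(nrow(read_fasta(empty)), 0)
})

test_that("header and record validation fails loudly", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">no_delimiter_here", "ACGT"), f)
  expect_error(read_fasta(f), "parseable")
  expect_error(barcode_records(c("a", "a"), c("x", "y"), c("AC", "GT")),
               "duplicate")
  expect_error(barcode_records("a", "x", "ACGZ"), "alphabet")
})

test_that("primer trimming excises the insert between both primers", {
  fwd <- "ATTCACACCAAGTATCGCAT"
  rev <- "ATTGTAGTCTGGAGAAGCGTC"
  amplicon <- paste0(fwd, "GGGG", revcomp(rev))
  recs <- barcode_records("q1", "X_y", amplicon)
  out <- trim_primers(recs, fwd, rev, max_mismatch = 0)
  expect_equal(out$sequence, "GGGG")
  expect_equal(unname(attr(out, "rev_primer_interpretation")), "revcomp")
})

test_that("primer trimming tolerates mismatches up to the budget", {
  fwd <- "ATTCACACCAAGTATCGCAT"
  rev <- "ATTGTAGTCTGGAGAAGCGTC"
  fwd_mut <- paste0("ATTCACACCAAGTATCGCA", "A") # 1 substitution at the end
  amplicon <- paste0("TT", fwd_mut, "GGGG", revcomp(rev), "AA")
  recs <- barcode_records("q1", "X_y", amplicon)
  expect_error(trim_primers(recs, fwd, rev, max_mismatch = 0), "forward")
  out <- trim_primers(recs, fwd, rev, max_mismatch = 1)
  expect_equal(out$sequence, "GGGG")
  # oracle: sliding-window Hamming search finds the same forward location
  o <- brute_force_primer_pos(amplicon, fwd)
  expect_equal(o$mismatches, 1)
  expect_equal(substr(amplicon, o$start + nchar(fwd), o$start + nchar(fwd) + 3),
               "GGGG")
})

test_that("missing reverse primer and bad geometry raise typed errors", {
  fwd <- "ATTCACACCAAGTATCGCAT"
  rev <- "ATTGTAGTCTGGAGAAGCGTC"
  no_rev <- barcode_records("q1", "X_y", paste0(fwd, "GGGGGGGG"))
  expect_error(trim_primers(no_rev, fwd, rev), "reverse")
})

test_that("fixed-flank annotation reproduces the 84/141 flank rule", {
  lens <- c(451, 453, 455)
  recs <- barcode_records(paste0("s", lens), "X_y",
                          vapply(lens, random_dna, character(1)))
  ann <- annotate_regions(recs)
  expect_equal(ann$p58s_end - ann$p58s_start, rep(84L, 3))
  expect_equal(ann$p28s_end - ann$p28s_start, rep(141L, 3))
  expect_equal(ann$its2_end - ann$its2_start, lens - 225L)
  # intervals partition [1, full_len]
  expect_equal(ann$p58s_end, ann$its2_start)
  expect_equal(ann$its2_end, ann$p28s_start)
  expect_equal(ann$p28s_end, ann$full_len + 1L)

  short <- barcode_records("s450", "X_y", random_dna(450))
  expect_error(annotate_regions(short), "shorter")
})

test_that("trim + annotate recovers a planted ITS2 core exactly", {
  fwd <- "ATTCACACCAAGTATCGCAT"
  rev <- "ATTGTAGTCTGGAGAAGCGTC"
  set.seed(11)
  flank58 <- random_dna(84)
  core <- random_dna(228)
  flank28 <- random_dna(141)
  amplicon <- paste0(fwd, flank58, core, flank28, revcomp(rev))
  recs <- trim_primers(barcode_records("p1", "X_y", amplicon), fwd, rev)
  ann <- annotate_regions(recs)
  expect_equal(substr(recs$sequence, ann$its2_start, ann$its2_end - 1), core)
})

test_that("GC content excludes ambiguity codes and gaps", {
  expect_equal(gc_percent("GGCC"), 100)
  expect_equal(gc_percent("ATAT"), 0)
  expect_equal(gc_percent("ATGC"), 50)
  expect_equal(gc_percent("ATGCNNNRY--"), 50)
  expect_error(gc_percent("NNN"), "undefined")
})

test_that("GC of the AT<->GC relabelled sequence is the complement of GC", {
  set.seed(5)
  for (i in 1:20) {
    s <- random_dna(sample(10:200, 1))
    relabelled <- chartr("AGTC", "GACT", s) # A<->G, T<->C relabelling
    expect_equal(gc_percent(relabelled), 100 - gc_percent(s))
  }
})

test_that("region stats report length and GC per region", {
  recs <- barcode_records("r1", "X_y", random_dna(455))
  ann <- annotate_regions(recs)
  st <- region_stats(recs, ann)
  expect_setequal(st$region, c("full", "p58s", "its2", "p28s"))
  expect_equal(st$length_bp[st$region == "full"], 455)
  expect_equal(st$length_bp[st$region == "p58s"], 84)
  expect_equal(st$length_bp[st$region == "its2"], 230)
  expect_equal(st$length_bp[st$region == "p28s"], 141)
  expect_true(all(st$gc_percent >= 0 & st$gc_percent <= 100))
})
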