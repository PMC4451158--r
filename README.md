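# its2barcode

DNA-barcode species identification with the nuclear ribosomal **ITS2**
region, built for the common design of medicinal-plant authentication
studies: a reference collection of a few dozen Sanger-sequenced amplicons
covering ~10 closely related species (genuine drugs plus their substitutes
and adulterants), where morphology fails but a short barcode separates the
species cleanly.

The package implements the whole desk-side analysis as composable,
deterministic functions:

* **Amplicons** — labelled FASTA I/O, universal-primer trimming
  (minimum-Hamming windows, both readings of a 3'–5' reverse primer),
  fixed-flank annotation of partial 5.8S (84 bp) / ITS2 core / partial 28S
  (141 bp), per-region length and GC reports.
* **Alignment** — exact affine-gap Needleman–Wunsch and a progressive
  multiple aligner (identical sequences collapsed first, K2P/NJ guide tree,
  "once a gap, always a gap" profile merges), bit-reproducible tracebacks.
* **Distances** — Kimura 2-parameter distances under pairwise deletion,

  ```
  d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)
  ```

  with typed saturation errors, full distance matrices, and per-species
  intra/interspecific min–max (mean) summaries.
* **Variation** — disjoint column classification (substitution / indel /
  monomorphic, so counts add up), substitution tallies by unordered state
  set (`C/T`, `A/C/G`, ...), haplotype collapsing, and detection of
  species-diagnostic sites (a state fixed in one species and absent from
  all others).
* **Identification** — nearest-genetic-distance and BLAST1-style
  (Smith–Waterman top hit) classifiers with leave-one-out evaluation;
  ambiguous assignments count as failures.
* **Trees** — neighbor joining with negative-branch clamping, Felsenstein
  column bootstrap with seeded determinism, exact unrooted monophyly tests,
  Newick I/O.
* **Simulation** — a fully seeded generator of species-structured haplotype
  datasets (coalescent species tree, transition-biased substitutions, short
  indels, planted diagnostic sites, zero intraspecific variation) with an
  event log that replays byte-for-byte — the ground truth that makes every
  stage testable.

`run_full_pipeline()` chains everything and writes a TSV/FASTA/Newick
artifact bundle with a manifest; `inst/cli/its2barcode.R` exposes the same
stages as shell subcommands.

## Worked example

Simulate the default 10-species / 74-sample study design and run the
analysis:

```r
library(its2barcode)

sim <- simulate_dataset(simulation_config(seed = 7))
msa <- progressive_msa(sim$records)
msa
#> dna_msa: 74 sequences x 458 columns, 10 species

dm <- distance_matrix(msa)
ss <- species_summaries(dm, species_labels(msa))
head(ss[, c("species", "n_samples", "intra_mean", "inter_min", "inter_mean")], 4)
#>      species n_samples intra_mean inter_min inter_mean
#> 1 Species_01        13          0   0.00670     0.0481
#> 2 Species_02         6          0   0.00662     0.0290
#> 3 Species_03        14          0   0.00662     0.0340
#> 4 Species_04         6          0   0.00884     0.0314
```

Every species carries a single haplotype (`intra_mean` is exactly 0), while
interspecific K2P distances centre near 0.03 — the barcoding-gap regime.
Variable sites and their substitution spectrum:

```r
sites <- classify_sites(msa)
sum(sites$kind != "monomorphic")
#> [1] 50                         # 42 substitution + 8 indel columns
tally_substitutions(sites)
#> A/C A/G A/T C/G C/T G/T
#>   5  13   3   5   9   7

head(find_diagnostic_sites(msa), 3)
#>      species site state background
#> 1 Species_01    1     G          A
#> 2 Species_10   25     T          A
#> 3 Species_04   44     C          -
```

Each diagnostic row is a single character that authenticates its species
against all others. Identification and the NJ tree:

```r
leave_one_out_eval(sim$records, "nearest_distance", msa = msa)
#> Leave-one-out evaluation (nearest_distance)
#>   queries: 74, correct: 74, success rate: 100.0%

bst <- bootstrap_support(msa, replicates = 100, seed = 7)
bst
#> NJ tree with bootstrap supports (100 valid replicates)
#>   internal branches with support >= 50%: 57/71
all(vapply(unique(species_labels(msa)),
           function(x) is_monophyletic(bst$tree, species_labels(msa), x),
           logical(1)))
#> [1] TRUE
```

All ten species are monophyletic; with zero intraspecific variation the
100% leave-one-out success is the provable consequence of the strict
barcoding gap. Species separated by only a handful of sites draw
intermediate bootstrap supports, as expected for the column bootstrap at
barcode-scale divergence; the deep splits are recovered at ~100%.

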