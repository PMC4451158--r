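---
title: "Methods: ITS2 barcode identification with its2barcode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ITS2 barcode identification with its2barcode}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

DNA barcoding assigns an unknown specimen to a species by comparing a short,
standardized DNA region against a labelled reference collection. For
medicinal plants, the nuclear ribosomal ITS2 region (the spacer between the
5.8S and 28S rRNA genes) is a widely used barcode: it amplifies reliably
with universal primers, is short enough for routine Sanger sequencing, and
in many genera shows large between-species divergence against negligible
within-species variation — the "barcoding gap" that makes distance-based
identification reliable.

`its2barcode` implements the complete desk side of such a study: amplicon
trimming and sub-region annotation, multiple alignment, Kimura 2-parameter
(K2P) distances with per-species summaries, variable- and diagnostic-site
detection, two classifiers (nearest genetic distance and a BLAST1-style
local-alignment top hit) evaluated by leave-one-out, and neighbor-joining
(NJ) trees with column-bootstrap supports. A seeded simulator generates
species-structured datasets with full ground truth so that every stage is
testable end to end.

```{r setup}
library(its2barcode)
```

# Region annotation

Trimmed ITS2 amplicons of this primer design carry a constant-length partial
5.8S (84 bp) at the 5' end and a constant-length partial 28S (141 bp) at the
3' end, with the 226–230 bp ITS2 core between them. Because the flanks are
rRNA gene fragments they are essentially invariant in length across closely
related species, so `annotate_regions()` uses a fixed-flank rule: first 84
bases, last 141 bases, remainder ITS2. Profile-HMM annotation against an
ITS2 reference database would generalize to other marker designs; the
function is the interface point where such a backend could be swapped in,
and the rule refuses amplicons shorter than 451 bp rather than guessing.

Primer trimming (`trim_primers()`) is a minimum-Hamming sliding window (no
indels inside a 20-mer primer), leftmost tie-break for the forward primer and
rightmost for the reverse. Reverse primers are conventionally printed 3'–5',
which leaves two defensible readings of their sense-strand site — the
reverse complement of the printed string, or its in-place complement. Both
are searched; the better match wins and the choice is recorded per record.
GC content excludes IUPAC ambiguity codes from numerator and denominator, so
an ambiguous base call never moves the statistic.

# Alignment

Pairwise alignment is exact affine-gap Needleman–Wunsch. The gap convention
throughout the package is that a run of $k$ gap characters costs
$g_{open} + (k-1)\,g_{ext}$; traceback ties are broken diagonal, then up,
then left, so alignments are bit-reproducible. Defaults
(match 1, mismatch −1, open −4, extend −1) are deliberately conservative
about opening gaps, which suits near-identical barcode amplicons where most
length variation is a single short indel.

The multiple alignment is progressive: sequences identical at the string
level are grouped first (they co-align trivially, and in barcode data most
samples are exact duplicates of their species haplotype, so this collapses a
74-row problem to a 10-profile one), a guide tree is built by NJ on pairwise
K2P distances between the distinct sequences (p-distance fallback at
saturation; distinct sequences are processed in lexicographic sample-id
order so that equal guide distances resolve reproducibly), and profiles are
merged bottom-up under "once a gap, always a gap". Profile columns score as
the mean pairwise match/mismatch, residues against existing gaps score 0,
and new gap columns pay the affine penalties unscaled. Iterative refinement
is out of scope: on barcode-grade data (few, short indels between
near-identical haplotypes) progressive alignment already places gaps
consistently.

All downstream site numbers are 1-based columns of this alignment. Exact
reproduction of site coordinates quoted from other toolchains depends on
their aligner's gap placement, so coordinates should always be interpreted
against the alignment shipped alongside them.

# Distances

K2P distance is computed per pair under pairwise deletion: any column with a
gap or ambiguity code in either row of the pair is excluded for that pair
only, which keeps the compared-site count maximal and matches the default of
the standard barcoding toolchains. With $P$ and $Q$ the transition and
transversion proportions among compared sites,

$$d = -\tfrac{1}{2}\ln(1 - 2P - Q) - \tfrac{1}{4}\ln(1 - 2Q).$$

Indels contribute nothing to $d$ (K2P is a substitution model); indel
variation is surfaced by the site-classification functions instead. At or
beyond the saturation boundary ($1-2P-Q \le 0$ or $1-2Q \le 0$) the package
raises a typed error by default — degenerate barcodes should fail loudly —
with an opt-in `Inf` flag for exploratory use. Per-species summaries
(`species_summaries()`) take unweighted means over sample pairs, intra- over
unordered within-species pairs (reported empty, not zero, for singleton
species) and inter- over all pairs crossing the species boundary.

# Variable and diagnostic sites

Columns are classified disjointly: any gap makes a column an `indel` site
even if its bases also vary, otherwise two or more states make it a
`substitution` site. This disjointness is what lets substitution and indel
counts add up to the variable-site total. Each gap column counts as one
indel site (an event-based merge of multi-column gaps is a possible
alternative; with 1–4 bp indels the two conventions differ little, and the
per-column rule keeps the arithmetic transparent). Substitution columns are
tallied by their unordered state set (`C/T`, `A/C/G`, ...), so two-state and
three-state buckets coexist.

A (species, site) pair is *diagnostic* when every sample of the species
shares one symbol at the site (a gap may be that symbol) and no sample of
any other species carries it. This strict character-based rule is what makes
a single fixed transition sufficient to authenticate a species; a site can
diagnose several species at once (each with its own private state), so
diagnostic records are reported per species-site pair.

# Classification

*Nearest distance*: the query takes the species of its minimum-K2P
reference; ties across species yield `AMBIGUOUS`, which is always counted
as a failure — "correctly identified" should mean exactly that. The margin
is the distance to the nearest other species minus the distance to the
predicted one. Under pairwise deletion, removing a row changes no other
pairwise distance, so leave-one-out reuses one alignment and one distance
matrix across all folds.

*BLAST1 style*: the species of the top-scoring local alignment
(Smith–Waterman, match 2, mismatch −3, open −5, extend −2, approximating
megablast-like scoring). Reference sets in barcoding studies are tiny, so
exact local alignment replaces heuristic seeding while keeping the
top-hit semantics; E-values and database indexing are out of scope.

Singleton species are evaluated (and necessarily fail) by default; a config
switch excludes them and lists the exclusions, but a reference set in which
every species has at least two samples never exercises the choice.

# Trees and supports

`neighbor_joining()` delegates to the standard Saitou–Nei implementation in
`ape`, then clamps negative branch lengths to zero (recording the clamped
deficit); NJ output is unrooted, and any rooting for display is cosmetic
since no outgroup is designated. `bootstrap_support()` resamples alignment
columns with replacement (the Felsenstein bootstrap), rebuilds K2P + NJ per
replicate, and scores each reference bipartition by its recovery percentage;
replicates that saturate are dropped and counted. Supports are attached as
node labels, with a display threshold (default 50%) carried alongside.
Monophyly of a species is an exact bipartition test on the unrooted tree:
some branch must separate exactly that species' leaves from all others.

# The simulator

`simulate_dataset()` emulates the structure of a multi-species barcoding
study, with defaults fixed to a 10-species design: 74 samples split
13/6/14/6/11/5/10/4/3/2, a 453 bp ancestral amplicon at 55% GC, a
coalescent-shaped species tree, transition-biased substitutions
($\kappa = 4$, matching the C/T-heavy tallies typical of ITS2), at most one
1–4 bp indel per branch (probability 0.3, reproducing a ±few-bp length
spread), one planted private diagnostic substitution per species, and — the
key empirical feature being emulated — exactly one haplotype per species,
so intraspecific distances are identically zero. A
`within_species_mutations` knob exists purely to break the barcoding gap in
failure-mode tests.

Calibration: branch lengths are rescaled so the expected tip-to-tip path
length equals the target interspecific mean (default 0.03 substitutions/
site) *minus* the planted-diagnostic contribution (each cross-species pair
differs at the two species' planted sites, adding
$2k/L \approx 0.0044$ to its distance); without that correction the
realized mean would sit systematically above target. Substitutions are
simulated by per-branch Poisson event counts with jump-chain base choice
(transition probability $\kappa/(\kappa+2)$), exact for a constant-rate
model at these divergences. Every event is logged with its coordinates and
payload, and `replay_ground_truth()` re-derives all haplotypes from the log
with no random draws — byte-for-byte agreement is asserted in the tests.

What the simulator does *not* emulate: within-species polymorphism and
heterozygous (ambiguity-coded) positions, NUMT/pseudogene contamination,
alignment-hostile repeat regions, rate heterogeneity across sites, and
sequencing error. Passing tests on synthetic data therefore demonstrate the
correctness of the computations and the internal consistency of the
pipeline under a clean barcoding-gap regime, not robustness to those
real-data pathologies.

`make_worked_alignment()` complements the simulator with a fixed 10 × 40
fixture whose every downstream count (8 variable sites = 6 substitution +
2 indel; `C/T` ×3, `A/G`, `A/C`, `A/C/T`; exactly 2 diagnostic characters)
is verifiable by eye; its construction notes are in the function
documentation.

# Numerical and design choices

* Coordinates are 1-based; intervals are half-open `[start, end)`.
* Guide-tree and NJ tie-breaking: distinct sequences enter the guide build
  in lexicographic id order; the NJ step itself uses `ape`'s deterministic
  (implementation-defined) tie handling rather than an explicit
  lexicographic pair rule — on continuous distance matrices exact Q-ties are
  measure-zero, and determinism is what the reproducibility contract needs.
* Ambiguity codes: identical symbols score as matches in pairwise
  alignment, anything non-identical as mismatch; in profile merges all
  ambiguity codes share a residue class that scores mismatch against
  everything. Distance and site-pattern counting exclude them pairwise;
  site classification treats them as distinct, flagged states.
* Saturation is an error by default everywhere, with explicit opt-outs
  (`on_saturation = "inf"`, dropped-and-counted bootstrap replicates).
* Bootstrap in examples and tests uses 100 replicates (1000 is the
  default for production runs); the packaged test suite runs the full
  74-sample study at 100 replicates, where the deep central bipartition of
  the default design is recovered at ≥90% support. Shallow sister species
  separated by only ~3 alignment sites cannot exceed roughly
  $100(1-e^{-3}) \approx 95$ and often sit in the 60–90 range — an
  inherent property of the column bootstrap at barcode-scale divergence,
  not an implementation artifact.
* Problem sizes in the tests (74 × ~460 alignments, 100-replicate
  bootstraps, 50-seed calibration runs) were chosen as the smallest sizes at
  which the statistical assertions are stable.

# Known limitations

* Fixed-flank annotation is specific to this amplicon design; other primer
  pairs need their own flank lengths (both are arguments).
* The progressive MSA has no refinement pass; for data with long or
  overlapping indels a dedicated aligner should replace it behind the same
  `dna_msa` interface.
* BLAST1 here means "top local-alignment hit": no E-values, no heuristic
  acceleration, no composition-based statistics.
* NJ/bootstrap only; likelihood and Bayesian trees are out of scope.
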