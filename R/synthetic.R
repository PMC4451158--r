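#' Configuration for the species-structured barcode simulator
#'
#' Defaults emulate a 10-species barcoding study: 74 samples split
#' 13/6/14/6/11/5/10/4/3/2 across species, one shared haplotype per species
#' (zero intraspecific variation), a 453 bp ancestral amplicon at 55% GC,
#' transition-biased substitutions (kappa = 4), occasional short indels
#' (1-4 bp) between species, an interspecific K2P mean around 0.03, and one
#' planted private diagnostic substitution per species.
#'
#' @param n_species number of species.
#' @param samples_per_species integer vector of per-species sample counts;
#'   default is the 10-species design above, or draws from 2..14 for other
#'   `n_species`.
#' @param root_length ancestral sequence length (bp).
#' @param target_inter_mean target mean interspecific K2P distance
#'   (substitutions/site), in (0, 0.3).
#' @param kappa transition/transversion rate ratio.
#' @param gc_target stationary GC proportion of the ancestral sequence.
#' @param indel_prob_per_branch probability of one indel event per branch.
#' @param indel_len_range integer range of indel lengths, `c(min, max)`.
#' @param diagnostics_per_species private diagnostic substitutions planted
#'   per species.
#' @param within_species_mutations extra substitutions applied independently
#'   to each sample (default 0: every sample is an exact copy of its species
#'   haplotype). A non-zero value breaks the barcoding gap on purpose.
#' @param seed master seed; all stochastic draws flow from it.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_species = 10,
                              samples_per_species = NULL,
                              root_length = 453,
                              target_inter_mean = 0.03,
                              kappa = 4,
                              gc_target = 0.55,
                              indel_prob_per_branch = 0.3,
                              indel_len_range = c(1, 4),
                              diagnostics_per_species = 1,
                              within_species_mutations = 0,
                              seed = 1) {
  stopifnot(n_species >= 2, root_length > 0,
            target_inter_mean > 0, target_inter_mean < 0.3,
            kappa > 0, gc_target > 0, gc_target < 1,
            indel_prob_per_branch >= 0, indel_prob_per_branch <= 1,
            length(indel_len_range) == 2, indel_len_range[1] >= 1,
            indel_len_range[2] >= indel_len_range[1],
            diagnostics_per_species >= 0, within_species_mutations >= 0)
  if (!is.null(samples_per_species)) {
    stopifnot(length(samples_per_species) == n_species,
              all(samples_per_species >= 1))
  } else if (n_species == 10) {
    samples_per_species <- c(13, 6, 14, 6, 11, 5, 10, 4, 3, 2)
  }
  structure(list(
    n_species = n_species, samples_per_species = samples_per_species,
    root_length = root_length, target_inter_mean = target_inter_mean,
    kappa = kappa, gc_target = gc_target,
    indel_prob_per_branch = indel_prob_per_branch,
    indel_len_range = indel_len_range,
    diagnostics_per_species = diagnostics_per_species,
    within_species_mutations = within_species_mutations,
    seed = seed
  ), class = "simulation_config")
}

.random_dna <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# draw the target base of one substitution event under the K2P jump chain
.k2p_jump <- function(from, kappa) {
  transitions <- c(A = "G", G = "A", C = "T", T = "C")
  purine <- from %in% c("A", "G")
  transversions <- if (purine) c("C", "T") else c("A", "G")
  if (runif(1) < kappa / (kappa + 2)) transitions[[from]]
  else sample(transversions, 1)
}

# apply one logged event to a sequence string
.apply_event <- function(seq, ev) {
  switch(ev$type,
    sub = {
      stopifnot(substr(seq, ev$pos, ev$pos) == ev$from)
      substr(seq, ev$pos, ev$pos) <- ev$to
      seq
    },
    ins = paste0(substr(seq, 1, ev$pos), ev$detail,
                 substr(seq, ev$pos + 1, nchar(seq))),
    del = paste0(substr(seq, 1, ev$pos - 1),
                 substr(seq, ev$pos + nchar(ev$detail), nchar(seq))),
    stop("unknown event type: ", ev$type)
  )
}

#' Simulate a species-structured barcode dataset with full ground truth
#'
#' The generator (1) draws a random ancestral sequence at the target GC,
#' (2) draws a coalescent-shaped species tree and rescales its branch lengths
#' so that the expected pairwise tip-to-tip path length equals the target
#' interspecific divergence minus the contribution of the planted diagnostic
#' sites, (3) evolves the sequence down each branch under a continuous-time
#' K2P substitution process (per-branch Poisson event counts, jump-chain base
#' choice with transition bias `kappa`), (4) applies at most one short indel
#' per branch, (5) plants one private diagnostic substitution per species at
#' a column that is otherwise monomorphic across all tips, and (6) emits
#' every sample of a species as an exact copy of its species haplotype. All
#' draws are seeded; every event is logged so the output can be replayed
#' byte-for-byte with [replay_ground_truth()].
#'
#' @param cfg a [simulation_config()].
#' @return list with `records` (barcode record `data.frame`) and
#'   `ground_truth` (class `barcode_ground_truth`): `tree` (the scaled
#'   species tree, `ape::phylo`), `ancestral`, `events` (`data.frame`:
#'   `node`, `type`, `pos`, `from`, `to`, `detail`), `diagnostics`
#'   (`species`, `root_pos`, `tip_pos`, `state`), `haplotypes` (named by
#'   species), `cfg`.
#' @export
simulate_dataset <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  n_sp <- cfg$n_species
  species <- sprintf("Species_%02d", seq_len(n_sp))
  spp <- cfg$samples_per_species
  if (is.null(spp)) spp <- sample(2:14, n_sp, replace = TRUE)

  ancestral <- .random_dna(cfg$root_length, cfg$gc_target)

  tree <- ape::rcoal(n_sp, tip.label = species)
  planted_adj <- 2 * cfg$diagnostics_per_species / cfg$root_length
  target_path <- cfg$target_inter_mean - planted_adj
  if (target_path < 0) {
    stop("diagnostics_per_species too large for target_inter_mean")
  }
  cop <- cophenetic(tree)
  mean_path <- mean(cop[upper.tri(cop)])
  tree$edge.length <- tree$edge.length * (target_path / mean_path)

  # evolve down the tree; node states indexed by ape node number
  ntot <- n_sp + tree$Nnode
  node_seq <- vector("character", ntot)
  node_map <- vector("list", ntot) # root coordinate -> node coordinate (NA = deleted)
  root <- n_sp + 1
  node_seq[root] <- ancestral
  node_map[[root]] <- seq_len(cfg$root_length)
  events <- list()

  ord <- stats::reorder(tree, "cladewise") # preorder: parents before children
  for (e in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[e, 1]; child <- ord$edge[e, 2]
    t_len <- ord$edge.length[e]
    s <- node_seq[parent]
    pmap <- node_map[[parent]]
    L <- nchar(s)
    n_sub <- rpois(1, L * t_len)
    if (n_sub > 0) {
      pos <- sample.int(L, n_sub, replace = TRUE)
      for (p in pos) {
        from <- substr(s, p, p)
        to <- .k2p_jump(from, cfg$kappa)
        ev <- list(node = child, type = "sub", pos = p, from = from, to = to,
                   detail = "")
        s <- .apply_event(s, ev)
        events[[length(events) + 1]] <- ev
      }
    }
    if (runif(1) < cfg$indel_prob_per_branch) {
      len <- sample(seq(cfg$indel_len_range[1], cfg$indel_len_range[2]), 1)
      if (runif(1) < 0.5 && nchar(s) - len >= 1) { # deletion
        p <- sample.int(nchar(s) - len + 1, 1)
        ev <- list(node = child, type = "del", pos = p, from = "", to = "",
                   detail = substr(s, p, p + len - 1))
        s <- .apply_event(s, ev)
        dropped <- pmap >= p & pmap <= p + len - 1 & !is.na(pmap)
        shifted <- pmap > p + len - 1 & !is.na(pmap)
        pmap[dropped] <- NA_integer_
        pmap[shifted] <- pmap[shifted] - len
        events[[length(events) + 1]] <- ev
      } else { # insertion after position p (p = 0 allowed: prepend)
        p <- sample.int(nchar(s) + 1, 1) - 1
        ins <- .random_dna(len, cfg$gc_target)
        ev <- list(node = child, type = "ins", pos = p, from = "", to = "",
                   detail = ins)
        s <- .apply_event(s, ev)
        shifted <- pmap > p & !is.na(pmap)
        pmap[shifted] <- pmap[shifted] + len
        events[[length(events) + 1]] <- ev
      }
    }
    node_seq[child] <- s
    node_map[[child]] <- pmap
  }

  haplotypes <- setNames(node_seq[seq_len(n_sp)], tree$tip.label)[species]
  tip_map <- setNames(node_map[seq_len(n_sp)], tree$tip.label)[species]

  # plant private diagnostic substitutions at columns monomorphic across tips
  diagnostics <- data.frame(species = character(0), root_pos = integer(0),
                            tip_pos = integer(0), state = character(0),
                            stringsAsFactors = FALSE)
  k <- cfg$diagnostics_per_species
  if (k > 0) {
    present <- Reduce(`&`, lapply(tip_map, function(m) !is.na(m)))
    states <- vapply(species, function(sp) {
      m <- tip_map[[sp]]
      chars <- strsplit(haplotypes[[sp]], "", fixed = TRUE)[[1]]
      out <- rep(NA_character_, cfg$root_length)
      out[!is.na(m)] <- chars[m[!is.na(m)]]
      out
    }, character(cfg$root_length))
    mono <- present & apply(states, 1, function(r) length(unique(r)) == 1)
    cand <- which(mono)
    if (length(cand) < k * n_sp) {
      stop("not enough monomorphic columns to plant diagnostics")
    }
    picks <- sample(cand, k * n_sp)
    assign_sp <- rep(species, each = k)
    for (i in seq_along(picks)) {
      sp <- assign_sp[i]
      r <- picks[i]
      tp <- tip_map[[sp]][r]
      from <- substr(haplotypes[[sp]], tp, tp)
      to <- sample(setdiff(.DNA_BASES, from), 1)
      ev <- list(node = match(sp, tree$tip.label), type = "sub", pos = tp,
                 from = from, to = to, detail = "")
      haplotypes[[sp]] <- .apply_event(haplotypes[[sp]], ev)
      events[[length(events) + 1]] <- ev
      diagnostics <- rbind(diagnostics, data.frame(
        species = sp, root_pos = r, tip_pos = tp, state = to,
        stringsAsFactors = FALSE))
    }
  }

  events_df <- do.call(rbind, lapply(events, function(ev) {
    data.frame(node = ev$node, type = ev$type, pos = ev$pos,
               from = ev$from, to = ev$to, detail = ev$detail,
               stringsAsFactors = FALSE)
  }))
  if (is.null(events_df)) {
    events_df <- data.frame(node = integer(0), type = character(0),
                            pos = integer(0), from = character(0),
                            to = character(0), detail = character(0),
                            stringsAsFactors = FALSE)
  }

  # emit samples: exact copies of the species haplotype (plus optional
  # within-species noise when configured)
  recs <- list()
  for (i in seq_len(n_sp)) {
    hap <- haplotypes[[species[i]]]
    for (j in seq_len(spp[i])) {
      s <- hap
      if (cfg$within_species_mutations > 0) {
        for (m in seq_len(cfg$within_species_mutations)) {
          p <- sample.int(nchar(s), 1)
          from <- substr(s, p, p)
          substr(s, p, p) <- .k2p_jump(from, cfg$kappa)
        }
      }
      recs[[length(recs) + 1]] <- data.frame(
        sample_id = sprintf("%s_s%02d", species[i], j),
        species = species[i], sequence = s, source = "simulated",
        stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, recs)

  gt <- structure(list(
    tree = tree, ancestral = ancestral, events = events_df,
    diagnostics = diagnostics, haplotypes = haplotypes, cfg = cfg
  ), class = "barcode_ground_truth")
  list(records = records, ground_truth = gt)
}

#' Replay a simulation event log
#'
#' Re-derives every species haplotype from the ancestral sequence by applying
#' the logged substitution/indel/diagnostic events along the species tree, with
#' no random draws. Agreement with the emitted haplotypes byte-for-byte is the
#' generator's consistency guarantee.
#'
#' @param gt `barcode_ground_truth` from [simulate_dataset()].
#' @return named character vector of haplotypes, one per species.
#' @export
replay_ground_truth <- function(gt) {
  tree <- gt$tree
  n_sp <- length(tree$tip.label)
  node_seq <- vector("character", n_sp + tree$Nnode)
  node_seq[n_sp + 1] <- gt$ancestral
  ord <- stats::reorder(tree, "cladewise")
  ev <- gt$events
  for (e in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[e, 1]; child <- ord$edge[e, 2]
    s <- node_seq[parent]
    sel <- ev[ev$node == child, , drop = FALSE]
    for (i in seq_len(nrow(sel))) {
      s <- .apply_event(s, as.list(sel[i, ]))
    }
    node_seq[child] <- s
  }
  species <- sprintf("Species_%02d", seq_len(n_sp))
  setNames(node_seq[seq_len(n_sp)], tree$tip.label)[species]
}

#' A fixed worked alignment with hand-countable properties
#'
#' A hard-coded 10-row x 40-column alignment of two species (`Alpha`,
#' `Beta`, five samples each) constructed so that every downstream count can
#' be verified by eye:
#'
#' * 8 variable sites: 6 substitution columns (sites 5, 9, 14, 18, 23, 27)
#'   and 2 indel columns (sites 31, 35);
#' * substitution state sets: `C/T` x3 (sites 5, 9, 14), `A/G` (18),
#'   `A/C` (23), and one three-state `A/C/T` column (27);
#' * exactly 2 diagnostic characters: `Alpha` carries a private `A` at
#'   site 27, and `Beta` a private gap at site 35; every other variable
#'   column is polymorphic inside at least one species or shares its states
#'   across both, so it diagnoses nothing.
#'
#' @return a `dna_msa`.
#' @export
make_worked_alignment <- function() {
  base <- strsplit(paste0(
    "GATCGGTAGCTAGGATCGGATCGGATCGGATCGGATCGGA"), "", fixed = TRUE)[[1]]
  stopifnot(length(base) == 40)
  mk <- function(overrides) {
    x <- base
    x[as.integer(names(overrides))] <- overrides
    paste(x, collapse = "")
  }
  # columns: 5 {C,T}, 9 {C,T}, 14 {C,T}, 18 {A,G}, 23 {A,C}, 27 {A,C,T},
  #          31 indel {G,-}, 35 indel {A,C,-}
  alpha <- list(
    a1 = c(`5` = "C", `9` = "T", `14` = "C", `18` = "A", `23` = "A",
           `27` = "A", `31` = "-", `35` = "A"),
    a2 = c(`5` = "C", `9` = "C", `14` = "C", `18` = "G", `23` = "A",
           `27` = "A", `31` = "G", `35` = "C"),
    a3 = c(`5` = "C", `9` = "C", `14` = "T", `18` = "A", `23` = "A",
           `27` = "A", `31` = "G", `35` = "A"),
    a4 = c(`5` = "C", `9` = "C", `14` = "T", `18` = "A", `23` = "A",
           `27` = "A", `31` = "G", `35` = "A"),
    a5 = c(`5` = "C", `9` = "C", `14` = "C", `18` = "A", `23` = "C",
           `27` = "A", `31` = "G", `35` = "A")
  )
  beta <- list(
    b1 = c(`5` = "C", `9` = "T", `14` = "C", `18` = "G", `23` = "A",
           `27` = "C", `31` = "G", `35` = "-"),
    b2 = c(`5` = "T", `9` = "T", `14` = "C", `18` = "G", `23` = "A",
           `27` = "T", `31` = "G", `35` = "-"),
    b3 = c(`5` = "T", `9` = "T", `14` = "C", `18` = "G", `23` = "A",
           `27` = "C", `31` = "G", `35` = "-"),
    b4 = c(`5` = "T", `9` = "T", `14` = "T", `18` = "G", `23` = "A",
           `27` = "T", `31` = "-", `35` = "-"),
    b5 = c(`5` = "T", `9` = "T", `14` = "T", `18` = "G", `23` = "A",
           `27` = "C", `31` = "G", `35` = "-")
  )
  rows <- c(vapply(alpha, mk, character(1)), vapply(beta, mk, character(1)))
  species <- setNames(rep(c("Alpha", "Beta"), each = 5), names(rows))
  as_msa(rows, species)
}
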