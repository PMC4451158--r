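#' @name primer-trimming
#' @title Trim barcode amplicons at universal primers
#'
#' @description
#' `trim_primers()` excises, from each record, the subsequence strictly
#' between the best forward-primer match and the best reverse-primer match.
#' Primer matches are minimum-Hamming-distance sliding windows (no indels
#' inside a primer); ties are broken by the leftmost forward and rightmost
#' reverse match. The reverse primer is given as printed 3'-5' on primer
#' order sheets, so its sense-strand site is ambiguous between two readings:
#' the reverse complement of the printed string and its plain complement.
#' Both are searched and the better match (fewer mismatches, reverse
#' complement preferred on ties) is used; the reading chosen is recorded in
#' the `rev_primer_interpretation` attribute of the result.
#'
#' @param records barcode record `data.frame` (see [barcode_records()]).
#' @param fwd forward primer, 5'-3' on the sense strand.
#' @param rev reverse primer as printed (3'-5').
#' @param max_mismatch maximum Hamming mismatches tolerated per primer.
#' @return the records with `sequence` replaced by the trimmed insert;
#'   attribute `rev_primer_interpretation` is one of `"revcomp"`,
#'   `"complement"` (per record).
#' @examples
#' r <- barcode_records("S1", "X_y", paste0("ATTCACACCAAGTATCGCAT", "GGGG",
#'                                          revcomp("ATTGTAGTCTGGAGAAGCGTC")))
#' trim_primers(r, "ATTCACACCAAGTATCGCAT", "ATTGTAGTCTGGAGAAGCGTC")$sequence
#' @export
trim_primers <- function(records, fwd, rev, max_mismatch = 0) {
  stopifnot(nzchar(fwd), nzchar(rev), max_mismatch >= 0)
  fwd <- toupper(fwd); rev <- toupper(rev)
  .assert_dna(c(fwd, rev))
  rev_sites <- c(revcomp = revcomp(rev),
                 complement = .complement_only(rev))
  out <- records
  interp <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    s <- records$sequence[i]
    fm <- .best_primer_window(s, fwd, side = "left")
    if (fm$mismatches > max_mismatch) {
      stop("forward primer not found within ", max_mismatch,
           " mismatch(es) in record ", records$sample_id[i])
    }
    hits <- lapply(rev_sites, .best_primer_window, seq = s, side = "right")
    mm <- vapply(hits, `[[`, numeric(1), "mismatches")
    pick <- which.min(mm) # ties -> first, i.e. revcomp reading
    rm_ <- hits[[pick]]
    if (rm_$mismatches > max_mismatch) {
      stop("reverse primer not found within ", max_mismatch,
           " mismatch(es) in record ", records$sample_id[i])
    }
    interp[i] <- names(rev_sites)[pick]
    ins_start <- fm$start + nchar(fwd)
    ins_end <- rm_$start - 1
    if (ins_end < ins_start) {
      stop("primer matches overlap or are out of order in record ",
           records$sample_id[i])
    }
    out$sequence[i] <- substr(s, ins_start, ins_end)
  }
  attr(out, "rev_primer_interpretation") <- setNames(interp, records$sample_id)
  out
}

# complement without reversal (the 3'-5' string complemented in place)
.complement_only <- function(x) {
  ch <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  paste(.IUPAC_COMPLEMENT[ch], collapse = "")
}

# minimum-Hamming sliding window; side picks the tie-break direction
.best_primer_window <- function(seq, primer, side = c("left", "right")) {
  side <- match.arg(side)
  sc <- strsplit(seq, "", fixed = TRUE)[[1]]
  pc <- strsplit(primer, "", fixed = TRUE)[[1]]
  k <- length(pc); L <- length(sc)
  if (L < k) return(list(start = NA_integer_, mismatches = Inf))
  starts <- seq_len(L - k + 1)
  mism <- vapply(starts, function(i) sum(sc[i:(i + k - 1)] != pc), numeric(1))
  best <- min(mism)
  idx <- which(mism == best)
  start <- if (side == "left") idx[1] else idx[length(idx)]
  list(start = start, mismatches = best)
}

#' Annotate partial 5.8S / ITS2 / partial 28S sub-regions
#'
#' Fixed-flank annotation of a primer-trimmed ITS2 amplicon: the first 84
#' bases are partial 5.8S, the last 141 bases partial 28S, and the remainder
#' the ITS2 core. Coordinates are 1-based half-open intervals `[start, end)`.
#' The flank lengths are constant across ITS2 amplicons of this design, which
#' is what makes a fixed rule a faithful stand-in for profile-HMM annotation;
#' the function is the interface point where an HMM backend could be swapped
#' in.
#'
#' @param records barcode record `data.frame`.
#' @param p58s_len,p28s_len flank lengths in bp.
#' @return `data.frame` with one row per record: `sample_id`, `full_len`,
#'   `p58s_start`, `p58s_end`, `its2_start`, `its2_end`, `p28s_start`,
#'   `p28s_end`.
#' @export
annotate_regions <- function(records, p58s_len = 84, p28s_len = 141) {
  full_len <- nchar(records$sequence)
  min_len <- p58s_len + p28s_len + 226
  short <- full_len < min_len
  if (any(short)) {
    stop("amplicon(s) shorter than ", min_len, " bp: ",
         paste(records$sample_id[short], collapse = ", "))
  }
  data.frame(
    sample_id = records$sample_id,
    full_len = full_len,
    p58s_start = 1L, p58s_end = p58s_len + 1L,
    its2_start = p58s_len + 1L, its2_end = full_len - p28s_len + 1L,
    p28s_start = full_len - p28s_len + 1L, p28s_end = full_len + 1L,
    stringsAsFactors = FALSE
  )
}

#' GC content of DNA strings
#'
#' Percent G+C among unambiguous bases; IUPAC ambiguity codes and gaps are
#' excluded from both numerator and denominator, so GC is invariant to
#' ambiguous base calls.
#'
#' @param x character vector of (possibly gapped) DNA strings.
#' @return numeric vector of GC percentages in `[0, 100]`.
#' @export
gc_percent <- function(x) {
  vapply(x, function(s) {
    ch <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    gc <- sum(ch %in% c("G", "C"))
    at <- sum(ch %in% c("A", "T"))
    if (gc + at == 0) stop("undefined GC: no unambiguous bases in region")
    100 * gc / (gc + at)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Per-record, per-region length and GC statistics
#'
#' @param records barcode record `data.frame`.
#' @param annotation output of [annotate_regions()] for the same records, or
#'   `NULL` to report the full sequence only.
#' @return long-format `data.frame` with columns `sample_id`, `species`,
#'   `region` (`full`, `p58s`, `its2`, `p28s`), `length_bp`, `gc_percent`.
#' @export
region_stats <- function(records, annotation = NULL) {
  one <- function(region, seqs) {
    data.frame(
      sample_id = records$sample_id,
      species = records$species,
      region = region,
      length_bp = nchar(seqs),
      gc_percent = gc_percent(seqs),
      stringsAsFactors = FALSE
    )
  }
  out <- one("full", records$sequence)
  if (!is.null(annotation)) {
    stopifnot(identical(annotation$sample_id, records$sample_id))
    cut <- function(start, end) {
      substr(records$sequence, start, end - 1L)
    }
    out <- rbind(
      out,
      one("p58s", cut(annotation$p58s_start, annotation$p58s_end)),
      one("its2", cut(annotation$its2_start, annotation$its2_end)),
      one("p28s", cut(annotation$p28s_start, annotation$p28s_end))
    )
  }
  out
}
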