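#' Construct a set of labelled barcode records
#'
#' A barcode record set is a plain `data.frame` with one row per sequenced
#' sample and columns `sample_id`, `species`, `sequence` and `source`. It is
#' the common currency of the package: readers produce it, the aligner,
#' classifiers and pipeline consume it.
#'
#' @param sample_id character vector of unique sample/voucher identifiers.
#' @param species character vector of species labels (binomials, any format).
#' @param sequence character vector of DNA sequences over the IUPAC alphabet;
#'   stored uppercased.
#' @param source one of `"sampled"`, `"genbank"`, `"simulated"`; recycled.
#' @return a `data.frame` with columns `sample_id`, `species`, `sequence`,
#'   `source`.
#' @examples
#' barcode_records("S1", "Ferula_sinkiangensis", "acgt")
#' @export
barcode_records <- function(sample_id, species, sequence,
                            source = "sampled") {
  sample_id <- as.character(sample_id)
  species <- as.character(species)
  sequence <- toupper(as.character(sequence))
  source <- match.arg(source, c("sampled", "genbank", "simulated"),
                      several.ok = TRUE)
  n <- length(sample_id)
  if (length(species) == 1) species <- rep(species, n)
  if (length(species) != n || length(sequence) != n) {
    stop("sample_id, species and sequence must have equal length")
  }
  if (n > 0) {
    if (anyDuplicated(sample_id)) {
      stop("duplicate sample_id: ",
           paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
    }
    if (any(!nzchar(sequence))) stop("empty sequence(s)")
    .assert_dna(sequence)
  }
  data.frame(
    sample_id = sample_id,
    species = species,
    sequence = sequence,
    source = rep_len(source, n),
    stringsAsFactors = FALSE
  )
}

#' Read labelled barcode sequences from FASTA
#'
#' Headers are expected to carry the sample identifier and the species label
#' separated by `delim`, e.g. `>S1|Ferula_sinkiangensis`. Everything after a
#' second delimiter is ignored.
#'
#' @param path path to a FASTA file.
#' @param delim single-character field delimiter inside headers.
#' @param source record source tag applied to all entries.
#' @return a barcode record `data.frame` (see [barcode_records()]), in file
#'   order.
#' @export
read_fasta <- function(path, delim = "|", source = "sampled") {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    return(barcode_records(character(0), character(0), character(0)))
  }
  headers <- names(set)
  parts <- strsplit(headers, delim, fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 2
  if (any(bad)) {
    stop("header(s) not parseable as sample_id", delim, "species: ",
         paste(headers[bad], collapse = "; "))
  }
  barcode_records(
    sample_id = vapply(parts, `[[`, character(1), 1L),
    species = vapply(parts, `[[`, character(1), 2L),
    sequence = as.character(set),
    source = source
  )
}

#' Write labelled barcode sequences to FASTA
#'
#' @param records barcode record `data.frame`.
#' @param path output path.
#' @param delim header field delimiter.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, delim = "|", width = 70) {
  set <- Biostrings::BStringSet(setNames(
    records$sequence,
    paste(records$sample_id, records$species, sep = delim)
  ))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Species label lookup for a record set or alignment
#'
#' @param x barcode record `data.frame` or `dna_msa`.
#' @return named character vector mapping `sample_id` to species.
#' @export
species_labels <- function(x) {
  if (inherits(x, "dna_msa")) return(x$species)
  setNames(x$species, x$sample_id)
}
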