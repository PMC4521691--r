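#' Quality-control parameters for pyrosequencing reads
#'
#' A read is kept iff it has at most `max_ambiguous` ambiguous (non-ACGT)
#' bases, a mean Phred quality of at least `min_mean_quality`, and a length of
#' at least `min_length` bp. The defaults reject reads with two or more
#' ambiguous nucleotides, an average score below 25, or fewer than 300 bp.
#'
#' @param max_ambiguous maximum allowed ambiguous bases (default 1)
#' @param min_mean_quality minimum mean Phred score (default 25; rejection is
#'   strictly below the threshold)
#' @param min_length minimum read length in bp (default 300)
#' @return a `qc_params` list
#' @export
qc_params <- function(max_ambiguous = 1L, min_mean_quality = 25,
                      min_length = 300L) {
  if (max_ambiguous < 0 || min_mean_quality < 0 || min_length < 0)
    stop("QC thresholds must be non-negative")
  structure(list(max_ambiguous = as.integer(max_ambiguous),
                 min_mean_quality = min_mean_quality,
                 min_length = as.integer(min_length)),
            class = "qc_params")
}

#' Filter reads on ambiguity, mean quality and length
#'
#' Accepts either a `Biostrings::QualityScaledDNAStringSet` or a data.frame
#' with columns `read_id`, `sequence` and `quality` (Sanger Phred+33 quality
#' string). A read is kept iff ambiguous-base count <= `max_ambiguous` AND
#' mean quality >= `min_mean_quality` AND length >= `min_length`. Rejected
#' reads are attributed to the first failing rule in the order
#' ambiguous -> quality -> length.
#'
#' @param reads reads (see above)
#' @param params a [qc_params()]
#' @return list with `kept` (same type as input), `rejected` (counts named
#'   `ambiguous`, `quality`, `length`) and `n_input`.
#' @examples
#' rd <- data.frame(read_id = "r1",
#'                  sequence = strrep("ACGT", 75),
#'                  quality = strrep("I", 300))
#' filter_reads(rd, qc_params())$rejected
#' @export
filter_reads <- function(reads, params = qc_params()) {
  stopifnot(inherits(params, "qc_params"))
  if (inherits(reads, "QualityScaledDNAStringSet")) {
    seqs <- as.character(reads)
    quals <- as(Biostrings::quality(reads), "IntegerList")
    mean_q <- vapply(quals, function(q) mean(as.numeric(q)), numeric(1))
    lens <- Biostrings::width(reads)
    n_amb <- lens - as.integer(Biostrings::letterFrequency(reads, letters = "ACGT"))
  } else if (is.data.frame(reads)) {
    if (!all(c("read_id", "sequence", "quality") %in% names(reads)))
      stop("data.frame reads need columns read_id, sequence, quality")
    if (any(nchar(reads$sequence) != nchar(reads$quality)))
      stop("malformed read: sequence and quality lengths differ")
    seqs <- toupper(reads$sequence)
    lens <- nchar(seqs)
    n_amb <- lens - vapply(strsplit(seqs, ""), function(ch)
      sum(ch %in% c("A", "C", "G", "T")), integer(1))
    mean_q <- vapply(reads$quality, function(q)
      mean(utf8ToInt(q) - 33L), numeric(1), USE.NAMES = FALSE)
  } else {
    stop("unsupported read container")
  }
  fail_amb <- n_amb > params$max_ambiguous
  fail_q <- !fail_amb & mean_q < params$min_mean_quality
  fail_len <- !fail_amb & !fail_q & lens < params$min_length
  keep <- !(fail_amb | fail_q | fail_len)
  kept <- if (is.data.frame(reads)) reads[keep, , drop = FALSE] else reads[keep]
  list(kept = kept,
       rejected = c(ambiguous = sum(fail_amb), quality = sum(fail_q),
                    length = sum(fail_len)),
       n_input = length(keep))
}

#' Filter a FASTQ file and write the kept reads
#'
#' Reads Sanger (Phred+33) FASTQ through Biostrings, applies
#' [filter_reads()], writes kept reads as FASTQ and a JSON QC summary.
#'
#' @param input path to a FASTQ file
#' @param output path for the filtered FASTQ
#' @param params a [qc_params()]
#' @param summary_json optional path for a JSON summary of rejection counts
#' @return the rejection summary list, invisibly
#' @export
filter_fastq <- function(input, output, params = qc_params(),
                         summary_json = NULL) {
  reads <- Biostrings::readQualityScaledDNAStringSet(input)
  res <- filter_reads(reads, params)
  Biostrings::writeQualityScaledXStringSet(res$kept, output)
  summary <- list(n_input = res$n_input, n_kept = length(res$kept),
                  rejected = as.list(res$rejected),
                  params = unclass(params))
  if (!is.null(summary_json))
    jsonlite::write_json(summary, summary_json, auto_unbox = TRUE, digits = NA)
  invisible(summary)
}

#' Normalize taxonomy counts to percent abundance
#'
#' Each entry becomes `100 * count / preprocessed_read_count` for its sample,
#' i.e. the taxonomy abundance count divided by the number of pre-processed
#' reads, on the percent (0-100) scale.
#'
#' @param taxon_counts integer matrix, samples x taxa
#' @param preprocessed_read_count per-sample positive integer vector (recycled
#'   if length 1)
#' @param taxonomy taxonomy data.frame passed to [taxa_composition_table()];
#'   if `NULL` all taxa are treated as genus-level with unknown parents
#' @return a `taxa_table` of percent abundances
#' @examples
#' m <- matrix(c(450L, 160L), 1, dimnames = list("s1", c("Bacteroides", "Prevotella")))
#' normalize_abundance(m, 1000)$abundance
#' @export
normalize_abundance <- function(taxon_counts, preprocessed_read_count,
                                taxonomy = NULL) {
  if (!is.matrix(taxon_counts) || any(taxon_counts < 0))
    stop("taxon_counts must be a non-negative samples x taxa matrix")
  n <- nrow(taxon_counts)
  rc <- rep_len(preprocessed_read_count, n)
  if (any(rc <= 0)) stop("zero or negative pre-processed read count")
  if (any(rowSums(taxon_counts) > rc + 1e-9))
    stop("taxon counts exceed the per-sample read count")
  pct <- sweep(taxon_counts, 1, rc, "/") * 100
  if (is.null(taxonomy))
    taxonomy <- data.frame(taxon = colnames(taxon_counts), rank = "genus",
                           parent = NA_character_, stringsAsFactors = FALSE)
  taxa_composition_table(pct, taxonomy)
}
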