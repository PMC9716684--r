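#' Predicted mean read identity from Phred qualities
#'
#' Converts each base's Phred score to an error probability, averages the
#' probabilities, and converts back at the end:
#' `100 * (1 - mean(10^(-Q/10)))`.  This is the arithmetic-mean-of-error
#' convention of long-read quality filters (not a mean in Phred space; the
#' two differ materially on mixed-quality reads).
#'
#' @param record a single-record [seq_set] with qualities, or a bare
#'   integer vector of Phred scores.
#' @return Predicted identity in percent.
#' @export
predicted_identity <- function(record) {
  q <- if (is.numeric(record)) record
  else {
    stopifnot(is_seq_set(record), length(record) == 1L)
    record$qual[[1]]
  }
  if (is.null(q) || length(q) == 0L)
    stop("record has no qualities; predicted identity needs FASTQ input")
  100 * (1 - mean(10^(-q / 10)))
}

predicted_identity_all <- function(reads) {
  vapply(reads$qual, function(q) {
    if (is.null(q)) stop("read(s) without qualities; FASTQ input required")
    100 * (1 - mean(10^(-q / 10)))
  }, numeric(1))
}

#' Quality-aware read filtering (the QA80/QA90/QA95 rule)
#'
#' Keeps a read iff its length is at least `min_length` AND its predicted
#' mean identity is at least `min_identity` (both comparisons inclusive).
#' The defaults implement the 1 kb / QA90 working point.
#'
#' @param reads a [seq_set] with qualities.
#' @param min_length minimum read length in bases.
#' @param min_identity minimum predicted identity in percent (80/90/95
#'   for QA80/QA90/QA95, or any custom value).
#' @return List with `kept` (a [seq_set], input order preserved) and
#'   `log` (data.frame `read_id`, `length`, `predicted_identity`, `kept`,
#'   `reason` with reason `""`, `"length"` or `"identity"`; a read failing
#'   both is logged under `"length"`).
#' @export
filter_reads <- function(reads, min_length = 1000, min_identity = 90) {
  stopifnot(is_seq_set(reads))
  len <- nchar(reads$seq)
  pid <- predicted_identity_all(reads)
  ok_len <- len >= min_length
  ok_id <- pid >= min_identity
  kept <- ok_len & ok_id
  reason <- ifelse(kept, "", ifelse(!ok_len, "length", "identity"))
  list(kept = reads[which(kept)],
       log = data.frame(read_id = reads$id, length = len,
                        predicted_identity = pid, kept = kept,
                        reason = reason, stringsAsFactors = FALSE))
}

#' Mapped (BLAST-convention) accuracy of an alignment
#'
#' `100 * #match / (#match + #mismatch + #ins + #del)` over the aligned
#' region: matches divided by all alignment columns including indel
#' columns.
#'
#' @param aln a single-row `aln_tbl` (or any data.frame row with `cigar`
#'   or `n_match`/`n_cols`).
#' @return Accuracy in percent.
#' @export
mapped_accuracy <- function(aln) {
  if (nrow(aln) != 1L) stop("mapped_accuracy expects a single alignment")
  mapped_accuracy_all(aln)
}

mapped_accuracy_all <- function(alignments) {
  has_cg <- !is.na(alignments$cigar)
  if (any(has_cg)) {
    st <- cpp_cigar_stats(alignments$cigar[has_cg])
    if (any(st[, "n_m"] > 0))
      stop("unresolved M ops: supply sequences to resolve M before ",
           "computing mapped accuracy")
  }
  100 * alignments$n_match / alignments$n_cols
}

#' Predicted-vs-mapped read accuracy profile
#'
#' One profile row per read, using the read's single best alignment
#' (highest mapped accuracy, ties broken by longer aligned span then
#' target id).  Unaligned reads appear with `NA` mapped identity and are
#' excluded from the binned density.
#'
#' @param reads a [seq_set] with qualities.
#' @param alignments an `aln_tbl` over (a subset of) the reads.
#' @param bin_width bin width in percent for the 2-D density.
#' @return List with `profiles` (data.frame `read_id`, `length`,
#'   `predicted_identity`, `mapped_identity`), `density` (matrix of
#'   counts, predicted x mapped), `median_predicted`, `median_mapped`.
#' @export
accuracy_profile <- function(reads, alignments, bin_width = 1.0) {
  stopifnot(is_seq_set(reads))
  a <- alignments[alignments$query_id %in% reads$id, , drop = FALSE]
  if (nrow(a) == 0L) stop("no alignments reference the supplied reads")
  acc <- mapped_accuracy_all(a)
  span <- a$query_end - a$query_start
  ord <- order(a$query_id, -acc, -span, a$target_id)
  best <- ord[!duplicated(a$query_id[ord])]
  mapped <- setNames(acc[best], a$query_id[best])
  profiles <- data.frame(
    read_id = reads$id,
    length = nchar(reads$seq),
    predicted_identity = predicted_identity_all(reads),
    mapped_identity = unname(mapped[reads$id]),
    stringsAsFactors = FALSE)
  with_aln <- !is.na(profiles$mapped_identity)
  brk <- function(x) floor(x / bin_width) * bin_width
  dens <- table(predicted = brk(profiles$predicted_identity[with_aln]),
                mapped = brk(profiles$mapped_identity[with_aln]))
  list(profiles = profiles,
       density = unclass(dens),
       median_predicted = median(profiles$predicted_identity),
       median_mapped = median(profiles$mapped_identity[with_aln]))
}
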