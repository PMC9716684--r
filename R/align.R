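#' Build a k-mer index over target sequences
#'
#' Forward-strand k-mers sampled every `w` bases; reverse-strand hits are
#' recovered at query time by looking up reverse-complemented query
#' k-mers.  K-mers containing `N` are skipped.
#'
#' @param targets a [seq_set] of target sequences (contigs/bins/genomes).
#' @param k odd k-mer size, 11-31 (default 15).
#' @param w sampling stride on the target (default 5).
#' @return A `kmer_index` (holds an external pointer; rebuild rather than
#'   serialize).
#' @export
build_index <- function(targets, k = 15L, w = 5L) {
  stopifnot(is_seq_set(targets))
  if (length(targets) == 0L) stop("empty target set")
  k <- as.integer(k); w <- as.integer(w)
  if (k %% 2L == 0L || k < 11L || k > 31L)
    stop("k must be odd and within [11, 31]")
  if (w < 1L) stop("w must be >= 1")
  short <- nchar(targets$seq) < k
  if (any(short))
    warning("target(s) shorter than k skipped: ",
            paste(targets$id[short], collapse = ", "))
  ptr <- cpp_build_index(targets$id, targets$seq, k, w)
  structure(list(ptr = ptr, k = k, w = w, target_ids = targets$id,
                 target_lengths = seq_lengths(targets)),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  info <- cpp_index_info(x$ptr)
  cat("kmer_index: k =", x$k, ", w =", x$w, ",", length(x$target_ids),
      "target(s),", info$n_positions, "indexed positions\n")
  invisible(x)
}

#' Map reads against a k-mer index
#'
#' Seeds are looked up on both strands, chained per (target, strand)
#' within a diagonal tolerance of `band_fraction * read_length`
#' (floor 64), and each chain with at least `min_chain_seeds` seeds is
#' extended by banded unit-cost edit-distance DP over the chained span
#' plus flanks, with free end gaps on the target side.  Emitted
#' alignments carry resolved `=`/`X` CIGARs and are sorted per read by
#' descending mapped accuracy (ties: longer span, then target id, then
#' smaller target start).  A read with no sufficiently seeded chain
#' yields no rows; this is not an error.
#'
#' @param reads a [seq_set] (for a single read use `reads[i]`).
#' @param index a [build_index()] result.
#' @param band_fraction band half-width as a fraction of read length.
#' @param min_chain_seeds minimum colinear seeds per chain.
#' @param max_occ ignore k-mers with more than this many index hits.
#' @return An [alignment_table()] with `query_seq` filled (oriented).
#' @export
map_reads <- function(reads, index, band_fraction = 0.15,
                      min_chain_seeds = 3L, max_occ = 200L) {
  stopifnot(is_seq_set(reads), inherits(index, "kmer_index"))
  df <- cpp_map_reads(index$ptr, reads$id, reads$seq, band_fraction,
                      as.integer(min_chain_seeds), as.integer(max_occ))
  if (nrow(df) == 0L) return(empty_alignments())
  acc <- 100 * df$n_match / df$n_cols
  span <- df$query_end - df$query_start
  ord <- order(match(df$query_id, reads$id), -acc, -span, df$target_id,
               df$target_start)
  df <- df[ord, , drop = FALSE]
  seqs <- reads$seq[match(df$query_id, reads$id)]
  rev <- df$strand == "-"
  seqs[rev] <- cpp_revcomp(seqs[rev])
  df$query_seq <- seqs
  alignment_table(df)
}

#' @rdname map_reads
#' @param read a single-record [seq_set].
#' @export
map_read <- function(read, index, band_fraction = 0.15,
                     min_chain_seeds = 3L, max_occ = 200L) {
  stopifnot(length(read) == 1L)
  map_reads(read, index, band_fraction, min_chain_seeds, max_occ)
}

#' Aligned fraction of a read
#'
#' Length of the union of the read's aligned query intervals divided by
#' the read length — the "coverage" operand of the read-to-bin
#' assignment rule.
#'
#' @param read_length full read length in bases.
#' @param alignments the read's alignments (to one bin's contigs).
#' @return Fraction in `[0, 1]`.
#' @export
aligned_fraction <- function(read_length, alignments) {
  if (nrow(alignments) == 0L) return(0)
  s <- alignments$query_start; e <- alignments$query_end
  if (any(s < 0 | e > read_length))
    stop("aligned interval outside [0, read_length)")
  interval_union_length(s, e) / read_length
}

interval_union_length <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  tot <- 0; cur_s <- start[1]; cur_e <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] > cur_e) {
      tot <- tot + (cur_e - cur_s)
      cur_s <- start[i]; cur_e <- end[i]
    } else cur_e <- max(cur_e, end[i])
  }
  tot + (cur_e - cur_s)
}

#' Align assembled contigs to a reference
#'
#' Convenience wrapper for evaluation: cuts each contig into overlapping
#' chunks, maps the chunks with a narrow band (a polished assembly sits
#' close to its reference, so a small band suffices and bounds memory),
#' and returns the chunk alignments with query ids
#' `"<contig>:<chunk_start>"`.
#'
#' @param contigs a [seq_set] of assembled/polished contigs.
#' @param reference a [seq_set] of reference genomes.
#' @param chunk chunk length (default 50000).
#' @param band_fraction band for chunk alignment (default 0.02).
#' @return An [alignment_table()] of best chunk alignments.
#' @export
align_to_reference <- function(contigs, reference, chunk = 50000L,
                               band_fraction = 0.02) {
  idx <- build_index(reference)
  pieces_id <- character(0); pieces_seq <- character(0)
  for (i in seq_along(contigs$id)) {
    n <- nchar(contigs$seq[i])
    starts <- seq(0L, max(0L, n - 1L), by = chunk)
    # merge a short trailing chunk into its predecessor
    if (length(starts) > 1L && n - starts[length(starts)] < chunk / 2)
      starts <- starts[-length(starts)]
    for (s in starts) {
      e <- if (s == starts[length(starts)]) n else s + chunk
      pieces_id <- c(pieces_id, paste0(contigs$id[i], ":", s))
      pieces_seq <- c(pieces_seq, substring(contigs$seq[i], s + 1L, e))
    }
  }
  pieces <- seq_set(pieces_id, pieces_seq)
  aln <- map_reads(pieces, idx, band_fraction = band_fraction)
  if (nrow(aln) == 0L) return(aln)
  # best alignment per chunk
  acc <- 100 * aln$n_match / aln$n_cols
  ord <- order(aln$query_id, -acc)
  aln[ord[!duplicated(aln$query_id[ord])], , drop = FALSE]
}

#' @export
`[.aln_tbl` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("query_id", "cigar") %in% names(out)))
    class(out) <- c("aln_tbl", "data.frame")
  out
}
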