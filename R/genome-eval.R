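#' Contiguity statistics
#'
#' N50 is the length of the contig at which the cumulative sum of
#' descending-sorted lengths first reaches half the total assembly size.
#'
#' @param contigs a [seq_set] of contigs (or a bare numeric length
#'   vector).
#' @return List: `n_contigs`, `total_length`, `n50`, `l50`, `max_contig`.
#' @export
contig_stats <- function(contigs) {
  len <- if (is.numeric(contigs)) as.numeric(contigs)
  else {
    stopifnot(is_seq_set(contigs))
    as.numeric(nchar(contigs$seq))
  }
  if (length(len) == 0L) stop("empty contig set")
  len <- sort(len, decreasing = TRUE)
  cum <- cumsum(len)
  i <- which(cum >= sum(len) / 2)[1]
  list(n_contigs = length(len), total_length = sum(len), n50 = len[i],
       l50 = i, max_contig = len[1])
}

#' Count marker occurrences in a bin
#'
#' Exact occurrences of each detector sequence or its reverse complement
#' across the bin's contigs; overlapping occurrences are counted.
#'
#' @param contigs the bin's contigs ([seq_set]).
#' @param marker_set data.frame with `marker_id`, `sequence`.
#' @return data.frame `marker_id`, `count`.
#' @export
marker_hits <- function(contigs, marker_set) {
  stopifnot(is_seq_set(contigs), all(c("marker_id", "sequence") %in%
                                     names(marker_set)))
  seqs <- toupper(contigs$seq)
  counts <- vapply(marker_set$sequence, function(m) {
    m <- toupper(m)
    rc <- as.character(cpp_revcomp(m))
    n <- cpp_count_occ(seqs, m)
    if (rc != m) n <- n + cpp_count_occ(seqs, rc)
    n
  }, numeric(1))
  data.frame(marker_id = marker_set$marker_id, count = as.integer(counts),
             stringsAsFactors = FALSE)
}

#' Marker-based completeness and contamination
#'
#' The transparent set-based simplification of single-copy-marker genome
#' appraisal: completeness is the percentage of markers present at least
#' once; contamination is the percentage of extra copies,
#' `100 * sum(count - 1 over present markers) / n_markers`.
#'
#' @param hits a [marker_hits()] table (must cover the set's ids).
#' @param marker_set data.frame with `marker_id`.
#' @return Named numeric `c(completeness =, contamination =)`.
#' @export
marker_quality <- function(hits, marker_set) {
  ids <- marker_set$marker_id
  if (length(ids) == 0L) stop("empty marker set")
  cnt <- hits$count[match(ids, hits$marker_id)]
  if (anyNA(cnt)) stop("hit table does not cover the marker set")
  c(completeness = 100 * sum(cnt >= 1L) / length(ids),
    contamination = 100 * sum(pmax(cnt - 1L, 0L)) / length(ids))
}

#' MAG retention filter
#'
#' Retains bins with completeness strictly above 50% and contamination
#' strictly below 10%.
#'
#' @param reports data.frame with `completeness` and `contamination`
#'   columns (e.g. rows of quality reports).
#' @return List with `retained` and `rejected` subsets of `reports`.
#' @export
retain_mags <- function(reports) {
  stopifnot(all(c("completeness", "contamination") %in% names(reports)))
  keep <- reports$completeness > 50 & reports$contamination < 10
  list(retained = reports[keep, , drop = FALSE],
       rejected = reports[!keep, , drop = FALSE])
}

#' MAG quality tier
#'
#' `"high"` requires completeness > 90, contamination < 5, full-length
#' 5S/16S/23S rRNAs and at least 18 tRNAs (the stringent reference-quality
#' criteria including full-length rRNA operons); `"medium"` is anything
#' else passing [retain_mags()]; the rest is `"fail"`.  Missing
#' annotation flags cap the tier at `"medium"` with a warning (rRNA/tRNA
#' detection itself is external).
#'
#' @param report one report row (list or single-row data.frame with
#'   `completeness`, `contamination`).
#' @param annotation_flags list with logicals `rrna_5s`, `rrna_16s`,
#'   `rrna_23s` and integer `n_trna`, or `NULL` when unavailable.
#' @return `"high"`, `"medium"` or `"fail"`.
#' @export
quality_tier <- function(report, annotation_flags = NULL) {
  comp <- report$completeness
  cont <- report$contamination
  retained <- comp > 50 && cont < 10
  if (!retained) return("fail")
  flags_ok <- !is.null(annotation_flags) &&
    all(c("rrna_5s", "rrna_16s", "rrna_23s", "n_trna") %in%
        names(annotation_flags))
  if (!flags_ok) {
    warning("annotation flags missing; tier capped at 'medium'")
    return("medium")
  }
  f <- annotation_flags
  high <- comp > 90 && cont < 5 && isTRUE(f$rrna_5s) && isTRUE(f$rrna_16s) &&
    isTRUE(f$rrna_23s) && f$n_trna >= 18
  if (high) "high" else "medium"
}

#' Indel and mismatch rates against a reference
#'
#' Indels are counted as events (one multi-base gap is one event, the
#' convention of standard assembly evaluators), normalised per 100 kb of
#' aligned reference bases;
#' the mismatch analogue counts `X` columns.
#'
#' @param alignments assembly-to-reference `aln_tbl` with resolved
#'   CIGARs.
#' @return Named numeric `c(indels_per_100kb =, mismatches_per_100kb =,
#'   aligned_ref_bases =)`.
#' @export
indel_rate <- function(alignments) {
  if (nrow(alignments) == 0L) stop("no alignments to evaluate")
  if (any(is.na(alignments$cigar))) stop("indel_rate requires CIGARs")
  st <- cpp_cigar_stats(alignments$cigar)
  ref_bases <- sum(st[, "n_eq"] + st[, "n_x"] + st[, "n_d"] + st[, "n_m"])
  if (ref_bases == 0) stop("alignments cover no reference bases")
  events <- sum(st[, "i_events"] + st[, "d_events"])
  c(indels_per_100kb = 1e5 * events / ref_bases,
    mismatches_per_100kb = 1e5 * sum(st[, "n_x"]) / ref_bases,
    aligned_ref_bases = ref_bases)
}

#' Overall and homopolymer-masked identity against a reference
#'
#' BLAST-convention identity over all alignment columns, and the same
#' restricted to columns outside reference homopolymer runs of length at
#' least `min_run` (insertions at a masked run's boundary junctions count
#' as masked).
#'
#' @param alignments assembly-to-reference `aln_tbl` (resolved CIGARs).
#' @param reference the reference [seq_set].
#' @param min_run run length at which masking starts (default 5).
#' @return Named numeric `c(identity =, identity_outside_hp =)`, percent.
#' @export
reference_identity <- function(alignments, reference, min_run = 5L) {
  stopifnot(is_seq_set(reference))
  if (nrow(alignments) == 0L) stop("no alignments to evaluate")
  tot <- c(cols_all = 0, match_all = 0, cols_out = 0, match_out = 0)
  for (tid in unique(alignments$target_id)) {
    ti <- match(tid, reference$id)
    if (is.na(ti)) stop("alignment target '", tid, "' not in reference")
    sub <- alignments[alignments$target_id == tid, , drop = FALSE]
    m <- cpp_masked_identity(reference$seq[ti], as.integer(sub$target_start),
                             sub$cigar, as.integer(min_run))
    tot <- tot + colSums(m)
  }
  c(identity = 100 * tot[["match_all"]] / tot[["cols_all"]],
    identity_outside_hp = 100 * tot[["match_out"]] / tot[["cols_out"]])
}

#' Homopolymer confusion matrix
#'
#' For every maximal reference run of length `>= min_run` fully contained
#' in an alignment (with at least one aligned reference column on each
#' flank), the observed length is the number of query bases equal to the
#' run base aligned over the run's columns plus pure-base insertions at
#' the run's internal and two boundary junctions; one tally per
#' (run, spanning alignment).  Runs overlapping alignment ends are
#' skipped.  True lengths of `L_max` and above pool into the last row.
#'
#' @param alignments `aln_tbl` with resolved CIGARs and query sequences
#'   available.
#' @param reference the reference [seq_set].
#' @param reads optional [seq_set] for query sequences.
#' @param min_run smallest tallied true run length (default 3).
#' @param L_max pooling boundary for true lengths (default 10).
#' @return Object of class `hp_matrix`: list of per-base count matrices
#'   (`A`, `C`, `G`, `T`, `pooled`), rows true length `min_run..L_max`
#'   (last row pools `>= L_max`), columns observed length `0..L_max + 5`
#'   (last pools).  Also carries the raw long table as attribute
#'   `"long"`.
#' @export
homopolymer_matrix <- function(alignments, reference, reads = NULL,
                               min_run = 3L, L_max = 10L) {
  stopifnot(is_seq_set(reference))
  a <- alignments[!is.na(alignments$cigar), , drop = FALSE]
  st <- if (nrow(a)) cpp_cigar_stats(a$cigar) else NULL
  if (!is.null(st) && any(st[, "n_m"] > 0))
    stop("homopolymer matrix requires resolved =/X CIGARs")
  long <- list()
  for (tid in unique(a$target_id)) {
    ti <- match(tid, reference$id)
    if (is.na(ti)) stop("alignment target '", tid, "' not in reference")
    sub <- a[a$target_id == tid, , drop = FALSE]
    qseq <- oriented_query_seqs(sub, reads)
    qoff <- oriented_query_offset(sub, setNames(nchar(qseq), sub$query_id))
    long[[tid]] <- cpp_hp_observed(reference$seq[ti],
                                   as.integer(sub$target_start), sub$cigar,
                                   qseq, as.integer(qoff), as.integer(min_run))
  }
  long <- if (length(long)) do.call(rbind, long)
  else data.frame(base = character(), true_len = integer(),
                  obs_len = integer(), stringsAsFactors = FALSE)
  rownames(long) <- NULL
  obs_max <- L_max + 5L
  rows <- min_run:L_max
  cols <- 0:obs_max
  tab_for <- function(d) {
    m <- matrix(0L, nrow = length(rows), ncol = length(cols),
                dimnames = list(true_len = as.character(rows),
                                obs_len = as.character(cols)))
    if (nrow(d) == 0L) return(m)
    tl <- pmin(d$true_len, L_max)
    ol <- pmin(d$obs_len, obs_max)
    t2 <- table(factor(tl, levels = rows), factor(ol, levels = cols))
    m + unclass(t2)
  }
  out <- lapply(c(A = "A", C = "C", G = "G", T = "T"),
                function(b) tab_for(long[long$base == b, , drop = FALSE]))
  out$pooled <- tab_for(long)
  structure(out, long = long, min_run = min_run, L_max = L_max,
            class = "hp_matrix")
}

#' @export
print.hp_matrix <- function(x, ...) {
  cat("homopolymer confusion matrix (pooled; rows true length, cols",
      "observed):\n")
  print(x$pooled)
  invisible(x)
}

#' Long-format homopolymer matrix table
#' @param x an `hp_matrix`.
#' @return data.frame `base`, `true_len`, `obs_len`, `count`.
#' @export
hp_matrix_long <- function(x) {
  stopifnot(inherits(x, "hp_matrix"))
  parts <- lapply(c("A", "C", "G", "T"), function(b) {
    m <- x[[b]]
    d <- as.data.frame(as.table(m), stringsAsFactors = FALSE)
    names(d) <- c("true_len", "obs_len", "count")
    cbind(base = b, d)
  })
  out <- do.call(rbind, parts)
  out[out$count > 0, , drop = FALSE]
}

#' IDEEL full-length protein fraction
#'
#' A protein is full-length iff its predicted length is strictly more
#' than `threshold` (default 95%) of its best-hit known protein's length;
#' the score is the full-length fraction — an indirect, database-backed
#' indicator of frameshift-free assembly.
#'
#' @param pairs data.frame with `query_length`, `best_hit_length` (amino
#'   acids; both positive) and optionally `query_id`.
#' @param threshold length ratio that must be exceeded.
#' @return List: `score` (fraction full-length) and `flags` (data.frame
#'   with per-protein `full_length`).
#' @export
ideel_score <- function(pairs, threshold = 0.95) {
  stopifnot(all(c("query_length", "best_hit_length") %in% names(pairs)))
  if (nrow(pairs) == 0L) stop("empty protein length-pair table")
  if (any(pairs$query_length <= 0 | pairs$best_hit_length <= 0))
    stop("non-positive protein length(s)")
  fl <- pairs$query_length > threshold * pairs$best_hit_length
  flags <- data.frame(
    query_id = if (!is.null(pairs$query_id)) pairs$query_id
               else seq_len(nrow(pairs)),
    query_length = pairs$query_length,
    best_hit_length = pairs$best_hit_length,
    full_length = fl, stringsAsFactors = FALSE)
  list(score = mean(fl), flags = flags)
}

#' Run-level median summary over retained bins
#'
#' Medians (mean-of-middles for even counts, the `stats::median`
#' convention) of completeness, contamination, N50, contig count,
#' coverage and IDEEL across the bins retained by [retain_mags()].
#'
#' @param reports data.frame of per-bin quality reports.
#' @return One-row data.frame of medians plus `n_bins`/`n_retained`.
#' @export
summarize_run <- function(reports) {
  stopifnot(nrow(reports) >= 1L)
  ret <- retain_mags(reports)$retained
  med <- function(col) {
    if (is.null(ret[[col]]) || nrow(ret) == 0L) return(NA_real_)
    median(ret[[col]], na.rm = TRUE)
  }
  data.frame(n_bins = nrow(reports), n_retained = nrow(ret),
             median_completeness = med("completeness"),
             median_contamination = med("contamination"),
             median_n50 = med("n50"),
             median_n_contigs = med("n_contigs"),
             median_coverage = med("coverage"),
             median_ideel = med("ideel"),
             stringsAsFactors = FALSE)
}
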