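#' Alignment tables
#'
#' Alignments are kept in a plain `data.frame` of class `aln_tbl` with one
#' row per alignment and columns: `query_id`, `target_id`, `strand`
#' (`"+"`/`"-"`), `query_start`/`query_end` (0-based half-open, on the
#' original read), `target_start`/`target_end` (0-based half-open),
#' `cigar` (ops `=`,`X`,`I`,`D`, plus `M` kept only for length
#' bookkeeping; `NA` when identity came from PAF block columns),
#' `n_match`, `n_cols`, `identity_source` (`"cigar"` or `"paf_blocks"`),
#' and optionally `query_seq` (the query in target-forward orientation,
#' i.e. reverse-complemented for `-` alignments).
#'
#' The CIGAR of a `-` alignment describes the reverse-complemented read
#' against the forward target; `query_start`/`query_end` always refer to
#' the original read. [oriented_query_offset()] centralises the offset
#' arithmetic.
#'
#' @param df data.frame with at least the coordinate columns above.
#' @param validate check the CIGAR-sum invariants (default `TRUE`).
#' @return An `aln_tbl`.
#' @export
alignment_table <- function(df, validate = TRUE) {
  need <- c("query_id", "target_id", "strand", "query_start", "query_end",
            "target_start", "target_end", "cigar")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("alignment table missing column(s): ",
                         paste(miss, collapse = ", "))
  df$query_id <- as.character(df$query_id)
  df$target_id <- as.character(df$target_id)
  df$strand <- as.character(df$strand)
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  for (col in c("query_start", "query_end", "target_start", "target_end"))
    df[[col]] <- as.numeric(df[[col]])
  if (any(df$query_start < 0 | df$target_start < 0 |
          df$query_end < df$query_start | df$target_end < df$target_start))
    stop("invalid alignment coordinates")
  if (is.null(df$query_seq)) df$query_seq <- rep(NA_character_, nrow(df))
  has_cg <- !is.na(df$cigar)
  if (is.null(df$identity_source))
    df$identity_source <- ifelse(has_cg, "cigar", "paf_blocks")
  if (any(has_cg)) {
    st <- cpp_cigar_stats(df$cigar[has_cg])
    if (is.null(df$n_match)) df$n_match <- rep(NA_real_, nrow(df))
    if (is.null(df$n_cols)) df$n_cols <- rep(NA_real_, nrow(df))
    df$n_match[has_cg] <- st[, "n_eq"] + st[, "n_m"]  # M bookkeeping: match
    df$n_cols[has_cg] <- st[, "n_eq"] + st[, "n_x"] + st[, "n_i"] +
      st[, "n_d"] + st[, "n_m"]
    if (validate) {
      qbad <- st[, "qspan"] != (df$query_end - df$query_start)[has_cg]
      tbad <- st[, "tspan"] != (df$target_end - df$target_start)[has_cg]
      if (any(qbad | tbad)) {
        i <- which(has_cg)[which(qbad | tbad)[1]]
        stop("CIGAR length inconsistency for alignment of '", df$query_id[i],
             "' to '", df$target_id[i], "'")
      }
    }
  }
  if (is.null(df$n_match) || is.null(df$n_cols))
    stop("alignments without CIGAR need n_match and n_cols")
  rownames(df) <- NULL
  class(df) <- c("aln_tbl", "data.frame")
  df
}

empty_alignments <- function() {
  alignment_table(data.frame(
    query_id = character(), target_id = character(), strand = character(),
    query_start = numeric(), query_end = numeric(),
    target_start = numeric(), target_end = numeric(),
    cigar = character(), n_match = numeric(), n_cols = numeric(),
    stringsAsFactors = FALSE))
}

#' Offset of an alignment's first aligned base in the oriented query
#'
#' For `+` alignments this is `query_start`; for `-` alignments it is
#' `query_length - query_end`, the position within the
#' reverse-complemented read where the CIGAR walk starts.
#'
#' @param alignments an `aln_tbl`.
#' @param query_lengths named vector of full read lengths.
#' @return Numeric vector of 0-based offsets.
#' @export
oriented_query_offset <- function(alignments, query_lengths) {
  qlen <- query_lengths[alignments$query_id]
  if (anyNA(qlen)) stop("missing query length(s) for oriented offset")
  ifelse(alignments$strand == "+", alignments$query_start,
         qlen - alignments$query_end)
}

# Attach oriented query sequences (target-forward orientation) to an
# aln_tbl, pulling them from `reads` where the query_seq column is NA.
oriented_query_seqs <- function(alignments, reads = NULL) {
  qs <- alignments$query_seq
  need <- is.na(qs)
  if (any(need)) {
    if (is.null(reads)) stop("query sequences required but not supplied")
    idx <- match(alignments$query_id[need], reads$id)
    if (anyNA(idx)) stop("alignment query id(s) absent from reads")
    s <- reads$seq[idx]
    rev <- alignments$strand[need] == "-"
    s[rev] <- cpp_revcomp(s[rev])
    qs[need] <- s
  }
  qs
}

#' Parse a CIGAR string into ops
#' @param cigar a single CIGAR string.
#' @return data.frame with columns `op`, `len`.
#' @export
cigar_ops <- function(cigar) {
  m <- gregexpr("[0-9]+[=XIDMSH]", cigar)[[1]]
  toks <- regmatches(cigar, list(m))[[1]]
  if (sum(nchar(toks)) != nchar(cigar)) stop("malformed CIGAR: ", cigar)
  data.frame(op = substring(toks, nchar(toks)),
             len = as.integer(substring(toks, 1L, nchar(toks) - 1L)),
             stringsAsFactors = FALSE)
}
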