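#' Parse alignments from SAM or PAF
#'
#' SAM text (not BAM) with CIGARs, or PAF with optional `cg:Z` CIGAR tags.
#' SAM 1-based positions are converted to the internal 0-based half-open
#' convention; PAF coordinates (already 0-based, forward-query) are taken
#' as-is.  Unmapped records, records without a CIGAR (SAM) and records
#' whose CIGAR is inconsistent with the stated coordinates are skipped and
#' counted; the counts are attached as the `"skipped"` attribute and
#' reported via `message()`.
#'
#' PAF records without a `cg:Z` tag keep `cigar = NA` and carry identity
#' from the residue-match/block-length columns (`identity_source =
#' "paf_blocks"`); they cannot be used for pileups or homopolymer tallies.
#'
#' `M` CIGAR ops are resolved to `=`/`X` when `targets` (and a SAM `SEQ`)
#' are available; otherwise they are kept and treated as matches for
#' length bookkeeping only.
#'
#' @param path file path.
#' @param format `"sam"` or `"paf"`.
#' @param targets optional [seq_set] of target sequences, used to resolve
#'   `M` ops.
#' @return An [alignment_table()].
#' @export
parse_alignments <- function(path, format = c("sam", "paf"), targets = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (format == "sam") parse_sam_lines(lines, targets)
  else parse_paf_lines(lines, targets)
}

parse_sam_lines <- function(lines, targets = NULL) {
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  skipped <- c(unmapped = 0L, no_cigar = 0L, inconsistent = 0L)
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11L) stop("malformed SAM record at data line ", i)
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) == 4L) { skipped["unmapped"] <- skipped["unmapped"] + 1L; next }
    if (f[6] == "*") { skipped["no_cigar"] <- skipped["no_cigar"] + 1L; next }
    ops <- tryCatch(cigar_ops(f[6]), error = function(e) NULL)
    if (is.null(ops) || any(!ops$op %in% c("=", "X", "I", "D", "M", "S", "H"))) {
      skipped["inconsistent"] <- skipped["inconsistent"] + 1L; next
    }
    nh <- length(ops$op)
    lead <- 0L
    while (lead < nh && ops$op[lead + 1L] %in% c("S", "H")) lead <- lead + 1L
    trail <- 0L
    while (trail < nh - lead && ops$op[nh - trail] %in% c("S", "H")) trail <- trail + 1L
    core <- ops[seq_len(nh)[seq(lead + 1L, length.out = nh - lead - trail)], ,
                drop = FALSE]
    if (nrow(core) == 0L || any(core$op %in% c("S", "H"))) {
      skipped["inconsistent"] <- skipped["inconsistent"] + 1L; next
    }
    qcons <- sum(core$len[core$op %in% c("=", "X", "I", "M")])
    tcons <- sum(core$len[core$op %in% c("=", "X", "D", "M")])
    clip_lead <- sum(ops$len[seq_len(lead)])
    clip_trail <- if (trail > 0L) sum(ops$len[seq(nh - trail + 1L, nh)]) else 0L
    qlen <- clip_lead + qcons + clip_trail
    strand <- if (bitwAnd(flag, 16L) == 16L) "-" else "+"
    # oriented aligned interval -> original-read coordinates
    qs <- if (strand == "+") clip_lead else qlen - (clip_lead + qcons)
    hard <- any(ops$op == "H")
    seqfield <- f[10]
    qseq <- if (seqfield != "*" && !hard) seqfield else NA_character_
    if (!is.na(qseq) && nchar(qseq) != qlen) {
      skipped["inconsistent"] <- skipped["inconsistent"] + 1L; next
    }
    cg <- paste0(core$len, core$op, collapse = "")
    tstart <- as.numeric(f[4]) - 1
    if (any(core$op == "M") && !is.null(targets) && !is.na(qseq)) {
      ti <- match(f[3], targets$id)
      if (!is.na(ti))
        cg <- cpp_resolve_m(targets$seq[ti], qseq, tstart, clip_lead, cg)
    }
    rows[[i]] <- data.frame(
      query_id = f[1], target_id = f[3], strand = strand,
      query_start = qs, query_end = qs + qcons,
      target_start = tstart, target_end = tstart + tcons,
      cigar = cg, query_seq = qseq, stringsAsFactors = FALSE)
  }
  skipped_total <- sum(skipped)
  if (skipped_total > 0L)
    message("parse_alignments: skipped ", skipped_total, " record(s) (",
            paste(names(skipped), skipped, sep = "=", collapse = ", "), ")")
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) alignment_table(do.call(rbind, rows))
         else empty_alignments()
  attr(out, "skipped") <- skipped
  out
}

parse_paf_lines <- function(lines, targets = NULL) {
  lines <- lines[nzchar(lines)]
  skipped <- c(inconsistent = 0L)
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12L) stop("malformed PAF record at line ", i)
    tags <- f[-(1:12)]
    cg <- tags[startsWith(tags, "cg:Z:")]
    cigar <- if (length(cg)) substring(cg[1], 6L) else NA_character_
    qs <- as.numeric(f[3]); qe <- as.numeric(f[4])
    ts <- as.numeric(f[8]); te <- as.numeric(f[9])
    if (!is.na(cigar)) {
      st <- tryCatch(cpp_cigar_stats(cigar), error = function(e) NULL)
      if (is.null(st) || st[1, "qspan"] != qe - qs || st[1, "tspan"] != te - ts) {
        skipped["inconsistent"] <- skipped["inconsistent"] + 1L
        next
      }
    }
    rows[[i]] <- data.frame(
      query_id = f[1], target_id = f[6], strand = f[5],
      query_start = qs, query_end = qe,
      target_start = ts, target_end = te,
      cigar = cigar, n_match = as.numeric(f[10]), n_cols = as.numeric(f[11]),
      query_seq = NA_character_, stringsAsFactors = FALSE)
  }
  if (skipped[["inconsistent"]] > 0L)
    message("parse_alignments: skipped ", skipped[["inconsistent"]],
            " PAF record(s) with inconsistent CIGARs")
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) alignment_table(do.call(rbind, rows))
         else empty_alignments()
  attr(out, "skipped") <- skipped
  out
}

#' Write alignments as PAF (with cg:Z CIGAR tags)
#'
#' @param alignments an `aln_tbl`.
#' @param query_lengths,target_lengths named vectors of full sequence
#'   lengths (query lengths may be omitted when every alignment spans its
#'   full query and carries `query_seq`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(alignments, query_lengths, target_lengths, path) {
  a <- alignments
  qlen <- query_lengths[a$query_id]
  tlen <- target_lengths[a$target_id]
  if (anyNA(qlen) || anyNA(tlen)) stop("missing sequence length(s) for PAF")
  tag <- ifelse(is.na(a$cigar), "", paste0("\tcg:Z:", a$cigar))
  lines <- paste0(a$query_id, "\t", format_int(qlen), "\t",
                  format_int(a$query_start), "\t", format_int(a$query_end),
                  "\t", a$strand, "\t", a$target_id, "\t", format_int(tlen),
                  "\t", format_int(a$target_start), "\t",
                  format_int(a$target_end), "\t", format_int(a$n_match),
                  "\t", format_int(a$n_cols), "\t60", tag)
  writeLines(lines, path)
  invisible(path)
}

#' Write alignments as SAM
#'
#' Emits soft clips for the unaligned read ends so that positions
#' round-trip through [parse_alignments()].
#'
#' @param alignments an `aln_tbl`.
#' @param target_lengths named vector of target lengths (for `@SQ`).
#' @param path output path.
#' @param reads optional [seq_set] supplying query sequences/lengths.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, target_lengths, path, reads = NULL) {
  a <- alignments
  if (any(is.na(a$cigar))) stop("cannot write SAM for alignments without CIGARs")
  qseq <- tryCatch(oriented_query_seqs(a, reads), error = function(e) NULL)
  if (is.null(qseq)) {
    qlen <- a$query_end  # best effort: no trailing clip information
    qseq <- rep(NA_character_, nrow(a))
  } else qlen <- nchar(qseq)
  off <- ifelse(a$strand == "+", a$query_start, qlen - a$query_end)
  lead <- off
  trail <- qlen - off - (a$query_end - a$query_start)
  cg <- paste0(ifelse(lead > 0, paste0(format_int(lead), "S"), ""),
               a$cigar,
               ifelse(trail > 0, paste0(format_int(trail), "S"), ""))
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           paste0("@SQ\tSN:", names(target_lengths),
                  "\tLN:", format_int(target_lengths)))
  body <- paste0(a$query_id, "\t", ifelse(a$strand == "-", 16L, 0L), "\t",
                 a$target_id, "\t", format_int(a$target_start + 1), "\t60\t",
                 cg, "\t*\t0\t0\t", ifelse(is.na(qseq), "*", qseq), "\t*")
  writeLines(c(hdr, body), path)
  invisible(path)
}

format_int <- function(x) format(x, scientific = FALSE, trim = TRUE)

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
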