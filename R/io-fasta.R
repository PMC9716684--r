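#' Read a FASTQ file
#'
#' Strict 4-line-record FASTQ with Phred+33 qualities (Phred+64 is not
#' supported; post-2011 data only).
#'
#' @param path path to an (uncompressed) FASTQ file.
#' @return A [seq_set] with qualities.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L) return(seq_set(character(), character()))
  if (length(lines) %% 4L != 0L)
    stop("truncated FASTQ: ", length(lines),
         " lines (not a multiple of 4) in ", path)
  hdr <- lines[seq(1L, length(lines), by = 4L)]
  seqs <- lines[seq(2L, length(lines), by = 4L)]
  plus <- lines[seq(3L, length(lines), by = 4L)]
  quals <- lines[seq(4L, length(lines), by = 4L)]
  bad <- !startsWith(hdr, "@")
  if (any(bad))
    stop("malformed FASTQ header at line ", (which(bad)[1] - 1L) * 4L + 1L)
  bad <- !startsWith(plus, "+")
  if (any(bad))
    stop("malformed FASTQ separator at line ", (which(bad)[1] - 1L) * 4L + 3L)
  ids <- sub("[[:space:]].*$", "", substring(hdr, 2L))
  mism <- nchar(seqs) != nchar(quals)
  if (any(mism)) {
    i <- which(mism)[1]
    stop("malformed record '", ids[i], "': sequence length ", nchar(seqs[i]),
         " != quality length ", nchar(quals[i]))
  }
  qual <- lapply(quals, function(q) utf8ToInt(q) - 33L)
  seq_set(ids, seqs, qual)
}

#' Write a FASTQ file
#' @param records a [seq_set] with qualities on every record.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  stopifnot(is_seq_set(records))
  if (any(vapply(records$qual, is.null, logical(1))))
    stop("cannot write FASTQ: record(s) without qualities")
  qstr <- vapply(records$qual, function(q) intToUtf8(q + 33L), character(1))
  out <- character(4L * length(records))
  out[seq(1L, by = 4L, length.out = length(records))] <- paste0("@", records$id)
  out[seq(2L, by = 4L, length.out = length(records))] <- records$seq
  out[seq(3L, by = 4L, length.out = length(records))] <- "+"
  out[seq(4L, by = 4L, length.out = length(records))] <- qstr
  writeLines(out, path)
  invisible(path)
}

#' Read a FASTA file
#'
#' The header token before the first whitespace becomes the record id.
#'
#' @param path path to an (uncompressed) FASTA file.
#' @return A [seq_set] without qualities.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(seq_set(character(), character()))
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1]) stop("FASTA parse error: file does not start with '>'")
  rec <- cumsum(is_hdr)
  ids <- sub("[[:space:]].*$", "", substring(lines[is_hdr], 2L))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- vapply(split(lines[!is_hdr], rec[!is_hdr]),
                 paste, character(1), collapse = "")
  # headers with no sequence lines are an error
  if (length(seqs) != length(ids)) {
    have <- as.integer(names(seqs))
    miss <- setdiff(seq_along(ids), have)
    stop("FASTA record(s) without sequence: ",
         paste(ids[miss], collapse = ", "))
  }
  seq_set(ids, unname(seqs[order(as.integer(names(seqs)))]))
}

#' Write a FASTA file
#' @param records a [seq_set].
#' @param path output path.
#' @param line_width bases per sequence line (default 80).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, line_width = 80L) {
  stopifnot(is_seq_set(records), line_width >= 1L)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(records$id)) {
    writeLines(paste0(">", records$id[i]), con)
    s <- records$seq[i]
    n <- nchar(s)
    starts <- seq(1L, n, by = line_width)
    writeLines(substring(s, starts, pmin(starts + line_width - 1L, n)), con)
  }
  invisible(path)
}
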