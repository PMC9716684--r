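#' Sequence record collections
#'
#' A `seq_set` is the package's container for named DNA sequences (reads,
#' contigs, genomes): a column-oriented list with one entry per record.
#' Qualities, when present, are integer Phred scores (0-93), one per base.
#'
#' @param id character vector of record ids (unique, no whitespace).
#' @param sequence character vector of sequences over `A,C,G,T,N`
#'   (lower case tolerated and preserved; computations upper-case).
#' @param qualities `NULL`, or a list with one integer vector per record
#'   (entries may individually be `NULL` for quality-less records).
#' @param circular logical, recycled; marks circular replicons.
#' @return An object of class `seq_set`.
#' @export
seq_set <- function(id, sequence, qualities = NULL, circular = FALSE) {
  id <- as.character(id)
  sequence <- as.character(sequence)
  stopifnot(length(id) == length(sequence))
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    stop("duplicate sequence ids: ", paste(dup, collapse = ", "))
  }
  if (any(grepl("[[:space:]]", id))) stop("sequence ids must not contain whitespace")
  if (any(!nzchar(sequence))) stop("empty sequences are not allowed")
  bad <- grepl("[^ACGTNacgtn]", sequence)
  if (any(bad)) stop("non-ACGTN characters in sequence(s): ",
                     paste(utils::head(id[bad], 5), collapse = ", "))
  if (is.null(qualities)) {
    qualities <- vector("list", length(id))
  } else {
    stopifnot(is.list(qualities), length(qualities) == length(id))
    for (i in seq_along(qualities)) {
      q <- qualities[[i]]
      if (is.null(q)) next
      q <- as.integer(q)
      if (length(q) != nchar(sequence[i]))
        stop("record '", id[i], "': ", length(q), " quality values for ",
             nchar(sequence[i]), " bases")
      if (any(q < 0L | q > 93L))
        stop("record '", id[i], "': Phred scores outside [0, 93]")
      qualities[[i]] <- q
    }
  }
  circular <- rep_len(as.logical(circular), length(id))
  structure(list(id = id, seq = sequence, qual = qualities,
                 circular = circular),
            class = "seq_set")
}

#' @export
length.seq_set <- function(x) length(x$id)

#' @export
names.seq_set <- function(x) x$id

#' @export
`[.seq_set` <- function(x, i) {
  if (is.character(i)) i <- match(i, x$id)
  if (anyNA(i)) stop("unknown record id(s) in subset")
  seq_set(x$id[i], x$seq[i], x$qual[i], x$circular[i])
}

#' @export
print.seq_set <- function(x, ...) {
  cat("seq_set with", length(x), "record(s),",
      sum(as.numeric(nchar(x$seq))), "bases;",
      if (all(vapply(x$qual, is.null, logical(1)))) "no qualities"
      else "with qualities", "\n")
  invisible(x)
}

#' Sequence lengths of a `seq_set`
#' @param x a `seq_set`.
#' @return Named integer vector of record lengths.
#' @export
seq_lengths <- function(x) {
  stopifnot(inherits(x, "seq_set"))
  setNames(nchar(x$seq), x$id)
}

#' Reverse complement
#' @param x character vector of DNA sequences.
#' @return Character vector of reverse complements (case preserved).
#' @export
revcomp <- function(x) cpp_revcomp(x)

is_seq_set <- function(x) inherits(x, "seq_set")

# concatenate seq_sets
c_seq_set <- function(...) {
  parts <- list(...)
  seq_set(unlist(lapply(parts, `[[`, "id")),
          unlist(lapply(parts, `[[`, "seq")),
          do.call(c, lapply(parts, `[[`, "qual")),
          unlist(lapply(parts, `[[`, "circular")))
}
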