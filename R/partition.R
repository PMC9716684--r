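#' Genome bins
#'
#' A `genome_bin` is a set of contigs forming a draft MAG.  Contig ids
#' must be unique across all bins within a run (a contig belongs to at
#' most one bin); [assign_reads()] enforces this across its input bins.
#'
#' @param bin_id bin identifier.
#' @param contigs a [seq_set] of the bin's contigs.
#' @param provenance free-text provenance note.
#' @return A `genome_bin`.
#' @export
genome_bin <- function(bin_id, contigs, provenance = "") {
  stopifnot(is.character(bin_id), length(bin_id) == 1L, is_seq_set(contigs),
            length(contigs) >= 1L)
  structure(list(bin_id = bin_id, contigs = contigs,
                 provenance = provenance),
            class = "genome_bin")
}

#' @export
print.genome_bin <- function(x, ...) {
  cat("genome_bin '", x$bin_id, "': ", length(x$contigs), " contig(s), ",
      format_int(sum(as.numeric(nchar(x$contigs$seq)))), " bases\n", sep = "")
  invisible(x)
}

bin_length <- function(bin) sum(as.numeric(nchar(bin$contigs$seq)))

contig_to_bin_map <- function(bins) {
  ids <- unlist(lapply(bins, function(b) b$contigs$id))
  owner <- rep(vapply(bins, `[[`, character(1), "bin_id"),
               vapply(bins, function(b) length(b$contigs), integer(1)))
  if (anyDuplicated(ids))
    stop("contig id(s) shared between bins: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  setNames(owner, ids)
}

#' Identity and aligned fraction of one read against one bin
#'
#' Identity is the length-weighted mapped accuracy over all of the read's
#' alignments to the bin's contigs (sum of matches over sum of all
#' alignment columns), so split alignments across contig ends aggregate
#' stably; the fraction is the aligned query-interval union over the read
#' length.  A read with no alignments scores `(0, 0)`.
#'
#' @param read_length full read length.
#' @param alignments the read's alignments to that bin's contigs.
#' @return Named numeric vector `c(identity =, fraction =)`.
#' @export
read_bin_metrics <- function(read_length, alignments) {
  if (nrow(alignments) == 0L) return(c(identity = 0, fraction = 0))
  c(identity = 100 * sum(alignments$n_match) / sum(alignments$n_cols),
    fraction = aligned_fraction(read_length, alignments))
}

#' Assign reads to draft bins by identity and coverage thresholds
#'
#' The genome-resolved detangling step: a read joins every bin for which
#' its length-weighted identity is at least `min_identity` percent AND
#' its aligned read fraction is at least `min_fraction` (both inclusive),
#' producing one read cluster per bin for independent polishing.  With
#' `unique_best = TRUE` a read joins only its best bin (highest identity,
#' then fraction, then bin id).
#'
#' @param reads a [seq_set] of (filtered) reads.
#' @param bins list of [genome_bin()]s.
#' @param alignments an `aln_tbl` of read-to-contig alignments; targets
#'   not in any bin are ignored with a warning.
#' @param min_identity identity threshold in percent (default 90).
#' @param min_fraction aligned-fraction threshold (default 0.9).
#' @param unique_best restrict each read to its single best bin.
#' @return List with `clusters` (named list of `read_cluster`s: `bin_id`,
#'   `members` data.frame, `alignments`, `n_reads`, `total_bases`,
#'   thresholds) and `unassigned` (data.frame of reads joining no bin,
#'   with their best identity/fraction).
#' @export
assign_reads <- function(reads, bins, alignments, min_identity = 90,
                         min_fraction = 0.90, unique_best = FALSE) {
  stopifnot(is_seq_set(reads), is.list(bins))
  owner <- contig_to_bin_map(bins)
  a <- alignments
  known <- a$target_id %in% names(owner)
  if (any(!known)) {
    warning("ignoring ", sum(!known),
            " alignment(s) to contigs not in any bin")
    a <- a[known, , drop = FALSE]
  }
  a <- a[a$query_id %in% reads$id, , drop = FALSE]
  rlen <- seq_lengths(reads)
  bin_of <- owner[a$target_id]
  key <- paste(a$query_id, bin_of, sep = "\r")
  groups <- split(seq_len(nrow(a)), key)
  met <- lapply(groups, function(ix) {
    m <- read_bin_metrics(rlen[[a$query_id[ix[1]]]], a[ix, , drop = FALSE])
    data.frame(read_id = a$query_id[ix[1]], bin_id = bin_of[ix[1]],
               identity = m[["identity"]], fraction = m[["fraction"]],
               stringsAsFactors = FALSE)
  })
  met <- if (length(met)) do.call(rbind, met)
  else data.frame(read_id = character(), bin_id = character(),
                  identity = numeric(), fraction = numeric(),
                  stringsAsFactors = FALSE)
  rownames(met) <- NULL
  pass <- met$identity >= min_identity & met$fraction >= min_fraction
  memb <- met[pass, , drop = FALSE]
  if (unique_best && nrow(memb) > 1L) {
    ord <- order(memb$read_id, -memb$identity, -memb$fraction, memb$bin_id)
    memb <- memb[ord[!duplicated(memb$read_id[ord])], , drop = FALSE]
  }
  bin_ids <- vapply(bins, `[[`, character(1), "bin_id")
  clusters <- lapply(bin_ids, function(b) {
    mb <- memb[memb$bin_id == b, , drop = FALSE]
    sub <- a[bin_of == b & a$query_id %in% mb$read_id, , drop = FALSE]
    structure(list(bin_id = b, members = mb[, c("read_id", "identity",
                                                "fraction")],
                   alignments = sub,
                   n_reads = nrow(mb),
                   total_bases = sum(rlen[mb$read_id]),
                   min_identity = min_identity,
                   min_fraction = min_fraction),
              class = "read_cluster")
  })
  names(clusters) <- bin_ids
  # unassigned: reads with no passing bin, carrying their best metrics
  assigned <- unique(memb$read_id)
  un_ids <- setdiff(reads$id, assigned)
  best <- met[met$read_id %in% un_ids, , drop = FALSE]
  if (nrow(best)) {
    ord <- order(best$read_id, -best$identity, -best$fraction)
    best <- best[ord[!duplicated(best$read_id[ord])], , drop = FALSE]
  }
  no_aln <- setdiff(un_ids, best$read_id)
  unassigned <- rbind(
    best[, c("read_id", "identity", "fraction")],
    data.frame(read_id = no_aln, identity = numeric(length(no_aln)),
               fraction = numeric(length(no_aln)), stringsAsFactors = FALSE))
  unassigned <- unassigned[match(un_ids, unassigned$read_id), , drop = FALSE]
  rownames(unassigned) <- NULL
  list(clusters = clusters, unassigned = unassigned)
}

#' @export
print.read_cluster <- function(x, ...) {
  cat("read_cluster for bin '", x$bin_id, "': ", x$n_reads, " read(s), ",
      format_int(x$total_bases), " bases\n", sep = "")
  invisible(x)
}

#' Fold coverage of a bin by its read cluster
#'
#' Sum of target-consuming alignment lengths of the cluster members over
#' the total bin length.
#'
#' @param cluster a `read_cluster` from [assign_reads()].
#' @param bin the corresponding [genome_bin()].
#' @return Fold coverage (e.g. `17.3`).
#' @export
bin_coverage <- function(cluster, bin) {
  stopifnot(inherits(cluster, "read_cluster"), inherits(bin, "genome_bin"))
  if (cluster$bin_id != bin$bin_id)
    stop("cluster belongs to bin '", cluster$bin_id, "', not '",
         bin$bin_id, "'")
  len <- bin_length(bin)
  if (len == 0) stop("empty bin")
  a <- cluster$alignments
  if (nrow(a) == 0L) return(0)
  sum(a$target_end - a$target_start) / len
}
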