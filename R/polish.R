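#' Build a pileup over one contig
#'
#' Walks each alignment's CIGAR: `=`/`X` contribute the query base at the
#' column, `D` a deletion mark, and an insertion contributes its string to
#' the junction after the preceding consumed column.  Columns outside any
#' alignment have zero counts.  `N` query bases never vote.  Alignments
#' whose CIGAR would walk off either sequence are skipped and counted.
#'
#' @param contig a single-record [seq_set] (the current draft contig).
#' @param alignments `aln_tbl` rows targeting this contig, with resolved
#'   `=`/`X` CIGARs.
#' @param reads optional [seq_set] supplying query sequences when the
#'   alignments do not carry them.
#' @return A `pileup` list: `counts` (n x 4 matrix A,C,G,T), `del`,
#'   `span`, `junction_span` (integer vectors of length n), `insertions`
#'   (data.frame `pos`, `seq`, `count`; `pos` is the column the insertion
#'   follows) and `skipped`.
#' @export
build_pileup <- function(contig, alignments, reads = NULL) {
  stopifnot(is_seq_set(contig), length(contig) == 1L)
  a <- alignments[alignments$target_id == contig$id[1], , drop = FALSE]
  if (nrow(a) > 0L) {
    if (any(is.na(a$cigar)))
      stop("pileup requires CIGARs (PAF without cg:Z cannot be used)")
    st <- cpp_cigar_stats(a$cigar)
    if (any(st[, "n_m"] > 0))
      stop("pileup requires resolved =/X CIGARs (found M ops)")
  }
  qseq <- if (nrow(a)) oriented_query_seqs(a, reads) else character(0)
  qoff <- if (nrow(a)) oriented_query_offset(a, setNames(nchar(qseq),
                                                         a$query_id))
          else integer(0)
  pu <- cpp_build_pileup(contig$seq[1], as.integer(a$target_start),
                         a$cigar, qseq, as.integer(qoff))
  if (pu$skipped > 0)
    message("build_pileup: skipped ", pu$skipped, " inconsistent alignment(s)")
  structure(pu, class = "pileup")
}

#' Consensus call over a pileup
#'
#' Per column: if fewer than `min_depth` reads span it the draft base is
#' kept; otherwise the argmax over `{A, C, G, T, deletion}` is emitted,
#' with ties broken in favour of the draft base, then `A < C < G < T`,
#' then deletion (so a deletion must strictly outnumber every base).  A
#' deletion winner omits the base.  Per junction: the plurality inserted
#' string is emitted iff its count reaches `ins_fraction` of the reads
#' spanning the junction and the junction itself reaches `min_depth`
#' (symmetric with columns); ties or plurality insertions longer than
#' `max_ins` (a guard against chimeric artifacts) yield no insertion.
#' `N` is never emitted at a covered column.
#'
#' @param pileup a [build_pileup()] result.
#' @param draft the draft contig ([seq_set], single record).
#' @param min_depth minimum spanning reads to override the draft.
#' @param ins_fraction junction insertion threshold.
#' @param max_ins longest insertion accepted at a junction (bases).
#' @return List: `sequence` (polished contig string), `changed`
#'   (positions changed: substitutions + deletions + emitted insertions),
#'   `n_sub`, `n_del`, `n_ins`, `n_ins_skipped_long`.
#' @export
consensus <- function(pileup, draft, min_depth = 2L, ins_fraction = 0.5,
                      max_ins = 50L) {
  stopifnot(is_seq_set(draft), length(draft) == 1L)
  dseq <- toupper(draft$seq[1])
  n <- nchar(dseq)
  if (is.null(pileup$counts) || nrow(pileup$counts) == 0L)
    return(list(sequence = draft$seq[1], changed = 0L, n_sub = 0L,
                n_del = 0L, n_ins = 0L, n_ins_skipped_long = 0L))
  stopifnot(nrow(pileup$counts) == n)
  M <- pileup$counts
  del <- pileup$del
  span <- pileup$span
  dchar <- strsplit(dseq, "", fixed = TRUE)[[1]]
  di <- match(dchar, c("A", "C", "G", "T"))  # NA for N
  best_val <- pmax(M[, 1], M[, 2], M[, 3], M[, 4])
  best_col <- max.col(M, ties.method = "first")
  # draft priority on ties
  dval <- ifelse(is.na(di), -1L, M[cbind(seq_len(n), ifelse(is.na(di), 1L, di))])
  use_draft <- !is.na(di) & dval == best_val
  chosen <- ifelse(use_draft, di, best_col)
  out <- c("A", "C", "G", "T")[chosen]
  # deletion only when strictly above the best base
  deleted <- del > best_val
  # no information: keep draft
  keep <- span < min_depth | (best_val == 0L & del == 0L)
  emitted <- ifelse(deleted, "", out)
  emitted[keep] <- dchar[keep]
  # insertions
  ins_after <- character(n)
  n_ins <- 0L; n_long <- 0L
  it <- pileup$insertions
  if (!is.null(it) && nrow(it) > 0L) {
    jspan <- pileup$junction_span
    ord <- order(it$pos, -it$count, it$seq)
    it <- it[ord, , drop = FALSE]
    idx_first <- which(!duplicated(it$pos))
    # a tie for the plurality string suppresses the insertion
    nxt <- pmin(idx_first + 1L, nrow(it))
    tied <- idx_first < nrow(it) & it$pos[nxt] == it$pos[idx_first] &
      it$count[nxt] == it$count[idx_first]
    win <- it[idx_first, , drop = FALSE]
    for (r in seq_len(nrow(win))) {
      p <- win$pos[r]
      if (tied[r]) next
      js <- jspan[p + 1L]
      if (js < min_depth || win$count[r] < ins_fraction * js) next
      if (nchar(win$seq[r]) > max_ins) { n_long <- n_long + 1L; next }
      if (grepl("N", win$seq[r], fixed = TRUE)) next
      ins_after[p + 1L] <- win$seq[r]
      n_ins <- n_ins + 1L
    }
  }
  polished <- paste(c(rbind(emitted, ins_after)), collapse = "")
  n_sub <- sum(emitted != dchar & emitted != "")
  n_del <- sum(emitted == "")
  list(sequence = polished, changed = n_sub + n_del + n_ins,
       n_sub = n_sub, n_del = n_del, n_ins = n_ins,
       n_ins_skipped_long = n_long)
}

#' Polish one bin from its own read cluster
#'
#' Iterates align -> pileup -> consensus up to `rounds` times, stopping
#' early once a round changes nothing.  The output for a bin is a pure
#' function of that bin's draft and its read cluster (genome-resolved
#' independence).  External alignments may seed round 1; later rounds
#' always realign internally because coordinates shift.
#'
#' @param bin a [genome_bin()] (the draft).
#' @param cluster the bin's `read_cluster` from [assign_reads()].
#' @param reads a [seq_set] holding (at least) the cluster's reads.
#' @param rounds maximum polishing rounds (default 2; additional
#'   long-read rounds tend to degrade quality slightly, so fewer, with a
#'   convergence stop, is the recommended regime).
#' @param min_depth,ins_fraction,max_ins consensus parameters.
#' @param band_fraction band for internal realignment.
#' @param alignments optional external `aln_tbl` for round 1.
#' @return List with `bin` (polished [genome_bin()]) and `report` (list:
#'   `bin_id`, `rounds_executed`, `changed_per_round`, `converged`).
#' @export
polish_bin <- function(bin, cluster, reads, rounds = 2L, min_depth = 2L,
                       ins_fraction = 0.5, max_ins = 50L,
                       band_fraction = 0.15, alignments = NULL) {
  stopifnot(inherits(bin, "genome_bin"), inherits(cluster, "read_cluster"))
  report <- list(bin_id = bin$bin_id, rounds_executed = 0L,
                 changed_per_round = integer(0), converged = FALSE)
  if (rounds < 1L) return(list(bin = bin, report = report))
  member_ids <- cluster$members$read_id
  if (length(member_ids) == 0L) {
    warning("bin '", bin$bin_id, "': empty read cluster; returned unpolished")
    return(list(bin = bin, report = report))
  }
  creads <- reads[member_ids]
  contigs <- bin$contigs
  for (r in seq_len(rounds)) {
    if (r == 1L && !is.null(alignments)) {
      aln <- alignments[alignments$query_id %in% member_ids &
                        alignments$target_id %in% contigs$id, , drop = FALSE]
    } else {
      idx <- build_index(contigs)
      aln <- map_reads(creads, idx, band_fraction = band_fraction)
    }
    # one vote per read: its best alignment
    if (nrow(aln) > 1L) {
      acc <- 100 * aln$n_match / aln$n_cols
      ord <- order(aln$query_id, -acc,
                   -(aln$query_end - aln$query_start), aln$target_id)
      aln <- aln[ord[!duplicated(aln$query_id[ord])], , drop = FALSE]
    }
    changed <- 0L
    new_seqs <- contigs$seq
    for (ci in seq_along(contigs$id)) {
      pu <- build_pileup(contigs[ci], aln, reads = creads)
      cons <- consensus(pu, contigs[ci], min_depth = min_depth,
                        ins_fraction = ins_fraction, max_ins = max_ins)
      new_seqs[ci] <- cons$sequence
      changed <- changed + cons$changed
    }
    contigs <- seq_set(contigs$id, new_seqs, circular = contigs$circular)
    report$rounds_executed <- r
    report$changed_per_round <- c(report$changed_per_round, changed)
    if (changed == 0L) {
      report$converged <- TRUE
      break
    }
  }
  list(bin = genome_bin(bin$bin_id, contigs, bin$provenance),
       report = report)
}
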