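#' Nanopore-like error model
#'
#' Per-base substitution/insertion/deletion probabilities plus a
#' homopolymer length-error component: every maximal single-base run of
#' length at least `hp_min` is independently contracted or extended by one
#' base with the stated per-run probabilities (at most one length change
#' per run), the dominant Nanopore error mode.
#'
#' Two presets are provided: `"kit9-like"` (total base error 4.5%) and
#' `"q20-like"` (2.0%), calibrations chosen to echo the median accuracies
#' of the two pore chemistries they are named after.
#'
#' @param p_sub,p_ins,p_del per-base probabilities in `[0,1]` with
#'   `p_sub + p_ins + p_del < 0.5`.
#' @param hp_min minimum run length subject to length errors.
#' @param p_hp_contract,p_hp_extend per-run probabilities of shortening /
#'   lengthening a qualifying run by one base.
#' @param read_level_sd log-sd of a per-read error-rate multiplier
#'   (lognormal with mean 1) applied to the base-level probabilities:
#'   real libraries vary in quality read to read, which is what makes
#'   predicted read identity informative about mapped identity.  `0`
#'   disables the variation.
#' @return An `error_model` list.
#' @export
error_model <- function(p_sub = 0.02, p_ins = 0.02, p_del = 0.02,
                        hp_min = 5L, p_hp_contract = 0.1, p_hp_extend = 0.05,
                        read_level_sd = 0.3) {
  p <- c(p_sub, p_ins, p_del, p_hp_contract, p_hp_extend)
  if (any(p < 0 | p > 1)) stop("error probabilities must be in [0, 1]")
  if (p_sub + p_ins + p_del >= 0.5)
    stop("p_sub + p_ins + p_del must be < 0.5")
  if (p_hp_contract + p_hp_extend > 1)
    stop("p_hp_contract + p_hp_extend must be <= 1")
  if (read_level_sd < 0) stop("read_level_sd must be >= 0")
  structure(list(p_sub = p_sub, p_ins = p_ins, p_del = p_del,
                 hp_min = as.integer(hp_min),
                 p_hp_contract = p_hp_contract, p_hp_extend = p_hp_extend,
                 read_level_sd = read_level_sd),
            class = "error_model")
}

# per-read scaled copy of an error model (multiplier m, E[m] = 1)
scale_error_model <- function(em, m) {
  tot <- em$p_sub + em$p_ins + em$p_del
  if (tot * m >= 0.45) m <- 0.45 / tot
  em$p_sub <- em$p_sub * m
  em$p_ins <- em$p_ins * m
  em$p_del <- em$p_del * m
  em
}

#' @rdname error_model
#' @param name preset name.
#' @export
error_model_preset <- function(name = c("kit9-like", "q20-like", "error-free")) {
  switch(match.arg(name),
    "kit9-like" = error_model(0.015, 0.015, 0.015, 5L, 0.25, 0.10),
    "q20-like" = error_model(1 / 150, 1 / 150, 1 / 150, 6L, 0.10, 0.05),
    "error-free" = error_model(0, 0, 0, 5L, 0, 0))
}

#' Mock community specification
#'
#' Defines what [simulate_reads()] emulates: a set of member genomes with
#' relative abundances (the mock communities this models span roughly
#' 0.0001-14% with a log spread), a truncated-lognormal read-length law
#' targeting a read N50 around 6 kb, a total sequencing yield, and an
#' [error_model()].
#'
#' @param genomes a [seq_set] of member genomes (distinct ids).
#' @param abundance numeric vector of relative abundances summing to 1
#'   (within 1e-9); recycled uniform when omitted.
#' @param total_bases target yield in bases.
#' @param read_mu,read_sigma lognormal log-scale parameters of read length;
#'   defaults give N50 near 6 kb.
#' @param min_read_length shortest emitted read (default 1000).
#' @param model an [error_model()].
#' @param seed integer seed driving every random choice.
#' @param markers optional marker coordinate table (from [plant_markers()])
#'   passed through to the ground truth.
#' @param prophages optional prophage region table (see [region()]) passed
#'   through to the ground truth.
#' @return A `community_spec` list.
#' @export
community_spec <- function(genomes, abundance = NULL, total_bases,
                           read_mu = 8.45, read_sigma = 0.55,
                           min_read_length = 1000L,
                           model = error_model(), seed = 1L,
                           markers = NULL, prophages = NULL) {
  stopifnot(is_seq_set(genomes), length(genomes) >= 1L)
  if (is.null(abundance)) abundance <- rep(1 / length(genomes), length(genomes))
  if (length(abundance) != length(genomes))
    stop("one abundance per genome required")
  if (abs(sum(abundance) - 1) > 1e-9)
    stop("abundances must sum to 1 (got ", sum(abundance), ")")
  if (any(abundance < 0)) stop("negative abundance")
  stopifnot(inherits(model, "error_model"), total_bases > 0)
  if (total_bases < 10 * exp(read_mu + 3 * read_sigma))
    warning("total_bases is small relative to the read-length scale")
  structure(list(genomes = genomes, abundance = abundance,
                 total_bases = total_bases, read_mu = read_mu,
                 read_sigma = read_sigma,
                 min_read_length = as.integer(min_read_length),
                 model = model, seed = as.integer(seed),
                 markers = markers, prophages = prophages),
            class = "community_spec")
}

#' Generate a random genome sequence
#'
#' I.i.d. GC-weighted base draws with an optional geometric run-extension
#' component: after each emitted base the next base repeats it with
#' probability `hp_enrichment`, enriching homopolymer runs beyond the
#' i.i.d. law while leaving the expected GC content at `gc_fraction`.
#'
#' @param length genome length (>= 1000).
#' @param gc_fraction target GC in (0, 1).
#' @param hp_enrichment per-base probability of repeating the previous
#'   base (0 = i.i.d.).
#' @param seed integer seed.
#' @param id record id (default `"genome"`).
#' @param circular mark the record circular.
#' @return A single-record [seq_set].
#' @export
generate_genome <- function(length, gc_fraction = 0.5, hp_enrichment = 0,
                            seed = 1L, id = "genome", circular = FALSE) {
  stopifnot(length >= 1000, gc_fraction > 0, gc_fraction < 1,
            hp_enrichment >= 0, hp_enrichment < 1)
  withr::with_seed(seed, {
    p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
           G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
    fresh <- sample(names(p), length, replace = TRUE, prob = p)
    if (hp_enrichment > 0) {
      extend <- runif(length) < hp_enrichment
      extend[1] <- FALSE
      grp <- cumsum(!extend)
      bases <- fresh[!extend][grp]
    } else bases <- fresh
    seq_set(id, paste(bases, collapse = ""), circular = circular)
  })
}

#' Plant unique single-copy marker tags into a genome
#'
#' Overwrites `n_markers` non-overlapping genome intervals with random
#' tags that are verified absent elsewhere in the final genome (forward
#' and reverse complement), the substrate for marker-based completeness
#' and contamination scoring.  `copy_numbers[i]` occurrences of marker `i`
#' are planted (extra copies emulate contamination).
#'
#' @param genome a single-record [seq_set].
#' @param n_markers number of distinct markers.
#' @param marker_length tag length (>= 21).
#' @param copy_numbers integer vector (recycled) of copies per marker.
#' @param seed integer seed.
#' @param max_tries placement retries before giving up.
#' @return List with `genome` (modified), `marker_set` (data.frame
#'   `marker_id`, `sequence`) and `coordinates` (data.frame `marker_id`,
#'   `genome_id`, `start`, `end`, `copy`).
#' @export
plant_markers <- function(genome, n_markers, marker_length = 30L,
                          copy_numbers = 1L, seed = 1L, max_tries = 200L) {
  stopifnot(is_seq_set(genome), length(genome) == 1L, marker_length >= 21L,
            n_markers >= 1L)
  copy_numbers <- rep_len(as.integer(copy_numbers), n_markers)
  glen <- nchar(genome$seq[1])
  total <- sum(copy_numbers)
  if (total * marker_length > glen)
    stop("placement error: ", total, " markers of length ", marker_length,
         " cannot fit in a ", glen, "-base genome without overlap")
  withr::with_seed(seed, {
    # non-overlapping interval placement by rejection
    starts <- integer(0)
    tries <- 0L
    while (length(starts) < total) {
      cand <- sample.int(glen - marker_length + 1L, 1L) - 1L
      if (!any(abs(cand - starts) < marker_length)) {
        starts <- c(starts, cand)
      } else {
        tries <- tries + 1L
        if (tries > max_tries * total)
          stop("placement error: could not place ", total,
               " non-overlapping markers after bounded retries")
      }
    }
    seqs <- character(n_markers)
    g <- genome$seq[1]
    marker_id <- sprintf("marker_%03d", seq_len(n_markers))
    idx <- rep(seq_len(n_markers), copy_numbers)
    for (m in seq_len(n_markers)) {
      for (t in seq_len(max_tries)) {
        tag <- paste(sample(c("A", "C", "G", "T"), marker_length,
                            replace = TRUE), collapse = "")
        # uniqueness checked against the current genome and other tags
        if (cpp_count_occ(g, tag) == 0L &&
            cpp_count_occ(g, as.character(cpp_revcomp(tag))) == 0L &&
            !tag %in% seqs) {
          seqs[m] <- tag
          break
        }
        if (t == max_tries) stop("could not draw a unique marker tag")
      }
    }
    for (j in seq_len(total)) {
      substr(g, starts[j] + 1L, starts[j] + marker_length) <- seqs[idx[j]]
    }
    # verify by search that each marker occurs exactly its copy number
    for (m in seq_len(n_markers)) {
      n_found <- cpp_count_occ(g, seqs[m]) +
        cpp_count_occ(g, as.character(cpp_revcomp(seqs[m])))
      if (n_found != copy_numbers[m])
        stop("marker ", marker_id[m], " occurs ", n_found,
             " times after planting (expected ", copy_numbers[m], ")")
    }
    out <- genome
    out$seq[1] <- g
    list(genome = out,
         marker_set = data.frame(marker_id = marker_id, sequence = seqs,
                                 stringsAsFactors = FALSE),
         coordinates = data.frame(
           marker_id = marker_id[idx], genome_id = genome$id[1],
           start = starts, end = starts + marker_length,
           copy = stats::ave(idx, idx, FUN = seq_along),
           stringsAsFactors = FALSE))
  })
}

#' Insert a prophage into a genome
#'
#' Splices a random prophage-like segment into the genome at `position`,
#' growing it by `prophage_length`, and returns the occupied [region()] —
#' the ground-truth analogue of prophage coordinates within a MAG.
#'
#' @param genome a single-record [seq_set].
#' @param prophage_length inserted length.
#' @param position 0-based insertion point (`0` to genome length).
#' @param seed integer seed.
#' @param name region name (default `"prophage_1"`).
#' @return List with `genome` (lengthened) and `region`.
#' @export
insert_prophage <- function(genome, prophage_length, position, seed = 1L,
                            name = "prophage_1") {
  stopifnot(is_seq_set(genome), length(genome) == 1L, prophage_length >= 1)
  glen <- nchar(genome$seq[1])
  if (position < 0 || position > glen)
    stop("position must be within [0, genome length]")
  withr::with_seed(seed, {
    phage <- paste(sample(c("A", "C", "G", "T"), prophage_length,
                          replace = TRUE, prob = c(0.3, 0.2, 0.2, 0.3)),
                   collapse = "")
    g <- genome$seq[1]
    out <- genome
    out$seq[1] <- paste0(substring(g, 1L, position), phage,
                         substring(g, position + 1L, glen))
    list(genome = out,
         region = region(genome$id[1], position, position + prophage_length,
                         name))
  })
}

# ---- read error engine -----------------------------------------------------

BASES <- c("A", "C", "G", "T")

# Apply the error model to one true (oriented) substring.  Returns the slot
# arrays from which sequence, qualities and (possibly split) CIGARs are
# assembled: ins_before[i] holds bases inserted before true position i
# (ins_before[n+1] after the last), emit[i] the emitted base ("" for a
# deletion), op[i] in {=,X,D}.
apply_read_errors <- function(true_seq, em) {
  bases <- strsplit(true_seq, "", fixed = TRUE)[[1]]
  n <- length(bases)
  ins_before <- character(n + 1L)
  # homopolymer length errors: one decision per qualifying run
  r <- rle(bases)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hp <- which(r$lengths >= em$hp_min)
  forced_del <- logical(n)
  hp_share <- numeric(n)
  if (length(hp)) {
    u <- runif(length(hp))
    contract <- u < em$p_hp_contract
    extend <- !contract & u < em$p_hp_contract + em$p_hp_extend
    forced_del[ends[hp][contract]] <- TRUE
    for (j in which(extend)) {
      pos <- ends[hp][j] + 1L
      ins_before[pos] <- paste0(r$values[hp[j]], ins_before[pos])
    }
    for (j in seq_along(hp))
      hp_share[starts[hp[j]]:ends[hp[j]]] <-
        (em$p_hp_contract + em$p_hp_extend) / r$lengths[hp[j]]
  }
  # per-base errors
  del <- (runif(n) < em$p_del) | forced_del
  sub <- runif(n) < em$p_sub & !del
  ins <- runif(n) < em$p_ins
  if (any(ins)) {
    at <- which(ins)
    ins_before[at] <- paste0(sample(BASES, length(at), replace = TRUE),
                             ins_before[at])
  }
  emit <- bases
  if (any(sub)) {
    at <- which(sub)
    shift <- sample.int(3L, length(at), replace = TRUE)
    cur <- match(bases[at], BASES)
    cur[is.na(cur)] <- 1L  # N substituted like A
    emit[at] <- BASES[((cur - 1L + shift) %% 4L) + 1L]
  }
  emit[del] <- ""
  op <- rep("=", n)
  op[sub] <- "X"
  # an N in the truth can never be emitted as a match
  op[!del & !sub & bases == "N"] <- "X"
  emit[op == "X" & emit == "N"] <- "A"
  op[del] <- "D"
  p_base <- em$p_sub + em$p_ins + em$p_del + hp_share
  list(ins_before = ins_before, emit = emit, op = op, p_base = p_base)
}

# Assemble sequence, CIGAR and qualities for true positions lo..hi of an
# error-script, with `extra_ins` appended after position hi.
assemble_read_part <- function(es, lo, hi, tail_ins = "") {
  idx <- lo:hi
  ins <- es$ins_before[idx]
  nc_ins <- nchar(ins)
  seqs <- paste0(paste(ins, es$emit[idx], sep = "", collapse = ""), tail_ins)
  slot <- paste0(strrep("I", nc_ins), es$op[idx])   # vectorized strrep
  opstr <- paste0(paste(slot, collapse = ""), strrep("I", nchar(tail_ins)))
  rl <- rle(strsplit(opstr, "", fixed = TRUE)[[1]])
  cigar <- paste0(rl$lengths, rl$values, collapse = "")
  # qualities: one value per emitted base (insertions inherit the local rate)
  emitted <- nzchar(es$emit[idx])
  q_at <- rep(es$p_base[idx], nc_ins + emitted)
  if (nchar(tail_ins) > 0)
    q_at <- c(q_at, rep(es$p_base[hi], nchar(tail_ins)))
  list(seq = seqs, cigar = cigar, p = q_at)
}

phred_from_p <- function(p, jitter) {
  q <- ifelse(p <= 0, 41, round(-10 * log10(pmax(p, 1e-9))))
  pmin(pmax(q + jitter, 2), 41)
}

# ---- read simulation -------------------------------------------------------

#' Simulate Nanopore-like reads with full ground truth
#'
#' Draws reads from the community genomes proportional to
#' `abundance * genome_length`, applies the error model left-to-right
#' (recording the exact edit script as a CIGAR), writes Phred qualities
#' from each base's local error probability with uniform integer jitter on
#' `{-2,...,2}` clamped to `[2, 41]`, and returns both the reads and the
#' complete truth: read origins and exact true alignments.  Reads from
#' circular genomes may wrap the origin, in which case the truth holds two
#' alignments for the read.
#'
#' `coverage_overrides` multiplies the sampling density of reads falling
#' wholly inside named regions — the mechanism for emulating the coverage
#' excess of an actively replicating prophage.
#'
#' @param spec a [community_spec()].
#' @param coverage_overrides optional data.frame of regions (see
#'   [region()]) with an extra `fold` column (>= 1).
#' @return List with `reads` (a [seq_set] with qualities) and `truth`
#'   (list: `origins` data.frame, `alignments` [alignment_table()],
#'   `markers`, `prophages` passed through from the community spec).
#' @export
simulate_reads <- function(spec, coverage_overrides = NULL) {
  stopifnot(inherits(spec, "community_spec"))
  g <- spec$genomes
  glen <- nchar(g$seq)
  w <- spec$abundance * glen
  # virtual members for coverage overrides
  ov_from <- integer(0); ov_start <- numeric(0); ov_end <- numeric(0)
  if (!is.null(coverage_overrides) && nrow(coverage_overrides) > 0) {
    if (is.null(coverage_overrides$fold)) stop("coverage_overrides need a fold column")
    for (i in seq_len(nrow(coverage_overrides))) {
      gi <- match(coverage_overrides$contig_id[i], g$id)
      if (is.na(gi)) stop("override region on unknown genome: ",
                          coverage_overrides$contig_id[i])
      if (coverage_overrides$end[i] > glen[gi])
        stop("override region outside genome ", g$id[gi])
      fold <- coverage_overrides$fold[i]
      if (fold < 1) stop("override fold must be >= 1")
      if (fold > 1) {
        ov_from <- c(ov_from, gi)
        ov_start <- c(ov_start, coverage_overrides$start[i])
        ov_end <- c(ov_end, coverage_overrides$end[i])
        w <- c(w, spec$abundance[gi] * (fold - 1) *
                 (coverage_overrides$end[i] - coverage_overrides$start[i]))
      }
    }
  }
  n_real <- length(g)
  em <- spec$model
  withr::with_seed(spec$seed, {
    reads_id <- list(); reads_seq <- list(); reads_qual <- list()
    # origin fields
    o_rid <- list(); o_gid <- list(); o_start <- list(); o_end <- list()
    o_strand <- list(); o_wrap <- list()
    # truth alignment fields
    a_rid <- list(); a_tid <- list(); a_strand <- list()
    a_qs <- list(); a_qe <- list(); a_ts <- list(); a_te <- list()
    a_cg <- list()
    total <- 0; i <- 0L; k <- 0L
    while (total < spec$total_bases) {
      i <- i + 1L
      mi <- sample.int(length(w), 1L, prob = w)
      gi <- if (mi <= n_real) mi else ov_from[mi - n_real]
      lo <- if (mi <= n_real) 0 else ov_start[mi - n_real]
      hi <- if (mi <= n_real) glen[gi] else ov_end[mi - n_real]
      span <- hi - lo
      L <- round(rlnorm(1, spec$read_mu, spec$read_sigma))
      L <- min(max(L, spec$min_read_length), span)
      if (L < spec$min_read_length) next
      circ <- g$circular[gi] && mi <= n_real
      max_start <- if (circ) span - 1 else span - L
      start <- lo + floor(runif(1, 0, max_start + 1))
      strand <- sample(c("+", "-"), 1L)
      rid <- sprintf("read_%06d", i)
      wraps <- circ && (start + L > hi)
      true_seq <- if (wraps)
        paste0(substring(g$seq[gi], start + 1, hi),
               substring(g$seq[gi], 1, start + L - hi))
      else substring(g$seq[gi], start + 1, start + L)
      em_r <- if (em$read_level_sd > 0)
        scale_error_model(em, exp(stats::rnorm(1, -em$read_level_sd^2 / 2,
                                               em$read_level_sd)))
      else em
      es <- apply_read_errors(toupper(true_seq), em_r)
      k <- k + 1L
      if (wraps) {
        m <- hi - start  # true bases in part 1
        a1 <- assemble_read_part(es, 1L, m)
        a2 <- assemble_read_part(es, m + 1L, L, tail_ins = es$ins_before[L + 1L])
        seq_o <- paste0(a1$seq, a2$seq)
        p_all <- c(a1$p, a2$p)
        len1 <- nchar(a1$seq); len2 <- nchar(a2$seq)
        qs <- c(0, len1); qe <- c(len1, len1 + len2)
        if (strand == "-") {
          tot_len <- len1 + len2
          tmp <- tot_len - qs
          qs <- tot_len - qe
          qe <- tmp
        }
        keep <- c(a1$cigar, a2$cigar) != ""
        a_rid[[k]] <- rep(rid, sum(keep))
        a_tid[[k]] <- rep(g$id[gi], sum(keep))
        a_strand[[k]] <- rep(strand, sum(keep))
        a_qs[[k]] <- qs[keep]; a_qe[[k]] <- qe[keep]
        a_ts[[k]] <- c(start, 0)[keep]
        a_te[[k]] <- c(hi, start + L - hi)[keep]
        a_cg[[k]] <- c(a1$cigar, a2$cigar)[keep]
      } else {
        a1 <- assemble_read_part(es, 1L, L, tail_ins = es$ins_before[L + 1L])
        seq_o <- a1$seq
        p_all <- a1$p
        a_rid[[k]] <- rid; a_tid[[k]] <- g$id[gi]; a_strand[[k]] <- strand
        a_qs[[k]] <- 0; a_qe[[k]] <- nchar(seq_o)
        a_ts[[k]] <- start; a_te[[k]] <- start + L
        a_cg[[k]] <- a1$cigar
      }
      nb <- nchar(seq_o)
      if (nb == 0L) {  # degenerate read: drop the slot written above
        a_rid[[k]] <- NULL; a_tid[[k]] <- NULL; a_strand[[k]] <- NULL
        a_qs[[k]] <- NULL; a_qe[[k]] <- NULL; a_ts[[k]] <- NULL
        a_te[[k]] <- NULL; a_cg[[k]] <- NULL
        k <- k - 1L
        next
      }
      qual_o <- phred_from_p(p_all, sample(-2:2, nb, replace = TRUE))
      if (strand == "-") {
        reads_seq[[k]] <- as.character(cpp_revcomp(seq_o))
        reads_qual[[k]] <- as.integer(rev(qual_o))
      } else {
        reads_seq[[k]] <- seq_o
        reads_qual[[k]] <- as.integer(qual_o)
      }
      reads_id[[k]] <- rid
      o_rid[[k]] <- rid; o_gid[[k]] <- g$id[gi]
      o_start[[k]] <- start; o_end[[k]] <- min(start + L, hi)
      o_strand[[k]] <- strand; o_wrap[[k]] <- wraps
      total <- total + nb
    }
    reads <- seq_set(unlist(reads_id), unlist(reads_seq), reads_qual)
    truth_aln <- alignment_table(data.frame(
      query_id = unlist(a_rid), target_id = unlist(a_tid),
      strand = unlist(a_strand),
      query_start = unlist(a_qs), query_end = unlist(a_qe),
      target_start = unlist(a_ts), target_end = unlist(a_te),
      cigar = unlist(a_cg), stringsAsFactors = FALSE))
    list(reads = reads,
         truth = list(
           origins = data.frame(
             read_id = unlist(o_rid), genome_id = unlist(o_gid),
             contig_id = unlist(o_gid), start = unlist(o_start),
             end = unlist(o_end), strand = unlist(o_strand),
             wrapped = unlist(o_wrap), stringsAsFactors = FALSE),
           alignments = truth_aln,
           markers = spec$markers,
           prophages = spec$prophages))
  })
}
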