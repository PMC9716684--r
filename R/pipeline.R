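#' Log-spread relative abundances
#'
#' Geometric series from `top` down over `n` members, normalised to sum
#' to 1 — the shape of staggered mock communities whose members span
#' roughly 0.0001 to 14% of the community.
#'
#' @param n number of members.
#' @param ratio fold drop per member (default chosen so 21 members span
#'   ~5 orders of magnitude).
#' @return Numeric vector of length `n` summing to 1.
#' @export
log_spread_abundance <- function(n, ratio = 0.56) {
  w <- ratio^(seq_len(n) - 1)
  w / sum(w)
}

#' Build a mock community with planted markers (and optional prophage)
#'
#' Convenience constructor for simulation studies: generates `n_genomes`
#' random genomes, plants single-copy markers in each (the completeness/
#' contamination substrate), optionally splices a prophage into the first
#' genome, and wraps everything in a [community_spec()].
#'
#' @param n_genomes number of member genomes.
#' @param genome_length length of each genome.
#' @param total_bases total sequencing yield to simulate.
#' @param abundance `"even"`, `"log"` (see [log_spread_abundance()]) or a
#'   numeric vector.
#' @param gc_fraction,hp_enrichment genome composition (see
#'   [generate_genome()]).
#' @param model an [error_model()].
#' @param n_markers,marker_length markers planted per genome.
#' @param prophage `NULL`, or list(`length`, `fold`) splicing a prophage
#'   into the middle of the first genome with a coverage override.
#' @param seed master seed; per-genome seeds are derived from it.
#' @return List: `spec` (a [community_spec()]), `genomes`, `marker_table`
#'   (marker_id, genome_id, start, end, sequence), `prophages` (regions
#'   or NULL), `overrides` (coverage override table or NULL).
#' @export
mock_community <- function(n_genomes = 5L, genome_length = 400000L,
                           total_bases = 4e7, abundance = "even",
                           gc_fraction = 0.45, hp_enrichment = 0.02,
                           model = error_model(), n_markers = 40L,
                           marker_length = 30L, prophage = NULL,
                           seed = 1L) {
  seed <- as.integer(seed)
  abund <- if (is.character(abundance)) {
    switch(match.arg(abundance, c("even", "log")),
           even = rep(1 / n_genomes, n_genomes),
           log = log_spread_abundance(n_genomes))
  } else abundance
  genomes <- NULL
  marker_rows <- list()
  prophages <- NULL
  overrides <- NULL
  for (i in seq_len(n_genomes)) {
    gid <- sprintf("genome_%02d", i)
    g <- generate_genome(genome_length, gc_fraction, hp_enrichment,
                         seed = seed + 1000L * i, id = gid)
    pm <- plant_markers(g, n_markers, marker_length,
                        seed = seed + 1000L * i + 1L)
    g <- pm$genome
    marker_rows[[i]] <- data.frame(
      marker_id = paste0(gid, ".", pm$coordinates$marker_id),
      genome_id = gid,
      start = pm$coordinates$start, end = pm$coordinates$end,
      sequence = pm$marker_set$sequence[match(pm$coordinates$marker_id,
                                              pm$marker_set$marker_id)],
      stringsAsFactors = FALSE)
    if (i == 1L && !is.null(prophage)) {
      ip <- insert_prophage(g, prophage$length,
                            position = floor(genome_length / 2),
                            seed = seed + 77L, name = "prophage_1")
      g <- ip$genome
      prophages <- ip$region
      if (!is.null(prophage$fold) && prophage$fold != 1) {
        overrides <- ip$region
        overrides$fold <- prophage$fold
      }
      # marker coordinates after the insertion point shift right
      shift <- marker_rows[[i]]$start >= ip$region$start
      marker_rows[[i]]$start[shift] <- marker_rows[[i]]$start[shift] +
        prophage$length
      marker_rows[[i]]$end[shift] <- marker_rows[[i]]$end[shift] +
        prophage$length
    }
    genomes <- if (is.null(genomes)) g else c_seq_set(genomes, g)
  }
  marker_table <- do.call(rbind, marker_rows)
  spec <- community_spec(genomes, abund, total_bases = total_bases,
                         model = model, seed = seed + 500L,
                         markers = marker_table, prophages = prophages)
  list(spec = spec, genomes = genomes, marker_table = marker_table,
       prophages = prophages, overrides = overrides)
}

#' Evaluate polished bins
#'
#' Builds one quality-report row per bin: contiguity, marker-based
#' completeness/contamination, optional coverage, optional indel rate and
#' identity against a truth reference, optional IDEEL score, and the
#' quality tier.
#'
#' @param bins list of [genome_bin()]s.
#' @param marker_table data.frame `marker_id`, `sequence` and optionally
#'   `genome_id`; when `genome_id` matches a bin id, only that genome's
#'   markers score the bin, otherwise the pooled set is used.
#' @param coverage optional named vector of per-bin fold coverage.
#' @param truth optional [seq_set] of reference genomes for indel/identity
#'   evaluation.
#' @param ideel optional named vector of per-bin IDEEL scores.
#' @param annotations optional named list of per-bin annotation flag
#'   lists (see [quality_tier()]).
#' @return data.frame with one row per bin.
#' @export
evaluate_bins <- function(bins, marker_table, coverage = NULL, truth = NULL,
                          ideel = NULL, annotations = NULL) {
  rows <- lapply(bins, function(b) {
    cs <- contig_stats(b$contigs)
    mt <- marker_table
    if (!is.null(mt$genome_id) && b$bin_id %in% mt$genome_id)
      mt <- mt[mt$genome_id == b$bin_id, , drop = FALSE]
    mq <- marker_quality(marker_hits(b$contigs, mt), mt)
    ind <- c(indels_per_100kb = NA_real_, mismatches_per_100kb = NA_real_)
    idy <- c(identity = NA_real_, identity_outside_hp = NA_real_)
    if (!is.null(truth)) {
      aln <- align_to_reference(b$contigs, truth)
      if (nrow(aln) > 0L) {
        ir <- indel_rate(aln)
        ind <- ir[c("indels_per_100kb", "mismatches_per_100kb")]
        idy <- reference_identity(aln, truth)
      }
    }
    rep_row <- data.frame(
      bin_id = b$bin_id,
      completeness = mq[["completeness"]],
      contamination = mq[["contamination"]],
      n_contigs = cs$n_contigs, n50 = cs$n50,
      total_length = cs$total_length,
      coverage = if (!is.null(coverage)) coverage[[b$bin_id]] else NA_real_,
      indels_per_100kb = ind[[1]], mismatches_per_100kb = ind[[2]],
      identity = idy[[1]], identity_outside_hp = idy[[2]],
      ideel = if (!is.null(ideel) && b$bin_id %in% names(ideel))
        ideel[[b$bin_id]] else NA_real_,
      circular_contigs = sum(b$contigs$circular),
      stringsAsFactors = FALSE)
    fl <- if (!is.null(annotations)) annotations[[b$bin_id]] else NULL
    rep_row$tier <- if (is.null(fl))
      suppressWarnings(quality_tier(rep_row, NULL))
    else quality_tier(rep_row, fl)
    rep_row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full long-read MAG pipeline
#'
#' Orchestrates simulate -> filter -> map -> partition -> polish ->
#' evaluate -> prophage over a configuration list, writing every stage's
#' outputs under `config$out_dir` and logging stage parameters and counts
#' to `run_log.jsonl`.  Deterministic for a fixed config and seed: stage
#' seeds are derived from `config$seed` by fixed offsets.  Existing stage
#' outputs are reused unless `force = TRUE`.
#'
#' The configuration is a nested list; every component has a default (see
#' the pipeline vignette).  Minimal forms: either `simulate = list(...)`
#' (arguments to [mock_community()]) with truth bins, or explicit
#' `reads`/`bins_fasta` paths.
#'
#' @param config configuration list: `out_dir`, `seed`, `force`,
#'   `simulate`, `reads`, `bins_fasta`, `alignments`, `filter`, `map`,
#'   `partition`, `polish`, `evaluate`, `prophage` entries.
#' @return List: `report` (the evaluation table), `summary` (run-level
#'   medians), `prophage_calls` (or NULL), `paths` of written files.
#' @export
run_pipeline <- function(config) {
  cfg <- merge_config(config)
  out <- cfg$out_dir
  if (is.null(out)) stop("config$out_dir is required")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out, "run_log.jsonl")
  if (cfg$force && file.exists(logf)) unlink(logf)
  log_stage <- function(stage, ...) {
    rec <- c(list(stage = stage), list(...))
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
        file = logf, append = TRUE, sep = "")
    message("[", stage, "] ",
            paste(names(rec)[-1], unlist(rec[-1]), sep = "=",
                  collapse = " "))
  }

  # --- simulate ------------------------------------------------------------
  truth <- NULL; marker_table <- NULL; prophage_regions <- NULL
  genomes <- NULL
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    sim_args$seed <- cfg$seed
    mc <- do.call(mock_community, sim_args)
    genomes <- mc$genomes
    marker_table <- mc$marker_table
    prophage_regions <- mc$prophages
    reads_path <- file.path(out, "reads.fastq")
    if (cfg$force || !file.exists(reads_path)) {
      sim <- simulate_reads(mc$spec, coverage_overrides = mc$overrides)
      write_fastq(sim$reads, reads_path)
      write_fasta(genomes, file.path(out, "genomes.fasta"))
      write_tsv(sim$truth$origins, file.path(out, "origins.tsv"))
      write_tsv(marker_table, file.path(out, "markers.tsv"))
      if (!is.null(prophage_regions))
        write_bed(prophage_regions, file.path(out, "prophages.bed"))
      write_sam(sim$truth$alignments, seq_lengths(genomes),
                file.path(out, "truth.sam"), reads = sim$reads)
      log_stage("simulate", n_genomes = length(genomes),
                n_reads = length(sim$reads),
                bases = sum(nchar(sim$reads$seq)))
    } else log_stage("simulate", resumed = TRUE)
    cfg$reads <- reads_path
    if (is.null(cfg$bins_fasta)) cfg$bins_fasta <- "truth"
    truth <- genomes
  }
  if (is.null(cfg$reads)) stop("filter stage: no reads available")
  if (!is.null(cfg$truth_fasta)) truth <- read_fasta(cfg$truth_fasta)
  if (!is.null(cfg$markers_tsv)) marker_table <- read_tsv(cfg$markers_tsv)
  if (!is.null(cfg$prophage_bed)) prophage_regions <- read_bed(cfg$prophage_bed)

  # --- filter --------------------------------------------------------------
  kept_path <- file.path(out, "kept.fastq")
  reads_all <- read_fastq(cfg$reads)
  if (cfg$force || !file.exists(kept_path)) {
    fl <- filter_reads(reads_all, cfg$filter$min_length,
                       cfg$filter$min_identity)
    write_fastq(fl$kept, kept_path)
    write_tsv(fl$log, file.path(out, "filter_log.tsv"))
    log_stage("filter", input = length(reads_all), kept = length(fl$kept),
              min_length = cfg$filter$min_length,
              min_identity = cfg$filter$min_identity)
    reads <- fl$kept
  } else {
    reads <- read_fastq(kept_path)
    log_stage("filter", resumed = TRUE)
  }

  # --- bins ----------------------------------------------------------------
  if (is.null(cfg$bins_fasta))
    stop("partition stage: no bins supplied (bins_fasta missing)")
  bins <- if (identical(cfg$bins_fasta, "truth")) {
    if (is.null(truth)) stop("partition stage: truth bins requested but no truth")
    lapply(seq_along(truth$id), function(i)
      genome_bin(truth$id[i], truth[i], provenance = "truth genome"))
  } else {
    fas <- if (dir.exists(cfg$bins_fasta))
      list.files(cfg$bins_fasta, "\\.(fa|fasta|fna)$", full.names = TRUE)
    else cfg$bins_fasta
    lapply(fas, function(f)
      genome_bin(sub("\\.(fa|fasta|fna)$", "", basename(f)), read_fasta(f),
                 provenance = f))
  }

  # --- map -----------------------------------------------------------------
  paf_path <- file.path(out, "mapped.paf")
  all_contigs <- do.call(c_seq_set, lapply(bins, `[[`, "contigs"))
  if (!is.null(cfg$alignments)) {
    fmt <- if (grepl("\\.sam$", cfg$alignments)) "sam" else "paf"
    aln <- parse_alignments(cfg$alignments, fmt, targets = all_contigs)
    log_stage("map", external = cfg$alignments, n = nrow(aln))
  } else if (!cfg$force && file.exists(paf_path)) {
    aln <- parse_alignments(paf_path, "paf")
    log_stage("map", resumed = TRUE)
  } else {
    idx <- build_index(all_contigs, cfg$map$k, cfg$map$w)
    aln <- map_reads(reads, idx, band_fraction = cfg$map$band_fraction)
    write_paf(aln, seq_lengths(reads), seq_lengths(all_contigs), paf_path)
    log_stage("map", n_reads = length(reads), n_alignments = nrow(aln))
  }

  # --- partition -----------------------------------------------------------
  part <- assign_reads(reads, bins, aln,
                       min_identity = cfg$partition$min_identity,
                       min_fraction = cfg$partition$min_fraction,
                       unique_best = cfg$partition$unique_best)
  cl_dir <- file.path(out, "clusters")
  dir.create(cl_dir, showWarnings = FALSE)
  coverage <- numeric(0)
  cl_rows <- lapply(bins, function(b) {
    cl <- part$clusters[[b$bin_id]]
    writeLines(cl$members$read_id,
               file.path(cl_dir, paste0(b$bin_id, ".reads.txt")))
    cov <- bin_coverage(cl, b)
    data.frame(bin_id = b$bin_id, n_reads = cl$n_reads,
               bases = cl$total_bases, coverage = cov,
               stringsAsFactors = FALSE)
  })
  cl_tab <- do.call(rbind, cl_rows)
  write_tsv(cl_tab, file.path(out, "clusters.tsv"))
  coverage <- setNames(cl_tab$coverage, cl_tab$bin_id)
  log_stage("partition", n_clusters = length(bins),
            assigned = sum(cl_tab$n_reads),
            unassigned = nrow(part$unassigned),
            min_identity = cfg$partition$min_identity,
            min_fraction = cfg$partition$min_fraction)

  # --- polish --------------------------------------------------------------
  pol_dir <- file.path(out, "polished")
  dir.create(pol_dir, showWarnings = FALSE)
  pol_rows <- list()
  polished <- list()
  for (b in bins) {
    res <- polish_bin(b, part$clusters[[b$bin_id]], reads,
                      rounds = cfg$polish$rounds,
                      min_depth = cfg$polish$min_depth,
                      ins_fraction = cfg$polish$ins_fraction,
                      band_fraction = cfg$map$band_fraction,
                      alignments = aln)
    polished[[b$bin_id]] <- res$bin
    write_fasta(res$bin$contigs,
                file.path(pol_dir, paste0(b$bin_id, ".fasta")))
    pol_rows[[b$bin_id]] <- data.frame(
      bin_id = b$bin_id, rounds = res$report$rounds_executed,
      changed = paste(res$report$changed_per_round, collapse = ","),
      converged = res$report$converged, stringsAsFactors = FALSE)
  }
  write_tsv(do.call(rbind, pol_rows), file.path(out, "polish_report.tsv"))
  log_stage("polish", rounds = cfg$polish$rounds, n_bins = length(bins))

  # --- evaluate ------------------------------------------------------------
  if (is.null(marker_table)) stop("evaluate stage: no marker table available")
  ideel <- NULL
  if (!is.null(cfg$ideel_tsv)) {
    pairs <- read_tsv(cfg$ideel_tsv)
    ideel <- vapply(split(pairs, pairs$bin_id),
                    function(p) ideel_score(p)$score, numeric(1))
  }
  annotations <- NULL
  if (!is.null(cfg$annotations_tsv)) {
    at <- read_tsv(cfg$annotations_tsv)
    annotations <- setNames(lapply(seq_len(nrow(at)), function(i)
      list(rrna_5s = as.logical(at$rrna_5s[i]),
           rrna_16s = as.logical(at$rrna_16s[i]),
           rrna_23s = as.logical(at$rrna_23s[i]),
           n_trna = as.integer(at$n_trna[i]))), at$bin_id)
  }
  report <- evaluate_bins(polished, marker_table, coverage = coverage,
                          truth = truth, ideel = ideel,
                          annotations = annotations)
  write_tsv(report, file.path(out, "report.tsv"))
  summary_tab <- summarize_run(report)
  jsonlite::write_json(as.list(summary_tab),
                       file.path(out, "summary.json"), auto_unbox = TRUE,
                       digits = NA)
  log_stage("evaluate", n_bins = nrow(report),
            n_retained = summary_tab$n_retained)

  # --- prophage ------------------------------------------------------------
  prophage_calls <- NULL
  if (!is.null(prophage_regions) && nrow(prophage_regions) > 0) {
    kept_regions <- filter_prophages(prophage_regions,
                                     cfg$prophage$min_length)
    if (nrow(kept_regions) > 0) {
      prophage_calls <- call_prophages(
        kept_regions, aln, seq_lengths(all_contigs),
        buffer = cfg$prophage$buffer, min_ratio = cfg$prophage$min_ratio,
        min_effect = cfg$prophage$min_effect,
        min_host_depth = cfg$prophage$min_host_depth)
      write_tsv(prophage_calls, file.path(out, "prophage_calls.tsv"))
      log_stage("prophage", n_regions = nrow(kept_regions),
                n_active = sum(prophage_calls$verdict == "active"))
    }
  }

  list(report = report, summary = summary_tab,
       prophage_calls = prophage_calls,
       paths = list(out_dir = out, report = file.path(out, "report.tsv"),
                    summary = file.path(out, "summary.json")))
}

merge_config <- function(config) {
  defaults <- list(
    out_dir = NULL, seed = 1L, force = FALSE,
    simulate = NULL, reads = NULL, bins_fasta = NULL, alignments = NULL,
    truth_fasta = NULL, markers_tsv = NULL, prophage_bed = NULL,
    ideel_tsv = NULL, annotations_tsv = NULL,
    filter = list(min_length = 1000, min_identity = 90),
    map = list(k = 15L, w = 5L, band_fraction = 0.15),
    partition = list(min_identity = 90, min_fraction = 0.90,
                     unique_best = FALSE),
    polish = list(rounds = 2L, min_depth = 2L, ins_fraction = 0.5),
    prophage = list(min_length = 1000, min_ratio = 1.65, min_effect = 0.70,
                    min_host_depth = 1.0, buffer = 500L))
  for (nm in names(config)) {
    if (is.list(defaults[[nm]]) && is.list(config[[nm]]) &&
        !is.null(names(defaults[[nm]]))) {
      for (sub in names(config[[nm]]))
        defaults[[nm]][[sub]] <- config[[nm]][[sub]]
    } else defaults[[nm]] <- config[[nm]]
  }
  defaults$seed <- as.integer(defaults$seed)
  defaults
}

#' Read a pipeline configuration from YAML
#' @param path YAML file.
#' @return Configuration list for [run_pipeline()].
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  merge_config(cfg)
}
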