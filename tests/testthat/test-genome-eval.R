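test_that("contiguity statistics follow the N50 definition", {
  expect_equal(contig_stats(c(100))$n50, 100)
  cs <- contig_stats(c(50, 40, 30, 20, 10))
  expect_equal(cs$n50, 40)
  expect_equal(cs$l50, 2)
  expect_equal(contig_stats(c(10, 10, 10))$n50, 10)
  expect_error(contig_stats(numeric(0)), "empty")
})

test_that("marker quality is the set-based completeness/contamination", {
  ms <- data.frame(marker_id = paste0("m", 1:100),
                   sequence = replicate(100, rand_dna(25)))
  hits <- data.frame(marker_id = ms$marker_id, count = 1L)
  expect_equal(unname(marker_quality(hits, ms)), c(100, 0))
  hits$count[51:100] <- 0L
  expect_equal(unname(marker_quality(hits, ms)), c(50, 0))
  hits$count <- 1L
  hits$count[1:10] <- 2L
  expect_equal(unname(marker_quality(hits, ms)), c(100, 10))
  expect_error(marker_quality(hits, ms[0, ]), "empty")
})

test_that("marker hits count forward, reverse-complement and overlaps", {
  contigs <- seq_set("c", "TTAAAATTTTGGGG")
  ms <- data.frame(marker_id = c("fwd", "rc", "none", "ovl"),
                   sequence = c("AAAATTTT", "CCCCAA", "ACACAC", "TTTT"))
  h <- marker_hits(contigs, ms)
  expect_equal(h$count, c(1L, 1L, 0L, 2L))  # TTTT: forward + rc(AAAA)
  ovl <- marker_hits(seq_set("c", "AAAAA"),
                     data.frame(marker_id = "m", sequence = "AAAA"))
  expect_equal(ovl$count, 2L)  # overlapping occurrences (fwd + rc collapse)
})

test_that("parameter recovery: deletions and duplications score exactly", {
  # 100 contigs each carrying one planted marker
  withr::with_seed(303, {
    tags <- replicate(100, rand_dna(30))
    contigs <- seq_set(sprintf("c%03d", 1:100),
                       paste0(replicate(100, rand_dna(60)), tags,
                              replicate(100, rand_dna(60))))
    ms <- data.frame(marker_id = sprintf("m%03d", 1:100), sequence = tags)
    # delete contigs carrying markers 81..100, duplicate those of 1..10
    kept <- contigs[1:80]
    dup <- contigs[1:10]
    dup$id <- paste0(dup$id, "_dup")
    bin <- seq_set(c(kept$id, dup$id), c(kept$seq, dup$seq))
    mq <- marker_quality(marker_hits(bin, ms), ms)
    expect_identical(unname(mq), c(80.0, 10.0))
  })
})

test_that("MAG retention is strict on both boundaries", {
  rep <- data.frame(bin_id = c("a", "b", "c", "d"),
                    completeness = c(89.5, 50.0, 95.0, 50.1),
                    contamination = c(3.0, 5.0, 10.0, 9.9))
  res <- retain_mags(rep)
  expect_setequal(res$retained$bin_id, c("a", "d"))
  expect_setequal(res$rejected$bin_id, c("b", "c"))
})

test_that("quality tiers require the full rRNA/tRNA annotation", {
  flags <- list(rrna_5s = TRUE, rrna_16s = TRUE, rrna_23s = TRUE,
                n_trna = 20L)
  r <- list(completeness = 95, contamination = 2)
  expect_equal(quality_tier(r, flags), "high")
  flags16 <- modifyList(flags, list(rrna_16s = FALSE))
  expect_equal(quality_tier(r, flags16), "medium")
  expect_equal(quality_tier(list(completeness = 45, contamination = 2),
                            flags), "fail")
  expect_warning(t <- quality_tier(r, NULL), "capped")
  expect_equal(t, "medium")
  expect_equal(quality_tier(list(completeness = 91, contamination = 4.9),
                            modifyList(flags, list(n_trna = 17L))),
               "medium")
})

test_that("indel rate counts events, not bases", {
  perfect <- aln_row(cigar = "100000=")
  expect_equal(unname(indel_rate(perfect)[1:2]), c(0, 0))
  one <- aln_row(cigar = paste0(
    paste(rep("10000=1I", 5), collapse = ""),
    paste(rep("9000=1D", 5), collapse = ""), "4995="))
  ir <- indel_rate(one)
  expect_equal(unname(ir[["indels_per_100kb"]]),
               1e5 * 10 / ir[["aligned_ref_bases"]])
  three <- aln_row(cigar = "50=3D47=")
  expect_equal(unname(indel_rate(three)[["indels_per_100kb"]]), 1e5 / 100)
})

test_that("homopolymer observations follow the junction rules", {
  ref <- seq_set("ref", "CCGTCAAAAAGTCGG")  # run of 5 A at positions 5..9
  # deletion inside the run: observed 4
  del <- aln_row("r1", "ref", cigar = "7=1D7=", query_seq = "CCGTCAAAAGTCGG")
  m <- homopolymer_matrix(del, ref, min_run = 3, L_max = 10)
  expect_equal(m$A["5", "4"], 1L)
  expect_equal(sum(m$pooled), 1L)
  # error-free: diagonal
  ok <- aln_row("r2", "ref", cigar = "15=", query_seq = ref$seq)
  m2 <- homopolymer_matrix(ok, ref, min_run = 3, L_max = 10)
  expect_equal(m2$A["5", "5"], 1L)
  # "AA" inserted at an internal junction: observed 7
  ins <- aln_row("r3", "ref", cigar = "7=2I8=",
                 query_seq = "CCGTCAAAAAAAGTCGG")
  m3 <- homopolymer_matrix(ins, ref, min_run = 3, L_max = 10)
  expect_equal(m3$A["5", "7"], 1L)
  # run overlapping the alignment end is skipped
  clipped <- aln_row("r4", "ref", cigar = "8=", query_seq = "CCGTCAAA",
                     target_start = 0)
  m4 <- homopolymer_matrix(clipped, ref, min_run = 3, L_max = 10)
  expect_equal(sum(m4$pooled), 0L)
})

test_that("homopolymer matrix distinguishes bases and pools the tail", {
  ref <- seq_set("ref", paste0("ACGT", strrep("G", 14), "ACGA",
                               strrep("T", 4), "CAGT"))
  aln <- aln_row("r", "ref", cigar = paste0(nchar(ref$seq), "="),
                 query_seq = ref$seq)
  m <- homopolymer_matrix(aln, ref, min_run = 3, L_max = 10)
  expect_equal(m$G["10", "14"], 1L)   # true length 14 pools into row 10
  expect_equal(m$T["4", "4"], 1L)
  expect_equal(sum(m$A), 0L)
  long <- hp_matrix_long(m)
  expect_equal(sum(long$count), 2L)
})

test_that("IDEEL is strict at the 95% boundary", {
  expect_true(ideel_score(data.frame(query_length = 100,
                                     best_hit_length = 100))$flags$full_length)
  expect_false(ideel_score(data.frame(query_length = 95,
                                      best_hit_length = 100))$flags$full_length)
  two <- ideel_score(data.frame(query_length = c(96, 50),
                                best_hit_length = c(100, 100)))
  expect_equal(two$score, 0.5)
  expect_error(ideel_score(data.frame(query_length = 0,
                                      best_hit_length = 10)),
               "non-positive")
})

test_that("IDEEL never drops when a query grows", {
  withr::with_seed(404, {
    pairs <- data.frame(query_length = sample(50:500, 40, TRUE),
                        best_hit_length = sample(50:500, 40, TRUE))
    s0 <- ideel_score(pairs)$score
    for (i in sample(40, 10)) {
      grown <- pairs
      grown$query_length[i] <- grown$query_length[i] + sample(1:100, 1)
      expect_gte(ideel_score(grown)$score, s0)
    }
  })
})

test_that("run summaries take medians over retained bins", {
  rep <- data.frame(bin_id = c("a", "b", "c", "low"),
                    completeness = c(98, 99, 100, 20),
                    contamination = c(0, 1, 2, 0),
                    n50 = c(10, 20, 30, 5), n_contigs = c(1, 2, 3, 9),
                    coverage = c(10, 20, 30, 1), ideel = c(0.5, 0.6, 0.7, 0.1))
  s <- summarize_run(rep)
  expect_equal(s$n_retained, 3)
  expect_equal(s$median_completeness, 99)
  expect_equal(s$median_n50, 20)
  s2 <- summarize_run(rep[1:2, ])
  expect_equal(s2$median_completeness, 98.5)  # mean-of-middles
  s1 <- summarize_run(rep[1, ])
  expect_equal(s1$median_coverage, 10)
})

test_that("polishing improves the evaluation metrics it feeds", {
  for (seed in c(1, 2)) {
    g <- generate_genome(40000, seed = 500 + seed, id = "bin1")
    pm <- plant_markers(g, 30, 30, seed = 600 + seed)
    g <- pm$genome
    corrupted <- withr::with_seed(700 + seed, {
      ch <- strsplit(g$seq, "")[[1]]
      n <- length(ch)
      subs <- sample(n, round(0.005 * n))
      ch[subs] <- vapply(ch[subs], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
      dels <- sample(setdiff(seq_len(n), subs), round(0.001 * n))
      inss <- sample(setdiff(seq_len(n), c(subs, dels)), round(0.001 * n))
      ch[inss] <- paste0(ch[inss], sample(c("A", "C", "G", "T"),
                                          length(inss), TRUE))
      ch[dels] <- ""
      seq_set("bin1", paste(ch, collapse = ""))
    })
    spec <- community_spec(g, 1, total_bases = 30 * 40000,
                           model = error_model(0.02, 0.02, 0.02),
                           seed = 800 + seed)
    sim <- simulate_reads(spec)
    res <- polish_bin(genome_bin("bin1", corrupted),
                      whole_cluster("bin1", sim$reads), sim$reads,
                      rounds = 2)
    ms <- pm$marker_set
    comp0 <- marker_quality(marker_hits(corrupted, ms), ms)[["completeness"]]
    comp1 <- marker_quality(marker_hits(res$bin$contigs, ms),
                            ms)[["completeness"]]
    expect_gte(comp1, comp0)
    ir0 <- indel_rate(align_to_reference(corrupted, g))[["indels_per_100kb"]]
    ir1 <- indel_rate(align_to_reference(res$bin$contigs,
                                         g))[["indels_per_100kb"]]
    expect_lte(ir1, ir0)
  }
})
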