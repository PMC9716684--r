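test_that("generate_genome is deterministic and hits its GC target", {
  g1 <- generate_genome(5000, seed = 7)
  g2 <- generate_genome(5000, seed = 7)
  expect_identical(g1$seq, g2$seq)
  g <- generate_genome(100000, gc_fraction = 0.5, seed = 1)
  gc <- mean(strsplit(g$seq, "")[[1]] %in% c("G", "C"))
  expect_gte(gc, 0.48)
  expect_lte(gc, 0.52)
})

test_that("hp_enrichment = 0 gives i.i.d. geometric run lengths", {
  g <- generate_genome(100000, gc_fraction = 0.5, hp_enrichment = 0,
                       seed = 5)
  r <- rle(strsplit(g$seq, "")[[1]])
  lens <- pmin(r$lengths, 6L)  # pool the tail
  obs <- tabulate(lens, 6L)
  # run length law for iid uniform bases: P(len = k) = (3/4) (1/4)^(k-1)
  p <- c(0.75 * 0.25^(0:4), 0.25^5)
  expect_gt(stats::chisq.test(obs, p = p)$p.value, 0.01)
})

test_that("enriched genomes have heavier run-length tails", {
  runs0 <- rle(strsplit(generate_genome(50000, hp_enrichment = 0,
                                        seed = 2)$seq, "")[[1]])$lengths
  runs1 <- rle(strsplit(generate_genome(50000, hp_enrichment = 0.15,
                                        seed = 2)$seq, "")[[1]])$lengths
  expect_gt(mean(runs1 >= 4), mean(runs0 >= 4))
})

test_that("plant_markers places verified unique tags at recorded spots", {
  g <- generate_genome(20000, seed = 9, id = "gX")
  pm <- plant_markers(g, n_markers = 10, marker_length = 25, seed = 4)
  hits <- marker_hits(pm$genome, pm$marker_set)
  expect_equal(hits$count, rep(1L, 10))
  # coordinates contain exactly the planted tag
  for (i in seq_len(nrow(pm$coordinates))) {
    co <- pm$coordinates[i, ]
    tag <- pm$marker_set$sequence[pm$marker_set$marker_id == co$marker_id]
    expect_equal(substring(pm$genome$seq, co$start + 1, co$end), tag)
  }

  pm2 <- plant_markers(g, n_markers = 5, marker_length = 25,
                       copy_numbers = c(2, 1, 1, 1, 1), seed = 4)
  hits2 <- marker_hits(pm2$genome, pm2$marker_set)
  expect_equal(hits2$count, c(2L, 1L, 1L, 1L, 1L))

  tiny <- seq_set("t", rand_dna(1000, seed = 1))
  expect_error(plant_markers(tiny, n_markers = 100, marker_length = 21),
               "placement error")
})

test_that("insert_prophage grows the genome and records the region", {
  g <- seq_set("h", rand_dna(20000, seed = 6))
  ip <- insert_prophage(g, prophage_length = 15000, position = 5000,
                        seed = 2)
  expect_equal(ip$region$start, 5000)
  expect_equal(ip$region$end, 20000)
  expect_equal(nchar(ip$genome$seq), 35000)
  # extracting the region returns the inserted sequence exactly
  inserted <- substring(ip$genome$seq, 5001, 20000)
  expect_equal(paste0(substring(ip$genome$seq, 1, 5000),
                      substring(ip$genome$seq, 20001, 35000)), g$seq)
  ip0 <- insert_prophage(g, 1200, position = 0, seed = 2)
  expect_equal(ip0$region$start, 0)
  expect_equal(substring(ip0$genome$seq, 1201, 1200 + 20000), g$seq)
  expect_false(inserted == substring(g$seq, 5001, 20000))
})

test_that("error-free simulation emits exact substrings with pure-match CIGARs", {
  g <- generate_genome(30000, seed = 3, id = "gA")
  spec <- community_spec(g, 1, total_bases = 3e5,
                         model = error_model_preset("error-free"), seed = 8)
  sim <- simulate_reads(spec)
  a <- sim$truth$alignments
  expect_true(all(grepl("^[0-9]+=$", a$cigar)))
  for (i in seq_len(min(nrow(a), 20))) {
    tru <- substring(g$seq, a$target_start[i] + 1, a$target_end[i])
    read <- sim$reads$seq[match(a$query_id[i], sim$reads$id)]
    if (a$strand[i] == "-") read <- as.character(revcomp(read))
    expect_equal(read, tru)
  }
})

test_that("simulation is deterministic for a fixed spec and seed", {
  g <- generate_genome(20000, seed = 3, id = "gA")
  spec <- community_spec(g, 1, total_bases = 2.5e5, seed = 21)
  s1 <- simulate_reads(spec)
  s2 <- simulate_reads(spec)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth$alignments, s2$truth$alignments)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fastq(s1$reads, f1); write_fastq(s2$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("mean depth matches total_bases / genome_length", {
  g <- generate_genome(100000, seed = 13, id = "gA")
  spec <- community_spec(g, 1, total_bases = 2e6, seed = 5)
  sim <- simulate_reads(spec)
  a <- sim$truth$alignments
  depth <- sum(a$target_end - a$target_start) / 100000
  expect_gte(depth, 19)
  expect_lte(depth, 21)
})

test_that("realized accuracy matches the error-model expectation", {
  g <- generate_genome(100000, seed = 17, id = "gA")
  em <- error_model(0.02, 0.02, 0.02, p_hp_contract = 0, p_hp_extend = 0,
                    read_level_sd = 0)
  spec <- community_spec(g, 1, total_bases = 3e6, model = em, seed = 19,
                         read_mu = 8.0)
  sim <- simulate_reads(spec)
  a <- sim$truth$alignments
  expect_gte(nrow(a), 500)
  acc <- 100 * a$n_match / a$n_cols
  expect_lt(abs(mean(acc) - 94.0), 0.5)
})

test_that("every true alignment validates against read and genome", {
  g <- generate_genome(30000, seed = 23, id = "gA")
  spec <- community_spec(g, 1, total_bases = 4e5,
                         model = error_model(0.03, 0.03, 0.03), seed = 29)
  sim <- simulate_reads(spec)
  a <- sim$truth$alignments
  qs <- nanomag:::oriented_query_seqs(a, sim$reads)
  qo <- oriented_query_offset(a, seq_lengths(sim$reads))
  msgs <- vapply(seq_len(nrow(a)), function(i)
    as.character(nanomag:::cpp_check_alignment(g$seq, qs[i],
                                               a$target_start[i], qo[i],
                                               a$cigar[i])), character(1))
  expect_true(all(msgs == ""))
  # origins table covers every read exactly once
  expect_setequal(sim$truth$origins$read_id, sim$reads$id)
  expect_equal(anyDuplicated(sim$truth$origins$read_id), 0L)
})

test_that("reads can wrap the origin of circular genomes with split truth", {
  g <- generate_genome(3000, seed = 31, id = "circ", circular = TRUE)
  spec <- community_spec(g, 1, total_bases = 1e5, seed = 37,
                         model = error_model_preset("error-free"),
                         read_mu = 7.3, min_read_length = 1000)
  sim <- simulate_reads(spec)
  wrapped <- sim$truth$origins$read_id[sim$truth$origins$wrapped]
  expect_gt(length(wrapped), 0L)
  a <- sim$truth$alignments
  expect_true(all(table(a$query_id[a$query_id %in% wrapped]) == 2L))
  qs <- nanomag:::oriented_query_seqs(a, sim$reads)
  qo <- oriented_query_offset(a, seq_lengths(sim$reads))
  for (i in which(a$query_id %in% wrapped)) {
    expect_equal(as.character(nanomag:::cpp_check_alignment(
      g$seq, qs[i], a$target_start[i], qo[i], a$cigar[i])), "")
  }
})

test_that("predicted identity tracks true mapped accuracy across reads", {
  g <- generate_genome(60000, seed = 41, id = "gA")
  spec <- community_spec(g, 1, total_bases = 1.3e6,
                         model = error_model(0.02, 0.02, 0.02),
                         read_mu = 6.9, seed = 43)
  sim <- simulate_reads(spec)
  expect_gte(length(sim$reads), 1000L)
  a <- sim$truth$alignments
  acc <- 100 * a$n_match / a$n_cols
  pid <- nanomag:::predicted_identity_all(sim$reads)
  rho <- stats::cor(pid[match(a$query_id, sim$reads$id)], acc,
                    method = "spearman")
  expect_gt(rho, 0.3)
})

test_that("coverage overrides boost sampling density inside the region", {
  g <- seq_set("h", rand_dna(50000, seed = 47))
  ov <- region("h", 10000, 25000, "ph")
  ov$fold <- 3
  spec <- community_spec(g, 1, total_bases = 1e6, seed = 53,
                         model = error_model_preset("error-free"))
  sim <- simulate_reads(spec, coverage_overrides = ov)
  a <- sim$truth$alignments
  dp <- depth_profile(a, "h", 50000)
  inside <- mean(dp[10501:24500])
  outside <- mean(dp[c(1:9000, 26500:50000)])
  expect_gt(inside / outside, 2)
  bad <- region("nope", 0, 100, "x"); bad$fold <- 2
  expect_error(simulate_reads(spec, coverage_overrides = bad),
               "unknown genome")
})
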