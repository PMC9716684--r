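test_that("predicted identity follows the mean-error-probability convention", {
  expect_equal(predicted_identity(rep(10L, 50)), 90.0)
  expect_equal(predicted_identity(rep(20L, 50)), 99.0)
  expect_equal(predicted_identity(c(10L, 20L, 30L)), 100 * (1 - 0.037))
  expect_error(predicted_identity(seq_set("r", "ACGT")), "qualit")
})

test_that("predicted identity matches a brute-force per-base oracle", {
  withr::with_seed(99, {
    for (i in 1:50) {
      q <- sample(2:41, sample(10:300, 1), replace = TRUE)
      oracle <- 0
      for (qi in q) oracle <- oracle + 10^(-qi / 10)
      oracle <- 100 * (1 - oracle / length(q))
      expect_equal(predicted_identity(q), oracle, tolerance = 1e-12)
    }
  })
})

test_that("filter applies the length-and-identity rule inclusively", {
  reads <- seq_set(
    c("short", "good", "noisy"),
    c(rand_dna(999, 1), rand_dna(1000, 2), rand_dna(1500, 3)),
    list(rep(30L, 999), rep(20L, 1000), rep(9L, 1500)))
  fl <- filter_reads(reads, min_length = 1000, min_identity = 90)
  expect_equal(fl$kept$id, "good")
  expect_equal(fl$log$reason, c("length", "", "identity"))
  # Q9 -> 87.4% sits below the QA90 cut
  expect_lt(fl$log$predicted_identity[3], 90)
  expect_equal(fl$log$predicted_identity[3], 100 * (1 - 10^-0.9))
})

test_that("filtering is idempotent and trivial thresholds keep everything", {
  reads <- withr::with_seed(5, {
    seqs <- replicate(20, rand_dna(sample(500:2000, 1)))
    seq_set(paste0("r", 1:20), seqs,
            lapply(nchar(seqs), function(n) sample(5:30, n, replace = TRUE)))
  })
  all_kept <- filter_reads(reads, 0, 0)
  expect_identical(all_kept$kept$id, reads$id)
  once <- filter_reads(reads, 1000, 90)
  twice <- filter_reads(once$kept, 1000, 90)
  expect_identical(twice$kept, once$kept)
})

test_that("mapped accuracy uses the BLAST column convention", {
  expect_equal(mapped_accuracy(aln_row(cigar = "100=")), 100.0)
  expect_equal(mapped_accuracy(aln_row(cigar = "90=5X5I")), 90.0)
  expect_equal(mapped_accuracy(aln_row(cigar = "50=2D48=")), 98.0)
  m_aln <- alignment_table(data.frame(
    query_id = "r", target_id = "c", strand = "+", query_start = 0,
    query_end = 10, target_start = 0, target_end = 10, cigar = "10M",
    stringsAsFactors = FALSE))
  expect_error(mapped_accuracy(m_aln), "unresolved M")
})

test_that("accuracy profiles pick each read's best alignment", {
  reads <- uniform_reads(c("a", "b", "c", "d"),
                         replicate(4, rand_dna(100)), 20L)
  a <- rbind(aln_row("a", cigar = "95=5X"),
             aln_row("a", cigar = "80=20X"),
             aln_row("b", cigar = "96=4X"),
             aln_row("c", cigar = "97=3X"))
  ap <- accuracy_profile(reads, alignment_table(a))
  expect_equal(ap$median_mapped, 96.0)
  prof <- ap$profiles
  expect_equal(prof$mapped_identity[prof$read_id == "a"], 95)
  expect_true(is.na(prof$mapped_identity[prof$read_id == "d"]))
  expect_equal(ap$median_predicted, 99.0)
  expect_error(accuracy_profile(reads[4], alignment_table(a)),
               "no alignments")
})

test_that("pessimistic qualities put mass below the profile diagonal", {
  # qualities say ~Q11 (92.1%) while realized errors are ~2%: the mapped
  # axis then sits above the predicted axis
  g <- generate_genome(30000, seed = 61, id = "gA")
  em <- error_model(0.02 / 3, 0.02 / 3, 0.02 / 3, read_level_sd = 0)
  spec <- community_spec(g, 1, total_bases = 3e5, model = em, seed = 67)
  sim <- simulate_reads(spec)
  pessimistic <- sim$reads
  pessimistic$qual <- lapply(pessimistic$qual, function(q) pmax(q - 6L, 2L))
  ap <- accuracy_profile(pessimistic, sim$truth$alignments)
  expect_gt(ap$median_mapped, ap$median_predicted)
})
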