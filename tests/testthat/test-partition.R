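make_bins <- function(...) {
  seqs <- list(...)
  lapply(names(seqs), function(b)
    genome_bin(b, seq_set(paste0(b, "_c1"), seqs[[b]])))
}

test_that("read-bin metrics aggregate identity length-weighted", {
  one <- aln_row(cigar = "950=50X")
  m <- read_bin_metrics(1000, one)
  expect_equal(unname(m), c(95.0, 1.0))
  two <- alignment_table(rbind(aln_row(cigar = "400=", query_start = 0),
                               aln_row(cigar = "400=", query_start = 500)))
  m2 <- read_bin_metrics(1000, two)
  expect_equal(unname(m2), c(100.0, 0.8))
  expect_equal(unname(read_bin_metrics(1000, nanomag:::empty_alignments())),
               c(0, 0))
})

test_that("assignment applies both inclusive thresholds", {
  bins <- make_bins(A = rand_dna(5000, 1), B = rand_dna(5000, 2))
  reads <- uniform_reads(c("pass", "lowid", "multi"),
                         replicate(3, rand_dna(1000)), 20L)
  a <- alignment_table(rbind(
    aln_row("pass", "A_c1", cigar = paste0("920=", "80X")),   # 92%, 1.0
    aln_row("lowid", "A_c1", cigar = "899=101X"),             # 89.9%, 1.0
    aln_row("lowid", "B_c1", cigar = "899=101X"),
    aln_row("multi", "A_c1", cigar = "950=50X"),
    aln_row("multi", "B_c1", cigar = "940=60X")))
  res <- assign_reads(reads, bins, a)
  expect_setequal(res$clusters$A$members$read_id, c("pass", "multi"))
  expect_setequal(res$clusters$B$members$read_id, "multi")
  expect_equal(res$unassigned$read_id, "lowid")
  expect_equal(res$unassigned$identity, 89.9)
  # boundary: exactly 90 / 0.9 is kept (inclusive)
  edge <- alignment_table(aln_row("pass", "A_c1", cigar = "810=90X",
                                  query_start = 0))
  res_edge <- assign_reads(reads[1], bins, edge)
  expect_equal(res_edge$clusters$A$members$identity, 90)
  expect_equal(res_edge$clusters$A$members$fraction, 0.9)
  expect_equal(res_edge$clusters$A$n_reads, 1L)
  # unique-best keeps only the higher-identity bin
  ub <- assign_reads(reads, bins, a, unique_best = TRUE)
  expect_setequal(ub$clusters$A$members$read_id, c("pass", "multi"))
  expect_equal(ub$clusters$B$n_reads, 0L)
})

test_that("alignments to unknown contigs are ignored with a warning", {
  bins <- make_bins(A = rand_dna(2000, 3))
  reads <- uniform_reads("r1", rand_dna(1000, 4), 20L)
  a <- alignment_table(rbind(aln_row("r1", "A_c1", cigar = "1000="),
                             aln_row("r1", "ghost", cigar = "1000=")))
  expect_warning(res <- assign_reads(reads, bins, a), "not in any bin")
  expect_equal(res$clusters$A$n_reads, 1L)
})

test_that("raising either threshold never grows any cluster", {
  withr::with_seed(111, {
    bins <- make_bins(A = rand_dna(3000), B = rand_dna(3000),
                      C = rand_dna(3000))
    reads <- uniform_reads(paste0("r", 1:15),
                           replicate(15, rand_dna(1000)), 20L)
    rows <- list()
    for (r in reads$id) {
      for (b in sample(c("A_c1", "B_c1", "C_c1"), sample(0:3, 1))) {
        nx <- sample(0:150, 1)
        cov <- sample(700:1000, 1)
        rows[[length(rows) + 1]] <- aln_row(
          r, b, cigar = paste0(cov - nx, "=", if (nx) paste0(nx, "X")),
          query_start = sample(0:(1000 - cov), 1))
      }
    }
    a <- alignment_table(do.call(rbind, rows))
    sizes <- function(res) vapply(res$clusters, `[[`, integer(1), "n_reads")
    base <- sizes(assign_reads(reads, bins, a, 85, 0.8))
    expect_true(all(sizes(assign_reads(reads, bins, a, 90, 0.8)) <= base))
    expect_true(all(sizes(assign_reads(reads, bins, a, 85, 0.9)) <= base))
  })
})

test_that("assignment equals a brute-force recomputation per (read, bin)", {
  withr::with_seed(222, {
    bins <- make_bins(A = rand_dna(3000), B = rand_dna(3000),
                      C = rand_dna(3000))
    reads <- uniform_reads(paste0("r", 1:20),
                           replicate(20, rand_dna(1000)), 20L)
    rows <- list()
    for (r in reads$id) {
      for (b in sample(c("A_c1", "B_c1", "C_c1"), sample(0:2, 1))) {
        nx <- sample(0:120, 1)
        cov <- sample(800:1000, 1)
        rows[[length(rows) + 1]] <- aln_row(
          r, b, cigar = paste0(cov - nx, "=", if (nx) paste0(nx, "X")),
          query_start = sample(0:(1000 - cov), 1))
      }
    }
    a <- alignment_table(do.call(rbind, rows))
    res <- assign_reads(reads, bins, a)
    # oracle: recompute both metrics per pair from the raw rows
    for (r in reads$id) for (bn in c("A", "B", "C")) {
      sub <- a[a$query_id == r & a$target_id == paste0(bn, "_c1"), ,
               drop = FALSE]
      if (nrow(sub) == 0) {
        expect_false(r %in% res$clusters[[bn]]$members$read_id)
        next
      }
      st <- nanomag:::cpp_cigar_stats(sub$cigar)
      idy <- 100 * sum(st[, "n_eq"]) / sum(st[, "n_eq"] + st[, "n_x"] +
                                           st[, "n_i"] + st[, "n_d"])
      iv <- sort(unique(unlist(mapply(seq, sub$query_start + 1,
                                      sub$query_end, SIMPLIFY = FALSE))))
      frac <- length(iv) / 1000
      expect_equal(r %in% res$clusters[[bn]]$members$read_id,
                   idy >= 90 && frac >= 0.9)
    }
  })
})

test_that("bin coverage is total aligned target length over bin length", {
  bins <- make_bins(A = rand_dna(10000, 5))
  reads <- uniform_reads(paste0("r", 1:10),
                         replicate(10, rand_dna(1000)), 20L)
  rows <- do.call(rbind, lapply(reads$id, function(r)
    aln_row(r, "A_c1", cigar = "1000=", target_start = 0)))
  res <- assign_reads(reads, bins, alignment_table(rows))
  expect_equal(bin_coverage(res$clusters$A, bins[[1]]), 1.0)
  empty <- assign_reads(reads[0], bins, nanomag:::empty_alignments())
  expect_equal(bin_coverage(empty$clusters$A, bins[[1]]), 0.0)
})
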