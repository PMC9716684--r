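test_that("pileup columns follow CIGAR semantics", {
  contig <- seq_set("c", "ACGTA")
  a1 <- aln_row("r1", "c", cigar = "5=", query_seq = "ACGTA")
  pu <- build_pileup(contig, a1)
  expect_equal(pu$counts[cbind(1:5, match(c("A", "C", "G", "T", "A"),
                                          c("A", "C", "G", "T")))],
               rep(1L, 5))
  expect_equal(sum(pu$counts), 5L)

  a2 <- aln_row("r1", "c", cigar = "2=1D2=", query_seq = "ACTA")
  pu2 <- build_pileup(contig, a2)
  expect_equal(pu2$del, c(0L, 0L, 1L, 0L, 0L))
  expect_equal(pu2$span, rep(1L, 5))

  a3 <- aln_row("r1", "c", cigar = "2=1I2=", query_seq = "ACGGT")
  pu3 <- build_pileup(contig, a3)
  expect_equal(pu3$insertions$pos, 1)
  expect_equal(pu3$insertions$seq, "G")
  expect_equal(pu3$insertions$count, 1L)
})

test_that("consensus majority, tie and depth rules", {
  contig <- seq_set("c", "G")
  mk_pileup <- function(A = 0, C = 0, G = 0, T = 0, del = 0) {
    list(counts = matrix(as.integer(c(A, C, G, T)), 1, 4,
                         dimnames = list(NULL, c("A", "C", "G", "T"))),
         del = as.integer(del), span = as.integer(A + C + G + T + del),
         junction_span = 0L,
         insertions = data.frame(pos = numeric(), seq = character(),
                                 count = integer()))
  }
  # strict majority overrides the draft
  expect_equal(consensus(mk_pileup(A = 7, G = 3), contig)$sequence, "A")
  # base/deletion tie keeps the base
  expect_equal(consensus(mk_pileup(A = 5, del = 5),
                         seq_set("c", "A"))$sequence, "A")
  # deletion strictly ahead deletes
  expect_equal(consensus(mk_pileup(A = 2, del = 5),
                         seq_set("c", "A"))$sequence, "")
  # below min_depth the draft wins
  expect_equal(consensus(mk_pileup(A = 1), contig)$sequence, "G")
  # base tie resolves toward the draft
  expect_equal(consensus(mk_pileup(A = 4, G = 4), contig)$sequence, "G")
  # zero-depth region: draft verbatim
  z <- consensus(mk_pileup(), contig)
  expect_equal(z$sequence, "G")
  expect_equal(z$changed, 0L)
})

test_that("junction insertions require plurality and quorum", {
  contig <- seq_set("c", "ACGT")
  reads <- uniform_reads(paste0("r", 1:4), rep("ACGGT", 4) |>
                           replace(4, "ACGT"), 20L)
  rows <- rbind(aln_row("r1", "c", cigar = "2=1I2=", query_seq = "ACGGT"),
                aln_row("r2", "c", cigar = "2=1I2=", query_seq = "ACGGT"),
                aln_row("r3", "c", cigar = "2=1I2=", query_seq = "ACGGT"),
                aln_row("r4", "c", cigar = "4=", query_seq = "ACGT"))
  pu <- build_pileup(contig, alignment_table(rows))
  out <- consensus(pu, contig)
  expect_equal(out$sequence, "ACGGT")
  expect_equal(out$n_ins, 1L)
  # 1 of 4 inserting reads is below the 0.5 quorum
  rows2 <- rbind(rows[4:4, ], rows[4:4, ], rows[4:4, ], rows[1, ])
  rows2$query_id <- paste0("q", 1:4)
  out2 <- consensus(build_pileup(contig, alignment_table(rows2)), contig)
  expect_equal(out2$sequence, "ACGT")
})

test_that("polishing the truth with error-free reads is a fixed point", {
  g <- generate_genome(20000, seed = 101, id = "bin1")
  spec <- community_spec(g, 1, total_bases = 4e5,
                         model = error_model_preset("error-free"),
                         seed = 103)
  sim <- simulate_reads(spec)
  res <- polish_bin(genome_bin("bin1", g), whole_cluster("bin1", sim$reads),
                    sim$reads, rounds = 2)
  expect_identical(res$bin$contigs$seq, g$seq)
  expect_true(res$report$converged)
  expect_equal(res$report$changed_per_round[1], 0L)
})

test_that("planted substitutions are corrected in one round", {
  g <- generate_genome(20000, seed = 107, id = "bin1")
  spec <- community_spec(g, 1, total_bases = 4e5,
                         model = error_model_preset("error-free"),
                         seed = 109)
  sim <- simulate_reads(spec)
  corrupted <- withr::with_seed(113, {
    ch <- strsplit(g$seq, "")[[1]]
    at <- sample(2000:18000, 50)  # inside the well-covered interior
    ch[at] <- vapply(ch[at], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    seq_set("bin1", paste(ch, collapse = ""))
  })
  res <- polish_bin(genome_bin("bin1", corrupted),
                    whole_cluster("bin1", sim$reads), sim$reads, rounds = 2)
  expect_identical(res$bin$contigs$seq, g$seq)
  expect_equal(res$report$changed_per_round, c(50L, 0L))
  expect_true(res$report$converged)
})

test_that("rounds = 0 returns the draft untouched", {
  g <- seq_set("bin1", rand_dna(2000, 1))
  reads <- uniform_reads("r1", substring(g$seq, 1, 1500), 20L)
  res <- polish_bin(genome_bin("bin1", g), whole_cluster("bin1", reads),
                    reads, rounds = 0)
  expect_identical(res$bin$contigs$seq, g$seq)
  expect_equal(res$report$rounds_executed, 0L)
})

test_that("an empty cluster leaves the bin unpolished with a warning", {
  g <- seq_set("bin1", rand_dna(2000, 2))
  empty <- structure(list(bin_id = "bin1",
                          members = data.frame(read_id = character()),
                          alignments = NULL, n_reads = 0L),
                     class = "read_cluster")
  expect_warning(res <- polish_bin(genome_bin("bin1", g), empty,
                                   uniform_reads("r", "ACGT", 20L)),
                 "empty")
  expect_identical(res$bin$contigs$seq, g$seq)
})

test_that("polishing a bin depends only on its own draft and cluster", {
  g <- generate_genome(15000, seed = 127, id = "bin1")
  spec <- community_spec(g, 1, total_bases = 3e5,
                         model = error_model(0.02, 0.02, 0.02), seed = 131)
  sim <- simulate_reads(spec)
  cl <- whole_cluster("bin1", sim$reads)
  res1 <- polish_bin(genome_bin("bin1", g), cl, sim$reads, rounds = 1)
  # permute the member order (as reshuffling other bins would)
  perm <- withr::with_seed(137, sample(nrow(cl$members)))
  cl2 <- cl
  cl2$members <- cl$members[perm, , drop = FALSE]
  res2 <- polish_bin(genome_bin("bin1", g), cl2, sim$reads, rounds = 1)
  expect_identical(res1$bin$contigs$seq, res2$bin$contigs$seq)
})
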