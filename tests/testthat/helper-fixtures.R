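# Shared fixture builders: everything is generated in code at test time.

# a seq_set of reads with uniform quality
uniform_reads <- function(ids, seqs, q) {
  seq_set(ids, seqs, lapply(nchar(seqs), function(n) rep.int(q, n)))
}

# build an aln_tbl row from minimal fields
aln_row <- function(query_id = "r1", target_id = "c1", strand = "+",
                    query_start = 0, query_end = NULL, target_start = 0,
                    target_end = NULL, cigar, query_seq = NA_character_) {
  st <- nanomag:::cpp_cigar_stats(cigar)
  if (is.null(query_end)) query_end <- query_start + st[1, "qspan"]
  if (is.null(target_end)) target_end <- target_start + st[1, "tspan"]
  alignment_table(data.frame(
    query_id = query_id, target_id = target_id, strand = strand,
    query_start = query_start, query_end = query_end,
    target_start = target_start, target_end = target_end,
    cigar = cigar, query_seq = query_seq, stringsAsFactors = FALSE))
}

rand_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# single-cluster stand-in when partitioning is not under test
whole_cluster <- function(bin_id, reads) {
  structure(list(bin_id = bin_id,
                 members = data.frame(read_id = reads$id, identity = 100,
                                      fraction = 1,
                                      stringsAsFactors = FALSE),
                 alignments = NULL, n_reads = length(reads),
                 total_bases = sum(nchar(reads$seq)),
                 min_identity = 0, min_fraction = 0),
            class = "read_cluster")
}

# a reference genome studded with homopolymer runs of a given length:
# each block is a random spacer whose flanks differ from the run base
hp_run_genome <- function(n_runs, run_len = 5L, spacer = 60L, seed = 1L) {
  withr::with_seed(seed, {
    blocks <- character(n_runs)
    for (i in seq_len(n_runs)) {
      sp <- sample(c("A", "C", "G", "T"), spacer, replace = TRUE)
      b <- sample(setdiff(c("A", "C", "G", "T"), sp[spacer]), 1L)
      sp2_first <- sample(setdiff(c("A", "C", "G", "T"), b), 1L)
      blocks[i] <- paste0(paste(sp, collapse = ""), strrep(b, run_len),
                          sp2_first)
    }
    seq_set("hpref", paste(blocks, collapse = ""))
  })
}
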