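test_that("the reference builder is deterministic and lays out the locus as configured", {
  r1 <- make_reference(seed = 55)
  r2 <- make_reference(seed = 55)
  expect_identical(as.character(r1$seqs), as.character(r2$seqs))
  r3 <- make_reference(seed = 56)
  expect_false(identical(as.character(r1$seqs), as.character(r3$seqs)))

  expect_equal(length(r1$seqs[["chrA"]]), 200000)
  expect_equal(sum(r1$exons$kind == "canonical"), 8)
  expect_gt(sum(r1$exons$kind %in% c("cryptic", "upstream")), 0)
  # exon sequences contain no ambiguity bases
  for (i in which(r1$exons$chrom == "chrA")) {
    s <- ref_fetch(r1$seqs, "chrA", r1$exons$start[i], r1$exons$end[i])
    expect_false(grepl("N", s, fixed = TRUE))
  }
  expect_error(make_reference(seed = 1, locus_len = 60000), "too short")
})

test_that("clone fractions must sum to one", {
  expect_error(sample_spec("x", list(clone_spec(0.5), clone_spec(0.4))),
               "sum to 1")
  expect_silent(sample_spec("x", list(clone_spec(0.5), clone_spec(0.5))))
})

test_that("read simulation is a pure function of the seed", {
  smp <- sample_spec("s", list(clone_spec(1.0, list(STD_DEL), locus_cn = 2)))
  a1 <- simulate_dna(smp, REF, sim_config(coverage = 5), seed = 3)$aln
  a2 <- simulate_dna(smp, REF, sim_config(coverage = 5), seed = 3)$aln
  expect_identical(a1, a2)
  a3 <- simulate_dna(smp, REF, sim_config(coverage = 5), seed = 4)$aln
  expect_false(identical(a1, a3))
  # FASTQ emission is likewise reproducible
  f1 <- tempfile(); f2 <- tempfile()
  write_fastq(a1, f1); write_fastq(a2, f2)
  expect_identical(readLines(paste0(f1, "_1.fastq")),
                   readLines(paste0(f2, "_1.fastq")))
})

test_that("total emitted bases conserve the configured coverage within 2%", {
  sim <- std_neutral_sample()
  pri <- !argsr:::has_flag(sim$aln$flag, argsr:::FLAG_SUPP)
  total <- sum(nchar(sim$aln$seq[pri]))
  genome <- sum(length(REF$seqs[["chrA"]]), length(REF$seqs[["chrB"]]))
  expect_lt(abs(total - 100 * genome) / (100 * genome), 0.02)
})

test_that("a sample with no events produces no discordant or split evidence", {
  sim <- std_neutral_sample()
  a <- sim$aln
  expect_equal(sum(!is.na(a$sa)), 0)
  expect_equal(sum(!argsr:::has_flag(a$flag, argsr:::FLAG_PROPER) &
                     !argsr:::has_flag(a$flag, argsr:::FLAG_SUPP)), 0)
  s <- extract_support(STD_DEL, a)
  expect_equal(unname(s), c(0L, 0L))
})

test_that("junction-crossing read counts match the generator's own geometry", {
  sim <- std_del_sample()
  s <- extract_support(STD_DEL, sim$aln)
  # expected split reads: read-start density times crossing positions.
  rl <- 150
  # clone genome: chrA minus the deleted span, plus chrB
  La <- 200000 - (127617 - 120000 - 1)
  nfrag_a <- round(La * 100 / (2 * rl))
  e_sr <- 2 * nfrag_a * (rl - 1) / La
  expect_lt(abs(s[["sr"]] - e_sr), 3 * sqrt(e_sr) + 1)
  expect_gt(s[["pe"]], 10)
})

test_that("copy number scales coverage over the locus region", {
  smp <- sample_spec("cn3", list(clone_spec(1.0, list(), locus_cn = 3)))
  sim <- simulate_dna(smp, REF, sim_config(coverage = 40), seed = 21)
  cov_locus <- mean_coverage(sim$aln, REF$gene)
  cov_ctrl <- mean_coverage(sim$aln, REF$controls$C1)
  expect_lt(abs(cov_locus / cov_ctrl - 1.5), 0.1)
})

test_that("spliced simulation respects expression weights and transcript structure", {
  d0 <- derivative_new(list(chrA = LOCUS_WIN), name = "g0")
  # near-identical mRNA lengths so junction-crossing probability cancels
  t_a <- make_transcript(d0, REF$seqs, REF$exons, c("exon 1", "exon 2"),
                         name = "tA", weight = 9)
  t_b <- make_transcript(d0, REF$seqs, REF$exons, c("exon 1", "exon 3"),
                         name = "tB", weight = 1)
  aln <- simulate_rna_reads(list(t_a, t_b), sim_config(rna_pairs = 6000),
                            seed = 8, sample = "w")
  js <- extract_junctions(aln)
  j <- js$junctions
  key_a <- j$donor == t_a$exons$dend[1] - 1 & j$acceptor == t_a$exons$dstart[2]
  key_b <- j$donor == t_b$exons$dend[1] - 1 & j$acceptor == t_b$exons$dstart[2]
  expect_equal(sum(key_a), 1); expect_equal(sum(key_b), 1)
  na <- j$count[key_a]; nb <- j$count[key_b]
  # binomial check on the 9:1 ratio
  p <- stats::binom.test(na, na + nb, p = 0.9)$p.value
  expect_gt(p, 0.001)
  # junction gaps fall exactly at exon boundaries
  expect_true(all(j$donor %in% c(t_a$exons$dend - 1, t_b$exons$dend - 1)))
  expect_true(all(j$acceptor %in% c(t_a$exons$dstart, t_b$exons$dstart)))
})

test_that("a single-exon transcript emits no spliced junctions", {
  d0 <- derivative_new(list(chrA = LOCUS_WIN), name = "g0")
  t1 <- make_transcript(d0, REF$seqs, REF$exons, "exon 1", name = "mono")
  aln <- simulate_rna_reads(list(t1), sim_config(rna_pairs = 500), seed = 2)
  expect_equal(nrow(extract_junctions(aln)$junctions), 0)
})

test_that("a rearrangement-dependent exon chain cannot be built on a genome lacking the event", {
  d0 <- derivative_new(list(chrA = LOCUS_WIN), name = "g0")
  # 4-ups lies upstream of exon 3 in the unrearranged genome: not colinear
  expect_error(make_transcript(d0, REF$seqs, REF$exons,
                               c("exon 1", "exon 2", "exon 3", "4-ups")),
               "not colinear")
})

test_that("caller emulation reproduces the truth and controls jitter/decoys", {
  dup <- bfj(breakend("chrA", 125000), breakend("chrA", 118500))
  cs0 <- emit_caller_callsets(list(STD_DEL, dup), seed = 5)
  for (set in cs0) {
    expect_equal(nrow(set), 2)
    expect_equal(set$pos1, c(STD_DEL$left$pos, dup$left$pos))
    expect_equal(set$svclass, c("deletion", "duplication"))
  }
  # deterministic in seed
  cs1 <- emit_caller_callsets(list(STD_DEL), seed = 5, jitter_bp = 400)
  cs2 <- emit_caller_callsets(list(STD_DEL), seed = 5, jitter_bp = 400)
  expect_identical(cs1, cs2)
  # jitter 400 on both sides still merges under the 1 kb rule
  merged <- merge_callsets(cs1$A, cs1$B)
  expect_equal(nrow(merged), 1)
  # caller-unique decoys never merge
  cs3 <- emit_caller_callsets(list(STD_DEL), seed = 6, fp_count = 5,
                              decoy_region = genomic_interval("chrA", 5000,
                                                              60000))
  expect_equal(nrow(cs3$A), 6)
  m3 <- merge_callsets(cs3$A, cs3$B)
  expect_equal(nrow(m3), 1)
  expect_equal(m3$svclass, "deletion")
  # false negatives drop calls from a set
  cs4 <- emit_caller_callsets(list(STD_DEL, dup), seed = 7, fn_rate = 1)
  expect_equal(nrow(cs4$A), 0)
})

test_that("SAM text round-trips through the writer/reader pair", {
  sim <- cached("sam_small", {
    smp <- sample_spec("s", list(clone_spec(1.0, list(STD_DEL), locus_cn = 2)))
    simulate_dna(smp, REF, sim_config(coverage = 3), seed = 44)
  })
  f <- tempfile(fileext = ".sam")
  write_sam(sim$aln, f, seqinfo = c(chrA = 200000L, chrB = 50000L))
  back <- read_sam(f)
  orig <- sim$aln[order(sim$aln$rname, sim$aln$pos), ]
  rownames(orig) <- NULL
  expect_equal(nrow(back), nrow(orig))
  for (col in c("flag", "rname", "pos", "cigar", "seq")) {
    expect_identical(back[[col]], orig[[col]], label = col)
  }
  expect_identical(is.na(back$sa), is.na(orig$sa))
})
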