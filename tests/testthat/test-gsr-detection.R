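mk_call <- function(caller, c1, p1, c2, p2, class = "deletion",
                    o1 = "+", o2 = "+", precise = FALSE) {
  data.frame(caller = caller, chrom1 = c1, pos1 = p1, orient1 = o1,
             chrom2 = c2, pos2 = p2, orient2 = o2, svclass = class,
             qual = 50, precise = precise, stringsAsFactors = FALSE)
}

test_that("the 1 kb consensus rule is inclusive and applies to both breakends", {
  a <- mk_call("lumpy", "chrX", 100000, "chrX", 150000)
  near <- mk_call("delly", "chrX", 100999, "chrX", 150000)
  at <- mk_call("delly", "chrX", 101000, "chrX", 150000)
  beyond <- mk_call("delly", "chrX", 101001, "chrX", 150000)
  expect_equal(nrow(merge_callsets(a, near)), 1)
  expect_equal(nrow(merge_callsets(a, at)), 1)
  expect_equal(nrow(merge_callsets(a, beyond)), 0)
  # the second breakend is subject to the same rule
  far2 <- mk_call("delly", "chrX", 100000, "chrX", 151001)
  expect_equal(nrow(merge_callsets(a, far2)), 0)
})

test_that("consensus requires both callers, matching class and chromosome pair", {
  a <- mk_call("lumpy", "chrX", 100000, "chrX", 150000)
  expect_equal(nrow(merge_callsets(a, a[0, ])), 0)
  b_class <- mk_call("delly", "chrX", 100000, "chrX", 150000,
                     class = "duplication")
  expect_equal(nrow(merge_callsets(a, b_class)), 0)
  b_chrom <- mk_call("delly", "chr11", 100000, "chrX", 150000,
                     class = "deletion")
  expect_equal(nrow(merge_callsets(a, b_chrom)), 0)
  b <- mk_call("delly", "chrX", 100400, "chrX", 149800)
  expect_equal(nrow(merge_callsets(a, b)), 1)
  three <- rbind(a, b, mk_call("manta", "chrX", 1, "chrX", 2))
  expect_error(merge_callsets(three, b), "more than two caller")
})

test_that("matching is one-to-one, greedy by summed distance, and symmetric in count", {
  a <- rbind(mk_call("lumpy", "chrX", 100000, "chrX", 150000),
             mk_call("lumpy", "chrX", 100900, "chrX", 150000))
  b <- mk_call("delly", "chrX", 100100, "chrX", 150000)
  m <- merge_callsets(a, b)
  expect_equal(nrow(m), 1)           # one b call participates once
  expect_equal(m$pos1, 100000)       # nearest a wins, coordinates from set_a
  m_rev <- merge_callsets(b, a)
  expect_equal(nrow(m_rev), 1)
  expect_identical(m_rev$svclass, m$svclass)
  # consensus coordinates prefer the split-read-precise call
  bp <- mk_call("delly", "chrX", 100100, "chrX", 150050, precise = TRUE)
  mp <- merge_callsets(a, bp)
  expect_equal(mp$pos1, 100100)
})

test_that("validation enforces the gene body and the ten/ten support rule", {
  gb <- genomic_interval("chrA", 90000, 150000)
  cand <- merge_callsets(mk_call("lumpy", "chrA", 100000, "chrA", 120000),
                         mk_call("delly", "chrA", 100000, "chrA", 120000))
  cand$pe_support <- 10L; cand$sr_support <- 10L
  expect_identical(filter_candidates(cand, gb)$status, "validated")
  cand$pe_support <- 9L; cand$sr_support <- 50L
  expect_identical(filter_candidates(cand, gb)$status, "filtered")
  cand$pe_support <- 50L; cand$sr_support <- 9L
  expect_identical(filter_candidates(cand, gb)$status, "filtered")
  # both breakends outside the gene body
  out <- merge_callsets(mk_call("lumpy", "chrA", 10000, "chrA", 20000),
                        mk_call("delly", "chrA", 10000, "chrA", 20000))
  out$pe_support <- 50L; out$sr_support <- 50L
  expect_identical(filter_candidates(out, gb)$status, "filtered")
  # one breakend inside suffices
  half <- merge_callsets(mk_call("lumpy", "chrA", 10000, "chrA", 120000),
                         mk_call("delly", "chrA", 10000, "chrA", 120000))
  half$pe_support <- 50L; half$sr_support <- 50L
  expect_identical(filter_candidates(half, gb)$status, "validated")
})

test_that("raising support thresholds never adds validated events", {
  gb <- genomic_interval("chrA", 90000, 150000)
  set.seed(31)
  cand <- do.call(rbind, lapply(1:30, function(i) {
    m <- merge_callsets(
      mk_call("lumpy", "chrA", 90000 + i * 100, "chrA", 120000 + i * 100),
      mk_call("delly", "chrA", 90000 + i * 100, "chrA", 120000 + i * 100))
    m$pe_support <- sample(0:30, 1); m$sr_support <- sample(0:30, 1)
    m
  }))
  prev <- Inf
  for (thr in c(0L, 5L, 10L, 20L)) {
    n <- sum(filter_candidates(cand, gb, min_pe = thr,
                               min_sr = thr)$status == "validated")
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("support extraction enforces mapping quality, duplicates and sorting", {
  sim <- std_del_sample()
  a <- sim$aln
  s <- extract_support(STD_DEL, a)
  expect_gte(s[["pe"]], 10); expect_gte(s[["sr"]], 10)
  # mapping quality below 20 removes all evidence
  low <- a; low$mapq <- 19L
  expect_equal(unname(extract_support(STD_DEL, low)), c(0L, 0L))
  # duplicate-flagged reads are excluded
  dup <- a; dup$flag <- dup$flag + argsr:::FLAG_DUP
  expect_equal(unname(extract_support(STD_DEL, dup)), c(0L, 0L))
  # unsorted stream is an input error
  expect_error(extract_support(STD_DEL, a[rev(seq_len(nrow(a))), ]),
               "not coordinate-sorted")
})

test_that("engineered split reads are counted exactly once each", {
  n <- 30
  rows <- list()
  for (i in seq_len(n)) {
    m <- 100L + i %% 40                       # aligned bases left of the seam
    qn <- sprintf("sr%02d", i)
    rows[[length(rows) + 1]] <- data.frame(   # primary: ends at the left breakend
      qname = qn, flag = 65L, rname = "chrA", pos = 120002L - m,
      mapq = 60L, cigar = sprintf("%dM%dS", m, 150L - m),
      rnext = "chrA", pnext = 1L, tlen = 0L, seq = strrep("A", 150),
      sa = "chrA,127618,+,x,60,0;", stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- data.frame(   # supplementary: starts at the right
      qname = qn, flag = 65L + 2048L, rname = "chrA",
      pos = 127618L, mapq = 60L, cigar = sprintf("%dS%dM", m, 150L - m),
      rnext = "chrA", pnext = 1L, tlen = 0L, seq = strrep("A", 150),
      sa = "chrA,1,+,x,60,0;", stringsAsFactors = FALSE)
  }
  aln <- do.call(rbind, rows)
  aln <- aln[order(aln$rname, aln$pos), ]
  s <- extract_support(STD_DEL, aln)
  expect_equal(s[["sr"]], n)
})

test_that("the cDNA-contamination rule flags all-splice-coincident deletion sets", {
  ex <- REF$exons[REF$exons$kind == "canonical", ]
  intron_del <- function(i, shift = 0) {
    m <- merge_callsets(
      mk_call("lumpy", "chrA", ex$end[i] - 1 + shift, "chrA", ex$start[i + 1]),
      mk_call("delly", "chrA", ex$end[i] - 1 + shift, "chrA", ex$start[i + 1]))
    m$pe_support <- 20L; m$sr_support <- 20L
    m
  }
  three <- rbind(intron_del(1), intron_del(2), intron_del(3))
  f <- flag_cdna_contamination(three, ex)
  expect_true(f$contaminated)
  expect_true(all(f$candidates$splice_coincident))
  # tolerance: a 5 bp shift still coincides, 6 bp does not
  expect_true(flag_cdna_contamination(intron_del(1, 5), ex)$contaminated)
  expect_false(flag_cdna_contamination(intron_del(1, 6), ex)$contaminated)
  # one mid-intron deletion rescues the sample
  mid <- merge_callsets(
    mk_call("lumpy", "chrA", ex$end[1] + 5000, "chrA", ex$end[1] + 9000),
    mk_call("delly", "chrA", ex$end[1] + 5000, "chrA", ex$end[1] + 9000))
  mid$pe_support <- 20L; mid$sr_support <- 20L
  expect_false(flag_cdna_contamination(rbind(three, mid), ex)$contaminated)
  # no candidates, no flag
  empty <- flag_cdna_contamination(three[0, ], ex)
  expect_false(empty$contaminated)
})

test_that("full detection validates implanted events and reports contaminated samples negative", {
  sim <- std_del_sample()
  cs <- emit_caller_callsets(list(STD_DEL), seed = 9, jitter_bp = 3,
                             fp_count = 3,
                             decoy_region = genomic_interval("chrA", 5000,
                                                             60000))
  det <- detect_gsrs(cs$A, cs$B, sim$aln,
                     gene_body = REF$gene,
                     exons = REF$exons[REF$exons$kind == "canonical", ],
                     sample = "s_del")
  expect_equal(sum(det$events$status == "validated"), 1)
  expect_identical(det$events$svclass[det$events$status == "validated"],
                   "deletion")
  expect_true(det$gsr_positive)
  expect_false(det$contaminated)
})
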