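
test_that("a duplication-dependent junction set assembles into three variant models sharing exons 1-3", {
  fx <- dup_rna_fixture()
  calls <- call_rearrangement_dependent(fx$case, fx$ctrl, fx$d)
  bins <- make_bins(fx$d, REF$exons[REF$exons$chrom == "chrA", ])
  txs <- assemble_transcripts(calls, bins, fx$d, REF$seqs,
                              start_exon = "exon 1")
  chains <- vapply(txs, function(t) paste(t$exons$label, collapse = ">"),
                   character(1))
  vchains <- chains[grepl("-ups", chains)]
  expect_length(vchains, 3)
  expect_true(all(startsWith(vchains, "exon 1>exon 2>exon 3>4-ups (copy 2)>")))
  # one canonical model survives alongside
  expect_true(any(grepl("exon 8$", chains)))
  # exact mRNA recovery of every simulated variant transcript
  for (v in fx$variants) {
    expect_equal(sum(vapply(txs, function(t) identical(t$mrna, v$mrna),
                            logical(1))), 1, label = v$name)
  }
})

test_that("the full RNA round trip reproduces the generator's proteins, extensions and NLS flags", {
  fx <- dup_rna_fixture()
  canon <- canonical_protein()
  calls <- call_rearrangement_dependent(fx$case, fx$ctrl, fx$d)
  bins <- make_bins(fx$d, REF$exons[REF$exons$chrom == "chrA", ])
  txs <- assemble_transcripts(calls, bins, fx$d, REF$seqs,
                              start_exon = "exon 1")
  for (v in fx$variants) {
    truth <- translate_orf(v, CDS_OFFSET, canon)
    hit <- Filter(function(t) identical(t$mrna, v$mrna), txs)
    expect_length(hit, 1)
    got <- translate_orf(hit[[1]], CDS_OFFSET, canon)
    expect_identical(got$sequence, truth$sequence)
    expect_identical(got$cterm_extension, truth$cterm_extension)
    expect_identical(got$nls_like, truth$nls_like)
    expect_true(got$nls_like)            # planted VRRGR motifs
    expect_identical(got$nls_motif, "VRRGR")
  }
})

test_that("a translocation recruits a partner-chromosome terminal exon with a 13-residue extension", {
  tr <- bfj(breakend("chrA", 121000), breakend("chrB", 41000))
  wins <- list(chrA = LOCUS_WIN, chrB = genomic_interval("chrB", 0, 50000))
  d <- build_derivative(list(tr), wins, name = "der_tr")
  v <- make_transcript(d, REF$seqs, REF$exons,
                       c("exon 1", "exon 2", "exon 3", "B-term"), name = "vB")
  p <- translate_orf(v, CDS_OFFSET, canonical_protein())
  expect_equal(nchar(p$cterm_extension), 13)
  expect_true(p$nls_like)
  expect_identical(p$nls_motif, "VGKTK")
  # molecular weight in the truncated-receptor range, far below full length
  expect_lt(p$mol_weight, molecular_weight(canonical_protein()))
})

test_that("a canonical junction set reproduces the canonical protein with no extension", {
  d0 <- derivative_new(list(chrA = LOCUS_WIN), name = "g0")
  canon_tx <- make_transcript(d0, REF$seqs, REF$exons, paste("exon", 1:8))
  canon <- canonical_protein()
  p <- translate_orf(canon_tx, CDS_OFFSET, canon)
  expect_identical(p$sequence, canon)
  expect_identical(p$cterm_extension, "")
  expect_false(p$nls_like)
})

test_that("translation matches an independent codon-table oracle", {
  expect_identical(translate_orf("ATGTAA", 0)$sequence, "M")
  set.seed(99)
  for (i in 1:200) {
    n <- sample(5:60, 1)
    mrna <- paste0("ATG", paste(sample(c("A", "C", "G", "T"), 3 * n,
                                       replace = TRUE), collapse = ""))
    got <- translate_orf(mrna, 0)
    expect_identical(got$sequence, oracle_translate(mrna), label = mrna)
  }
  # engineered toy: canonical exons 1-3 then a cassette encoding
  # VGKTKSGVEDNLL and a stop, in frame
  d0 <- derivative_new(list(chrA = LOCUS_WIN))
  e123 <- make_transcript(d0, REF$seqs, REF$exons,
                          c("exon 1", "exon 2", "exon 3"))$mrna
  cds_len <- nchar(e123) - CDS_OFFSET
  pad <- strrep("G", (3 - cds_len %% 3) %% 3)
  codons <- c(V="GTG", G="GGT", K="AAA", T="ACT", S="TCT", E="GAA", D="GAT",
              N="AAT", L="CTG")
  cassette <- paste0(pad, paste(codons[strsplit("VGKTKSGVEDNLL", "")[[1]]],
                                collapse = ""), "TAA")
  toy <- paste0(e123, cassette)
  canon <- canonical_protein()
  p <- translate_orf(toy, CDS_OFFSET, canon)
  # 13 planted residues, plus possibly one frame-bridging residue at the seam
  expect_true(nchar(p$cterm_extension) %in% c(13L, 14L))
  expect_true(grepl("VGKTKSGVEDNLL$", p$sequence))
})

test_that("translation without an in-frame stop is flagged, not an error", {
  mrna <- paste0("ATG", strrep("GGT", 20))
  p <- translate_orf(mrna, 0)
  expect_true(p$non_stop)
  expect_equal(nchar(p$sequence), 21)
  expect_error(translate_orf("CCCGGG", 0), "no ATG")
})

test_that("NLS-like scanning follows the basic-residue window rule", {
  expect_true(scan_nls_like("VRRGRAAAA")$flag)
  expect_identical(scan_nls_like("VRRGRAAAA")$motif, "VRRGR")
  expect_true(scan_nls_like("VGKTKSGVEDNLL")$flag)
  expect_false(scan_nls_like("AAAAAAA")$flag)
  # invariant to residues beyond the scan window (first 15 residues fixed)
  a <- scan_nls_like(paste0("AAVRRGRAAAAAAAA", strrep("A", 20)))
  b <- scan_nls_like(paste0("AAVRRGRAAAAAAAA", strrep("K", 20)))
  expect_identical(a$flag, b$flag)
  expect_identical(a$motif, b$motif)
  # a motif outside the window is not seen
  expect_false(scan_nls_like(paste0(strrep("A", 16), "VRRGR"))$flag)
})

test_that("molecular weight uses average masses and is additive", {
  expect_lt(abs(molecular_weight("G") - 75.07), 0.01)
  expect_error(molecular_weight(""), "empty")
  expect_error(molecular_weight("GX"), "unknown residue")
  set.seed(12)
  for (i in 1:10) {
    a <- paste(sample(names(argsr:::AA_AVG_MASS), 8, replace = TRUE),
               collapse = "")
    b <- paste(sample(names(argsr:::AA_AVG_MASS), 5, replace = TRUE),
               collapse = "")
    expect_equal(molecular_weight(paste0(a, b)),
                 molecular_weight(a) + molecular_weight(b) -
                   argsr:::WATER_AVG_MASS,
                 tolerance = 1e-9)
  }
})

test_that("a cyclic junction graph is reported as a cycle error", {
  bins <- data.frame(label = c("exon 1", "exon 2"),
                     dstart = c(0, 1000), dend = c(200, 1200),
                     kind = "exon")
  win <- genomic_interval("chrA", 0, 5000)
  d <- derivative_new(list(chrA = win))
  calls <- data.frame(donor = c(199, 1199), acceptor = c(1000, 0),
                      count = c(5L, 5L))
  expect_error(assemble_transcripts(calls, bins, d, REF$seqs,
                                    start_exon = "exon 1"),
               "cyclic")
})
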