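# Toy coordinates small enough to assemble and inspect sequences directly;
# the published hg19 junctions are exercised coordinate-only.

test_that("an empty junction list yields the window with identity liftover", {
  win <- genomic_interval("tA", 100, 5100)
  d <- build_derivative(list(), win)
  expect_equal(der_length(d), 5000)
  src <- der_lift(d, c(0, 2500, 4999))
  expect_equal(src$pos, c(100, 2600, 5099))
  expect_equal(der_lift_back(d, "tA", 100), 0)
  expect_equal(nrow(der_seams(d)), 0)
})

test_that("the published 379 kb tandem duplication is reproduced from its breakends", {
  dup <- parse_bfj("chrX:66,909,930 (+)/chrX:66,530,990 (+)")
  win <- parse_region("chrX:66,400,000-67,050,000")
  d <- build_derivative(list(dup), win)
  added <- der_length(d) - gi_width(win)
  expect_equal(added, 378941)
  expect_equal(round(added / 1000), 379)
  # the duplicated source interval appears twice
  expect_length(der_lift_back(d, "chrX", 66700000), 2)
  expect_length(der_lift_back(d, "chrX", 66950000), 1)
})

test_that("deletion and duplication change the length by the bracketed span", {
  ref <- toy_reference()
  win <- genomic_interval("tA", 0, 6000)
  del <- bfj(breakend("tA", 1000), breakend("tA", 1500))
  d <- build_derivative(list(del), win)
  expect_equal(der_length(d), 6000 - (1500 - 1000 - 1))
  # assembled sequence equals prefix + suffix of the source (sequence-level
  # oracle)
  src <- as.character(ref[["tA"]])
  expect_identical(der_sequence(d, ref),
                   paste0(substr(src, 1, 1001), substr(src, 1501, 6000)))

  dup <- bfj(breakend("tA", 2000), breakend("tA", 1200))
  d2 <- build_derivative(list(dup), win)
  expect_equal(der_length(d2), 6000 + (2000 - 1200 + 1))
  expect_identical(der_sequence(d2, ref),
                   paste0(substr(src, 1, 2001), substr(src, 1201, 6000)))
})

test_that("inversion reverses the bracketed segment", {
  ref <- toy_reference()
  win <- genomic_interval("tA", 0, 6000)
  inv <- bfj(breakend("tA", 1000, "+"), breakend("tA", 1500, "-"))
  d <- build_derivative(list(inv), win)
  expect_equal(der_length(d), 6000)
  src <- as.character(ref[["tA"]])
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_identical(der_sequence(d, ref),
                   paste0(substr(src, 1, 1001), rc(substr(src, 1002, 1501)),
                          substr(src, 1502, 6000)))
  # both inversion seams are recorded; the first matches the junction
  expect_true(argsr:::junction_in_derivative(d, inv))
})

test_that("translocation splices the partner window with the inserted sequence", {
  ref <- toy_reference()
  wins <- list(tA = genomic_interval("tA", 0, 6000),
               tB = genomic_interval("tB", 0, 3000))
  tr <- bfj(breakend("tA", 2000), breakend("tB", 1000), inserted_seq = "TTTAG")
  d <- build_derivative(list(tr), wins)
  seq <- der_sequence(d, ref)
  a <- as.character(ref[["tA"]]); b <- as.character(ref[["tB"]])
  expect_identical(seq, paste0(substr(a, 1, 2001), "TTTAG",
                               substr(b, 1001, 3000)))
  # the seam sequence is source-base, insert, partner-base
  expect_identical(substr(seq, 2001, 2007),
                   paste0(substr(a, 2001, 2001), "TTTAG",
                          substr(b, 1001, 1001)))
  # both source windows are masked in the combined reference
  comb <- combined_reference(d, ref)
  expect_identical(as.character(Biostrings::subseq(comb[["tA"]], 1, 10)),
                   "NNNNNNNNNN")
  expect_true("der1" %in% names(comb))
})

test_that("liftover round-trips and splits intervals at seams", {
  dup <- parse_bfj("chrX:66,909,930 (+)/chrX:66,530,990 (+)")
  del <- parse_bfj("chrX:66,786,453 (+)/chrX:66,862,260 (+)")
  win <- parse_region("chrX:66,400,000-67,050,000")
  d <- build_derivative(list(dup), win)
  set.seed(9)
  probes <- sample(0:(der_length(d) - 1), 1000)
  src <- der_lift(d, probes)
  for (i in seq_len(1000)) {
    back <- der_lift_back(d, src$chrom[i], src$pos[i])
    expect_true(probes[i] %in% back)
    # every derivative copy lifts to the same source base
    expect_true(all(der_lift(d, back)$pos == src$pos[i]))
  }
  # interval straddling a deletion seam splits into two pieces whose source
  # gap equals the deleted length
  d2 <- build_derivative(list(del), win)
  dL <- der_lift_back(d2, "chrX", del$left$pos)
  pieces <- der_lift_interval(d2, dL - 100, dL + 101)
  expect_equal(nrow(pieces), 2)
  gap <- pieces$start[2] - pieces$end[1]
  expect_equal(gap, del$right$pos - del$left$pos - 1)
})

test_that("length conservation holds for random non-overlapping event sets", {
  win <- genomic_interval("tA", 0, 50000)
  for (seed in 1:10) {
    set.seed(seed)
    # carve disjoint slots, one event per slot
    slots <- seq(2000, 42000, by = 8000)
    events <- list(); delta <- 0
    for (s in slots) {
      kind <- sample(c("del", "dup", "ins"), 1)
      a <- s + sample(500:1500, 1); b <- a + sample(200:2000, 1)
      if (kind == "del") {
        events[[length(events) + 1]] <- bfj(breakend("tA", a), breakend("tA", b))
        delta <- delta - (b - a - 1)
      } else if (kind == "dup") {
        events[[length(events) + 1]] <- bfj(breakend("tA", b), breakend("tA", a))
        delta <- delta + (b - a + 1)
      } else {
        ins <- paste(sample(c("A", "C", "G", "T"), 7, replace = TRUE),
                     collapse = "")
        events[[length(events) + 1]] <- bfj(breakend("tA", a), breakend("tA", b),
                                            inserted_seq = ins)
        delta <- delta - (b - a - 1) + 7
      }
    }
    d <- build_derivative(events, win)
    expect_equal(der_length(d), 50000 + delta, label = paste("seed", seed))
  }
})

test_that("the three-junction single-allele architecture is reconstructed with the duplication first", {
  j_del1 <- parse_bfj("chrX:66,934,778 (+)/chrX:66,942,396 (+)")
  j_dup <- parse_bfj("chrX:66,942,924 (+)/chrX:66,939,551 (+)")
  j_del2 <- parse_bfj("chrX:66,940,040 (+)/chrX:66,943,474 (+)")
  win <- parse_region("chrX:66,900,000-66,960,000")
  rec <- reconstruct_allele(list(j_del1, j_dup, j_del2), win)
  expect_true(rec$consistent)
  expect_identical(rec$operation_order[[1]]$svclass, "duplication")
  expect_identical(vapply(rec$operation_order[2:3], function(j) j$svclass,
                          character(1)), c("deletion", "deletion"))
  # all three seams co-occur on the one derivative
  for (j in rec$junctions) {
    expect_true(argsr:::junction_in_derivative(rec$derivative, j))
  }
  expect_true(all(rec$junction_spans[upper.tri(rec$junction_spans)] > 0))
})

test_that("reconstruction agrees with a sequence-level seam oracle on a toy genome", {
  # same topology as the published three-junction allele, scaled to 20 kb
  ref <- Biostrings::DNAStringSet(c(tA = {
    set.seed(77)
    paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE), collapse = "")
  }))
  win <- genomic_interval("tA", 0, 20000)
  del1 <- bfj(breakend("tA", 4000), breakend("tA", 9500))
  dup <- bfj(breakend("tA", 10000), breakend("tA", 7000))
  del2 <- bfj(breakend("tA", 7500), breakend("tA", 11000))
  rec <- reconstruct_allele(list(del1, dup, del2), win)
  expect_true(rec$consistent)
  seq <- der_sequence(rec$derivative, ref)
  src <- as.character(ref[["tA"]])
  seam_kmer <- function(j) {
    paste0(substr(src, j$left$pos - 8, j$left$pos + 1),
           substr(src, j$right$pos + 1, j$right$pos + 10))
  }
  for (j in list(del1, dup, del2)) {
    expect_true(grepl(seam_kmer(j), seq, fixed = TRUE),
                label = format_bfj(j))
  }
})

test_that("a single deletion reconstructs trivially and erasing deletions do not", {
  win <- genomic_interval("tA", 0, 20000)
  del <- bfj(breakend("tA", 4000), breakend("tA", 6000))
  expect_true(reconstruct_allele(list(del), win)$consistent)
  # the outer deletion removes the inner junction's seam in either order
  inner <- bfj(breakend("tA", 5000), breakend("tA", 6000))
  outer <- bfj(breakend("tA", 3000), breakend("tA", 9000))
  rec <- reconstruct_allele(list(inner, outer), win)
  expect_false(rec$consistent)
  expect_null(rec$operation_order)
})

test_that("junctions referencing removed coordinates raise application errors", {
  win <- genomic_interval("tA", 0, 20000)
  del1 <- bfj(breakend("tA", 3000), breakend("tA", 9000))
  del2 <- bfj(breakend("tA", 5000), breakend("tA", 6000))
  expect_error(build_derivative(list(del1, del2), win), "not applicable")
  tr <- bfj(breakend("tA", 1000), breakend("tZ", 50))
  expect_error(build_derivative(list(tr), win), "no window")
})

test_that("the segment table exposes derivative and source coordinates", {
  win <- genomic_interval("tA", 0, 6000)
  dup <- bfj(breakend("tA", 2000), breakend("tA", 1200))
  d <- build_derivative(list(dup), win, name = "derX")
  st <- der_segment_table(d)
  expect_equal(st$derivative_start[1], 0)
  expect_equal(st$derivative_end[nrow(st)], der_length(d))
  expect_true(all(st$derivative_end - st$derivative_start ==
                    st$source_end - st$source_start))
})
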