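# Shared fixtures, built in code. The synthetic reference is deterministic in
# its seed; heavier read simulations are created inside the tests that need
# them so each file stays independently runnable.

REF <- make_reference(seed = 101)
LOCUS_WIN <- genomic_interval("chrA", 0, 200000)
CDS_OFFSET <- REF$cds_start - REF$exons$start[REF$exons$name == "exon 1"]

canonical_protein <- function() {
  d0 <- derivative_new(list(chrA = LOCUS_WIN))
  tx <- make_transcript(d0, REF$seqs, REF$exons, paste("exon", 1:8))
  translate_orf(tx, CDS_OFFSET)$sequence
}

# A small deterministic toy reference for sequence-level checks.
toy_reference <- function(seed = 5, len_a = 6000, len_b = 3000) {
  set.seed(seed)
  Biostrings::DNAStringSet(c(
    tA = paste(sample(c("A", "C", "G", "T"), len_a, replace = TRUE),
               collapse = ""),
    tB = paste(sample(c("A", "C", "G", "T"), len_b, replace = TRUE),
               collapse = "")))
}

# Independent hand-rolled codon translation used as the oracle against the
# package's translation path.
oracle_translate <- function(dna) {
  codon_tab <- c(
    TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
    ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
    TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
    ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
    TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
    AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
    TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
    AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")
  n <- nchar(dna) %/% 3
  out <- character(0)
  for (i in seq_len(n)) {
    aa <- codon_tab[[substr(dna, 3 * i - 2, 3 * i)]]
    if (aa == "*") return(paste(out, collapse = ""))
    out <- c(out, aa)
  }
  paste(out, collapse = "")
}

# Independent oracle for the two-tailed Fisher p-value: explicit
# log-binomial point masses, no hypergeometric distribution function.
oracle_fisher <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1]); n <- sum(m)
  supp <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, supp) + lchoose(r2, c1 - supp) - lchoose(n, c1)
  p <- exp(logp)
  p_obs <- p[supp == m[1, 1]]
  sum(p[p <= p_obs * (1 + 1e-12)])
}

# Bundled cohort junction strings and printed class labels.
bundled_junctions <- function() {
  tab <- ar_gsr_table()
  tab$class <- tolower(sub(" .*", "", tab$gsr))
  tab
}

# Memoised standard simulations shared across test files (built on first use).
.sim_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) assign(key, force(expr), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

STD_DEL <- bfj(breakend("chrA", 120000), breakend("chrA", 127617))

std_del_sample <- function() cached("del", {
  smp <- sample_spec("s_del", list(clone_spec(1.0, list(STD_DEL), locus_cn = 2)))
  simulate_dna(smp, REF, sim_config(coverage = 100), seed = 11)
})

std_neutral_sample <- function() cached("neutral", {
  smp <- sample_spec("s_neu", list(clone_spec(1.0, list(), locus_cn = 2)))
  simulate_dna(smp, REF, sim_config(coverage = 100), seed = 12)
})

# A duplication-bearing derivative with its expressed transcripts, shared
# across the assembly/translation tests.
dup_rna_fixture <- function() cached("dup_rna", {
  dup <- bfj(breakend("chrA", 120000), breakend("chrA", 55000))
  d <- build_derivative(list(dup), list(chrA = LOCUS_WIN), name = "der_dup")
  canon_case <- make_transcript(d, REF$seqs, REF$exons, paste("exon", 1:8),
                                copies = c(2, 2, 2, 1, 1, 1, 1, 1),
                                name = "canonical", weight = 6)
  variants <- lapply(c("5a-ups", "5b-ups", "5c-ups"), function(e) {
    make_transcript(d, REF$seqs, REF$exons,
                    c("exon 1", "exon 2", "exon 3", "4-ups", e),
                    copies = c(1, 1, 1, 2, 2), name = paste0("v_", e),
                    weight = 1)
  })
  case_aln <- simulate_rna_reads(c(list(canon_case), variants),
                                 sim_config(rna_pairs = 24000), seed = 61,
                                 sample = "caseA")
  ctrl_aln <- simulate_rna_reads(list(canon_case),
                                 sim_config(rna_pairs = 24000), seed = 62,
                                 sample = "caseB")
  list(d = d, variants = variants, case = extract_junctions(case_aln),
       ctrl = extract_junctions(ctrl_aln))
})
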