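#!/usr/bin/env Rscript
# Integrative RNA analysis of the duplication-bearing sample S3-A: build
# its tumour-specific derivative assembly, map simulated RNA-seq from S3-A
# and from a duplication-negative control tumour onto it, bin splice
# junctions into the exon/intron matrix, and call the
# rearrangement-dependent junctions.

suppressPackageStartupMessages(library(argsr))
cohort <- readRDS("scratch/cohort.rds")
ref <- make_reference(seed = cohort$seed)
lwin <- genomic_interval("chrA", 0, length(ref$seqs[["chrA"]]))

d <- build_derivative(list(cohort$events$dup_big), list(chrA = lwin),
                      name = "S3A_derivative")
message("derivative assembly: ", der_length(d), " bp (",
        der_length(d) - gi_width(lwin), " bp duplicated)")
write.table(der_segment_table(d), "results/S3A_derivative_segments.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

canon <- make_transcript(d, ref$seqs, ref$exons, paste("exon", 1:8),
                         copies = c(2, 2, 2, 1, 1, 1, 1, 1),
                         name = "canonical", weight = 6)
variants <- lapply(c("5a-ups", "5b-ups", "5c-ups"), function(e) {
  make_transcript(d, ref$seqs, ref$exons,
                  c("exon 1", "exon 2", "exon 3", "4-ups", e),
                  copies = c(1, 1, 1, 2, 2), name = paste0("ARV_", e),
                  weight = 1)
})
case_aln <- simulate_rna_reads(c(list(canon), variants),
                               sim_config(rna_pairs = 30000),
                               seed = cohort$seed + 100, sample = "S3-A")
ctrl_aln <- simulate_rna_reads(list(canon), sim_config(rna_pairs = 30000),
                               seed = cohort$seed + 101, sample = "S3-B")

case_j <- extract_junctions(case_aln)
ctrl_j <- extract_junctions(ctrl_aln)
message("case: ", case_j$retained_reads, " junction reads retained, ",
        case_j$discarded_short_overhang, " discarded (<5 bp overhang)")

bins <- make_bins(d, ref$exons[ref$exons$chrom == "chrA", ])
m_case <- junction_matrix(case_j, bins, "S3A_derivative")
m_ctrl <- junction_matrix(ctrl_j, bins, "S3A_derivative")
write_junction_matrix(m_case, "results/S3A_splice_matrix_case.tsv")
write_junction_matrix(m_ctrl, "results/S3A_splice_matrix_control.tsv")

calls <- call_rearrangement_dependent(case_j, ctrl_j, d)
write.table(calls, "results/S3A_junction_calls.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
saveRDS(list(d = d, calls = calls, bins = bins, variants = variants,
             canon = canon), "scratch/rna.rds")
n_rd <- sum(calls$status == "rearrangement_dependent")
message("wrote splice matrices and ", n_rd,
        " rearrangement-dependent junction call(s) to results/")
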