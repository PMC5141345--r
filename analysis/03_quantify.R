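#!/usr/bin/env Rscript
# Quantify the copy-number context and hotspot mutations: normalized locus
# coverage versus the five control regions, ratioed against the
# copy-neutral sample, and SNV calling over the hotspot exon under both
# rule-sets with consensus intersection.

suppressPackageStartupMessages(library(argsr))
cohort <- readRDS("scratch/cohort.rds")
ref <- make_reference(seed = cohort$seed)
ref_aln <- cohort$sims[["S5-A"]]$aln   # the copy-neutral reference sample

cn_rows <- list(); snv_rows <- list()
snv_results <- list()
e8 <- ref$exons[ref$exons$name == "exon 8", ]
hot_iv <- genomic_interval("chrA", e8$start, e8$end)

for (nm in names(cohort$sims)) {
  aln <- cohort$sims[[nm]]$aln
  prof <- copy_number(aln, ref_aln, locus = ref$gene,
                      controls = ref$controls)
  cn_rows[[nm]] <- data.frame(
    sample = nm, mean_cov_locus = round(prof$mean_cov_locus, 1),
    normalized_locus = round(prof$normalized_locus, 4),
    cn_ratio = round(prof$cn_ratio_vs_reference, 4),
    amplified = prof$amplified, stringsAsFactors = FALSE)

  cons <- consensus_snvs(call_ruleset_a(aln, hot_iv, ref$seqs),
                         call_ruleset_b(aln, hot_iv, ref$seqs))
  snv_results[[nm]] <- cons
  if (nrow(cons)) {
    cons$sample <- nm
    snv_rows[[nm]] <- cons
  }
  message(sprintf("%s: CN ratio %.2f%s, %d consensus SNV(s)", nm,
                  prof$cn_ratio_vs_reference,
                  if (prof$amplified) " (amplified)" else "", nrow(cons)))
}
saveRDS(list(cn = cn_rows, snvs = snv_results), "scratch/quantify.rds")
write.table(do.call(rbind, cn_rows), "results/copy_number.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
snvs <- if (length(snv_rows)) do.call(rbind, snv_rows) else
  data.frame(sample = character(0))
write.table(snvs, "results/snv_consensus.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
if (nrow(snvs)) {
  write_snv_vcf(snv_results[["S4-A"]], "results/S4-A_snvs.vcf")
}
message("wrote results/copy_number.tsv and results/snv_consensus.tsv")
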