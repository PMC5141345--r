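#!/usr/bin/env Rscript
# Assemble the variant transcripts implied by the observed splice
# junctions, translate them from the canonical start codon, and annotate
# the truncated-receptor features: canonical prefix, C-terminal extension,
# NLS-like basic motif, molecular weight.

suppressPackageStartupMessages(library(argsr))
cohort <- readRDS("scratch/cohort.rds")
rna <- readRDS("scratch/rna.rds")
ref <- make_reference(seed = cohort$seed)
lwin <- genomic_interval("chrA", 0, length(ref$seqs[["chrA"]]))
cds_off <- ref$cds_start - ref$exons$start[ref$exons$name == "exon 1"]

d0 <- derivative_new(list(chrA = lwin))
canon_prot <- translate_orf(
  make_transcript(d0, ref$seqs, ref$exons, paste("exon", 1:8)),
  cds_off)$sequence
message("canonical receptor: ", nchar(canon_prot), " aa, ",
        round(molecular_weight(canon_prot) / 1000, 1), " kDa")

txs <- assemble_transcripts(rna$calls, rna$bins, rna$d, ref$seqs,
                            start_exon = "exon 1")
rows <- list(); fasta <- character(0)
for (t in txs) {
  p <- translate_orf(t, cds_off, canon_prot)
  chain <- paste(t$exons$label, collapse = ">")
  rows[[t$name]] <- data.frame(
    transcript = t$name, exon_chain = chain, mrna_len = nchar(t$mrna),
    protein_len = nchar(p$sequence),
    canonical_prefix = p$canonical_prefix_len,
    cterm_extension = p$cterm_extension,
    extension_len = nchar(p$cterm_extension),
    nls_like = p$nls_like, nls_motif = p$nls_motif,
    mol_weight_kda = round(p$mol_weight / 1000, 1),
    stringsAsFactors = FALSE)
  fasta <- c(fasta, paste0(">", t$name, " ", chain), p$sequence)
  message(sprintf("%s: %s | %d aa, extension %d aa%s, %.1f kDa", t$name,
                  chain, nchar(p$sequence), nchar(p$cterm_extension),
                  if (p$nls_like) paste0(" (NLS-like ", p$nls_motif, ")")
                  else "", p$mol_weight / 1000))
}
write.table(do.call(rbind, rows), "results/arv_proteins.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(fasta, "results/arv_proteins.fasta")
message("wrote results/arv_proteins.tsv and results/arv_proteins.fasta")
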