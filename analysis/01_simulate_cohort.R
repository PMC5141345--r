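#!/usr/bin/env Rscript
# Build the synthetic study cohort: an AR-like locus and six tumour samples
# whose rearrangement classes, sub-clonal fractions and copy-number states
# mirror the structure of the clinical cohort (shared complex alleles
# between same-subject tumours, a sub-clonal translocation, a large
# duplication co-occurring with amplification, hotspot SNVs, and a
# copy-neutral GSR-negative sample that serves as the normalization
# reference). Alignments are cached under scratch/; truth tables land in
# results/.

suppressPackageStartupMessages(library(argsr))
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

SEED <- 20160
ref <- make_reference(seed = SEED)
# deep targeted coverage, as a hybrid-capture panel would deliver; needed so
# sub-clonal junctions clear the ten-read support thresholds
cfg <- sim_config(coverage = 150)

# C-6-like complex allele: tandem duplication plus two deletions on the one
# locus copy (applied in that order)
dup_c <- bfj(breakend("chrA", 125000), breakend("chrA", 121500))
del_1 <- bfj(breakend("chrA", 119000), breakend("chrA", 124000))
del_2 <- bfj(breakend("chrA", 122000), breakend("chrA", 126000))
complex_allele <- list(dup_c, del_1, del_2)

# C-12A-like 65 kb duplication spanning exons 1-3 and the upstream exons
dup_big <- bfj(breakend("chrA", 120000), breakend("chrA", 55000))
# C-9A-like translocation with a non-templated TTTAG insertion
transloc <- bfj(breakend("chrA", 121000), breakend("chrB", 41000),
                inserted_seq = "TTTAG")
hot <- ref$hotspots[1, ]
snv40 <- data.frame(pos = hot$pos, ref = hot$ref, alt = hot$alt,
                    zygosity = "hom")

samples <- list(
  sample_spec("S1-A", list(clone_spec(0.85, complex_allele, locus_cn = 1),
                           clone_spec(0.15, list(), locus_cn = 1))),
  sample_spec("S1-B", list(clone_spec(0.60, complex_allele, locus_cn = 1),
                           clone_spec(0.40, list(), locus_cn = 1))),
  sample_spec("S2-A", list(clone_spec(0.30, list(transloc), locus_cn = 1),
                           clone_spec(0.70, list(), locus_cn = 1))),
  sample_spec("S3-A", list(clone_spec(0.40, list(dup_big), locus_cn = 4),
                           clone_spec(0.60, list(), locus_cn = 4))),
  sample_spec("S4-A", list(clone_spec(0.7, list(), locus_cn = 3,
                                      snvs = snv40),
                           clone_spec(0.3, list(), locus_cn = 3))),
  sample_spec("S5-A", list(clone_spec(1.0, list(), locus_cn = 2)))  # reference
)

# the reference is rebuilt from its seed by the downstream scripts (S4
# sequence containers do not serialize portably), so only plain data goes
# into the cache
cohort <- list(cfg = cfg, seed = SEED, samples = samples,
               events = list(dup_c = dup_c, del_1 = del_1, del_2 = del_2,
                             dup_big = dup_big, transloc = transloc))
cohort$sims <- lapply(seq_along(samples), function(i) {
  s <- samples[[i]]
  message("simulating DNA reads for ", s$name)
  simulate_dna(s, ref, cfg, seed = SEED + i)
})
names(cohort$sims) <- vapply(samples, `[[`, character(1), "name")
saveRDS(cohort, "scratch/cohort.rds")

truth <- do.call(rbind, lapply(seq_along(samples), function(i) {
  t <- cohort$sims[[i]]$truth
  jv <- t$junction_vaf
  data.frame(sample = samples[[i]]$name,
             mean_locus_cn = t$mean_locus_cn,
             n_events = length(jv),
             junction = if (length(jv)) names(jv) else "",
             expected_vaf = if (length(jv)) unname(jv) else NA_real_,
             stringsAsFactors = FALSE)
}))
write.table(truth, "results/cohort_truth.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("cohort of ", length(samples), " samples simulated; truth written ",
        "to results/cohort_truth.tsv")
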