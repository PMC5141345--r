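#' SNV calling by dual threshold rule-sets and consensus
#'
#' Two caller-style rule-sets are applied to pileups of the locus and
#' intersected; only variants called by both are considered bona fide
#' mutations. Rule-set A requires at least three alternate reads, an
#' allele fraction of at least 10%, and total depth of at least 20.
#' Rule-set B filters the pileup to mapping quality >= 5 and requires an
#' allele fraction of at least 1%. Multi-allelic sites emit one record per
#' alternate allele.
#'
#' @name snv_consensus
NULL

snv_frame <- function() {
  data.frame(chrom = character(0), pos = numeric(0), ref = character(0),
             alt = character(0), depth = integer(0), alt_reads = integer(0),
             vaf = numeric(0), rule_set = character(0),
             stringsAsFactors = FALSE)
}

calls_from_pileup <- function(pu, ref_bases, rule_set, min_alt, min_vaf,
                              min_depth) {
  out <- list()
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(nrow(pu))) {
    depth <- pu$depth[i]
    if (depth < min_depth || depth == 0) next
    rb <- ref_bases[i]
    for (b in setdiff(bases, rb)) {
      altn <- pu[[b]][i]
      vaf <- altn / depth
      if (altn >= min_alt && vaf >= min_vaf) {
        out[[length(out) + 1]] <- data.frame(
          chrom = pu$chrom[i], pos = pu$pos[i], ref = rb, alt = b,
          depth = as.integer(depth), alt_reads = as.integer(altn),
          vaf = vaf, rule_set = rule_set, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(snv_frame())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @rdname snv_consensus
#' @param aln Alignment data.frame.
#' @param interval Locus interval to pile up.
#' @param reference Named `DNAStringSet` providing the reference bases.
#' @return data.frame of `SnvCall` records (chrom, pos, ref, alt, depth,
#'   alt_reads, vaf, rule_set); positions 0-based.
#' @export
call_ruleset_a <- function(aln, interval, reference) {
  pu <- pileup(aln, interval, min_mapq = 20L)
  rb <- strsplit(ref_fetch(reference, interval$chrom, interval$start,
                           interval$end), "")[[1]]
  calls_from_pileup(pu, rb, "A", min_alt = 3L, min_vaf = 0.10,
                    min_depth = 20L)
}

#' @rdname snv_consensus
#' @export
call_ruleset_b <- function(aln, interval, reference) {
  pu <- pileup(aln, interval, min_mapq = 5L)
  rb <- strsplit(ref_fetch(reference, interval$chrom, interval$start,
                           interval$end), "")[[1]]
  calls_from_pileup(pu, rb, "B", min_alt = 1L, min_vaf = 0.01,
                    min_depth = 1L)
}

#' @rdname snv_consensus
#' @param a,b Call data.frames from the two rule-sets.
#' @return The intersection keyed on (chrom, pos, ref, alt), with depth,
#'   alt count and VAF taken from rule-set A's call.
#' @export
consensus_snvs <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(snv_frame())
  key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt)
  res <- a[key(a) %in% key(b), , drop = FALSE]
  res$rule_set <- "consensus"
  rownames(res) <- NULL
  res
}

#' Write SNV calls as a minimal VCF
#'
#' @param calls SNV call data.frame.
#' @param path Output path.
#' @export
write_snv_vcf <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
               "##INFO=<ID=AD,Number=1,Type=Integer,Description=\"Alt reads\">",
               "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele fraction\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(calls)) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;AD=%d;AF=%.4f",
                       calls$chrom, as.integer(calls$pos + 1), calls$ref,
                       calls$alt, calls$depth, calls$alt_reads, calls$vaf),
               con)
  }
  invisible(path)
}
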