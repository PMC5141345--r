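#' Copy-number and variant-allele-fraction quantification
#'
#' Locus copy number is estimated by the capture-panel normalization: mean
#' read coverage of the locus divided by the mean of the mean coverages of
#' five control regions, expressed as a ratio versus the same normalized
#' quantity in a copy-number-neutral reference sample. Sub-clonal variant
#' allele fraction of a junction is the deduplicated count of supporting
#' fragments over supporting plus reference-spanning reads.
#'
#' @name allele_quantification
NULL

#' Locus copy-number profile
#'
#' @param aln Tumour-sample alignments.
#' @param reference_aln Alignments of the copy-number-neutral reference
#'   sample.
#' @param locus Locus interval (default the AR gene body).
#' @param controls Named list of control intervals (default C1..C5).
#' @param amp_threshold Ratio above which the sample is called amplified
#'   (strict `>`; the stated definition is ratio > 1, a noise margin such
#'   as 1.2 is advisable at modest coverage).
#' @param min_mapq Mapping-quality cutoff for coverage.
#' @return A list of class `copy_number_profile`: `mean_cov_locus`,
#'   `mean_cov_controls`, `normalized_locus`, `normalized_reference`,
#'   `cn_ratio_vs_reference`, `amplified`.
#' @export
copy_number <- function(aln, reference_aln, locus = ar_gene_body(),
                        controls = control_regions(), amp_threshold = 1.0,
                        min_mapq = 20L) {
  norm <- function(a) {
    loc <- mean_coverage(a, locus, min_mapq = min_mapq)
    ctl <- vapply(controls, function(ci) {
      mean_coverage(a, ci, min_mapq = min_mapq)
    }, numeric(1))
    if (any(ctl == 0)) {
      stop("control region(s) with zero coverage: ",
           paste(names(ctl)[ctl == 0], collapse = ", "))
    }
    list(loc = loc, ctl = ctl, normalized = loc / mean(ctl))
  }
  t <- norm(aln); r <- norm(reference_aln)
  ratio <- t$normalized / r$normalized
  structure(list(mean_cov_locus = t$loc, mean_cov_controls = t$ctl,
                 normalized_locus = t$normalized,
                 normalized_reference = r$normalized,
                 cn_ratio_vs_reference = ratio,
                 amplified = ratio > amp_threshold),
            class = "copy_number_profile")
}

#' @export
print.copy_number_profile <- function(x, ...) {
  cat(sprintf("locus coverage %.1fx, normalized %.3f, ratio vs reference %.3f%s\n",
              x$mean_cov_locus, x$normalized_locus, x$cn_ratio_vs_reference,
              if (x$amplified) " (amplified)" else ""))
  invisible(x)
}

#' Estimate the variant allele fraction of a junction
#'
#' Supporting evidence counts each fragment once (union of discordant-pair
#' and split-read identifiers); the reference depth is the mean count of
#' concordant, non-duplicate, unsplit reads spanning each breakend with at
#' least `min_flank` aligned bases on both sides. The 95% interval is the
#' exact binomial (Clopper-Pearson) interval.
#'
#' @param junction A [bfj()].
#' @param aln Alignment data.frame.
#' @param tol,flank_window,min_mapq As in [extract_support()].
#' @param min_flank Minimum aligned bases on each side of a breakend for a
#'   read to count as spanning.
#' @return list of class `vaf_estimate`: `supporting`,
#'   `spanning_reference`, `vaf`, `ci95`.
#' @export
estimate_vaf <- function(junction, aln, tol = 10L, flank_window = 500L,
                         min_mapq = 20L, min_flank = 5L) {
  s <- support_sets(junction, aln, tol = tol, flank_window = flank_window,
                    min_mapq = min_mapq)
  supporting <- length(union(s$pe_qnames, s$sr_qnames))

  span_at <- function(bnd) {
    keep <- aln$rname == bnd$chrom & aln$mapq >= min_mapq &
      !has_flag(aln$flag, FLAG_DUP) & !has_flag(aln$flag, FLAG_SUPP) &
      (is.na(aln$sa) | aln$sa == "") & has_flag(aln$flag, FLAG_PROPER)
    a <- aln[keep, , drop = FALSE]
    if (!nrow(a)) return(0L)
    pos0 <- a$pos - 1
    end0 <- pos0 + cigar_ref_width(a$cigar) - 1
    sum(pos0 <= bnd$pos - min_flank & end0 >= bnd$pos + min_flank)
  }
  spanning <- mean(c(span_at(junction$left), span_at(junction$right)))
  total <- supporting + spanning
  if (total <= 0) stop("zero depth at junction; VAF undefined")
  vaf <- supporting / total
  ci <- stats::binom.test(supporting, round(total))$conf.int
  structure(list(supporting = supporting, spanning_reference = spanning,
                 vaf = vaf, ci95 = c(ci[1], ci[2])),
            class = "vaf_estimate")
}

#' @export
print.vaf_estimate <- function(x, ...) {
  cat(sprintf("VAF %.3f (%d supporting / %.1f spanning; 95%% CI %.3f-%.3f)\n",
              x$vaf, x$supporting, x$spanning_reference, x$ci95[1], x$ci95[2]))
  invisible(x)
}
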