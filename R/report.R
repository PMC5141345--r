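#' Cohort-level summary (oncoprint-style table)
#'
#' Collapses per-sample pipeline results into one row per sample —
#' amplification status and copy-number ratio, consensus SNVs, validated
#' GSR count and classes, the contamination flag (a contaminated sample is
#' reported GSR-negative regardless of candidates), and maximum GSR VAF —
#' plus the 2x2 tables feeding the exact tests.
#'
#' @param results List of per-sample result lists with elements `sample`,
#'   and optionally `type`, `cn` ([copy_number()] profile), `snvs`
#'   (consensus SNV data.frame), `detection` ([detect_gsrs()] output),
#'   `vafs` (numeric vector of junction VAFs).
#' @return list with `table` (data.frame, one row per sample) and
#'   `tables` (2x2 matrices: GSR status by amplification and by mutation).
#' @export
cohort_summary <- function(results) {
  cols <- c("sample", "type", "amplified", "cn_ratio", "n_snv", "snv_alleles",
            "gsr_count", "gsr_classes", "contaminated", "gsr_positive",
            "max_gsr_vaf")
  if (!length(results)) {
    tab <- as.data.frame(stats::setNames(
      lapply(cols, function(x) character(0)), cols))
    return(list(table = tab, tables = NULL))
  }
  rows <- lapply(results, function(r) {
    det <- r$detection
    events <- if (is.null(det)) NULL else det$events
    validated <- if (is.null(events)) 0L else sum(events$status == "validated")
    contaminated <- isTRUE(det$contaminated)
    classes <- if (validated > 0 && !contaminated) {
      paste(sort(unique(events$svclass[events$status == "validated"])),
            collapse = ",")
    } else ""
    snvs <- r$snvs
    data.frame(
      sample = r$sample,
      type = if (is.null(r$type)) NA_character_ else r$type,
      amplified = if (is.null(r$cn)) NA else r$cn$amplified,
      cn_ratio = if (is.null(r$cn)) NA_real_ else r$cn$cn_ratio_vs_reference,
      n_snv = if (is.null(snvs)) 0L else nrow(snvs),
      snv_alleles = if (is.null(snvs) || !nrow(snvs)) "" else
        paste(sprintf("%s%d%s>%s", snvs$chrom, snvs$pos + 1, snvs$ref,
                      snvs$alt), collapse = ","),
      gsr_count = if (contaminated) 0L else validated,
      gsr_classes = classes,
      contaminated = contaminated,
      gsr_positive = !contaminated && validated > 0,
      max_gsr_vaf = if (is.null(r$vafs) || !length(r$vafs)) NA_real_ else
        max(r$vafs),
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  two_by_two <- function(cond) {
    ok <- !is.na(cond)
    matrix(c(sum(cond[ok] & tab$gsr_positive[ok]),
             sum(cond[ok] & !tab$gsr_positive[ok]),
             sum(!cond[ok] & tab$gsr_positive[ok]),
             sum(!cond[ok] & !tab$gsr_positive[ok])),
           2, 2, byrow = TRUE,
           dimnames = list(c("cond+", "cond-"), c("GSR+", "GSR-")))
  }
  list(table = tab,
       tables = list(amplification = two_by_two(tab$amplified),
                     mutation = two_by_two(tab$n_snv > 0)))
}
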