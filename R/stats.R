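#' Exact statistics and the expression transform
#'
#' @name stats_report
NULL

#' Two-tailed Fisher exact test
#'
#' Conditional on both margins, the two-tailed p-value is the sum of
#' hypergeometric point probabilities over all tables whose probability
#' does not exceed that of the observed table (point-probability
#' convention, relative comparison tolerance 1e-12).
#'
#' @param tab 2x2 matrix or the four counts `a, b, c, d` (rows =
#'   condition, columns = outcome).
#' @param a,b,c,d Alternative scalar-count interface.
#' @return The two-tailed p-value.
#' @export
fisher_exact_two_tailed <- function(tab = NULL, a = NULL, b = NULL,
                                    c = NULL, d = NULL) {
  if (is.null(tab)) tab <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)))
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be non-negative integers")
  }
  if (sum(tab) == 0) stop("empty table")
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-12)])
}

#' One-sided Mann-Whitney U test
#'
#' Exact by enumeration for small untied samples, normal approximation
#' with tie correction otherwise (the behaviour of the standard
#' rank-sum machinery, which backs this wrapper).
#'
#' @param x,y Numeric samples.
#' @param alternative "x_greater" (x stochastically larger) or
#'   "y_greater".
#' @return list(`U`, `p`): U counts pairs (x_i, y_j) with x_i > y_j.
#' @export
mann_whitney_one_sided <- function(x, y,
                                   alternative = c("x_greater", "y_greater")) {
  alternative <- match.arg(alternative)
  alt <- if (alternative == "x_greater") "greater" else "less"
  res <- suppressWarnings(stats::wilcox.test(x, y, alternative = alt))
  list(U = unname(res$statistic), p = res$p.value)
}

#' Relative expression by the differential Ct method
#'
#' Per sample, delta-Ct = Ct_target - Ct_housekeeping; relative expression
#' is 2^-(delta-Ct_sample - delta-Ct_calibrator), so the calibrator maps
#' to 1.
#'
#' @param records data.frame with `sample`, `ct_target`,
#'   `ct_housekeeping`.
#' @param calibrator Sample label of the calibrator.
#' @return The data.frame with a `relative_expression` column appended.
#' @export
ddct_relative_expression <- function(records, calibrator) {
  stopifnot(calibrator %in% records$sample)
  dct <- records$ct_target - records$ct_housekeeping
  dct_cal <- dct[match(calibrator, records$sample)]
  records$relative_expression <- 2^(-(dct - dct_cal))
  records
}
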