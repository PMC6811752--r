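#' A qPCR measurement (one condition, one target gene)
#'
#' Replicate Ct values of the target and of the reference (housekeeping)
#' gene under one condition. Replicates are averaged before any delta is
#' taken, the usual practice for relative quantification.
#'
#' @param target_ct Numeric Ct values (> 0) of the target gene.
#' @param reference_ct Numeric Ct values (> 0) of the reference gene
#'   (e.g. Gapdh) in the same condition.
#' @return A list of class `qpcr_measurement` with the mean Cts and the
#'   delta Ct (target minus reference).
#' @export
qpcr_measurement <- function(target_ct, reference_ct) {
  if (any(target_ct <= 0) || any(reference_ct <= 0))
    stop("Ct values must be positive")
  structure(list(target_ct = mean(target_ct),
                 reference_ct = mean(reference_ct),
                 dct = mean(target_ct) - mean(reference_ct)),
            class = "qpcr_measurement")
}

#' Relative expression by the 2^-ddCt method
#'
#' `ddCt = dCt(test) - dCt(control)` with `dCt = Ct(target) - Ct(reference)`
#' per condition; the fold change of the test condition relative to the
#' control is `2^-ddCt`. Swapping test and control inverts the fold change
#' exactly.
#'
#' @param test,control [qpcr_measurement] objects for the two conditions.
#' @return The fold change, a positive number.
#' @examples
#' tst <- qpcr_measurement(20, 18)
#' ctl <- qpcr_measurement(25, 18)
#' ddct_fold_change(tst, ctl)  # ddCt = -5 -> 32
#' @export
ddct_fold_change <- function(test, control) {
  stopifnot(inherits(test, "qpcr_measurement"),
            inherits(control, "qpcr_measurement"))
  2^-(test$dct - control$dct)
}

#' Amplification efficiency from a dilution series
#'
#' Fits Ct against log10 template dilution by least squares and converts the
#' slope to a per-cycle amplification efficiency, `E = -1 + 10^(-1/slope)`.
#' A perfect doubling assay has slope -1/log10(2) = -3.3219 and E = 1.
#'
#' @param dilution_log10 log10 of the template dilutions (at least 3
#'   distinct values).
#' @param ct Observed Ct at each dilution.
#' @return A list with `slope`, `intercept`, `efficiency` and `r_squared`.
#' @export
amplification_efficiency <- function(dilution_log10, ct) {
  if (length(dilution_log10) != length(ct))
    stop("'dilution_log10' and 'ct' must have equal length")
  if (length(unique(dilution_log10)) < 3L)
    stop("need at least 3 distinct dilution points")
  fit <- stats::lm(ct ~ dilution_log10)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope == 0) stop("degenerate dilution series")
  ss_tot <- sum((ct - mean(ct))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::resid(fit)^2) / ss_tot else NA_real_
  list(slope = slope,
       intercept = unname(stats::coef(fit)[1]),
       efficiency = -1 + 10^(-1 / slope),
       r_squared = r2)
}

#' Two-sample Student's t-test (pooled variance)
#'
#' Classical two-sided Student's t-test with pooled variance, the comparison
#' used for qPCR significance calls. Degenerate inputs (zero pooled
#' variance) are handled explicitly: equal means give `t = 0, p = 1`;
#' unequal means with no variance are an error.
#'
#' @param group1,group2 Numeric vectors, each of length >= 2.
#' @return A list with `t` and `pvalue`.
#' @export
two_sample_ttest <- function(group1, group2) {
  if (length(group1) < 2L || length(group2) < 2L)
    stop("each group needs at least 2 values")
  if (stats::var(group1) == 0 && stats::var(group2) == 0) {
    if (mean(group1) == mean(group2)) return(list(t = 0, pvalue = 1))
    stop("degenerate input: zero variance with unequal means")
  }
  ht <- stats::t.test(group1, group2, var.equal = TRUE)
  list(t = unname(ht$statistic), pvalue = ht$p.value)
}
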