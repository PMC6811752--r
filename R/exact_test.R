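# Log conditional pmf of the compartment-A group sum k given the grand total
# T, when each of n_a + n_b samples is i.i.d. NB(mu, phi) under the null of
# no differential expression (equal effective library sizes). The group sums
# are NB(n_a / phi, p) and NB(n_b / phi, p) with a shared probability
# parameter, which cancels on conditioning, so the result is free of mu:
#   w_k ∝ C(k + n_a r - 1, k) * C(T - k + n_b r - 1, T - k),  r = 1/phi.
# In the Poisson limit phi -> 0 this is Binomial(T, n_a / (n_a + n_b));
# below phi = 1e-7 the binomial limit is used outright (the NB conditional
# law then differs by less than T^2 phi / 2 in log-probability, and the
# direct lgamma evaluation would lose precision). The log binomial
# coefficients C(k + nr - 1, k) are built by cumulative sums of single logs,
# which stays accurate for very large nr.
.cond_logpmf <- function(total, n_a, n_b, phi) {
  if (phi < 1e-7)
    return(stats::dbinom(0:total, total, n_a / (n_a + n_b), log = TRUE))
  r <- 1 / phi
  i <- seq_len(total)
  la <- c(0, cumsum(log(n_a * r - 1 + i) - log(i)))
  lb <- c(0, cumsum(log(n_b * r - 1 + i) - log(i)))
  lw <- la + rev(lb)
  lw <- lw - max(lw)
  lw - log(sum(exp(lw)))
}

# Two-sided p by probability mass: sum P(split) over all splits whose null
# probability is <= that of the observed split (ties included, so the
# conditional mode yields p = 1 in a balanced design). The log-scale slack
# absorbs floating-point noise in the tie comparison only.
.exact_p_from_sums <- function(s_a, s_b, n_a, n_b, phi) {
  total <- s_a + s_b
  if (total == 0) return(1)
  lw <- .cond_logpmf(total, n_a, n_b, phi)
  obs <- lw[s_a + 1L]
  min(1, sum(exp(lw[lw <= obs + 1e-9])))
}

#' Conditional exact test for two-group NB counts
#'
#' Tests equality of expression between two compartments by conditioning on
#' the total count: after equalizing effective library sizes (scaling to the
#' geometric-mean library size and rounding), the per-compartment sums
#' `(s_a, s_b)` are reduced to the conditional distribution of `s_a` given
#' `s_a + s_b`, which under a common dispersion `phi` is a negative
#' hypergeometric law (Binomial in the Poisson limit `phi = 0`). The
#' two-sided p-value sums the probabilities of all splits at most as probable
#' as the observed one.
#'
#' @param counts_a,counts_b Nonnegative integer count vectors, one entry per
#'   replicate in each compartment.
#' @param lib_a,lib_b Library sizes per replicate (defaults: all equal).
#' @param phi Common NB dispersion (`variance = mu + phi mu^2`), >= 0.
#' @return The exact p-value, in (0, 1].
#' @examples
#' # Poisson limit, one sample per group, counts 3 vs 13:
#' nb_exact_test(3, 13, phi = 0)  # 1394/65536
#' @export
nb_exact_test <- function(counts_a, counts_b,
                          lib_a = rep(1, length(counts_a)),
                          lib_b = rep(1, length(counts_b)),
                          phi = 0) {
  if (any(counts_a < 0) || any(counts_b < 0))
    stop("counts must be nonnegative")
  if (phi < 0) stop("'phi' must be >= 0")
  n_a <- length(counts_a)
  n_b <- length(counts_b)
  libs <- c(lib_a, lib_b)
  if (length(libs) != n_a + n_b || any(libs <= 0))
    stop("library sizes must be positive, one per replicate")
  eq <- .equalize_counts(matrix(c(counts_a, counts_b), nrow = 1), libs)
  s_a <- sum(eq[1, seq_len(n_a)])
  s_b <- sum(eq[1, n_a + seq_len(n_b)])
  .exact_p_from_sums(s_a, s_b, n_a, n_b, phi)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate, in the
#' input order. Thin validated front to [stats::p.adjust].
#'
#' @param pvalues Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, each >= its raw p and <= 1.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}
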