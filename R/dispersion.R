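# Library-size equalization: scale every sample's counts to the geometric
# mean library size and round to integers, so that conditioning on group
# sums is exact on an integer lattice. An approximation for unequal
# libraries; a no-op when libraries are equal.
.equalize_counts <- function(counts, lib_size) {
  ref <- exp(mean(log(lib_size)))
  round(sweep(counts, 2L, ref / lib_size, "*"))
}

# Conditional log-likelihood of a common NB dispersion phi, summed over genes
# and over both compartments. Within a group of n i.i.d. NB(mu, phi)
# replicates, the distribution of the counts given their sum t is free of mu:
#   P(y | t) = prod_i C(y_i + r - 1, y_i) / C(t + n r - 1, t),  r = 1/phi.
.cond_loglik <- function(phi, group_counts) {
  r <- 1 / phi
  ll <- 0
  for (y in group_counts) {             # one matrix per compartment
    n <- ncol(y)
    t_g <- rowSums(y)
    ll <- ll +
      sum(lgamma(y + r)) - length(y) * lgamma(r) +
      nrow(y) * lgamma(n * r) - sum(lgamma(t_g + n * r))
  }
  ll
}

#' Estimate a common negative-binomial dispersion
#'
#' Maximizes the conditional (on per-compartment totals) log-likelihood of a
#' single dispersion phi shared by all genes, under the parameterization
#' `variance = mu + phi * mu^2`. Counts are first scaled to the geometric-mean
#' library size and rounded, so the conditional likelihood is exact. The
#' estimate is floored at zero: data that are under-dispersed relative to
#' Poisson (e.g. identical replicates) return `phi = 0`.
#'
#' A single common dispersion is used deliberately: a 2-vs-2 design carries
#' far too little replication for per-gene (tagwise) estimates.
#'
#' @param x An [xtalk_counts] object with at least 2 replicates per
#'   compartment.
#' @param phi_max Upper bound of the search interval (default 20).
#' @return A list with elements `phi` (the estimate, >= 0) and `loglik` (the
#'   conditional log-likelihood at the maximum).
#' @export
estimate_common_dispersion <- function(x, phi_max = 20) {
  idx <- .group_index(x)
  if (any(lengths(idx) < 2L))
    stop("dispersion is unidentifiable with a single replicate in a group")
  eq <- .equalize_counts(x$counts, x$samples$lib_size)
  eq <- eq[rowSums(eq) > 0, , drop = FALSE]
  if (nrow(eq) == 0L) stop("no genes with nonzero counts")
  groups <- lapply(idx, function(j) eq[, j, drop = FALSE])

  f <- function(lphi) .cond_loglik(exp(lphi), groups)
  lo <- log(1e-7)
  opt <- stats::optimize(f, interval = c(lo, log(phi_max)), maximum = TRUE,
                         tol = 1e-6)
  # boundary check: if the likelihood keeps rising toward phi -> 0, floor at 0
  if (opt$maximum < lo + 0.5 || f(lo) >= opt$objective) {
    return(list(phi = 0, loglik = f(lo)))
  }
  list(phi = exp(opt$maximum), loglik = opt$objective)
}
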