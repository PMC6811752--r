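#' Counts-per-million normalization
#'
#' Scales each sample's counts by its library size in millions:
#' `cpm(g, s) = count(g, s) / lib_size(s) * 1e6`. When every gene is present,
#' each column of the result sums to one million. No between-sample
#' compositional correction (such as TMM) is applied: library-size scaling is
#' the normalization the downstream marker and crosstalk steps are defined on.
#'
#' @param x An [xtalk_counts] object, or a count matrix if `lib_size` is given.
#' @param lib_size Library sizes per sample; taken from `x` when it is an
#'   `xtalk_counts` object.
#' @return Numeric matrix of CPM values, same dimnames as the counts.
#' @examples
#' m <- matrix(c(100, 300), nrow = 2,
#'             dimnames = list(c("g1", "g2"), "s1"))
#' compute_cpm(m, lib_size = 400)  # g1 -> 250000 CPM
#' @export
compute_cpm <- function(x, lib_size = NULL) {
  if (inherits(x, "xtalk_counts")) {
    m <- x$counts
    lib_size <- x$samples$lib_size
  } else {
    m <- as.matrix(x)
    if (is.null(lib_size)) lib_size <- colSums(m)
  }
  bad <- lib_size <= 0
  if (any(bad))
    stop("zero or negative library size for sample(s): ",
         paste(colnames(m)[bad], collapse = ", "))
  sweep(m, 2L, lib_size, "/") * 1e6
}

#' Principal-component projection of samples on log-CPM
#'
#' Sample-level QC: projects samples onto principal components of
#' `log2(CPM + 1)` (genes centred, unscaled). With a clean two-compartment
#' signal the compartments separate on the first component.
#'
#' @param cpm Numeric CPM matrix, genes x samples.
#' @return A list with `coords` (samples x components score matrix) and
#'   `var_explained` (fraction of variance per component, summing to <= 1).
#' @export
pca_projection <- function(cpm) {
  cpm <- as.matrix(cpm)
  if (ncol(cpm) < 2L) stop("PCA needs at least 2 samples")
  lg <- t(log2(cpm + 1))
  fit <- stats::prcomp(lg, center = TRUE, scale. = FALSE)
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  list(coords = fit$x, var_explained = ve)
}
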