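#' Differential expression between two compartments
#'
#' Full DE stage: CPM normalization, common-dispersion estimation (unless
#' `phi` is supplied), per-gene conditional exact test, Benjamini-Hochberg
#' adjustment, and the selection rule `|log2FC| >= lfc_threshold` and
#' `FDR <= fdr_threshold`. The log2 fold change is computed from mean CPM per
#' compartment with a pseudocount, positive values meaning enrichment in the
#' first compartment level. Genes with zero counts in every sample are
#' dropped (with a message) before testing.
#'
#' @param x An [xtalk_counts] object with >= 2 replicates per compartment.
#' @param lfc_threshold Minimum absolute log2 fold change (default 1).
#' @param fdr_threshold Maximum adjusted p-value (default 0.05).
#' @param pseudocount CPM pseudocount stabilizing the fold change (default 0.5).
#' @param phi Optional fixed common dispersion; estimated from the data via
#'   [estimate_common_dispersion] when `NULL`.
#' @return A data.frame with one row per retained gene: `gene_id`, `log2fc`,
#'   `pvalue`, `fdr`, `cpm_mean_a`, `cpm_mean_b`, `significant`. The
#'   compartment levels and the dispersion used are attached as attributes
#'   `compartments` and `phi`.
#' @export
run_de <- function(x, lfc_threshold = 1, fdr_threshold = 0.05,
                   pseudocount = 0.5, phi = NULL) {
  stopifnot(inherits(x, "xtalk_counts"))
  idx <- .group_index(x)
  if (any(lengths(idx) < 2L))
    stop("at least 2 replicates per compartment are required for testing")

  keep <- rowSums(x$counts) > 0
  if (any(!keep))
    message("dropping ", sum(!keep), " gene(s) with zero counts in all samples")
  counts <- x$counts[keep, , drop = FALSE]

  if (is.null(phi)) {
    xk <- x
    xk$counts <- counts
    phi <- estimate_common_dispersion(xk)$phi
  }

  cpm <- compute_cpm(counts, x$samples$lib_size)
  cpm_a <- rowMeans(cpm[, idx[[1]], drop = FALSE])
  cpm_b <- rowMeans(cpm[, idx[[2]], drop = FALSE])
  log2fc <- log2((cpm_a + pseudocount) / (cpm_b + pseudocount))

  eq <- .equalize_counts(counts, x$samples$lib_size)
  s_a <- rowSums(eq[, idx[[1]], drop = FALSE])
  s_b <- rowSums(eq[, idx[[2]], drop = FALSE])
  n_a <- length(idx[[1]])
  n_b <- length(idx[[2]])
  pvalue <- vapply(
    seq_along(s_a),
    function(i) .exact_p_from_sums(s_a[i], s_b[i], n_a, n_b, phi),
    numeric(1)
  )
  fdr <- bh_adjust(pvalue)

  res <- data.frame(
    gene_id = rownames(counts),
    log2fc = log2fc,
    pvalue = pvalue,
    fdr = fdr,
    cpm_mean_a = cpm_a,
    cpm_mean_b = cpm_b,
    significant = abs(log2fc) >= lfc_threshold & fdr <= fdr_threshold,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  attr(res, "compartments") <- compartment_levels(x)
  attr(res, "phi") <- phi
  res
}

#' Write / read a DE result table as TSV
#'
#' The compartment levels are stored in a comment header line so that a
#' round-tripped table keeps its orientation.
#'
#' @param de A DE result table from [run_de].
#' @param file Path to the TSV.
#' @return `write_de_results` returns `de` invisibly; `read_de_results`
#'   returns the table with its `compartments` attribute restored.
#' @export
write_de_results <- function(de, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("# compartments: ",
                    paste(attr(de, "compartments"), collapse = "\t")), con)
  utils::write.table(de, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(de)
}

#' @rdname write_de_results
#' @export
read_de_results <- function(file) {
  first <- readLines(file, n = 1)
  de <- utils::read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
  if (startsWith(first, "# compartments: ")) {
    attr(de, "compartments") <-
      strsplit(sub("^# compartments: ", "", first), "\t")[[1]]
  }
  de
}
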