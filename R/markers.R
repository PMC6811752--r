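#' Marker-selection configuration
#'
#' Settings of the marker flowchart: a replicate-variability window applied
#' in both compartments and a control-gene CPM floor in the target
#' compartment. Defaults follow the study design: window \[0.8, 1.2\], Pdx1
#' as the positive expression control for the bud compartment, Nepn as the
#' (background-level) control for the mesenchyme, top 50 genes kept.
#'
#' @param variability_low,variability_high Inclusive bounds of the
#'   replicate CPM-ratio window; must bracket 1.
#' @param positive_control_gene Control gene whose CPM sets the floor when
#'   selecting markers of the first (A) compartment.
#' @param negative_control_gene Control gene setting the floor for the
#'   second (B) compartment.
#' @param top_n Maximum list length.
#' @return A list of class `marker_config`.
#' @export
marker_config <- function(variability_low = 0.8, variability_high = 1.2,
                          positive_control_gene = "Pdx1",
                          negative_control_gene = "Nepn",
                          top_n = 50) {
  if (!(variability_low > 0 && variability_low <= 1 &&
        variability_high >= 1))
    stop("need 0 < variability_low <= 1 <= variability_high")
  if (top_n < 1) stop("top_n must be >= 1")
  structure(list(variability_low = variability_low,
                 variability_high = variability_high,
                 positive_control_gene = positive_control_gene,
                 negative_control_gene = negative_control_gene,
                 top_n = as.integer(top_n)),
            class = "marker_config")
}

#' Replicate variability ratio
#'
#' The between-replicate variability of a gene in one compartment, defined as
#' the ratio of the first replicate's CPM to the second's. Two zero
#' replicates agree perfectly (`v = 1`); a zero denominator with nonzero
#' numerator gives `Inf`, which fails any finite window. Vectorized.
#'
#' @param cpm_rep1,cpm_rep2 Nonnegative CPM values of the two replicates.
#' @return The ratio `v = cpm_rep1 / cpm_rep2`.
#' @examples
#' replicate_variability(100, 130)  # ~0.769, outside [0.8, 1.2]
#' @export
replicate_variability <- function(cpm_rep1, cpm_rep2) {
  if (any(cpm_rep1 < 0) || any(cpm_rep2 < 0))
    stop("CPM values must be nonnegative")
  v <- cpm_rep1 / cpm_rep2
  v[cpm_rep1 == 0 & cpm_rep2 == 0] <- 1
  v
}

#' Select top compartment-enriched marker genes
#'
#' The marker flowchart: among genes significantly enriched in the target
#' compartment, keep those whose replicate CPM ratio lies inside the
#' variability window in *both* compartments and whose mean CPM in the
#' target compartment is at least the control gene's mean CPM there; return
#' the `top_n` by descending CPM (ties broken by gene id). The active
#' control gene itself is a threshold reference and is never reported as a
#' marker.
#'
#' Requires exactly two replicates per compartment — the replicate ratio is
#' defined for a pair.
#'
#' @param de DE result table from [run_de] on the same data.
#' @param x The [xtalk_counts] object the DE table came from.
#' @param target_compartment Which compartment's markers to select (one of
#'   [compartment_levels]).
#' @param config A [marker_config].
#' @return A data.frame `gene_id`, `cpm_mean` (mean CPM in the target
#'   compartment), at most `top_n` rows, descending CPM. Empty with a
#'   warning if nothing passes.
#' @export
select_markers <- function(de, x, target_compartment,
                           config = marker_config()) {
  stopifnot(inherits(x, "xtalk_counts"), inherits(config, "marker_config"))
  lv <- compartment_levels(x)
  if (!target_compartment %in% lv)
    stop("unknown compartment '", target_compartment, "'")
  idx <- .group_index(x)
  if (any(lengths(idx) != 2L))
    stop("marker selection requires exactly 2 replicates per compartment")

  control <- if (target_compartment == lv[1]) config$positive_control_gene
             else config$negative_control_gene
  if (!control %in% rownames(x$counts))
    stop("control gene '", control, "' is absent from the count matrix")

  cpm <- compute_cpm(x)
  target_is_a <- target_compartment == lv[1]
  sig <- de$significant & (if (target_is_a) de$log2fc > 0 else de$log2fc < 0)
  # the active control is the threshold reference, not a candidate marker
  cand <- setdiff(de$gene_id[sig], control)

  v_ok <- rep(TRUE, length(cand))
  for (g in lv) {
    j <- idx[[g]]
    v <- replicate_variability(cpm[cand, j[1]], cpm[cand, j[2]])
    v_ok <- v_ok & v >= config$variability_low & v <= config$variability_high
  }
  cand <- cand[v_ok]

  tcol <- idx[[target_compartment]]
  cpm_target <- rowMeans(cpm[, tcol, drop = FALSE])
  cutoff <- cpm_target[control]
  cand <- cand[cpm_target[cand] >= cutoff]

  if (length(cand) == 0L) {
    warning("no gene passes the marker filters for ", target_compartment)
    return(data.frame(gene_id = character(0), cpm_mean = numeric(0),
                      stringsAsFactors = FALSE))
  }
  ord <- order(-cpm_target[cand], cand)
  cand <- cand[ord][seq_len(min(config$top_n, length(cand)))]
  data.frame(gene_id = cand, cpm_mean = unname(cpm_target[cand]),
             stringsAsFactors = FALSE)
}
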