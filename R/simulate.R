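#' Simulation configuration
#'
#' Parameters of the synthetic two-compartment RNA-seq generator, which
#' emulates the microdissected bud-vs-mesenchyme design: NB-distributed
#' counts for two compartments with a small number of replicates, planted
#' compartment-enriched genes, planted secreted/surface localization
#' annotations, and planted high-confidence cross-compartment interacting
#' pairs. Default values describe a typical bulk design with two biological
#' replicates per compartment and a biological coefficient of variation of
#' about 0.22 (`dispersion = 0.05`).
#'
#' @param n_genes Number of background genes (controls are added on top).
#' @param n_reps_per_group Replicates per compartment (study design: 2).
#' @param mean_expression_range Range of baseline expression, CPM scale;
#'   baselines are drawn log-uniformly within it.
#' @param dispersion NB dispersion phi, `variance = mu + phi mu^2`; 0 gives
#'   Poisson counts.
#' @param n_planted_de Planted enriched genes per direction.
#' @param planted_log2fc Planted log2 fold change (>= 1), applied
#'   symmetrically: an A-enriched gene has baseline CPM multiplied by
#'   `2^(lfc/2)` in A and divided by it in B, so the expected CPM ratio is
#'   `2^planted_log2fc`.
#' @param library_sizes Library size per sample (recycled); default 1e6 so
#'   CPM approximately equals counts.
#' @param n_planted_pairs Planted cross-compartment interacting pairs, each
#'   joining one A-enriched and one B-enriched gene with complementary
#'   surface/extracellular localization and confidence >= 0.9.
#' @param confidence_background Upper bound (exclusive of 0.9) for decoy
#'   interaction confidences.
#' @param decoy_localization_fraction Fraction of non-pair genes receiving a
#'   random decoy localization term.
#' @param n_decoy_pairs Random low-confidence decoy interactions.
#' @param n_within_decoys High-confidence decoy interactions whose members
#'   lie in the same compartment (exercise the cross-compartment rule).
#' @param compartments Names of the two compartments (A first).
#' @param control_genes Named list configuring the two control genes: ids and
#'   expected CPM of the positive control (A-compartment marker, e.g. Pdx1)
#'   and the negative control's background CPM in compartment B (e.g. Nepn).
#' @param seed Integer seed; fully determines all generated tables.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       n_reps_per_group = 2,
                       mean_expression_range = c(20, 2000),
                       dispersion = 0.05,
                       n_planted_de = 50,
                       planted_log2fc = 2,
                       library_sizes = 1e6,
                       n_planted_pairs = 5,
                       confidence_background = 0.85,
                       decoy_localization_fraction = 0.1,
                       n_decoy_pairs = 200,
                       n_within_decoys = 20,
                       compartments = c("DPB", "MeDPB"),
                       control_genes = list(positive = "Pdx1", positive_cpm = 50,
                                            negative = "Nepn", negative_cpm = 5),
                       seed = 1) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_reps_per_group = as.integer(n_reps_per_group),
    mean_expression_range = as.numeric(mean_expression_range),
    dispersion = dispersion,
    n_planted_de = as.integer(n_planted_de),
    planted_log2fc = planted_log2fc,
    library_sizes = rep_len(library_sizes, 2L * n_reps_per_group),
    n_planted_pairs = as.integer(n_planted_pairs),
    confidence_background = confidence_background,
    decoy_localization_fraction = decoy_localization_fraction,
    n_decoy_pairs = as.integer(n_decoy_pairs),
    n_within_decoys = as.integer(n_within_decoys),
    compartments = compartments,
    control_genes = control_genes,
    seed = as.integer(seed)
  )
  if (cfg$n_genes < 1L || cfg$n_reps_per_group < 1L)
    stop("n_genes and n_reps_per_group must be positive")
  if (2L * cfg$n_planted_de > cfg$n_genes)
    stop("more planted DE genes (2 x ", cfg$n_planted_de,
         ") than genes (", cfg$n_genes, ")")
  if (cfg$n_planted_pairs > max(cfg$n_planted_de, 0L))
    stop("n_planted_pairs cannot exceed n_planted_de")
  if (cfg$dispersion < 0) stop("dispersion must be >= 0")
  if (cfg$n_planted_de > 0L && cfg$planted_log2fc < 1)
    stop("planted_log2fc must be >= 1")
  if (cfg$confidence_background < 0 || cfg$confidence_background >= 0.9)
    stop("confidence_background must lie in [0, 0.9)")
  if (any(cfg$mean_expression_range <= 0) ||
      diff(cfg$mean_expression_range) < 0)
    stop("mean_expression_range must be an increasing pair of positive CPM")
  class(cfg) <- "sim_config"
  cfg
}

# NB draw with the phi = 0 Poisson limit
.rcounts <- function(n, mu, phi) {
  if (phi < 1e-12) stats::rpois(n, mu) else stats::rnbinom(n, size = 1 / phi, mu = mu)
}

#' Simulate a two-compartment count matrix with planted ground truth
#'
#' Draws NB counts for `n_genes` background genes plus the two control genes.
#' Planted genes get the configured symmetric fold change; the remaining
#' genes share their expected CPM across compartments. Planted
#' cross-compartment pairs are assigned complementary surface/extracellular
#' localization; a configurable fraction of the other genes gets a random
#' decoy localization term.
#'
#' @param config A [sim_config].
#' @return A list with `counts` (an [xtalk_counts]) and `truth`, a list with
#'   `de_genes_up` / `de_genes_down` (planted A- and B-enriched gene ids),
#'   `planted_pairs` (data.frame `gene_a`, `gene_b`), and `localization`
#'   (named character vector over all genes with values "surface",
#'   "extracellular", "both", or "none").
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  nr <- config$n_reps_per_group
  genes <- sprintf("gene%05d", seq_len(n))
  ctrl <- config$control_genes
  all_genes <- c(genes, ctrl$positive, ctrl$negative)

  rng <- log(config$mean_expression_range)
  base <- exp(stats::runif(n, rng[1], rng[2]))
  half <- 2^(config$planted_log2fc / 2)

  mu_a <- mu_b <- base
  up <- down <- character(0)
  if (config$n_planted_de > 0L) {
    iu <- seq_len(config$n_planted_de)
    id <- config$n_planted_de + iu
    mu_a[iu] <- base[iu] * half; mu_b[iu] <- base[iu] / half
    mu_a[id] <- base[id] / half; mu_b[id] <- base[id] * half
    up <- genes[iu]; down <- genes[id]
  }
  # controls: the positive control marks compartment A; the negative control
  # sits at background level in compartment B (its cutoff compartment)
  mu_a <- c(mu_a, ctrl$positive_cpm, ctrl$negative_cpm * 20)
  mu_b <- c(mu_b, ctrl$positive_cpm / 25, ctrl$negative_cpm)

  libs <- config$library_sizes
  counts <- matrix(0, nrow = n + 2L, ncol = 2L * nr,
                   dimnames = list(all_genes,
                                   sprintf("%s_rep%d",
                                           rep(config$compartments, each = nr),
                                           rep(seq_len(nr), 2L))))
  for (j in seq_len(2L * nr)) {
    mu <- if (j <= nr) mu_a else mu_b
    counts[, j] <- .rcounts(n + 2L, mu * libs[j] / 1e6, config$dispersion)
  }

  # planted pairs: one A-enriched and one B-enriched member, complementary
  # localization with random orientation
  loc <- stats::setNames(rep("none", n + 2L), all_genes)
  pairs <- data.frame(gene_a = character(0), gene_b = character(0),
                      stringsAsFactors = FALSE)
  if (config$n_planted_pairs > 0L) {
    pa <- up[seq_len(config$n_planted_pairs)]
    pb <- down[seq_len(config$n_planted_pairs)]
    flip <- stats::runif(config$n_planted_pairs) < 0.5
    loc[pa] <- ifelse(flip, "surface", "extracellular")
    loc[pb] <- ifelse(flip, "extracellular", "surface")
    pairs <- data.frame(gene_a = pa, gene_b = pb, stringsAsFactors = FALSE)
  }
  free <- all_genes[loc == "none"]
  decoy <- free[stats::runif(length(free)) < config$decoy_localization_fraction]
  loc[decoy] <- sample(c("surface", "extracellular", "both"),
                       length(decoy), replace = TRUE)

  x <- xtalk_counts(counts,
                    factor(rep(config$compartments, each = nr),
                           levels = config$compartments),
                    lib_size = libs)
  truth <- list(
    de_genes_up = c(up, ctrl$positive, ctrl$negative),
    de_genes_down = down,
    planted_pairs = pairs,
    localization = loc
  )
  list(counts = x, truth = truth)
}

#' Emit a gene-to-GO annotation table from planted localization
#'
#' Every gene whose ground-truth localization is "surface" is annotated with
#' GO:0009986 (cell surface), "extracellular" with GO:0005615 (extracellular
#' space), "both" with both terms, "none" with no localization term.
#' Deterministic given the truth object.
#'
#' @param truth Ground truth from [simulate_counts].
#' @param config The matching [sim_config] (reserved for extensions; the
#'   decoy fraction is already applied in the truth).
#' @return A data.frame with columns `gene_id`, `go_id`.
#' @export
simulate_annotations <- function(truth, config) {
  loc <- truth$localization
  rows <- list(
    data.frame(gene_id = names(loc)[loc %in% c("surface", "both")],
               go_id = "GO:0009986", stringsAsFactors = FALSE),
    data.frame(gene_id = names(loc)[loc %in% c("extracellular", "both")],
               go_id = "GO:0005615", stringsAsFactors = FALSE)
  )
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_id, out$go_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate a STRING-like interaction table
#'
#' Planted cross-compartment pairs receive confidence drawn from
#' \[0.9, 1.0\]; decoys are random gene pairs with confidence strictly below
#' 0.9, plus (when enough planted genes exist) high-confidence pairs whose
#' members share a compartment. Pairs are stored canonically (lexicographic)
#' and deduplicated.
#'
#' @inheritParams simulate_annotations
#' @return A data.frame with columns `gene_a`, `gene_b`, `confidence`.
#' @export
simulate_interactions <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  genes <- names(truth$localization)
  out <- list()
  if (nrow(truth$planted_pairs) > 0L) {
    out$planted <- data.frame(
      gene_a = truth$planted_pairs$gene_a,
      gene_b = truth$planted_pairs$gene_b,
      confidence = stats::runif(nrow(truth$planted_pairs), 0.9, 1.0),
      stringsAsFactors = FALSE
    )
  }
  if (config$n_decoy_pairs > 0L) {
    a <- sample(genes, config$n_decoy_pairs, replace = TRUE)
    b <- sample(genes, config$n_decoy_pairs, replace = TRUE)
    keep <- a != b
    out$decoy <- data.frame(
      gene_a = a[keep], gene_b = b[keep],
      confidence = stats::runif(sum(keep), 0.15,
                                config$confidence_background),
      stringsAsFactors = FALSE
    )
  }
  n_within <- min(config$n_within_decoys,
                  floor(length(truth$de_genes_up) / 2))
  if (n_within > 0L) {
    pick <- sample(truth$de_genes_up, 2L * n_within)
    out$within <- data.frame(
      gene_a = pick[seq_len(n_within)],
      gene_b = pick[n_within + seq_len(n_within)],
      confidence = stats::runif(n_within, 0.9, 1.0),
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, out)
  if (is.null(tab))
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      confidence = numeric(0), stringsAsFactors = FALSE))
  swap <- tab$gene_a > tab$gene_b
  tmp <- tab$gene_a[swap]; tab$gene_a[swap] <- tab$gene_b[swap]
  tab$gene_b[swap] <- tmp
  tab <- tab[!duplicated(tab[c("gene_a", "gene_b")]), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' One-call synthetic dataset
#'
#' Convenience wrapper running [simulate_counts], [simulate_annotations] and
#' [simulate_interactions] with a shared configuration.
#'
#' @param config A [sim_config].
#' @return A list with `counts`, `truth`, `annotations`, `interactions`.
#' @export
simulate_dataset <- function(config) {
  cs <- simulate_counts(config)
  list(
    counts = cs$counts,
    truth = cs$truth,
    annotations = simulate_annotations(cs$truth, config),
    interactions = simulate_interactions(cs$truth, config)
  )
}
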