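#' Pipeline configuration
#'
#' Describes one end-to-end run: either a simulation configuration (the
#' generator supplies counts, annotations and interactions) or paths to the
#' four input tables, plus every stage threshold and the output directory.
#'
#' @param output_dir Directory for all written artifacts (created if absent).
#' @param simulation Optional [sim_config]; when given, input files are
#'   ignored and a synthetic dataset (with its ground truth) is generated.
#' @param counts_file,samples_file,annotations_file,interactions_file Input
#'   TSV paths, required when `simulation` is `NULL`.
#' @param lfc_threshold,fdr_threshold DE selection thresholds.
#' @param min_confidence Interaction confidence filter for the crosstalk
#'   stage.
#' @param marker A [marker_config].
#' @param seed Integer seed recorded in the report; the generator's own seed
#'   governs simulation.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir,
                            simulation = NULL,
                            counts_file = NULL, samples_file = NULL,
                            annotations_file = NULL,
                            interactions_file = NULL,
                            lfc_threshold = 1, fdr_threshold = 0.05,
                            min_confidence = 0.9,
                            marker = marker_config(),
                            seed = 1) {
  if (is.null(simulation)) {
    miss <- c(counts = is.null(counts_file), samples = is.null(samples_file),
              annotations = is.null(annotations_file),
              interactions = is.null(interactions_file))
    if (any(miss))
      stop("without a simulation config, input paths are required: ",
           paste(names(miss)[miss], collapse = ", "))
  } else stopifnot(inherits(simulation, "sim_config"))
  structure(list(output_dir = output_dir, simulation = simulation,
                 counts_file = counts_file, samples_file = samples_file,
                 annotations_file = annotations_file,
                 interactions_file = interactions_file,
                 lfc_threshold = lfc_threshold,
                 fdr_threshold = fdr_threshold,
                 min_confidence = min_confidence,
                 marker = marker, seed = as.integer(seed)),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  nrow(df)
}

#' Run the whole pipeline
#'
#' Executes simulate/load, differential expression (with PCA QC), marker
#' selection for both compartments, GO over-representation on each
#' compartment's significant genes, and crosstalk scoring, writing every
#' stage's table under `output_dir` plus a machine-readable `report.json`
#' recording row counts, thresholds, the seed and all artifact paths.
#' Re-running with the same configuration reproduces identical files. Any
#' stage error aborts with the stage name.
#'
#' @param config A [pipeline_config].
#' @return The report, invisibly (a named list; also written as JSON).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)
  report <- list(seed = config$seed,
                 thresholds = list(lfc = config$lfc_threshold,
                                   fdr = config$fdr_threshold,
                                   min_confidence = config$min_confidence),
                 stages = list(), artifacts = list())

  if (!is.null(config$simulation)) {
    sim <- .stage("simulate", simulate_dataset(config$simulation))
    x <- sim$counts
    annotations <- sim$annotations
    interactions_src <- sim$interactions
    write_counts(x, out("counts.tsv"), out("samples.tsv"))
    .write_tsv(annotations, out("annotations.tsv"))
    .write_tsv(interactions_src, out("interactions.tsv"))
    jsonlite::write_json(sim$truth, out("truth.json"), auto_unbox = TRUE,
                         digits = NA)
    report$stages$simulate <- list(n_genes = nrow(x$counts),
                                   n_samples = ncol(x$counts),
                                   n_annotations = nrow(annotations),
                                   n_interactions = nrow(interactions_src))
    report$artifacts$truth <- out("truth.json")
  } else {
    x <- .stage("load_counts",
                read_counts(config$counts_file, config$samples_file))
    annotations <- .stage("load_annotations",
                          read_annotations(config$annotations_file))
    interactions_src <- config$interactions_file
    report$stages$load <- list(n_genes = nrow(x$counts),
                               n_samples = ncol(x$counts),
                               n_annotations = nrow(annotations))
  }
  comps <- compartment_levels(x)

  de <- .stage("de", run_de(x, lfc_threshold = config$lfc_threshold,
                            fdr_threshold = config$fdr_threshold))
  write_de_results(de, out("de_results.tsv"))
  pca <- .stage("de", pca_projection(compute_cpm(x)))
  .write_tsv(data.frame(sample_id = rownames(pca$coords),
                        pca$coords[, seq_len(min(3, ncol(pca$coords))),
                                   drop = FALSE]),
             out("pca.tsv"))
  report$stages$de <- list(n_tested = nrow(de),
                           n_significant = sum(de$significant),
                           phi = attr(de, "phi"))
  report$artifacts$de_results <- out("de_results.tsv")

  for (cc in comps) {
    mk <- .stage("markers", select_markers(de, x, cc, config$marker))
    .write_tsv(mk, out(paste0("markers_", cc, ".tsv")))
    report$stages$markers[[cc]] <- nrow(mk)
    report$artifacts[[paste0("markers_", cc)]] <-
      out(paste0("markers_", cc, ".tsv"))
  }

  universe <- de$gene_id
  for (cc in comps) {
    sel <- de$gene_id[de$significant &
                        (if (cc == comps[1]) de$log2fc > 0 else de$log2fc < 0)]
    enr <- .stage("enrich", hypergeom_overrep(sel, annotations, universe))
    .write_tsv(enr, out(paste0("enrichment_", cc, ".tsv")))
    report$stages$enrichment[[cc]] <- nrow(enr)
  }

  xt <- .stage("crosstalk", {
    if (is.character(interactions_src) && !file.exists(interactions_src))
      stop("interactions file not found: ", interactions_src)
    run_crosstalk(de, annotations, interactions_src,
                  min_confidence = config$min_confidence,
                  lfc_threshold = config$lfc_threshold)
  })
  .write_tsv(xt$table, out("crosstalk.tsv"))
  for (cc in names(xt$rank1))
    writeLines(xt$rank1[[cc]], out(paste0("rank1_", cc, ".txt")))
  report$stages$crosstalk <- list(
    n_candidates = nrow(xt$table),
    n_rank1 = sum(xt$table$rank == 1L),
    rank1_genes = lapply(xt$rank1, length)
  )
  report$artifacts$crosstalk <- out("crosstalk.tsv")

  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(report)
}
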