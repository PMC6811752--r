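#' Read a gene-to-GO annotation table
#'
#' Expects a TSV with columns `gene_id` and `go_id` (extra columns such as
#' `name`/`namespace` are kept). Duplicate (gene, term) rows are dropped;
#' term ids must look like `GO:NNNNNNN`.
#'
#' @param file Path to annotations.tsv.
#' @return A data.frame with at least `gene_id` and `go_id`.
#' @export
read_annotations <- function(file) {
  ann <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- setdiff(c("gene_id", "go_id"), names(ann))
  if (length(need))
    stop("annotation table lacks column(s): ", paste(need, collapse = ", "))
  bad <- !grepl("^GO:\\d{7}$", ann$go_id)
  if (any(bad))
    stop("malformed GO id(s): ", paste(unique(ann$go_id[bad]), collapse = ", "))
  ann[!duplicated(ann[c("gene_id", "go_id")]), , drop = FALSE]
}

#' GO over-representation test
#'
#' Hypergeometric test of each GO term's over-representation in a gene
#' selection relative to a universe: for a term annotating `m` universe genes
#' and overlapping the selection of size `k` in `q` genes, the p-value is
#' `P(X >= q)` with `X ~ Hypergeometric(N, m, k)`. Only terms with at least
#' one overlapping gene are tested; p-values are BH-adjusted across tested
#' terms. Annotations are used as given — no propagation over the GO graph.
#'
#' @param selection Character vector of selected genes (must lie in the
#'   universe).
#' @param annotations Annotation data.frame (`gene_id`, `go_id`), e.g. from
#'   [read_annotations] or [simulate_annotations].
#' @param universe Character vector of background genes.
#' @return A data.frame per tested term: `go_id`, `overlap_count`,
#'   `term_size` (in the universe), `gene_ratio` (= overlap / selection
#'   size), `pvalue`, `fdr`; ordered by increasing p-value.
#' @export
hypergeom_overrep <- function(selection, annotations, universe) {
  selection <- unique(selection)
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  out <- setdiff(selection, universe)
  if (length(out))
    stop("selection gene(s) outside the universe: ",
         paste(out, collapse = ", "))
  ann <- annotations[annotations$gene_id %in% universe, , drop = FALSE]
  terms <- split(ann$gene_id, ann$go_id)
  n_univ <- length(universe)
  n_sel <- length(selection)
  rows <- lapply(names(terms), function(tm) {
    genes <- unique(terms[[tm]])
    q <- sum(genes %in% selection)
    if (q == 0L) return(NULL)
    m <- length(genes)
    data.frame(
      go_id = tm,
      overlap_count = q,
      term_size = m,
      gene_ratio = q / n_sel,
      pvalue = stats::phyper(q - 1L, m, n_univ - m, n_sel,
                             lower.tail = FALSE),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(data.frame(go_id = character(0), overlap_count = integer(0),
                      term_size = integer(0), gene_ratio = numeric(0),
                      pvalue = numeric(0), fdr = numeric(0),
                      stringsAsFactors = FALSE))
  res$fdr <- bh_adjust(res$pvalue)
  res <- res[order(res$pvalue, res$go_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
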