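#' Labelled count matrix for a two-compartment design
#'
#' Bundles an integer gene-by-sample count matrix with its sample sheet, the
#' minimal container the rest of the pipeline operates on. The first level of
#' `compartment` is "compartment A": positive log2 fold changes downstream
#' mean A-enriched.
#'
#' @param counts Integer matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids). Counts must be nonnegative integers.
#' @param compartment Character or factor of length `ncol(counts)` with
#'   exactly two distinct values, one per sample. If not a factor, levels are
#'   taken in order of first appearance.
#' @param lib_size Optional numeric vector of library sizes per sample;
#'   defaults to column sums.
#' @return An object of class `xtalk_counts`: a list with elements `counts`
#'   (integer matrix) and `samples` (data.frame with `sample_id`,
#'   `compartment`, `lib_size`).
#' @examples
#' m <- matrix(rpois(40, 50), nrow = 10,
#'             dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
#' x <- xtalk_counts(m, c("DPB", "DPB", "MeDPB", "MeDPB"))
#' compartment_levels(x)
#' @export
xtalk_counts <- function(counts, compartment, lib_size = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("'counts' must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids in 'counts'")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids in 'counts'")
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be nonnegative and non-missing")
  if (max(abs(counts - round(counts))) > 1e-8)
    stop("counts must be integers")
  storage.mode(counts) <- "double"  # holds integers; avoids 32-bit overflow
  if (length(compartment) != ncol(counts))
    stop("'compartment' must label every sample")
  if (!is.factor(compartment))
    compartment <- factor(compartment, levels = unique(compartment))
  compartment <- droplevels(compartment)
  if (nlevels(compartment) != 2L)
    stop("exactly two compartments required, got ", nlevels(compartment))
  if (is.null(lib_size)) lib_size <- colSums(counts)
  if (length(lib_size) != ncol(counts) || any(lib_size < 0))
    stop("'lib_size' must be a nonnegative value per sample")
  structure(
    list(
      counts = counts,
      samples = data.frame(
        sample_id = colnames(counts),
        compartment = compartment,
        lib_size = as.numeric(lib_size),
        stringsAsFactors = FALSE
      )
    ),
    class = "xtalk_counts"
  )
}

#' @export
print.xtalk_counts <- function(x, ...) {
  tab <- table(x$samples$compartment)
  cat("xtalk_counts: ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples (", paste(names(tab), tab, sep = "=", collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' @rdname xtalk_counts
#' @param x An `xtalk_counts` object.
#' @export
compartment_levels <- function(x) levels(x$samples$compartment)

# sample indices of each compartment, named by level
.group_index <- function(x) {
  split(seq_len(ncol(x$counts)), x$samples$compartment)
}

#' Read a count table and sample sheet from TSV
#'
#' `counts.tsv` holds a `gene_id` column plus one integer column per sample;
#' `samples.tsv` holds `sample_id` and `compartment` (a `replicate` column is
#' tolerated and ignored).
#'
#' @param counts_file,samples_file Paths to the two TSV files.
#' @return An [xtalk_counts] object.
#' @export
read_counts <- function(counts_file, samples_file) {
  ct <- utils::read.delim(counts_file, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(ct))
    stop("counts file lacks a 'gene_id' column: ", counts_file)
  sm <- utils::read.delim(samples_file, stringsAsFactors = FALSE)
  need <- setdiff(c("sample_id", "compartment"), names(sm))
  if (length(need))
    stop("sample sheet lacks column(s): ", paste(need, collapse = ", "))
  m <- as.matrix(ct[setdiff(names(ct), "gene_id")])
  rownames(m) <- ct$gene_id
  missing <- setdiff(sm$sample_id, colnames(m))
  if (length(missing))
    stop("samples absent from count table: ", paste(missing, collapse = ", "))
  m <- m[, sm$sample_id, drop = FALSE]
  xtalk_counts(m, factor(sm$compartment, levels = unique(sm$compartment)))
}

#' Write a count object to counts.tsv + samples.tsv
#'
#' @param x An [xtalk_counts] object.
#' @param counts_file,samples_file Output paths.
#' @return Invisibly, `x`.
#' @export
write_counts <- function(x, counts_file, samples_file) {
  ct <- data.frame(gene_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(ct, counts_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sm <- x$samples
  sm$replicate <- stats::ave(seq_len(nrow(sm)), sm$compartment,
                             FUN = seq_along)
  utils::write.table(sm, samples_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}
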