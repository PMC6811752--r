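# strict TSV reader for the bundled reference tables: errors name the
# offending line so malformed edits are caught early
.read_fixture <- function(file, numeric_cols = character(0)) {
  lines <- readLines(file)
  if (length(lines) < 2L)
    stop("fixture ", basename(file), " is empty")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  parts <- strsplit(lines[-1], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != length(header)))
    stop("malformed fixture ", basename(file), ": wrong field count at line ",
         which(nf != length(header))[1] + 1L)
  df <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(df) <- header
  for (cc in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (anyNA(v))
      stop("malformed fixture ", basename(file), ": non-numeric '", cc,
           "' at line ", which(is.na(v))[1] + 1L)
    df[[cc]] <- v
  }
  df
}

#' Load the bundled reference marker and crosstalk tables
#'
#' Parses the three plain-TSV tables shipped with the package: the 50
#' bud-enriched markers with their mean CPM, the 50 mesenchyme-enriched
#' markers with their mean CPM, and the rank-1 crosstalk gene lists (16
#' bud-side and 17 mesenchyme-side genes). Printed order is preserved.
#'
#' @return A list with `dpb_markers` and `medpb_markers` (data.frames with
#'   `gene_id`, `cpm_mean`) and `crosstalk`, itself a list with `bud` and
#'   `mesenchyme` character vectors plus the full `table` (`compartment`,
#'   `gene_id`, `description`).
#' @examples
#' fx <- load_fixture_tables()
#' head(fx$dpb_markers, 1)     # Peg3, 3769.3
#' length(fx$crosstalk$bud)    # 16
#' @export
load_fixture_tables <- function() {
  path <- function(f) system.file("extdata", f, package = "pancrosstalk",
                                  mustWork = TRUE)
  t1 <- .read_fixture(path("table1_dpb_markers.tsv"), "cpm_mean")
  t2 <- .read_fixture(path("table2_medpb_markers.tsv"), "cpm_mean")
  t3 <- .read_fixture(path("table3_crosstalk.tsv"))
  bad <- setdiff(unique(t3$compartment), c("bud", "mesenchyme"))
  if (length(bad))
    stop("malformed fixture table3_crosstalk.tsv: unknown compartment ",
         paste(bad, collapse = ", "))
  list(
    dpb_markers = t1,
    medpb_markers = t2,
    crosstalk = list(
      bud = t3$gene_id[t3$compartment == "bud"],
      mesenchyme = t3$gene_id[t3$compartment == "mesenchyme"],
      table = t3
    )
  )
}
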