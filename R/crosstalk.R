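GO_CELL_SURFACE <- "GO:0009986"
GO_EXTRACELLULAR_SPACE <- "GO:0005615"

#' Read a STRING-like interaction table
#'
#' TSV with columns `gene_a`, `gene_b`, `confidence`. Confidences are
#' accepted on \[0, 1\]; if any value exceeds 1 the table is assumed to use
#' the 0-999/0-1000 integer dialect and is divided by 1000 (with a message).
#' Self-pairs are dropped; pairs are canonicalized (lexicographic) and
#' deduplicated keeping the highest confidence.
#'
#' @param file Path to interactions.tsv, or a data.frame with the same
#'   columns.
#' @return A data.frame `gene_a`, `gene_b`, `confidence` in \[0, 1\].
#' @export
read_interactions <- function(file) {
  tab <- if (is.data.frame(file)) file
         else utils::read.delim(file, stringsAsFactors = FALSE)
  need <- setdiff(c("gene_a", "gene_b", "confidence"), names(tab))
  if (length(need))
    stop("interaction table lacks column(s): ", paste(need, collapse = ", "))
  conf <- as.numeric(tab$confidence)
  if (anyNA(conf) || any(conf < 0))
    stop("confidences must be nonnegative numbers")
  if (any(conf > 1)) {
    message("interaction confidences exceed 1; interpreting as a 0-1000 ",
            "scale and dividing by 1000")
    conf <- conf / 1000
    if (any(conf > 1)) stop("confidences exceed 1000; unknown scale")
  }
  tab$confidence <- conf
  tab <- tab[tab$gene_a != tab$gene_b, , drop = FALSE]
  swap <- tab$gene_a > tab$gene_b
  tmp <- tab$gene_a[swap]; tab$gene_a[swap] <- tab$gene_b[swap]
  tab$gene_b[swap] <- tmp
  tab <- tab[order(tab$gene_a, tab$gene_b, -tab$confidence), , drop = FALSE]
  tab <- tab[!duplicated(tab[c("gene_a", "gene_b")]),
             c("gene_a", "gene_b", "confidence"), drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Restrict DE genes to secreted / cell-surface products
#'
#' Keeps significant DE genes annotated with at least one of the two
#' localization terms used as secreted/receptor proxies: extracellular space
#' (GO:0005615) or cell surface (GO:0009986). The compartment of each gene
#' is assigned from the sign of its log2 fold change.
#'
#' @param de DE result table from [run_de] (carries the compartment levels
#'   as an attribute).
#' @param annotations Annotation data.frame (`gene_id`, `go_id`).
#' @return A data.frame per retained gene: `gene_id`, `compartment`,
#'   `log2fc`, `is_surface`, `is_extracellular`.
#' @export
filter_localized <- function(de, annotations) {
  comps <- attr(de, "compartments")
  if (is.null(comps) || length(comps) != 2L)
    stop("DE table lacks its 'compartments' attribute")
  surf <- unique(annotations$gene_id[annotations$go_id == GO_CELL_SURFACE])
  extr <- unique(annotations$gene_id[annotations$go_id == GO_EXTRACELLULAR_SPACE])
  keep <- de$significant & de$gene_id %in% union(surf, extr)
  out <- data.frame(
    gene_id = de$gene_id[keep],
    compartment = ifelse(de$log2fc[keep] > 0, comps[1], comps[2]),
    log2fc = de$log2fc[keep],
    is_surface = de$gene_id[keep] %in% surf,
    is_extracellular = de$gene_id[keep] %in% extr,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "compartments") <- comps
  out
}

#' Cross-compartment candidate pairs
#'
#' Joins the localized DE genes with the interaction table: a candidate pair
#' has both members among the localized genes, members in *opposite*
#' compartments, and interaction confidence at or above the filter (the
#' highest-confidence STRING tier, 0.9, by default). Within-compartment
#' high-confidence pairs are counted in a message but not returned. Member A
#' of each pair is the gene from the first compartment level.
#'
#' @param localized Output of [filter_localized].
#' @param interactions Interaction table (see [read_interactions]; a path or
#'   data.frame is accepted).
#' @param min_confidence Confidence threshold in \[0, 1\] (default 0.9).
#' @return A data.frame per pair: `gene_a`, `gene_b` (A-compartment member
#'   first), `compartment_a`, `compartment_b`, `log2fc_a`, `log2fc_b`,
#'   localization flags for both members, `confidence`.
#' @export
candidate_pairs <- function(localized, interactions, min_confidence = 0.9) {
  if (min_confidence < 0 || min_confidence > 1)
    stop("'min_confidence' must lie in [0, 1]")
  tab <- read_interactions(interactions)
  loc <- localized
  ia <- match(tab$gene_a, loc$gene_id)
  ib <- match(tab$gene_b, loc$gene_id)
  known <- !is.na(ia) & !is.na(ib)
  hi <- tab$confidence >= min_confidence
  same <- known & hi & loc$compartment[ia] == loc$compartment[ib]
  if (any(same))
    message(sum(same), " high-confidence within-compartment pair(s) excluded")
  keep <- known & hi & !same
  tab <- tab[keep, , drop = FALSE]
  ia <- ia[keep]; ib <- ib[keep]
  # canonical orientation: compartment-A member first
  comps <- attr(localized, "compartments")
  if (is.null(comps)) comps <- sort(unique(loc$compartment))
  a_first <- loc$compartment[ia] == comps[1]
  m_a <- ifelse(a_first, ia, ib)
  m_b <- ifelse(a_first, ib, ia)
  out <- data.frame(
    gene_a = loc$gene_id[m_a],
    gene_b = loc$gene_id[m_b],
    compartment_a = loc$compartment[m_a],
    compartment_b = loc$compartment[m_b],
    log2fc_a = loc$log2fc[m_a],
    log2fc_b = loc$log2fc[m_b],
    surface_a = loc$is_surface[m_a],
    extracellular_a = loc$is_extracellular[m_a],
    surface_b = loc$is_surface[m_b],
    extracellular_b = loc$is_extracellular[m_b],
    confidence = tab$confidence,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "compartments") <- comps
  out
}

#' Score candidate pairs on the three priority criteria
#'
#' Each cross-compartment pair is scored on: (i) mode of regulation —
#' opposite fold-change directions for the two members (a zero fold change
#' has no direction and fails); (ii) size of regulation — absolute log2 fold
#' change at or above `lfc_threshold` for *both* members; (iii) cellular
#' localization — cell surface for one member and extracellular space for
#' the other (either orientation). The score is the number of satisfied
#' criteria and the rank is `4 - score`, so pairs meeting all three criteria
#' get rank 1.
#'
#' @param pairs Candidate pairs from [candidate_pairs].
#' @param lfc_threshold Effect-size threshold of criterion (ii), default 1.
#' @return `pairs` with added columns `crit_mode`, `crit_size`,
#'   `crit_localization`, `score`, `rank`.
#' @export
priority_score <- function(pairs, lfc_threshold = 1) {
  crit_mode <- sign(pairs$log2fc_a) * sign(pairs$log2fc_b) == -1
  crit_size <- abs(pairs$log2fc_a) >= lfc_threshold &
    abs(pairs$log2fc_b) >= lfc_threshold
  crit_loc <- (pairs$surface_a & pairs$extracellular_b) |
    (pairs$extracellular_a & pairs$surface_b)
  pairs$crit_mode <- crit_mode
  pairs$crit_size <- crit_size
  pairs$crit_localization <- crit_loc
  pairs$score <- crit_mode + crit_size + crit_loc
  pairs$rank <- 4L - pairs$score
  pairs
}

#' Rank scored crosstalk candidates
#'
#' Sorts scored pairs by rank (best first), then by descending confidence,
#' then by gene ids, and extracts the distinct rank-1 genes split by
#' compartment — the shape of the headline crosstalk gene lists.
#'
#' @param candidates Scored pairs from [priority_score].
#' @return A list with `table` (the sorted candidate table) and `rank1`, a
#'   list of two character vectors of distinct rank-1 genes named by
#'   compartment.
#' @export
rank_crosstalk <- function(candidates) {
  ord <- order(candidates$rank, -candidates$confidence,
               candidates$gene_a, candidates$gene_b)
  tab <- candidates[ord, , drop = FALSE]
  rownames(tab) <- NULL
  r1 <- tab[tab$rank == 1L, , drop = FALSE]
  comps <- attr(candidates, "compartments")
  if (is.null(comps))
    comps <- unique(c(tab$compartment_a, tab$compartment_b))
  rank1 <- if (length(comps)) {
    stats::setNames(lapply(comps, function(cc) {
      unique(c(r1$gene_a[r1$compartment_a == cc],
               r1$gene_b[r1$compartment_b == cc]))
    }), comps)
  } else list()
  list(table = tab, rank1 = rank1)
}

#' Full crosstalk stage
#'
#' Convenience wrapper: localization filter, confidence-filtered
#' cross-compartment pairing, priority scoring, and ranking.
#'
#' @inheritParams filter_localized
#' @inheritParams candidate_pairs
#' @inheritParams priority_score
#' @return See [rank_crosstalk].
#' @export
run_crosstalk <- function(de, annotations, interactions,
                          min_confidence = 0.9, lfc_threshold = 1) {
  loc <- filter_localized(de, annotations)
  pairs <- candidate_pairs(loc, interactions, min_confidence)
  rank_crosstalk(priority_score(pairs, lfc_threshold))
}
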