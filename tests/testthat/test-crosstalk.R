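localized_fixture <- function() {
  de <- make_de(
    gene_id = c("ligA", "recA", "bothA", "plainA", "weakA",
                "ligB", "recB", "downB"),
    log2fc = c(1.5, 2.0, 3.0, 2.5, 0.5, -2.0, -1.5, -2.5),
    fdr = c(rep(1e-6, 4), 0.2, rep(1e-6, 3))
  )
  ann <- data.frame(
    gene_id = c("ligA", "recA", "bothA", "weakA", "ligB", "recB"),
    go_id = c("GO:0005615", "GO:0009986", "GO:0005615", "GO:0005615",
              "GO:0005615", "GO:0009986"),
    stringsAsFactors = FALSE
  )
  ann <- rbind(ann, data.frame(gene_id = "bothA", go_id = "GO:0009986"))
  list(de = de, ann = ann)
}

test_that("localization filter keeps significant genes with either term", {
  fx <- localized_fixture()
  loc <- filter_localized(fx$de, fx$ann)
  expect_setequal(loc$gene_id, c("ligA", "recA", "bothA", "ligB", "recB"))
  # plainA lacks both terms; weakA is not significant (fdr 0.2 with lfc 0.5)
  expect_false(any(c("plainA", "weakA", "downB") %in% loc$gene_id))
  row <- loc[loc$gene_id == "ligA", ]
  expect_true(row$is_extracellular && !row$is_surface)
  expect_identical(row$compartment, "A")
  both <- loc[loc$gene_id == "bothA", ]
  expect_true(both$is_surface && both$is_extracellular)
  expect_identical(loc$compartment[loc$gene_id == "ligB"], "B")
})

test_that("candidate pairs require opposite compartments and high confidence", {
  fx <- localized_fixture()
  loc <- filter_localized(fx$de, fx$ann)
  inter <- data.frame(
    gene_a = c("ligA", "recA", "ligA", "ligA"),
    gene_b = c("recB", "ligB", "ligB", "recA"),
    confidence = c(0.95, 0.89, 0.92, 0.99),
    stringsAsFactors = FALSE
  )
  expect_message(pairs <- candidate_pairs(loc, inter), "within-compartment")
  # 0.89 fails the filter; ligA-recA is same-compartment despite 0.99
  expect_identical(sort(paste(pairs$gene_a, pairs$gene_b)),
                   c("ligA ligB", "ligA recB"))
  expect_true(all(pairs$compartment_a == "A" & pairs$compartment_b == "B"))

  # raising the threshold never enlarges the set
  for (th in c(0.9, 0.93, 0.96, 1)) {
    expect_lte(nrow(candidate_pairs(loc, inter, th)),
               nrow(candidate_pairs(loc, inter, 0.9)))
  }
})

test_that("integer-scaled confidences are detected and rescaled", {
  inter <- data.frame(gene_a = c("x", "y"), gene_b = c("y", "z"),
                      confidence = c(950, 899))
  expect_message(tab <- read_interactions(inter), "1000")
  expect_equal(tab$confidence, c(0.95, 0.899))
  expect_error(read_interactions(
    data.frame(gene_a = "x", gene_b = "y", confidence = 1500)), "scale")
})

test_that("priority scoring implements the three criteria and rank = 4 - score", {
  pair <- function(lfc_a, lfc_b, loc_a, loc_b) {
    data.frame(gene_a = "a", gene_b = "b",
               compartment_a = "A", compartment_b = "B",
               log2fc_a = lfc_a, log2fc_b = lfc_b,
               surface_a = loc_a %in% c("s", "sb"),
               extracellular_a = loc_a %in% c("e", "sb"),
               surface_b = loc_b %in% c("s", "sb"),
               extracellular_b = loc_b %in% c("e", "sb"),
               confidence = 0.95, stringsAsFactors = FALSE)
  }
  # all three criteria satisfied -> score 3, rank 1
  full <- priority_score(pair(1.5, -2.0, "s", "e"))
  expect_identical(full$score, 3L)
  expect_identical(full$rank, 1L)
  # nothing satisfied -> rank 4
  none <- priority_score(pair(0.5, 0.5, "e", "e"))
  expect_identical(none$score, 0L)
  expect_identical(none$rank, 4L)
  # opposite directions + size, same-kind localization -> rank 2
  two <- priority_score(pair(1.5, -2.0, "s", "s"))
  expect_identical(two$score, 2L)
  expect_identical(two$rank, 2L)
  # zero fold change has no direction
  z <- priority_score(pair(0, -2.0, "s", "e"))
  expect_false(z$crit_mode)
  # localization criterion is orientation-symmetric
  expect_identical(priority_score(pair(1.5, -2, "e", "s"))$score, 3L)
})

test_that("satisfying one more criterion never worsens the rank", {
  grid <- expand.grid(mode = c(FALSE, TRUE), size = c(FALSE, TRUE),
                      loc = c(FALSE, TRUE))
  mk <- function(g) {
    data.frame(gene_a = "a", gene_b = "b",
               compartment_a = "A", compartment_b = "B",
               log2fc_a = if (g$size) 1.5 else 0.5,
               log2fc_b = (if (g$size) 2 else 0.5) * (if (g$mode) -1 else 1),
               surface_a = TRUE, extracellular_a = FALSE,
               surface_b = !g$loc, extracellular_b = g$loc,
               confidence = 0.95, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    sc <- priority_score(mk(g))
    expect_identical(sc$score, sum(g$mode, g$size, g$loc))
    expect_identical(sc$rank, 4L - sc$score)
  }
})

test_that("ranking sorts by rank then confidence and splits rank-1 genes", {
  fx <- localized_fixture()
  loc <- filter_localized(fx$de, fx$ann)
  inter <- data.frame(
    gene_a = c("ligA", "recA", "bothA"),
    gene_b = c("recB", "ligB", "ligB"),
    confidence = c(0.91, 0.99, 0.95),
    stringsAsFactors = FALSE
  )
  res <- rank_crosstalk(priority_score(candidate_pairs(loc, inter)))
  expect_identical(res$table$rank, sort(res$table$rank))
  r1 <- res$table[res$table$rank == 1, ]
  expect_true(all(diff(r1$confidence) <= 0))
  expect_setequal(res$rank1$A,
                  unique(c(r1$gene_a[r1$compartment_a == "A"])))
  # every returned pair crosses compartments
  expect_true(all(res$table$compartment_a != res$table$compartment_b))
})

test_that("an empty candidate set yields empty outputs", {
  empty <- priority_score(candidate_pairs(
    data.frame(gene_id = character(0), compartment = character(0),
               log2fc = numeric(0), is_surface = logical(0),
               is_extracellular = logical(0)),
    data.frame(gene_a = character(0), gene_b = character(0),
               confidence = numeric(0))))
  res <- rank_crosstalk(empty)
  expect_identical(nrow(res$table), 0L)
  expect_true(all(lengths(res$rank1) == 0))
})

test_that("planted crosstalk pairs are recovered exactly at rank 1", {
  sim <- simulate_dataset(recovery_config(seed = 17, dispersion = 0.01))
  de <- run_de(sim$counts)
  res <- run_crosstalk(de, sim$annotations, sim$interactions)
  r1 <- res$table[res$table$rank == 1, ]
  expect_identical(
    sort(paste(r1$gene_a, r1$gene_b)),
    sort(paste(sim$truth$planted_pairs$gene_a,
               sim$truth$planted_pairs$gene_b))
  )
})

test_that("the reference rank-1 lists have the reported compartment sizes", {
  fx <- load_fixture_tables()
  expect_identical(length(fx$crosstalk$bud), 16L)
  expect_identical(length(fx$crosstalk$mesenchyme), 17L)
  expect_identical(length(unique(c(fx$crosstalk$bud,
                                   fx$crosstalk$mesenchyme))), 33L)
})
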