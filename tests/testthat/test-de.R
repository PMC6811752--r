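test_that("CPM is counts over library size times a million", {
  m <- matrix(c(500, 0, 100, 300), nrow = 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  cpm <- compute_cpm(m, lib_size = c(1e6, 400))
  expect_equal(cpm["g1", "s1"], 500)
  expect_equal(cpm["g2", "s1"], 0)
  expect_equal(cpm["g1", "s2"], 250000)
  expect_error(compute_cpm(m, lib_size = c(1e6, 0)), "s2")
})

test_that("full CPM columns sum to one million", {
  set.seed(1)
  m <- matrix(rpois(400, 30), nrow = 100,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:4)))
  cpm <- compute_cpm(m)
  expect_equal(unname(colSums(cpm)), rep(1e6, 4), tolerance = 1e-9)
})

test_that("common dispersion is recovered at known truth and floored at zero", {
  grp <- c("A", "A", "B", "B")
  set.seed(10)
  y0 <- matrix(rpois(2000, 80), ncol = 4,
               dimnames = list(paste0("g", 1:500), paste0("s", 1:4)))
  expect_lte(estimate_common_dispersion(make_counts(y0))$phi, 0.02)

  set.seed(11)
  y2 <- matrix(rnbinom(8000, size = 5, mu = 80), ncol = 4,
               dimnames = list(paste0("g", 1:2000), paste0("s", 1:4)))
  phi <- estimate_common_dispersion(make_counts(y2))$phi
  expect_gte(phi, 0.15)
  expect_lte(phi, 0.25)

  y3 <- matrix(rep(c(5, 5, 9, 9), each = 10), ncol = 4, byrow = FALSE,
               dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  y3[] <- rep(c(5, 5, 9, 9), each = 10)
  expect_identical(estimate_common_dispersion(make_counts(y3))$phi, 0)

  one_rep <- xtalk_counts(y0[, 1:2], c("A", "B"))
  expect_error(estimate_common_dispersion(one_rep), "single replicate")
})

test_that("dispersion estimate agrees with edgeR's conditional ML", {
  set.seed(7)
  y <- matrix(rnbinom(8000, size = 10, mu = 60), ncol = 4,
              dimnames = list(paste0("g", 1:2000), paste0("s", 1:4)))
  mine <- estimate_common_dispersion(make_counts(y))$phi
  ref <- edgeR::estimateCommonDisp(
    edgeR::DGEList(counts = y, group = factor(c("A", "A", "B", "B"))))
  expect_equal(mine, ref$common.dispersion, tolerance = 0.02)
})

test_that("exact test reproduces the binomial enumeration case and symmetry", {
  expect_equal(nb_exact_test(3, 13, phi = 0), 1394 / 65536,
               tolerance = 1e-12)
  # balanced case: the observed split is the conditional mode
  expect_equal(nb_exact_test(c(5, 5), c(5, 5), phi = 0.1), 1)
  expect_error(nb_exact_test(-1, 5), "nonnegative")
  expect_error(nb_exact_test(1, 5, phi = -0.1), "phi")
})

test_that("exact test matches exhaustive enumeration across designs", {
  designs <- list(c(1, 1), c(2, 2), c(2, 3))
  for (phi in c(0, 0.05, 0.2)) {
    for (d in designs) {
      for (total in c(5, 17, 30)) {
        for (s in 0:total) {
          split_a <- rep(s %/% d[1], d[1]); split_a[1] <- s - sum(split_a[-1])
          split_b <- rep((total - s) %/% d[2], d[2])
          split_b[1] <- (total - s) - sum(split_b[-1])
          p <- nb_exact_test(split_a, split_b, phi = phi)
          expect_lt(abs(p - oracle_exact_p(s, total - s, d[1], d[2], phi)),
                    1e-12)
          expect_gt(p, 0)
          expect_lte(p, 1)
        }
      }
    }
  }
})

test_that("exact test converges to the conditional binomial as phi -> 0", {
  for (s in 0:30) {
    expect_lt(abs(nb_exact_test(s, 30 - s, phi = 1e-8) -
                    nb_exact_test(s, 30 - s, phi = 0)), 1e-9)
  }
})

test_that("exact test agrees with edgeR's small-p exact test", {
  set.seed(7)
  y <- matrix(rnbinom(400, size = 10, mu = 60), ncol = 4,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:4)))
  ref <- edgeR::exactTest(
    edgeR::DGEList(counts = y, group = factor(c("A", "A", "B", "B")),
                   lib.size = rep(1e4, 4)),
    dispersion = 0.1, rejection.region = "smallp")$table$PValue
  mine <- vapply(seq_len(100), function(i)
    nb_exact_test(y[i, 1:2], y[i, 3:4], rep(1e4, 2), rep(1e4, 2), phi = 0.1),
    numeric(1))
  expect_equal(mine, ref, tolerance = 1e-10)
})

test_that("BH adjustment follows the step-up rule and dominates raw p", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03, 0.05)),
               c(0.04, 0.05, 0.05, 0.05))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
  set.seed(4)
  p <- runif(200)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p & adj <= 1))
  ord <- order(p)
  expect_true(all(diff(adj[ord]) >= -1e-15))
})

test_that("run_de applies both thresholds and is antisymmetric in labels", {
  # a gene with enormous counts but small fold change: tiny p, small lfc
  set.seed(2)
  base <- matrix(rpois(400, 50), nrow = 100)
  cpmM <- rbind(base, c(60000, 60000, 47000, 47000))
  rownames(cpmM) <- c(paste0("g", 1:100), "small_fc")
  colnames(cpmM) <- paste0("s", 1:4)
  x <- make_counts(cpmM)
  de <- run_de(x, phi = 0)
  row <- de[de$gene_id == "small_fc", ]
  expect_lt(row$fdr, 1e-9)
  expect_lt(abs(row$log2fc), 1)
  expect_false(row$significant)
  expect_true(all(de$fdr >= de$pvalue))

  x_swap <- xtalk_counts(round(cpmM),
                         factor(c("B", "B", "A", "A"), levels = c("A", "B")),
                         lib_size = rep(1e6, 4))
  de_swap <- run_de(x_swap, phi = 0)
  expect_equal(de_swap$log2fc, -de$log2fc)
  expect_equal(de_swap$pvalue, de$pvalue)
  expect_equal(de_swap$fdr, de$fdr)
})

test_that("all-zero genes are dropped with a message before testing", {
  m <- matrix(c(10, 12, 9, 11, 0, 0, 0, 0), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "gz"), paste0("s", 1:4)))
  x <- make_counts(m)
  expect_message(de <- run_de(x, phi = 0), "1 gene")
  expect_identical(de$gene_id, "g1")
})

test_that("PCA projection reflects structure and ignores gene order", {
  set.seed(3)
  # rank-1 structure: one direction of variation across samples
  load_vec <- rnorm(50)
  scores <- c(1, 2, 3, 4)
  cpmM <- 2^(outer(load_vec, scores)) * 100
  rownames(cpmM) <- paste0("g", 1:50); colnames(cpmM) <- paste0("s", 1:4)
  pr <- pca_projection(cpmM)
  expect_gt(pr$var_explained[1], 0.99)
  expect_lte(sum(pr$var_explained), 1 + 1e-12)

  perm <- sample(nrow(cpmM))
  pr2 <- pca_projection(cpmM[perm, ])
  expect_equal(abs(pr2$coords), abs(pr$coords), tolerance = 1e-8)

  # planted two-compartment data separate on the first component
  sim <- simulate_counts(recovery_config(seed = 8, n_genes = 500))
  pc <- pca_projection(compute_cpm(sim$counts))
  comp <- sim$counts$samples$compartment
  pc1 <- pc$coords[, 1]
  expect_true(max(pc1[comp == "DPB"]) < min(pc1[comp == "MeDPB"]) ||
                min(pc1[comp == "DPB"]) > max(pc1[comp == "MeDPB"]))
})
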