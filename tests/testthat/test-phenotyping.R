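test_that("univariate PERMANOVA pseudo-F equals the classical ANOVA F", {
  x <- c(1, 2, 3, 2, 3, 4, 6, 7, 8)
  g <- rep(c("a", "b", "c"), each = 3)
  pm <- permanova(matrix(x), g, n_permutations = 99, seed = 1)
  av <- one_way_anova(x, g)
  expect_equal(pm$pseudo_f, av$f_value, tolerance = 1e-10)
  expect_gt(pm$p_value, 0)  # +1 correction: never exactly zero
})

test_that("PERMANOVA SS decomposition is exact and rotation-invariant", {
  set.seed(31)
  X <- matrix(rnorm(24 * 6), 24, 6)
  g <- rep(c("A", "B", "C"), each = 8)
  pm <- permanova(X, g, n_permutations = 0)
  expect_equal(pm$ss_total, pm$ss_among + pm$ss_within,
               tolerance = 1e-8 * pm$ss_total)
  # distance-preserving rotation leaves pseudo-F unchanged
  Q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
  pm_rot <- permanova(X %*% Q, g, n_permutations = 0)
  expect_equal(pm$pseudo_f, pm_rot$pseudo_f, tolerance = 1e-8)
  # agreement with an independent implementation
  if (requireNamespace("vegan", quietly = TRUE)) {
    ad <- vegan::adonis2(as.data.frame(X) ~ g, permutations = 2,
                         method = "euclidean")
    expect_equal(pm$pseudo_f, ad$F[1], tolerance = 1e-8)
  }
})

test_that("identical duplicated groups give vanishing among-group SS", {
  base <- matrix(rnorm(12), 4, 3)
  X <- rbind(base, base)
  g <- rep(c("A", "B"), each = 4)
  pm <- permanova(X, g, n_permutations = 0)
  expect_lt(pm$ss_among / pm$ss_total, 1e-10)
  expect_error(permanova(X, c("A", rep("B", 7)), 10), "singleton")
})

test_that("PCoA on Euclidean distances reproduces PCA scores up to sign", {
  set.seed(32)
  for (rep in 1:20) {
    Y <- matrix(rnorm(10 * 4), 10, 4)
    pc <- pcoa(Y)
    pr <- prcomp(Y, center = TRUE)
    for (k in 1:4) {
      d <- min(max(abs(pc$scores[, k] - pr$x[, k])),
               max(abs(pc$scores[, k] + pr$x[, k])))
      expect_lt(d, 1e-6)
    }
  }
})

test_that("PCoA embeds collinear points in one dimension and handles zero distances", {
  D <- as.dist(matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3))
  pc <- pcoa(D)
  expect_equal(sum(pc$eigenvalues > 1e-8), 1L)
  emb <- stats::dist(pc$scores)
  expect_equal(as.numeric(emb), c(1, 2, 1), tolerance = 1e-8)
  z <- pcoa(matrix(0, 3, 3))
  expect_lt(max(abs(z$eigenvalues)), 1e-10)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("PLS-DA classifies separable classes and respects its contract", {
  sim <- simulate_labeled_spectra(10, separation = 1, seed = 33)
  X <- subset_range(sim$spectra, 400, 2400)$reflectance
  cal <- c(1:7, 11:17, 21:27)
  val <- setdiff(1:30, cal)
  pred <- plsda_fit_predict(X[cal, ], sim$labels[cal], X[val, ], 3)
  expect_equal(pred, sim$labels[val])
  # a validation row identical to a calibration row gets that row's class
  pred1 <- plsda_fit_predict(X[cal, ], sim$labels[cal],
                             X[cal[1], , drop = FALSE], 3)
  expect_equal(pred1, sim$labels[cal[1]])
  # one component on 3 classes still returns labels from the class set
  pred2 <- plsda_fit_predict(X[cal, ], sim$labels[cal], X[val, ], 1)
  expect_true(all(pred2 %in% unique(sim$labels)))
  expect_error(plsda_fit_predict(X[1:5, ], rep("AA", 5), X[6:7, ], 1),
               "2 classes")
})

test_that("Cohen's kappa matches hand computations", {
  expect_equal(cohen_kappa(diag(c(5, 8, 2))), 1)
  expect_equal(cohen_kappa(matrix(25, 2, 2)), 0)
  expect_equal(cohen_kappa(matrix(c(20, 10, 5, 15), 2, 2)), 0.4)
  expect_warning(k <- cohen_kappa(matrix(c(10, 0, 0, 0), 2, 2)),
                 "degenerate")
  expect_equal(k, 0)
  # kappa of the expected table under independence is 0
  cm <- matrix(c(20, 5, 10, 15), 2, 2)
  expected <- outer(rowSums(cm), colSums(cm)) / sum(cm)
  expect_equal(cohen_kappa(expected), 0, tolerance = 1e-12)
})

test_that("the PLS-DA grid finds separable structure and is reproducible", {
  sim <- simulate_labeled_spectra(8, separation = 1, seed = 34)
  X <- subset_range(sim$spectra, 400, 2400)
  g1 <- plsda_grid(X, sim$labels, component_grid = 1:6, n_iter = 40, seed = 7)
  g2 <- plsda_grid(X, sim$labels, component_grid = 1:6, n_iter = 40, seed = 7)
  expect_identical(g1$grid, g2$grid)
  expect_gte(g1$best$kappa_mean, 0.9)
  # accuracy never falls below the majority-class rate on separable data
  expect_gte(min(g1$grid$acc_mean), 1 / 3)
  # confusion matrix rows sum to class counts in the validation splits
  row_tot <- rowSums(g1$best_confusion)
  expect_true(all(row_tot == row_tot[1]))
  # infeasible component counts are capped with a warning
  expect_warning(
    plsda_grid(X, sim$labels, ratios = 0.5, component_grid = 1:15,
               n_iter = 5, seed = 1),
    "capped")
})
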