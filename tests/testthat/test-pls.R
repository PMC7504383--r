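test_that("single-predictor PLS reduces to the least squares line", {
  set.seed(10)
  x <- matrix(rnorm(30), 30, 1)
  y <- 2 + 3 * x[, 1] + rnorm(30, 0, 0.1)
  m <- fit_pls(x, y, 1)
  ols <- lm(y ~ x)
  expect_equal(m$coefficients_raw, unname(coef(ols)[2]), tolerance = 1e-8)
  expect_equal(m$intercept_raw, unname(coef(ols)[1]), tolerance = 1e-8)
})

test_that("at full rank PLS coefficients equal the normal-equations solution", {
  set.seed(11)
  for (rep in 1:50) {
    X <- matrix(rnorm(150), 30, 5)
    y <- rnorm(30)
    b_ols <- solve(crossprod(cbind(1, X)), crossprod(cbind(1, X), y))
    m <- fit_pls(X, y, 5)
    expect_lt(max(abs(m$coefficients_raw - b_ols[-1])) /
                max(abs(b_ols[-1])), 1e-6)
    G <- crossprod(m$scores)
    offdiag <- abs(G - diag(diag(G)))
    expect_lt(max(offdiag / sqrt(outer(diag(G), diag(G)))), 1e-8)
  }
})

test_that("a response unrelated to X yields near-zero training r2 at one component", {
  set.seed(12)
  X <- matrix(rnorm(200 * 20), 200, 20)
  y <- rnorm(200)
  m <- fit_pls(X, y, 1)
  fs <- fit_stats(y, predict(m, X))
  expect_lt(fs$r2, 0.2)
})

test_that("prediction honors centering and is affine-equivariant in y", {
  set.seed(13)
  X <- matrix(rnorm(120), 30, 4)
  y <- X[, 1] - X[, 3] + rnorm(30, 0, 0.2)
  m <- fit_pls(X, y, 3)
  # a row at the training mean predicts the training mean response
  expect_equal(predict(m, matrix(m$x_mean, 1)), mean(y), tolerance = 1e-10)
  # duplicated rows give duplicated predictions
  p2 <- predict(m, X[c(5, 5), ])
  expect_equal(p2[1], p2[2])
  # shifting y shifts all predictions by the same constant
  m2 <- fit_pls(X, y + 7, 3)
  expect_equal(predict(m2, X), predict(m, X) + 7, tolerance = 1e-8)
})

test_that("leave-one-out PRESS matches an independent full-rank oracle", {
  set.seed(14)
  X <- matrix(rnorm(12), 6, 2)
  y <- rnorm(6)
  curve <- loo_press(X, y, 2)
  # oracle: explicit OLS refits (PLS at A = p is OLS at full rank)
  press_ols <- sum(vapply(1:6, function(i) {
    Z <- cbind(1, X[-i, ])
    b <- solve(crossprod(Z), crossprod(Z, y[-i]))
    (y[i] - sum(c(1, X[i, ]) * b))^2
  }, numeric(1)))
  expect_equal(curve$press[2], press_ols, tolerance = 1e-8)
})

test_that("PRESS finds exact recovery on noiseless linear data", {
  set.seed(15)
  X <- matrix(rnorm(60), 20, 3)
  y <- X %*% c(1, -2, 0.5)
  curve <- loo_press(X, y, 3)
  expect_lt(curve$press[3], 1e-10)
})

test_that("PRESS on pure noise does not materially decrease with components", {
  set.seed(16)
  X <- matrix(rnorm(100 * 10), 100, 10)
  y <- rnorm(100)
  curve <- loo_press(X, y, 8)
  expect_lt(min(curve$press), 2 * curve$press[1])
})

test_that("component selection follows the stated rules", {
  curve <- data.frame(components = 1:4, press = c(10, 6, 3, 1))
  expect_equal(select_ncomp(curve, rule = "min"), 4L)
  flat <- data.frame(components = 1:4, press = rep(2, 4))
  expect_equal(select_ncomp(flat), 1L)
  kink <- data.frame(components = 1:4, press = c(10, 4, 3.9, 3.95))
  # smallest A with PRESS within 5% of the minimum (3.9 * 1.05 = 4.095)
  expect_equal(select_ncomp(kink, rule = "onesigma", tol = 0.05), 2L)
  expect_equal(select_ncomp(kink, rule = "min"), 3L)
})

test_that("VIP satisfies its normalization and closed forms", {
  set.seed(17)
  # orthogonal centered design: x1 = y direction, x2 orthogonal noise
  # -> weight vector (1, 0) (the fit centers internally, so center first)
  y <- rnorm(40); y <- y - mean(y)
  x2 <- rnorm(40); x2 <- x2 - mean(x2)
  x2 <- x2 - y * sum(x2 * y) / sum(y * y)
  X <- cbind(y, x2)
  m <- fit_pls(X, y, 1, scale = FALSE)
  v <- vip(m)
  expect_equal(as.numeric(v), c(sqrt(2), 0), tolerance = 1e-8)
  # symmetric two-column design: equal weights -> all VIP = 1
  Xs <- cbind(y + 0.01 * rnorm(40), y + 0.01 * rnorm(40))
  ms <- fit_pls(Xs, y, 1)
  expect_equal(as.numeric(vip(ms)), c(1, 1), tolerance = 0.05)
  # normalization on arbitrary fits
  for (rep in 1:10) {
    X <- matrix(rnorm(40 * 8), 40, 8)
    yy <- rnorm(40)
    mm <- fit_pls(X, yy, 3)
    expect_lt(abs(sum(vip(mm)^2) - 8), 1e-8)
  }
})

test_that("VIP localizes a single informative absorption band", {
  hits <- 0L
  for (s in 1:5) {
    sim <- simulate_band_signal(n = 80, center = 680, seed = s)
    sub <- subset_range(sim$spectra, 600, 900)
    m <- fit_pls(sub$reflectance, sim$y, 3)
    peak <- sub$wavelengths[which.max(vip(m))]
    hits <- hits + (peak >= 660 && peak <= 700)
  }
  expect_gte(hits, 4L)
})

test_that("standardized coefficients are invariant to predictor rescaling", {
  set.seed(18)
  X <- matrix(rnorm(50 * 6), 50, 6)
  y <- X[, 2] + rnorm(50, 0, 0.3)
  b1 <- standardized_coefficients(fit_pls(X, y, 3))
  X2 <- X
  X2[, 4] <- X2[, 4] * 10
  b2 <- standardized_coefficients(fit_pls(X2, y, 3))
  expect_lt(max(abs(b1 - b2)), 1e-8)
  # p = 1, A = 1: standardized coefficient equals the Pearson correlation
  x <- matrix(rnorm(60), 60, 1)
  yy <- 0.5 * x[, 1] + rnorm(60, 0, 1)
  m1 <- fit_pls(x, yy, 1)
  expect_equal(unname(standardized_coefficients(m1)), cor(x[, 1], yy),
               tolerance = 1e-10)
  # null response: coefficients near zero
  bn <- standardized_coefficients(fit_pls(X, rnorm(50), 2))
  expect_lt(max(abs(bn)), 0.5)
})

test_that("JSON serialization round-trips a model exactly", {
  set.seed(19)
  X <- matrix(rnorm(90), 30, 3)
  y <- X[, 1] + rnorm(30, 0, 0.1)
  m <- fit_pls(X, y, 2)
  path <- tempfile(fileext = ".json")
  write_pls_model(m, path)
  m2 <- read_pls_model(path)
  expect_equal(predict(m2, X), predict(m, X), tolerance = 1e-12)
  expect_equal(m2$n_components, m$n_components)
})
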