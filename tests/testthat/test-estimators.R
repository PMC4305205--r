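test_that("OLS recovers exact linear relations and is centering invariant", {
  x <- c(1, 2, 3, 4, 5)
  d <- iv_data(2 * x, x, x)
  expect_equal(unname(fit_ols(d)$beta_hat), 2, tolerance = 1e-12)

  set.seed(7)
  x <- rnorm(40); y <- 1.5 * x + rnorm(40)
  b1 <- fit_ols(iv_data(y, x, x))$beta_hat
  b2 <- fit_ols(iv_data(y - mean(y), x - mean(x), x - mean(x),
                        include_intercept = FALSE))$beta_hat
  expect_equal(unname(b1), unname(b2), tolerance = 1e-10)
})

test_that("OLS on a confounded genotype draw sits near its probability limit", {
  # x = pi*sum(z) + w + e so cov(x,u) = 1, var(x) = J pi^2 sigma_z^2 + 2
  d <- make_toy(3000, 9, seed = 42, pi_z = 0.1)
  plim <- 1 / (9 * 0.01 * 0.42 + 2)
  expect_equal(unname(fit_ols(d)$beta_hat), plim, tolerance = 0.12)
})

test_that("2SLS equals OLS when instruments equal exposures and matches the two-stage oracle", {
  set.seed(3)
  x <- rnorm(30); y <- 0.7 * x + rnorm(30)
  d_self <- iv_data(y, x, x)
  expect_equal(fit_2sls(d_self)$beta_hat, fit_ols(d_self)$beta_hat,
               tolerance = 1e-10)

  d <- toy6()
  expect_equal(unname(fit_2sls(d)$beta_hat), oracle_2sls_two_stage(d),
               tolerance = 1e-10)

  d2 <- make_toy(80, 4, seed = 11)
  expect_equal(unname(fit_2sls(d2)$beta_hat), oracle_2sls_two_stage(d2),
               tolerance = 1e-10)
})

test_that("two-step GMM collapses to 2SLS when just identified and diverges under heteroskedasticity", {
  d <- toy6()
  expect_equal(fit_gmm2(d)$beta_hat, fit_2sls(d)$beta_hat, tolerance = 1e-10)

  dh <- make_toy(400, 4, seed = 21, het = TRUE)
  expect_gt(abs(fit_gmm2(dh)$beta_hat - fit_2sls(dh)$beta_hat), 1e-6)
})

test_that("two-step GMM and 2SLS agree asymptotically under homoskedasticity", {
  set.seed(5)
  n <- 50000
  Z <- matrix(rbinom(n * 3, 2, 0.3), n, 3)
  w <- rnorm(n)
  x <- 0.5 * rowSums(Z) + w + rnorm(n)
  y <- 0.2 * x + w + rnorm(n)
  d <- iv_data(y, x, Z)
  b2 <- fit_2sls(d)
  bg <- fit_gmm2(d)
  se <- conventional_se(b2, d)$se
  expect_lt(abs(bg$beta_hat - b2$beta_hat), 2 * se)
})

test_that("cue_objective matches a loop-built oracle and is zero when just identified", {
  d <- make_toy(50, 3, seed = 9)
  for (b in c(-0.5, 0, 0.3, 1)) {
    expect_equal(as.numeric(cue_objective(b, d)),
                 oracle_cue_objective(b, d), tolerance = 1e-8)
  }

  dj <- toy6()
  b2 <- fit_2sls(dj)$beta_hat
  expect_lt(as.numeric(cue_objective(b2, dj)), 1e-8)
  expect_equal(fit_2sls(dj)$objective_value, 0, tolerance = 1e-8)

  # zero residuals make the weight matrix singular: flagged, not fatal
  x <- c(1, 2, 3, 4, 5, 7)
  dz <- iv_data(2 * x, x, cbind(x, c(0, 1, 0, 1, 1, 2)))
  val <- cue_objective(2, dz)
  expect_true(isTRUE(attr(val, "degenerate")))
})

test_that("fit_cue agrees with a fine grid search on the objective", {
  d <- make_toy(200, 5, seed = 13)
  b_grid <- oracle_cue_grid(d, -5, 5, step = 1e-4)
  b_opt <- fit_cue(d)$beta_hat
  expect_equal(unname(b_opt), b_grid, tolerance = 1e-3)
})

test_that("LIML matches direct minimization of the variance ratio", {
  for (seed in c(2, 4)) {
    d <- make_toy(100, 5, seed = seed)
    fit <- fit_liml(d)
    expect_equal(unname(fit$beta_hat), oracle_liml_ratio(d), tolerance = 1e-6)
    expect_gte(fit$liml_kappa, 1)
  }
})

test_that("all GMM-family estimators collapse to 2SLS when just identified", {
  for (seed in 1:4) {
    d <- make_toy(60, 1, seed = seed, pi_z = 0.4)
    b <- unname(fit_2sls(d)$beta_hat)
    expect_equal(unname(fit_gmm2(d)$beta_hat), b, tolerance = 1e-8)
    liml <- fit_liml(d)
    expect_equal(unname(liml$beta_hat), b, tolerance = 1e-8)
    expect_equal(liml$liml_kappa, 1, tolerance = 1e-8)
    expect_equal(unname(fit_cue(d)$beta_hat), b, tolerance = 1e-8)
  }
})

test_that("2SLS, LIML and CUE are invariant to invertible instrument rotations", {
  for (seed in 1:3) {
    d <- make_toy(120, 4, seed = seed)
    set.seed(seed + 100)
    A <- matrix(rnorm(16), 4, 4) + diag(4)
    dr <- iv_data(d$y, d$X, d$Z %*% A)
    expect_equal(fit_2sls(dr)$beta_hat, fit_2sls(d)$beta_hat,
                 tolerance = 1e-8)
    expect_equal(fit_liml(dr)$beta_hat, fit_liml(d)$beta_hat,
                 tolerance = 1e-8)
    expect_equal(unname(fit_cue(dr)$beta_hat), unname(fit_cue(d)$beta_hat),
                 tolerance = 1e-8)
  }
})

test_that("minimizing the homoskedastic CUE objective reproduces LIML", {
  for (seed in c(6, 8, 10)) {
    d <- make_toy(150, 5, seed = seed)
    b_liml <- unname(fit_liml(d)$beta_hat)
    b_hom <- optimize(function(b) cue_objective(b, d, homoskedastic = TRUE),
                      c(b_liml - 5, b_liml + 5), tol = 1e-12)$minimum
    expect_equal(b_hom, b_liml, tolerance = 1e-6)
    # and the minimized objectives agree: n * lambda
    expect_equal(as.numeric(cue_objective(b_liml, d, homoskedastic = TRUE)),
                 fit_liml(d)$objective_value, tolerance = 1e-6)
  }
})

test_that("sequential_fit matches direct fits per step and collapses at j = 1", {
  d <- make_toy(90, 3, seed = 15)
  res <- sequential_fit(d, order = c(2, 1, 3))
  expect_equal(nrow(res), 6L)

  step1 <- res[res$j == 1, ]
  expect_equal(step1$estimate[step1$estimator == "TSLS"],
               step1$estimate[step1$estimator == "CUE"], tolerance = 1e-8)

  for (j in 1:3) {
    dj <- iv_data(d$y, d$X, d$Z[, c(2, 1, 3)[seq_len(j)], drop = FALSE])
    expect_equal(res$estimate[res$j == j & res$estimator == "TSLS"],
                 unname(fit_2sls(dj)$beta_hat), tolerance = 1e-10)
    expect_equal(res$estimate[res$j == j & res$estimator == "CUE"],
                 unname(fit_cue(dj)$beta_hat), tolerance = 1e-6)
  }
})

test_that("with many weak instruments 2SLS drifts toward OLS along the sweep while CUE does not", {
  late_tsls <- late_cue <- numeric(0)
  set.seed(17)
  for (seed in 1:3) {
    n <- 1500; J <- 40
    Z <- matrix(rbinom(n * J, 2, 0.3), n, J)
    w <- rnorm(n)
    x <- 0.05 * rowSums(Z) + w + rnorm(n)
    y <- w + rnorm(n)                 # beta = 0
    d <- iv_data(y, x, Z)
    res <- sequential_fit(d, estimators = c("tsls", "cue"))
    late <- res$j > 30
    late_tsls <- c(late_tsls, res$estimate[late & res$estimator == "TSLS"])
    late_cue <- c(late_cue, res$estimate[late & res$estimator == "CUE"])
  }
  # once many weak instruments are in, 2SLS sits well towards the (positive)
  # OLS value while the CUE trajectory stays near the true beta = 0
  expect_gt(median(late_tsls), 0.1)
  expect_lt(abs(median(late_cue)), abs(median(late_tsls)))
})
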