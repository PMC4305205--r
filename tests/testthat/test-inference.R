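test_that("conventional standard errors match textbook sandwich oracles", {
  d <- make_toy(50, 3, seed = 31)
  ols <- fit_ols(d)
  expect_equal(unname(conventional_se(ols, d)$se), oracle_ols_se(d),
               tolerance = 1e-10)
  expect_equal(unname(conventional_se(ols, d, robust = TRUE)$se),
               oracle_ols_se(d, robust = TRUE), tolerance = 1e-10)

  tsls <- fit_2sls(d)
  expect_equal(unname(conventional_se(tsls, d)$se), oracle_2sls_se(d),
               tolerance = 1e-10)
  expect_equal(unname(conventional_se(tsls, d, robust = TRUE)$se),
               oracle_2sls_se(d, robust = TRUE), tolerance = 1e-10)

  cue <- fit_cue(d)
  expect_equal(unname(conventional_se(cue, d)$se), oracle_gmm_se(cue, d),
               tolerance = 1e-8)
})

test_that("standard errors shrink like 1/sqrt(n) with strong instruments", {
  ses <- sapply(c(2000, 4000), function(n) {
    set.seed(99)
    Z <- matrix(rbinom(n * 2, 2, 0.3), n, 2)
    w <- rnorm(n)
    x <- 0.8 * rowSums(Z) + w + rnorm(n)
    y <- 0.3 * x + w + rnorm(n)
    d <- iv_data(y, x, Z)
    conventional_se(fit_2sls(d), d)$se
  })
  expect_equal(unname(ses[2] / ses[1]), 1 / sqrt(2), tolerance = 0.1)
})

test_that("Wald tests behave at the null and at the 1.96 boundary", {
  d <- make_toy(100, 3, seed = 41)
  fit <- fit_2sls(d)
  inf <- conventional_se(fit, d)

  at_null <- wald_test(fit, inf, beta0 = unname(fit$beta_hat))
  expect_equal(at_null$statistic, 0, tolerance = 1e-12)
  expect_equal(at_null$p_value, 1)

  at_edge <- wald_test(fit, inf, beta0 = unname(fit$beta_hat) - 1.96 * inf$se)
  expect_equal(at_edge$p_value, 0.05, tolerance = 1e-3)
})

test_that("first-stage diagnostics: exact fit, null first stage, concentration identity", {
  z <- c(0, 1, 2, 0, 1, 2, 1, 0)
  d <- iv_data(rnorm(8), z, z)
  fs <- first_stage_diagnostics(d)
  expect_equal(fs$partial_r2, 1, tolerance = 1e-12)
  expect_equal(fs$expected_f, fs$concentration / fs$J + 1, tolerance = 1e-12)

  # pi = 0: central F with mean ~ 1
  set.seed(51)
  fvals <- replicate(400, {
    n <- 400
    Z <- matrix(rbinom(n * 5, 2, 0.3), n, 5)
    first_stage_diagnostics(iv_data(rnorm(n), rnorm(n), Z))$f_statistic
  })
  expect_lt(abs(mean(fvals) - 1), 3 * sd(fvals) / sqrt(length(fvals)) + 0.01)
})

test_that("concentration parameter and Stock's expected F reproduce the design constants", {
  designs <- list(c(J = 9, pi = 0.1), c(J = 25, pi = 0.06), c(J = 100, pi = 0.03))
  mu2 <- vapply(designs, function(d)
    concentration_parameter(3000, d["J"], d["pi"], 0.3, 2), numeric(1))
  expect_equal(mu2, rep(56.70, 3), tolerance = 1e-12)
  expect_equal(round(vapply(seq_along(designs), function(i)
    expected_f(mu2[i], designs[[i]]["J"]), numeric(1)), 2),
    c(7.30, 3.27, 1.57))
  expect_equal(concentration_parameter(3000, 9, 0, 0.3, 2), 0)
  expect_equal(expected_f(0, 17), 1)
})

test_that("bias approximations reproduce the design values and their qualitative laws", {
  mu2 <- 56.7
  expect_equal(round(bias_2sls_approx(9, mu2, 1, 2), 3), 0.057)
  expect_equal(round(bias_2sls_approx(25, mu2, 1, 2), 3), 0.147)
  expect_equal(round(bias_2sls_approx(100, mu2, 1, 2), 3), 0.318)
  expect_equal(round(bias_liml_approx(mu2, 1, 2), 3), -0.009)

  # no confounding, no bias
  expect_equal(bias_2sls_approx(9, mu2, 0, 2), 0)
  expect_equal(bias_liml_approx(mu2, 0, 2), 0)

  # increasing in J at fixed mu2; LIML bias J-free and opposite in sign
  b <- vapply(c(5, 10, 20, 50, 100), bias_2sls_approx, numeric(1),
              mu2 = mu2, sigma_uv = 1, sigma_v2 = 2)
  expect_true(all(diff(b) > 0))
  expect_true(all(b > 0) && bias_liml_approx(mu2, 1, 2) < 0)

  expect_error(bias_2sls_approx(9, 0, 1, 2), class = "weakivmr_degenerate")
  expect_error(bias_liml_approx(0, 1, 2), class = "weakivmr_degenerate")
})

test_that("corrected standard errors agree with conventional ones when instruments are strong", {
  set.seed(61)
  n <- 10000
  Z <- matrix(rbinom(n * 2, 2, 0.3), n, 2)
  w <- rnorm(n)
  x <- rowSums(Z) + w + rnorm(n)
  y <- 0.1 * x + w + rnorm(n)
  d <- iv_data(y, x, Z)
  expect_gt(first_stage_diagnostics(d)$f_statistic, 1000)

  liml <- fit_liml(d)
  expect_equal(unname(bekker_se(liml, d)$se),
               unname(conventional_se(liml, d)$se), tolerance = 0.02)

  cue <- fit_cue(d)
  expect_equal(unname(nw_se(cue, d)$se),
               unname(conventional_se(cue, d)$se), tolerance = 0.02)
})

test_that("corrected-SE preconditions are enforced", {
  d <- make_toy(60, 3, seed = 71)
  expect_error(bekker_se(fit_2sls(d), d), class = "weakivmr_data_error")
  expect_error(nw_se(fit_liml(d), d), class = "weakivmr_data_error")
})

test_that("overidentification tests: df, error when just identified, size and power", {
  d <- toy6()
  expect_error(sargan_test(fit_2sls(d), d),
               class = "weakivmr_not_overidentified")

  dd <- make_toy(200, 4, seed = 81)
  s <- sargan_test(fit_2sls(dd), dd)
  expect_equal(s$df, 3L)
  h <- hansen_j_test(fit_cue(dd), dd)
  expect_equal(h$df, 3L)
  # Hansen J at the CUE optimum is the minimized objective
  expect_equal(h$statistic, fit_cue(dd)$objective_value, tolerance = 1e-8)

  # size under valid homoskedastic instruments
  set.seed(91)
  reps <- 1000
  rej <- replicate(reps, {
    des <- simulation_design(J = 9, reps = 1, seed = 1)
    dat <- simulate_dataset(des)
    sargan_test(fit_2sls(dat), dat)$p_value < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), mc_se_prop(0.05, reps))

  # power when one instrument violates the exclusion restriction
  set.seed(93)
  rej_bad <- replicate(200, {
    n <- 3000
    Z <- matrix(rbinom(n * 4, 2, 0.3), n, 4)
    w <- rnorm(n)
    x <- 0.15 * rowSums(Z) + w + rnorm(n)
    y <- 0.3 * Z[, 1] + w + rnorm(n)   # direct effect of z1 on y
    dat <- iv_data(y, x, Z)
    sargan_test(fit_2sls(dat), dat)$p_value < 0.05
  })
  expect_gt(mean(rej_bad), 0.3)
})

test_that("Hausman test: degenerate equality, size under exogeneity, power under confounding", {
  # IV estimate equal to OLS estimate -> statistic 0 (clamped with warning)
  set.seed(95)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  d_self <- iv_data(y, x, x)
  expect_warning(
    h0 <- hausman_test(fit_2sls(d_self), fit_ols(d_self), d_self),
    "Hausman")
  expect_equal(h0$statistic, 0)

  # size: no confounding
  set.seed(97)
  reps <- 1000
  rej <- replicate(reps, {
    n <- 1000
    Z <- matrix(rbinom(n * 3, 2, 0.3), n, 3)
    x <- 0.3 * rowSums(Z) + rnorm(n)
    y <- rnorm(n)
    dat <- iv_data(y, x, Z)
    suppressWarnings(
      hausman_test(fit_2sls(dat), fit_ols(dat), dat)$p_value < 0.05)
  })
  expect_lt(abs(mean(rej) - 0.05), mc_se_prop(0.05, reps) + 0.005)

  # power: strong instruments, confounded
  set.seed(98)
  rej_conf <- replicate(100, {
    n <- 3000
    Z <- matrix(rbinom(n * 3, 2, 0.3), n, 3)
    w <- rnorm(n)
    x <- 0.5 * rowSums(Z) + w + rnorm(n)
    y <- w + rnorm(n)
    dat <- iv_data(y, x, Z)
    hausman_test(fit_2sls(dat), fit_ols(dat), dat)$p_value < 0.05
  })
  expect_gt(mean(rej_conf), 0.9)
})
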