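#' Simulation design for the genotype-based data-generating process
#'
#' Describes one cell of the Monte Carlo study: `n` individuals, `J`
#' independent variants with minor allele frequency `maf`, a common
#' first-stage coefficient `pi_z`, and a causal effect `beta`. The generating
#' model is
#' \deqn{x_i = \pi_z \sum_j z_{ij} + w_i + \epsilon_{xi}, \qquad
#'       y_i = \beta x_i + w_i + \epsilon_{yi},}
#' with \eqn{w, \epsilon_x, \epsilon_y} independent standard normal, so the
#' shared confounder \eqn{w} induces error covariance
#' \eqn{\sigma_{uv} = 1} and first-stage error variance \eqn{\sigma_v^2 = 2};
#' genotypes are i.i.d. Binomial(2, maf). The default designs pair
#' `J = 9, 25, 100` with `pi_z = 0.1, 0.06, 0.03`, which hold the
#' concentration parameter fixed at \eqn{\mu^2 = 56.70} so instruments grow
#' weaker as they grow more numerous.
#'
#' @param J Number of variants.
#' @param n Sample size per replicate. Default 3000.
#' @param pi_z Common first-stage coefficient. Defaults to 0.1, 0.06, 0.03
#'   for `J` = 9, 25, 100 and must be given explicitly otherwise.
#' @param maf Minor allele frequency, in (0, 1). Default 0.3.
#' @param beta True causal effect. Default 0.
#' @param reps Monte Carlo replicates. Default 10000.
#' @param seed Master seed for the replicate stream.
#' @param estimators Character subset of
#'   `c("ols", "tsls", "gmm2", "liml", "cue", "allele_score")`.
#' @param alpha Nominal test size for rejection frequencies. Default 0.05.
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(J, n = 3000, pi_z = NULL, maf = 0.3, beta = 0,
                              reps = 10000, seed = 1,
                              estimators = c("tsls", "liml", "cue",
                                             "allele_score"),
                              alpha = 0.05) {
  if (is.null(pi_z)) {
    pi_z <- c(`9` = 0.1, `25` = 0.06, `100` = 0.03)[as.character(J)]
    if (is.na(pi_z))
      iv_error("no default pi_z for this J; supply pi_z explicitly",
               "weakivmr_data_error")
    pi_z <- unname(pi_z)
  }
  stopifnot(maf > 0, maf < 1, reps >= 1, is.finite(pi_z), J >= 1, n > J,
            alpha > 0, alpha < 1)
  estimators <- match.arg(estimators,
                          c("ols", "tsls", "gmm2", "liml", "cue",
                            "allele_score"),
                          several.ok = TRUE)
  structure(list(n = as.integer(n), J = as.integer(J), pi_z = pi_z, maf = maf,
                 beta = beta, reps = as.integer(reps), seed = as.integer(seed),
                 estimators = estimators, alpha = alpha,
                 sigma_v2 = 2, sigma_uv = 1),
            class = "simulation_design")
}

#' @export
print.simulation_design <- function(x, ...) {
  cat(sprintf("<simulation_design> n = %d, J = %d, pi_z = %g, maf = %g, beta = %g, reps = %d, seed = %d\n",
              x$n, x$J, x$pi_z, x$maf, x$beta, x$reps, x$seed))
  cat("estimators:", paste(x$estimators, collapse = ", "), "\n")
  invisible(x)
}

#' Generate a genotype matrix
#'
#' Independent additive genotype dosages, entries i.i.d. Binomial(2, maf),
#' mimicking Hardy-Weinberg allele counts with dosage variance
#' `2 * maf * (1 - maf)`. Uses the current RNG state.
#'
#' @param n Individuals.
#' @param J Variants.
#' @param maf Minor allele frequency in [0, 1).
#' @return A [genotype_matrix].
#' @export
generate_genotypes <- function(n, J, maf) {
  stopifnot(maf >= 0, maf < 1, n >= 1, J >= 1)
  G <- matrix(stats::rbinom(n * J, 2L, maf), n, J)
  genotype_matrix(G)
}

#' Draw one dataset from a simulation design
#'
#' Draws genotypes and the confounded outcome/exposure pair from the model in
#' [simulation_design], using the current RNG state (seed replicate streams
#' with `set.seed`; [run_monte_carlo] does this per replicate).
#'
#' @param design A [simulation_design].
#' @return An [iv_data] with the genotype dosages as instruments.
#' @export
simulate_dataset <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  n <- design$n
  G <- generate_genotypes(n, design$J, design$maf)
  w <- stats::rnorm(n)
  x <- design$pi_z * rowSums(G$G) + w + stats::rnorm(n)
  y <- design$beta * x + w + stats::rnorm(n)
  iv_data(y, x, G$G)
}

# (estimator, se_kind) pairs run for a design
mc_se_plan <- function(estimators) {
  plan <- list(ols = "conventional", tsls = "conventional",
               gmm2 = "conventional",
               liml = c("conventional", "bekker"),
               cue = c("conventional", "newey_windmeijer"),
               allele_score = "conventional")
  out <- do.call(rbind, lapply(estimators, function(e)
    data.frame(estimator = e, se_kind = plan[[e]])))
  rownames(out) <- NULL
  out
}

#' Run the Monte Carlo study for one design
#'
#' For each replicate: simulate a dataset, fit the requested estimators (CUE
#' started from \{-2,-1,0,1,2\} times the two-step GMM estimate), compute
#' conventional and — for LIML and CUE — many-weak-instrument corrected
#' standard errors, and test `H0: beta = beta_true` by Wald tests at level
#' `alpha`. Replicates use independent substreams spawned from the master
#' seed, so results are reproducible and independent of execution order.
#' Medians and interquartile ranges are reported (not means) because LIML and
#' CUE occasionally produce very large outliers; no trimming is applied.
#'
#' @param design A [simulation_design].
#' @param keep_reps Keep the per-replicate long table? Default `TRUE`.
#' @return An object of class `mc_summary`: `estimates` (median and IQR per
#'   estimator), `rejections` (rejection frequency per estimator and SE kind),
#'   `mean_first_stage_F`, `theoretical` (`mu2`, `expected_f`, `bias_2sls`,
#'   `bias_liml`), `failures`, `reps`, `design`, and (optionally) `per_rep`.
#'   Per-replicate failures are recorded, not fatal; a warning flags failure
#'   rates above 1%.
#' @export
run_monte_carlo <- function(design, keep_reps = TRUE) {
  stopifnot(inherits(design, "simulation_design"))
  reps <- design$reps
  plan <- mc_se_plan(design$estimators)
  ncmb <- nrow(plan)
  zcrit <- stats::qnorm(1 - design$alpha / 2)

  set.seed(design$seed)
  rep_seeds <- sample.int(2147483646L, reps, replace = TRUE)

  beta <- se <- matrix(NA_real_, reps, ncmb)
  fstat <- rep(NA_real_, reps)
  failures <- 0L

  for (r in seq_len(reps)) {
    set.seed(rep_seeds[r])
    dat <- simulate_dataset(design)
    fstat[r] <- first_stage_diagnostics(dat)$f_statistic
    fits <- list()
    score_dat <- NULL
    for (i in seq_len(ncmb)) {
      est <- plan$estimator[i]
      kind <- plan$se_kind[i]
      res <- tryCatch({
        if (is.null(fits[[est]])) {
          fits[[est]] <- switch(est,
            ols = fit_ols(dat),
            tsls = fit_2sls(dat),
            gmm2 = fit_gmm2(dat),
            liml = fit_liml(dat),
            cue = fit_cue(dat),
            allele_score = {
              if (is.null(score_dat)) {
                s <- rowSums(dat$Z)
                score_dat <- iv_data(dat$y, dat$X, matrix(s, ncol = 1),
                                     include_intercept = dat$include_intercept)
              }
              fit_2sls(score_dat)
            })
        }
        fit <- fits[[est]]
        d_use <- if (est == "allele_score") score_dat else dat
        inf <- switch(kind,
                      conventional = conventional_se(fit, d_use),
                      bekker = bekker_se(fit, d_use),
                      newey_windmeijer = nw_se(fit, d_use))
        c(fit$beta_hat[1L], inf$se[1L])
      }, error = function(e) NULL)
      if (is.null(res)) failures <- failures + 1L else {
        beta[r, i] <- res[1L]
        se[r, i] <- res[2L]
      }
    }
  }

  reject <- abs(beta - design$beta) / se > zcrit
  est_rows <- !duplicated(plan$estimator)
  estimates <- data.frame(
    estimator = plan$estimator[est_rows],
    median = apply(beta[, est_rows, drop = FALSE], 2, stats::median,
                   na.rm = TRUE),
    iqr = apply(beta[, est_rows, drop = FALSE], 2, stats::IQR, na.rm = TRUE))
  rownames(estimates) <- NULL
  rejections <- cbind(plan,
                      rejection_frequency = colMeans(reject, na.rm = TRUE))

  mu2 <- concentration_parameter(design$n, design$J, design$pi_z, design$maf,
                                 design$sigma_v2)
  theoretical <- list(
    mu2 = mu2,
    expected_f = expected_f(mu2, design$J),
    bias_2sls = bias_2sls_approx(design$J, mu2, design$sigma_uv,
                                 design$sigma_v2),
    bias_liml = bias_liml_approx(mu2, design$sigma_uv, design$sigma_v2))

  if (failures > 0.01 * reps * ncmb)
    warning(sprintf("%d of %d fits failed (> 1%% of replicates)",
                    failures, reps * ncmb))

  per_rep <- NULL
  if (keep_reps) {
    per_rep <- data.frame(
      rep = rep(seq_len(reps), each = ncmb),
      estimator = rep(plan$estimator, reps),
      beta_hat = as.vector(t(beta)),
      se_kind = rep(plan$se_kind, reps),
      se = as.vector(t(se)),
      reject = as.vector(t(reject)))
  }

  structure(list(estimates = estimates, rejections = rejections,
                 mean_first_stage_F = mean(fstat, na.rm = TRUE),
                 first_stage_F = fstat,
                 theoretical = theoretical, failures = failures,
                 reps = reps, design = design, per_rep = per_rep),
            class = "mc_summary")
}

#' @export
print.mc_summary <- function(x, ...) {
  d <- x$design
  cat(sprintf("<mc_summary> J = %d, n = %d, reps = %d (failures: %d)\n",
              d$J, d$n, x$reps, x$failures))
  cat(sprintf("mu2 = %.2f, E[F] = %.2f, mean empirical F = %.2f\n",
              x$theoretical$mu2, x$theoretical$expected_f,
              x$mean_first_stage_F))
  m <- merge(x$rejections, x$estimates, by = "estimator", sort = FALSE)
  print(m, digits = 3)
  invisible(x)
}

#' Write Monte Carlo outputs
#'
#' Writes the per-replicate long table as TSV and the summary as JSON.
#'
#' @param summary An `mc_summary`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_mc_summary <- function(summary, dir) {
  stopifnot(inherits(summary, "mc_summary"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if (!is.null(summary$per_rep)) {
    p <- file.path(dir, "replicates.tsv")
    utils::write.table(summary$per_rep, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "summary.json")
  jsonlite::write_json(
    list(design = unclass(summary$design),
         estimates = summary$estimates,
         rejections = summary$rejections,
         mean_first_stage_F = summary$mean_first_stage_F,
         theoretical = summary$theoretical,
         failures = summary$failures, reps = summary$reps),
    p, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, p))
}

#' Side-by-side theoretical and empirical simulation table
#'
#' Runs [run_monte_carlo] for each design and arranges theoretical bias
#' approximations next to empirical medians, interquartile ranges and Wald
#' rejection frequencies, one block per number of instruments, in the layout
#' Bias / Median / IQR / RF with separate corrected-SE rows for LIML and CUE.
#'
#' @param designs List of [simulation_design] objects (possibly empty).
#' @return An object of class `iv_table_one` with elements `table` (data
#'   frame) and `summaries` (the underlying `mc_summary` objects).
#' @export
table_one <- function(designs) {
  stopifnot(is.list(designs))
  summaries <- lapply(designs, run_monte_carlo, keep_reps = FALSE)
  rows <- list()
  for (s in summaries) {
    J <- s$design$J
    g <- function(est) s$estimates[s$estimates$estimator == est, , drop = FALSE]
    rf <- function(est, kind) {
      r <- s$rejections
      v <- r$rejection_frequency[r$estimator == est & r$se_kind == kind]
      if (length(v)) v else NA_real_
    }
    add <- function(label, bias, est, kind) {
      e <- g(est)
      if (!nrow(e)) return()
      rows[[length(rows) + 1L]] <<- data.frame(
        k = J, estimator = label, bias = bias,
        median = e$median, iqr = e$iqr, rf = rf(est, kind))
    }
    add("2SLS", s$theoretical$bias_2sls, "tsls", "conventional")
    add("LIML", s$theoretical$bias_liml, "liml", "conventional")
    if ("liml" %in% s$design$estimators)
      rows[[length(rows) + 1L]] <- data.frame(
        k = J, estimator = "Corrected LIML", bias = NA_real_,
        median = NA_real_, iqr = NA_real_, rf = rf("liml", "bekker"))
    add("CUE", NA_real_, "cue", "conventional")
    if ("cue" %in% s$design$estimators)
      rows[[length(rows) + 1L]] <- data.frame(
        k = J, estimator = "Corrected CUE", bias = NA_real_,
        median = NA_real_, iqr = NA_real_, rf = rf("cue", "newey_windmeijer"))
    add("Allele score IV", NA_real_, "allele_score", "conventional")
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(k = integer(0), estimator = character(0), bias = numeric(0),
               median = numeric(0), iqr = numeric(0), rf = numeric(0))
  structure(list(table = tab, summaries = summaries), class = "iv_table_one")
}

#' @export
print.iv_table_one <- function(x, ...) {
  cat("Simulation results: theoretical bias and empirical median / IQR / RF\n")
  if (!nrow(x$table)) {
    cat("(no designs)\n")
    return(invisible(x))
  }
  tab <- x$table
  fm <- function(v, d = 3) ifelse(is.na(v), "", formatC(v, digits = d,
                                                        format = "f"))
  out <- data.frame(k = tab$k, Estimator = tab$estimator,
                    Bias = fm(tab$bias), Median = fm(tab$median),
                    IQR = fm(tab$iqr), RF = fm(tab$rf))
  print(out, row.names = FALSE, right = FALSE)
  for (s in x$summaries)
    cat(sprintf("k = %d: mu2 = %.2f, E[F] = %.2f, mean empirical F = %.2f\n",
                s$design$J, s$theoretical$mu2, s$theoretical$expected_f,
                s$mean_first_stage_F))
  invisible(x)
}

#' Write the simulation table and its JSON twin
#'
#' @param x An `iv_table_one`.
#' @param txt_path Path for the fixed-width text rendering (optional).
#' @param json_path Path for the machine-readable JSON twin (optional).
#' @return Invisibly, the paths written.
#' @export
write_table_one <- function(x, txt_path = NULL, json_path = NULL) {
  stopifnot(inherits(x, "iv_table_one"))
  paths <- character(0)
  if (!is.null(txt_path)) {
    con <- file(txt_path, "w")
    sink(con)
    print(x)
    sink()
    close(con)
    paths <- c(paths, txt_path)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(table = x$table,
           designs = lapply(x$summaries, function(s) unclass(s$design)),
           theoretical = lapply(x$summaries, `[[`, "theoretical"),
           mean_first_stage_F = vapply(x$summaries, `[[`, numeric(1),
                                       "mean_first_stage_F")),
      json_path, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, json_path)
  }
  invisible(paths)
}
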