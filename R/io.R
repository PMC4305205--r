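#' Read an analysis dataset from delimited text files
#'
#' Reads a phenotype table (one row per individual, containing the outcome and
#' exposure columns) and a genotype table (one row per individual, one 0/1/2
#' column per variant), plus an optional two-column weights file
#' (`variant_id`, `weight`). Comma or tab delimiters are sniffed from the
#' header line. Rows with missing outcome, exposure or genotype entries are
#' dropped complete-case style, with the exclusion count reported via
#' `message()`.
#'
#' @param phenotype Path to the phenotype table.
#' @param genotype Path to the genotype table.
#' @param weights Optional path to the weights file.
#' @param outcome,exposure Column names in the phenotype table. Defaults
#'   `"outcome"`, `"exposure"`.
#' @param id_col Optional shared id column name present in both tables; when
#'   given, tables are matched on it (and it is excluded from the genotype
#'   columns).
#' @return A list with `data` (an [iv_data] using all variants as
#'   instruments), `genotypes` (a [genotype_matrix], carrying weights when
#'   supplied), `ids`, and `n_dropped`.
#' @export
read_iv_dataset <- function(phenotype, genotype, weights = NULL,
                            outcome = "outcome", exposure = "exposure",
                            id_col = NULL) {
  ph <- read_delim_sniff(phenotype)
  gt <- read_delim_sniff(genotype)
  for (col in c(outcome, exposure))
    if (!col %in% names(ph))
      iv_error(sprintf("column '%s' not found in %s", col, phenotype),
               "weakivmr_data_error")
  if (!is.null(id_col)) {
    if (!id_col %in% names(ph) || !id_col %in% names(gt))
      iv_error(sprintf("id column '%s' missing from an input table", id_col),
               "weakivmr_data_error")
    m <- match(ph[[id_col]], gt[[id_col]])
    if (anyNA(m))
      iv_error("phenotype ids missing from the genotype table",
               "weakivmr_data_error")
    gt <- gt[m, , drop = FALSE]
    ids <- ph[[id_col]]
    gt[[id_col]] <- NULL
  } else {
    if (nrow(ph) != nrow(gt))
      iv_error("phenotype and genotype tables differ in length and no id column was given",
               "weakivmr_data_error")
    ids <- seq_len(nrow(ph))
  }
  G <- as.matrix(gt)
  if (!is.numeric(G))
    iv_error("genotype table contains non-numeric entries", "weakivmr_data_error")
  y <- ph[[outcome]]
  x <- ph[[exposure]]
  keep <- !(is.na(y) | is.na(x) | rowSums(is.na(G)) > 0)
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(sprintf("excluded %d of %d individuals with missing outcome, exposure or genotype data",
                    n_dropped, length(keep)))
  if (!any(keep))
    iv_error("no complete cases remain", "weakivmr_data_error")
  G <- G[keep, , drop = FALSE]

  w <- NULL
  if (!is.null(weights)) {
    wt <- read_delim_sniff(weights)
    if (!all(c("variant_id", "weight") %in% names(wt)))
      iv_error("weights file needs columns variant_id and weight",
               "weakivmr_data_error")
    m <- match(colnames(G), wt$variant_id)
    if (anyNA(m))
      iv_error("weights file is missing some variants", "weakivmr_data_error")
    w <- wt$weight[m]
  }
  gm <- genotype_matrix(G, weights = w)
  list(data = iv_data(y[keep], matrix(x[keep], ncol = 1,
                                      dimnames = list(NULL, exposure)),
                      gm$G),
       genotypes = gm, ids = ids[keep], n_dropped = n_dropped)
}

read_delim_sniff <- function(path) {
  if (!file.exists(path))
    iv_error(paste0("file not found: ", path), "weakivmr_data_error")
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >=
             lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write a synthetic fixture dataset to disk
#'
#' Generates a small synthetic dataset and writes `phenotype.csv`,
#' `genotype.csv` and (for `kind = "alspac_like"`) `weights.csv` into `dir`,
#' in the format [read_iv_dataset] expects. `kind = "dgp"` draws from the
#' equal-effect simulation model of [simulation_design]; `kind =
#' "alspac_like"` emulates the *shape* of a height-style cohort analysis —
#' many variants with heterogeneous small effects, variable allele
#' frequencies, and an external-weights file — without any real cohort data
#' (all values are synthetic).
#'
#' @param dir Output directory (created if needed).
#' @param n Individuals. Default 50.
#' @param J Variants. Default 5 (`"dgp"`); use e.g. 180 for `"alspac_like"`.
#' @param kind `"dgp"` or `"alspac_like"`.
#' @param seed Seed for the draw.
#' @return Invisibly, a named character vector of file paths.
#' @export
make_fixture <- function(dir, n = 50, J = 5, kind = c("dgp", "alspac_like"),
                         seed = 1) {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  if (kind == "dgp") {
    design <- simulation_design(J = J, n = n, pi_z = 0.1, maf = 0.3,
                                beta = 0, reps = 1, seed = seed)
    dat <- simulate_dataset(design)
    G <- dat$Z
    y <- dat$y
    x <- drop(dat$X)
    w <- NULL
  } else {
    maf <- stats::runif(J, 0.1, 0.5)
    G <- sapply(maf, function(p) stats::rbinom(n, 2L, p))
    ext_w <- abs(stats::rnorm(J, 0.05, 0.03)) + 0.005   # external effect sizes
    gamma <- ext_w * (0.8 + 0.4 * stats::runif(J))      # in-sample effects differ
    conf <- stats::rnorm(n)
    x <- drop(G %*% gamma) + conf + stats::rnorm(n)
    y <- 0.4 * x + conf + stats::rnorm(n)
    w <- ext_w
  }
  colnames(G) <- paste0("v", seq_len(J))
  paths <- c(phenotype = file.path(dir, "phenotype.csv"),
             genotype = file.path(dir, "genotype.csv"))
  utils::write.csv(data.frame(id = seq_len(n), outcome = y, exposure = x),
                   paths["phenotype"], row.names = FALSE, quote = FALSE)
  utils::write.csv(cbind(data.frame(id = seq_len(n)), as.data.frame(G)),
                   paths["genotype"], row.names = FALSE, quote = FALSE)
  if (!is.null(w)) {
    paths <- c(paths, weights = file.path(dir, "weights.csv"))
    utils::write.csv(data.frame(variant_id = colnames(G), weight = w),
                     paths["weights"], row.names = FALSE, quote = FALSE)
  }
  invisible(paths)
}

#' Serialize an estimate with its inference to JSON
#'
#' @param result An `iv_estimate`.
#' @param inferences List of `iv_inference` objects for that estimate.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_estimate_json <- function(result, inferences, path) {
  obj <- list(estimator = result$estimator,
              beta_hat = as.list(result$beta_hat),
              objective_value = result$objective_value,
              liml_kappa = result$liml_kappa,
              converged = result$converged,
              n = result$n, J = result$J, l = result$l,
              inference = lapply(inferences, function(i)
                list(se_kind = i$se_kind, se = as.list(i$se),
                     wald_stat = i$wald_stat, p_value = i$p_value,
                     ci_low = as.list(i$ci_low), ci_high = as.list(i$ci_high))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
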