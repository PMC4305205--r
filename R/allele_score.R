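#' Genotype matrix with optional external weights
#'
#' Validates a matrix of additively coded genotypes (0, 1 or 2 copies of the
#' trait-increasing allele per variant) and optional per-variant weights, e.g.
#' effect sizes from an external genome-wide association study. Weights from
#' an external study avoid the overfitting that in-sample weight estimation
#' reintroduces.
#'
#' @param G Integer matrix, individuals in rows, variants in columns, entries
#'   in \{0, 1, 2\}.
#' @param variant_ids Optional variant labels (defaults to column names).
#' @param weights Optional numeric vector of per-allele effects, length
#'   `ncol(G)`, all finite.
#' @return An object of class `genotype_matrix` with elements `G`,
#'   `variant_ids`, `weights`, `n`, `J`.
#' @export
genotype_matrix <- function(G, variant_ids = colnames(G), weights = NULL) {
  G <- as.matrix(G)
  if (anyNA(G))
    iv_error("missing genotypes are not allowed; drop incomplete rows first",
             "weakivmr_data_error")
  bad <- which(!(G %in% c(0, 1, 2)))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(G)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(G)) + 1L
    iv_error(sprintf("genotype entry not in {0,1,2} at row %d, column %d (value %s)",
                     i, j, format(G[i, j])), "weakivmr_data_error")
  }
  storage.mode(G) <- "double"
  if (is.null(variant_ids)) variant_ids <- paste0("v", seq_len(ncol(G)))
  colnames(G) <- variant_ids
  if (!is.null(weights)) {
    weights <- as.numeric(weights)
    if (length(weights) != ncol(G) || any(!is.finite(weights)))
      iv_error("weights must be finite and one per variant", "weakivmr_data_error")
  }
  structure(list(G = G, variant_ids = variant_ids, weights = weights,
                 n = nrow(G), J = ncol(G)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d variants%s\n",
              x$n, x$J, if (is.null(x$weights)) "" else " (weighted)"))
  invisible(x)
}

#' Unweighted allele score
#'
#' The count of trait-increasing alleles per individual,
#' \eqn{S_i = \sum_j G_{ij}}, used as a single instrument in place of the
#' individual variants.
#'
#' @param G A [genotype_matrix] (or plain 0/1/2 matrix).
#' @return Numeric vector of length `n`.
#' @export
unweighted_score <- function(G) {
  if (!inherits(G, "genotype_matrix")) G <- genotype_matrix(G)
  rowSums(G$G)
}

#' Weighted allele score
#'
#' \eqn{S_i = \sum_j w_j G_{ij}} with per-variant weights reflecting the
#' strength of each variant's association with the exposure.
#'
#' @param G A [genotype_matrix] carrying weights, or a plain matrix combined
#'   with `weights`.
#' @param weights Optional weights overriding those stored in `G`.
#' @return Numeric vector of length `n`.
#' @export
weighted_score <- function(G, weights = NULL) {
  if (!inherits(G, "genotype_matrix")) G <- genotype_matrix(G, weights = weights)
  w <- if (is.null(weights)) G$weights else weights
  if (is.null(w))
    iv_error("no weights available; supply weights or use unweighted_score()",
             "weakivmr_data_error")
  if (length(w) != G$J || any(!is.finite(w)))
    iv_error("weights must be finite and one per variant", "weakivmr_data_error")
  drop(G$G %*% w)
}

#' Standardize a variable to mean zero, standard deviation one
#'
#' Uses the sample (n - 1) standard deviation. IV point estimates and Wald
#' statistics using a score instrument are invariant to this rescaling; it
#' only eases interpretation.
#'
#' @param x Non-constant numeric vector.
#' @return Standardized vector.
#' @export
standardize <- function(x) {
  x <- as.numeric(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    iv_error("cannot standardize a constant vector", "weakivmr_degenerate")
  (x - mean(x)) / s
}
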