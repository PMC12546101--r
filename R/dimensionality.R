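#' Eigenvalues of the constrained matrix for a scree plot
#'
#' @param zhat Constrained matrix from [external_analysis()] (or any
#'   column-centered matrix).
#' @return Non-increasing eigenvalues of zhat'zhat/(N-1); their sum equals
#'   the constrained variance.
#' @export
scree_eigenvalues <- function(zhat) {
  svd(zhat, nu = 0, nv = 0)$d^2 / (nrow(zhat) - 1)
}

#' Horn's parallel analysis for component retention
#'
#' Compares the observed eigenvalues with quantiles of eigenvalues obtained
#' from datasets of independent standard normals with the same dimensions.
#' In `on_constrained` mode (the default) each null replicate is passed
#' through the external regression step before eigendecomposition, so the
#' null respects the inflation that fitting p predictors to N subjects
#' induces in the constrained spectrum; `on_criteria` runs classical
#' parallel analysis on the raw criterion block. Components are retained
#' while the observed eigenvalue exceeds the null quantile, counted from the
#' first.
#'
#' @param m A `sample_matrix`.
#' @param n_components_max Unused placeholder for symmetry with other
#'   retention rules; all q eigenvalues are always compared.
#' @param n_reps Number of null replicates (>= 100).
#' @param quantile Null quantile to exceed (default 0.95).
#' @param seed Optional integer seed for the null simulation.
#' @param mode `"on_constrained"` or `"on_criteria"`.
#' @return A `parallel_analysis` object with `observed_eigenvalues`,
#'   `null_eigenvalue_quantiles`, `n_retained`, `n_reps`, `quantile`,
#'   `seed`, `mode`.
#' @export
horns_parallel <- function(m, n_reps = 1000, quantile = 0.95, seed = NULL,
                           mode = c("on_constrained", "on_criteria"),
                           n_components_max = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_reps >= 100)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(m$values)
  p <- length(m$predictor_names)
  q <- length(m$criterion_names)

  G <- standardize(predictor_block(m))
  Z <- standardize(criterion_block(m))
  observed <- if (mode == "on_constrained") {
    scree_eigenvalues(external_analysis(Z, G)$constrained)
  } else {
    scree_eigenvalues(Z)
  }

  null_eig <- matrix(NA_real_, n_reps, q)
  for (b in seq_len(n_reps)) {
    z0 <- standardize(matrix(stats::rnorm(n * q), n))
    if (mode == "on_constrained") {
      g0 <- standardize(matrix(stats::rnorm(n * p), n))
      z0 <- external_analysis(z0, g0)$constrained
    }
    null_eig[b, ] <- scree_eigenvalues(z0)
  }
  qs <- apply(null_eig, 2, stats::quantile, probs = quantile, names = FALSE)

  above <- observed > qs
  n_retained <- if (above[1]) {
    which(c(!above, TRUE))[1] - 1L  # leading run of exceedances
  } else 0L

  structure(
    list(observed_eigenvalues = observed,
         null_eigenvalue_quantiles = qs,
         n_retained = as.integer(n_retained),
         n_reps = n_reps, quantile = quantile, seed = seed, mode = mode),
    class = "parallel_analysis")
}

#' @export
print.parallel_analysis <- function(x, ...) {
  cat("Horn's parallel analysis (", x$mode, ", ", x$n_reps, " reps, q = ",
      x$quantile, "): retain ", x$n_retained, " component(s)\n", sep = "")
  tab <- cbind(observed = x$observed_eigenvalues,
               null_quantile = x$null_eigenvalue_quantiles)
  print(round(utils::head(tab, 10), 4))
  invisible(x)
}
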