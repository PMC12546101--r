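#' External analysis: project criteria onto the predictor space
#'
#' The external (regression) step of constrained PCA. Each criterion column
#' of `Z` is replaced by its least-squares projection onto the column space
#' of the predictor block `G`, yielding the constrained matrix. The overlap
#' fraction trace(Zhat'Zhat)/trace(Z'Z) measures the share of criterion
#' variance predictable from the predictors; it equals the mean per-criterion
#' regression R-squared when columns are standardized.
#'
#' @param Z Standardized criterion matrix (N x q).
#' @param G Standardized predictor matrix (N x p), full column rank.
#' @param tol Relative tolerance for the rank check: singular directions
#'   below `tol` times the largest are treated as null.
#' @return List with `constrained` (the N x q projected matrix),
#'   `overlap_fraction`, and the predictor QR decomposition (reused
#'   internally).
#' @export
external_analysis <- function(Z, G, tol = 1e-10) {
  stopifnot(nrow(Z) == nrow(G))
  qrg <- qr(G, tol = tol)
  if (qrg$rank < ncol(G)) {
    bad <- colnames(G)[qrg$pivot[-seq_len(qrg$rank)]]
    if (is.null(bad)) bad <- qrg$pivot[-seq_len(qrg$rank)]
    stop("predictor block is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  zhat <- qr.fitted(qrg, Z)
  dimnames(zhat) <- dimnames(Z)
  list(constrained = zhat,
       overlap_fraction = sum(zhat * zhat) / sum(Z * Z),
       qr = qrg)
}

#' Internal analysis: principal components of the constrained matrix
#'
#' Singular value decomposition of the constrained matrix. Component scores
#' are the left singular vectors rescaled to zero mean and unit variance
#' (N - 1 denominator); loadings on the covariance scale are V d / sqrt(N-1).
#' Variance fractions are reported both relative to the constrained
#' (predictable) criterion variance and relative to the total criterion
#' variance.
#'
#' @param zhat Constrained matrix from [external_analysis()].
#' @param n_components Number of components m, at most rank(zhat).
#' @param total_ss Total criterion sum of squares trace(Z'Z); when `NULL`
#'   the constrained sum of squares is used (fractions of total then equal
#'   fractions of constrained).
#' @param tol Relative singular-value tolerance defining the rank.
#' @return List with `scores` (N x m), `loadings` (q x m, covariance scale),
#'   `singular_values` (full spectrum), `var_frac_constrained`,
#'   `var_frac_total` (each length m).
#' @export
internal_analysis <- function(zhat, n_components, total_ss = NULL,
                              tol = 1e-10) {
  n <- nrow(zhat)
  sv <- svd(zhat)
  rank <- sum(sv$d > tol * sv$d[1])
  if (n_components > rank) {
    stop("n_components = ", n_components, " exceeds rank(constrained) = ",
         rank)
  }
  ss_constrained <- sum(sv$d^2)
  if (is.null(total_ss)) total_ss <- ss_constrained
  k <- seq_len(n_components)
  scores <- sv$u[, k, drop = FALSE] * sqrt(n - 1)
  loadings <- sv$v[, k, drop = FALSE] %*%
    diag(sv$d[k] / sqrt(n - 1), n_components)
  rownames(loadings) <- colnames(zhat)
  colnames(loadings) <- colnames(scores) <- paste0("C", k)
  list(scores = scores,
       loadings = loadings,
       singular_values = sv$d,
       var_frac_constrained = sv$d[k]^2 / ss_constrained,
       var_frac_total = sv$d[k]^2 / total_ss)
}

#' Varimax rotation of a CPCA solution
#'
#' Applies an orthogonal varimax rotation jointly to the loadings and the
#' component scores, so that scores remain zero mean, unit variance and
#' pairwise uncorrelated while loadings approach simple structure. Kaiser
#' row-normalization is applied by default. With a single component the
#' solution is returned unchanged.
#'
#' @param solution A `cpca_solution` from [fit_cpca()] or the list returned
#'   by [internal_analysis()].
#' @param normalize Kaiser-normalize loading rows before rotation.
#' @return The solution with rotated `scores` and `loadings`, the rotation
#'   matrix in `rotation`, and variance fractions recomputed for the rotated
#'   axes.
#' @export
varimax_rotate <- function(solution, normalize = TRUE) {
  m <- ncol(solution$loadings)
  if (m < 2L) {
    solution$rotation <- diag(m)
    return(solution)
  }
  vr <- stats::varimax(solution$loadings, normalize = normalize, eps = 1e-8)
  rot <- vr$rotmat
  solution$loadings <- solution$loadings %*% rot
  dimnames(solution$loadings) <- list(rownames(vr$loadings),
                                      paste0("C", seq_len(m)))
  solution$scores <- solution$scores %*% rot
  colnames(solution$scores) <- paste0("C", seq_len(m))
  solution$rotation <- rot
  # variance carried by each rotated axis, same denominators as before
  ssq <- colSums(solution$loadings^2)
  cons <- solution$var_frac_constrained
  tot <- solution$var_frac_total
  solution$var_frac_constrained <- ssq * sum(cons) / sum(solution$loadings^2)
  solution$var_frac_total <- ssq * sum(tot) / sum(solution$loadings^2)
  solution
}

#' Loadings as correlations with the component scores
#'
#' Component loadings correlate each component's scores with the constrained
#' criterion variables; predictor loadings correlate them with the original
#' predictor variables. A constrained criterion column with zero variance
#' (a criterion orthogonal to every predictor) yields zero loadings with a
#' warning.
#'
#' @param scores N x m component score matrix.
#' @param zhat Constrained criterion matrix (N x q).
#' @param G Predictor matrix (N x p).
#' @return List with `component_loadings` (q x m) and `predictor_loadings`
#'   (p x m), Pearson correlations in [-1, 1].
#' @export
compute_loadings <- function(scores, zhat, G) {
  sdz <- apply(zhat, 2, stats::sd)
  comp <- matrix(0, ncol(zhat), ncol(scores),
                 dimnames = list(colnames(zhat), colnames(scores)))
  ok <- sdz > 0
  if (!all(ok)) {
    warning("zero-variance constrained column(s), loadings set to 0: ",
            paste(colnames(zhat)[!ok], collapse = ", "))
  }
  if (any(ok)) comp[ok, ] <- t(stats::cor(scores, zhat[, ok, drop = FALSE]))
  pred <- t(stats::cor(scores, G))
  list(component_loadings = comp, predictor_loadings = pred)
}

# Lean fitting core shared by fit_cpca and the split-half engine.
# G, Z are raw (unstandardized) blocks with dimnames; returns a
# cpca_solution. keep_constrained = FALSE drops the N x q matrix to save
# memory across thousands of iterations.
.cpca_fit <- function(G, Z, n_components, rotate = TRUE, normalize = TRUE,
                      keep_constrained = TRUE) {
  G <- standardize(G)
  Z <- standardize(Z)
  ext <- external_analysis(Z, G)
  int <- internal_analysis(ext$constrained, n_components,
                           total_ss = sum(Z * Z))
  if (rotate) int <- varimax_rotate(int, normalize = normalize)
  else int$rotation <- diag(n_components)
  ld <- compute_loadings(int$scores, ext$constrained, G)
  # sign convention: dominant criterion of each component loads positively
  for (k in seq_len(n_components)) {
    j <- which.max(abs(ld$component_loadings[, k]))
    if (ld$component_loadings[j, k] < 0) {
      int$scores[, k] <- -int$scores[, k]
      int$loadings[, k] <- -int$loadings[, k]
      ld$component_loadings[, k] <- -ld$component_loadings[, k]
      ld$predictor_loadings[, k] <- -ld$predictor_loadings[, k]
      int$rotation[, k] <- -int$rotation[, k]
    }
  }
  structure(
    list(n_components = n_components,
         constrained = if (keep_constrained) ext$constrained else NULL,
         scores = int$scores,
         component_loadings = ld$component_loadings,
         predictor_loadings = ld$predictor_loadings,
         overlap_fraction = ext$overlap_fraction,
         var_frac_constrained = int$var_frac_constrained,
         var_frac_total = int$var_frac_total,
         singular_values = int$singular_values,
         rotation = int$rotation),
    class = "cpca_solution")
}

#' Fit a constrained PCA on one sample
#'
#' The full single-sample pipeline: standardize both blocks, regress the
#' criterion block on the predictor block (external analysis), extract
#' principal components of the constrained matrix (internal analysis),
#' varimax-rotate, and express loadings as Pearson correlations between
#' component scores and the constrained criteria (component loadings) or the
#' predictors (predictor loadings). Each component's sign is fixed so its
#' largest-magnitude criterion loading is positive.
#'
#' @param m A `sample_matrix` from [assemble()].
#' @param n_components Number of components to extract.
#' @param rotate Apply varimax rotation (default `TRUE`).
#' @param normalize Kaiser row-normalization inside varimax.
#' @return A `cpca_solution`: scores (N x m, zero mean, unit variance,
#'   pairwise uncorrelated before rotation and after, since the rotation is
#'   orthogonal), component loadings (q x m), predictor loadings (p x m),
#'   `overlap_fraction`, and per-component variance fractions relative to
#'   the constrained and to the total criterion variance.
#' @export
fit_cpca <- function(m, n_components, rotate = TRUE, normalize = TRUE) {
  validate_sample_matrix(m)
  .cpca_fit(predictor_block(m), criterion_block(m), n_components,
            rotate = rotate, normalize = normalize)
}

#' @export
print.cpca_solution <- function(x, ...) {
  cat("cpca_solution:", x$n_components, "component(s),",
      nrow(x$predictor_loadings), "predictors,",
      nrow(x$component_loadings), "criteria\n")
  cat(sprintf("  overlap: %.1f%% of criterion variance\n",
              100 * x$overlap_fraction))
  cat(sprintf("  constrained variance by component: %s\n",
              paste(sprintf("%.1f%%", 100 * x$var_frac_constrained),
                    collapse = ", ")))
  invisible(x)
}
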