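#' Split-half replication of a constrained PCA
#'
#' Repeatedly partitions the subjects into two random halves, fits the CPCA
#' independently in each half (each half standardized internally), aligns
#' both half-solutions to the full-sample reference solution by Tucker
#' congruence, and records for every predictor-by-component cell whether the
#' predictor loading magnitude reached the reliability threshold in both
#' halves. With an odd number of subjects the larger half is assigned
#' uniformly at random.
#'
#' @param m A `sample_matrix`.
#' @param n_components Number of components.
#' @param n_iter Number of split-half iterations (default 1000).
#' @param threshold Loading-magnitude reliability threshold r* (default
#'   0.26).
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @param reference Optional precomputed full-sample `cpca_solution`; fitted
#'   when `NULL`.
#' @param keep_scores Store per-half scores and component loadings in each
#'   record (needed for [average_component_scores()]); disable to save
#'   memory in nested calls.
#' @param max_retries Resampling attempts when a half-fit is singular.
#' @return A `split_half_result`: list with `reference`, `records` (one slim
#'   record per iteration), `n_components`, `threshold`, `n_iter`,
#'   `n_resampled`.
#' @export
split_half_iterate <- function(m, n_components, n_iter = 1000,
                               threshold = 0.26, seed = NULL,
                               reference = NULL, keep_scores = TRUE,
                               max_retries = 10) {
  if (!is.null(seed)) set.seed(seed)
  G <- predictor_block(m)
  Z <- criterion_block(m)
  n <- nrow(G)
  p <- ncol(G)
  n_small <- floor(n / 2)
  if (n_small <= p + 2L) {
    stop("half-sample size ", n_small, " is too small for p = ", p,
         " predictors; reduce the predictor set (need N/2 > p + 2)")
  }
  if (is.null(reference)) {
    reference <- .cpca_fit(G, Z, n_components)
  }

  n_resampled <- 0L
  records <- vector("list", n_iter)
  for (it in seq_len(n_iter)) {
    rec <- NULL
    for (try in seq_len(max_retries)) {
      perm <- sample.int(n)
      na <- if (n %% 2L == 0L) n %/% 2L else
        n %/% 2L + stats::rbinom(1L, 1L, 0.5)
      idx_a <- sort(perm[seq_len(na)])
      idx_b <- sort(perm[(na + 1L):n])
      fits <- tryCatch({
        sa <- .cpca_fit(G[idx_a, , drop = FALSE], Z[idx_a, , drop = FALSE],
                        n_components, keep_constrained = FALSE)
        sb <- .cpca_fit(G[idx_b, , drop = FALSE], Z[idx_b, , drop = FALSE],
                        n_components, keep_constrained = FALSE)
        list(a = align_solution(sa, reference),
             b = align_solution(sb, reference))
      }, error = function(e) NULL)
      if (!is.null(fits)) {
        exceed <- abs(fits$a$predictor_loadings) >= threshold &
          abs(fits$b$predictor_loadings) >= threshold
        rec <- list(
          iteration = it, idx_a = idx_a, idx_b = idx_b,
          predictor_loadings_a = fits$a$predictor_loadings,
          predictor_loadings_b = fits$b$predictor_loadings,
          overlap_a = fits$a$overlap_fraction,
          overlap_b = fits$b$overlap_fraction,
          var_frac_constrained_a = fits$a$var_frac_constrained,
          var_frac_constrained_b = fits$b$var_frac_constrained,
          congruence_a = attr(fits$a, "alignment")$congruence,
          congruence_b = attr(fits$b, "alignment")$congruence,
          exceed = exceed)
        if (keep_scores) {
          rec$scores_a <- fits$a$scores
          rec$scores_b <- fits$b$scores
          rec$component_loadings_a <- fits$a$component_loadings
          rec$component_loadings_b <- fits$b$component_loadings
        }
        break
      }
      n_resampled <- n_resampled + 1L
    }
    if (is.null(rec)) {
      stop("split-half fit failed after ", max_retries,
           " resampling attempts at iteration ", it)
    }
    records[[it]] <- rec
  }
  structure(list(reference = reference, records = records,
                 n_components = n_components, threshold = threshold,
                 n_iter = n_iter, n_resampled = n_resampled),
            class = "split_half_result")
}

#' Predictor loading reliability proportion (PLRP)
#'
#' The percentage of split-half iterations in which a predictor's loading
#' magnitude reached the threshold in both half-solutions.
#'
#' @param x A `split_half_result` or its list of records.
#' @param threshold Recompute exceedance at a different threshold; `NULL`
#'   (default) uses the indicators stored at fit time.
#' @return p x m matrix of percentages in [0, 100].
#' @export
compute_plrp <- function(x, threshold = NULL) {
  records <- if (inherits(x, "split_half_result")) x$records else x
  stopifnot(length(records) > 0)
  acc <- 0
  for (rec in records) {
    e <- if (is.null(threshold)) rec$exceed else
      abs(rec$predictor_loadings_a) >= threshold &
      abs(rec$predictor_loadings_b) >= threshold
    acc <- acc + e
  }
  100 * acc / length(records)
}

#' Permutation null for PLRP significance
#'
#' Builds a null distribution for the PLRP by shuffling the subject rows of
#' the predictor block relative to the criterion block (destroying every
#' predictor-criterion association while preserving both blocks' marginal
#' structure), re-running the split-half engine on each permuted dataset,
#' and pooling the resulting null PLRP values. With `pool = "component"`
#' (default) null values are pooled across predictors within a component, so
#' that a modest number of permutation replicates yields a fine-grained
#' p-value resolution; `pool = "cell"` keeps a separate null per cell.
#' P-values use the add-one estimator p = (1 + #null >= observed) /
#' (1 + pool size), so larger PLRPs always map to smaller p.
#'
#' @param m A `sample_matrix`.
#' @param n_components Number of components.
#' @param observed Observed p x m PLRP matrix from [compute_plrp()].
#' @param n_perm Number of permutation replicates (>= 19).
#' @param n_iter Split-half iterations per replicate (reduced relative to
#'   the main run; default 200).
#' @param threshold Reliability threshold r*.
#' @param pool `"component"` or `"cell"` pooling of the null.
#' @param seed Optional integer seed.
#' @return List with `p_values` (p x m), `null_plrp` (p x m x n_perm array),
#'   `pool`, `n_perm`, `n_iter`.
#' @export
permutation_null_plrp <- function(m, n_components, observed, n_perm = 199,
                                  n_iter = 200, threshold = 0.26,
                                  pool = c("component", "cell"),
                                  seed = NULL) {
  pool <- match.arg(pool)
  stopifnot(n_perm >= 19)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(m$values)
  p <- length(m$predictor_names)
  mm <- n_components
  null_plrp <- array(NA_real_, c(p, mm, n_perm))
  for (b in seq_len(n_perm)) {
    mp <- m
    mp$values[, m$predictor_names] <-
      m$values[sample.int(n), m$predictor_names]
    sh <- split_half_iterate(mp, n_components, n_iter = n_iter,
                             threshold = threshold, keep_scores = FALSE)
    null_plrp[, , b] <- compute_plrp(sh)
  }
  pv <- matrix(NA_real_, p, mm, dimnames = dimnames(observed))
  for (k in seq_len(mm)) {
    if (pool == "component") {
      nk <- as.vector(null_plrp[, k, ])
      for (j in seq_len(p)) {
        pv[j, k] <- (1 + sum(nk >= observed[j, k])) / (1 + length(nk))
      }
    } else {
      for (j in seq_len(p)) {
        nk <- null_plrp[j, k, ]
        pv[j, k] <- (1 + sum(nk >= observed[j, k])) / (1 + n_perm)
      }
    }
  }
  list(p_values = pv, null_plrp = null_plrp, pool = pool,
       n_perm = n_perm, n_iter = n_iter)
}

#' Benjamini-Hochberg step-up significance flags
#'
#' Applies the Benjamini-Hochberg false-discovery-rate step-up rule jointly
#' over all supplied p-values and returns logical rejection flags at level
#' `alpha`. Uses [stats::p.adjust()] for the adjustment.
#'
#' @param p_values Numeric vector or matrix of p-values in (0, 1].
#' @param alpha FDR level (default 0.05).
#' @return Logical flags with the same shape as `p_values`.
#' @export
bh_adjust <- function(p_values, alpha = 0.05) {
  stopifnot(all(p_values > 0 & p_values <= 1))
  adj <- stats::p.adjust(as.vector(p_values), method = "BH")
  flags <- adj <= alpha
  if (is.matrix(p_values)) {
    flags <- matrix(flags, nrow(p_values), ncol(p_values),
                    dimnames = dimnames(p_values))
  }
  flags
}

#' Choose how many criterion variables to retain per component
#'
#' Strategy `"avg_plrp_curve"` (default): for each component, rank the
#' criteria by the magnitude of their reference component loading; for each
#' candidate count k, refit the split-half engine on the top-k criteria
#' only (with a reduced iteration count), identify the refitted component
#' matching the target component by Tucker congruence, and record the mean
#' PLRP of the component's significant predictors. The retained count is the
#' k maximizing this curve (ties resolved toward fewer criteria). Strategy
#' `"fixed_k"` simply honors a user-specified count per component.
#'
#' @param m A `sample_matrix`.
#' @param sh The main `split_half_result` (provides the reference solution).
#' @param plrp Observed PLRP matrix.
#' @param significant Logical p x m matrix of BH flags; for a component with
#'   no significant predictor the predictor with the largest PLRP is used.
#' @param strategy `"avg_plrp_curve"` or `"fixed_k"`.
#' @param k Integer vector (length m) of counts for `"fixed_k"`.
#' @param n_iter Split-half iterations per refit (default 100).
#' @param threshold Reliability threshold r*.
#' @param seed Optional integer seed.
#' @return A `retention_result`: per component, the ranked criterion names,
#'   the average-PLRP curve (named by k; `NA` where the target component
#'   could not be identified in the refit) and the chosen count with the
#'   retained criterion names.
#' @export
retain_component_loadings <- function(m, sh, plrp = NULL, significant = NULL,
                                      strategy = c("avg_plrp_curve",
                                                   "fixed_k"),
                                      k = NULL, n_iter = 100,
                                      threshold = sh$threshold,
                                      seed = NULL) {
  strategy <- match.arg(strategy)
  if (!is.null(seed)) set.seed(seed)
  ref <- sh$reference
  mm <- sh$n_components
  q <- length(m$criterion_names)
  out <- vector("list", mm)
  names(out) <- paste0("C", seq_len(mm))

  for (comp in seq_len(mm)) {
    ranked <- m$criterion_names[order(-abs(ref$component_loadings[, comp]))]
    if (strategy == "fixed_k") {
      stopifnot(!is.null(k), length(k) == mm)
      out[[comp]] <- list(ranked_criteria = ranked, curve = NULL,
                          chosen = as.integer(k[comp]),
                          retained = ranked[seq_len(k[comp])])
      next
    }
    if (is.null(plrp)) stop("avg_plrp_curve strategy requires `plrp`")
    focal <- if (!is.null(significant) && any(significant[, comp])) {
      which(significant[, comp])
    } else {
      which.max(plrp[, comp])
    }
    curve <- rep(NA_real_, q)
    names(curve) <- seq_len(q)
    for (kk in seq_len(q)) {
      top <- ranked[seq_len(kk)]
      sub <- subset_sample_matrix(m, criteria = top)
      nc_sub <- min(mm, kk)
      sub_sh <- split_half_iterate(sub, nc_sub, n_iter = n_iter,
                                   threshold = threshold,
                                   keep_scores = FALSE)
      # which refitted component corresponds to the target component?
      mt <- .match_components(
        sub_sh$reference$component_loadings,
        ref$component_loadings[top, , drop = FALSE])
      hit <- which(mt$perm == comp)
      if (length(hit) == 1L) {
        sub_plrp <- compute_plrp(sub_sh)
        curve[kk] <- mean(sub_plrp[focal, hit])
      }
    }
    chosen <- if (all(is.na(curve))) NA_integer_ else {
      cv <- ifelse(is.na(curve), -Inf, curve)
      as.integer(which.max(cv))
    }
    out[[comp]] <- list(ranked_criteria = ranked, curve = curve,
                        chosen = chosen,
                        retained = if (is.na(chosen)) character() else
                          ranked[seq_len(chosen)])
  }
  structure(list(components = out, strategy = strategy),
            class = "retention_result")
}

#' @export
print.retention_result <- function(x, ...) {
  cat("component-loading retention (", x$strategy, ")\n", sep = "")
  for (nm in names(x$components)) {
    ci <- x$components[[nm]]
    cat(" ", nm, ": retain ", ci$chosen, " criterion(s): ",
        paste(ci$retained, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Average component scores over split-half iterations
#'
#' Each subject appears in exactly one half per iteration; the averaged
#' score is that subject's mean aligned score over all iterations, centered
#' per component.
#'
#' @param sh A `split_half_result` fitted with `keep_scores = TRUE`.
#' @return N x m matrix of centered averaged scores, rows named by subject.
#' @export
average_component_scores <- function(sh) {
  stopifnot(inherits(sh, "split_half_result"))
  if (is.null(sh$records[[1]]$scores_a)) {
    stop("records were stored without scores (keep_scores = FALSE)")
  }
  n <- nrow(sh$reference$scores)
  mm <- sh$n_components
  acc <- matrix(0, n, mm)
  cnt <- matrix(0, n, mm)
  for (rec in sh$records) {
    acc[rec$idx_a, ] <- acc[rec$idx_a, ] + rec$scores_a
    acc[rec$idx_b, ] <- acc[rec$idx_b, ] + rec$scores_b
    cnt[rec$idx_a, ] <- cnt[rec$idx_a, ] + 1
    cnt[rec$idx_b, ] <- cnt[rec$idx_b, ] + 1
  }
  avg <- acc / cnt
  avg <- scale(avg, center = TRUE, scale = FALSE)
  attr(avg, "scaled:center") <- NULL
  colnames(avg) <- paste0("C", seq_len(mm))
  avg
}

#' Run the full iterative constrained PCA pipeline
#'
#' Composition of the whole method: full-sample reference fit, split-half
#' replication with alignment, PLRP computation, permutation significance
#' with Benjamini-Hochberg correction, criterion-retention selection, and
#' iteration-averaged component scores and variance summaries. The reported
#' overlap percentage is the mean, over all 2 x n_iter half-solutions, of
#' the constrained share of criterion variance.
#'
#' @param m A `sample_matrix`.
#' @param n_components Number of components (default 2).
#' @param n_iter Split-half iterations (default 1000).
#' @param threshold Reliability threshold r* (default 0.26).
#' @param alpha FDR level for the Benjamini-Hochberg flags (default 0.05).
#' @param n_perm Permutation replicates for the PLRP null (default 199;
#'   `0` skips significance).
#' @param n_iter_perm Split-half iterations per permutation replicate.
#' @param retention `"avg_plrp_curve"`, `"fixed_k"` or `"none"`.
#' @param retain_k Counts for `retention = "fixed_k"`.
#' @param n_iter_retention Split-half iterations per retention refit.
#' @param pool Pooling mode for the permutation null.
#' @param seed Integer seed governing every random draw in the run.
#' @return An `icpca_result` bundling the reference solution, the PLRP
#'   table (PLRP, p-values, BH flags), the retention result, averaged
#'   scores, the iteration-averaged overlap and per-component variance
#'   percentages, and the configuration.
#' @export
run_icpca <- function(m, n_components = 2, n_iter = 1000, threshold = 0.26,
                      alpha = 0.05, n_perm = 199, n_iter_perm = 200,
                      retention = c("avg_plrp_curve", "fixed_k", "none"),
                      retain_k = NULL, n_iter_retention = 100,
                      pool = c("component", "cell"), seed = NULL) {
  retention <- match.arg(retention)
  pool <- match.arg(pool)
  if (!is.null(seed)) set.seed(seed)
  config <- list(n_components = n_components, n_iter = n_iter,
                 threshold = threshold, alpha = alpha, n_perm = n_perm,
                 n_iter_perm = n_iter_perm, retention = retention,
                 retain_k = retain_k, n_iter_retention = n_iter_retention,
                 pool = pool, seed = seed)

  sh <- split_half_iterate(m, n_components, n_iter = n_iter,
                           threshold = threshold)
  plrp <- compute_plrp(sh)
  p_values <- NULL; significant <- NULL
  if (n_perm > 0) {
    pn <- permutation_null_plrp(m, n_components, observed = plrp,
                                n_perm = n_perm, n_iter = n_iter_perm,
                                threshold = threshold, pool = pool)
    p_values <- pn$p_values
    significant <- bh_adjust(p_values, alpha)
  }
  ret <- if (retention == "none") NULL else {
    retain_component_loadings(m, sh, plrp = plrp, significant = significant,
                              strategy = retention, k = retain_k,
                              n_iter = n_iter_retention,
                              threshold = threshold)
  }
  scores <- average_component_scores(sh)
  rownames(scores) <- m$subject_ids

  overlaps <- unlist(lapply(sh$records, function(r) c(r$overlap_a,
                                                      r$overlap_b)))
  vf <- sapply(sh$records, function(r)
    (r$var_frac_constrained_a + r$var_frac_constrained_b) / 2)
  vf <- matrix(vf, nrow = n_components)

  structure(
    list(reference = sh$reference,
         split_half = sh,
         plrp = plrp,
         p_values = p_values,
         significant = significant,
         retention = ret,
         scores = scores,
         overlap_pct = 100 * mean(overlaps),
         reference_overlap_pct = 100 * sh$reference$overlap_fraction,
         var_pct_constrained = 100 * rowMeans(vf),
         config = config),
    class = "icpca_result")
}

#' @export
print.icpca_result <- function(x, ...) {
  cat("iterative constrained PCA (", x$config$n_iter, " split-half ",
      "iterations, r* = ", x$config$threshold, ")\n", sep = "")
  cat(sprintf("  overlap: %.2f%% of criterion variance (half-sample mean); %.2f%% (full sample)\n",
              x$overlap_pct, x$reference_overlap_pct))
  cat(sprintf("  constrained variance by component: %s (total %.1f%%)\n",
              paste(sprintf("%.1f%%", x$var_pct_constrained), collapse = ", "),
              sum(x$var_pct_constrained)))
  if (!is.null(x$significant) && any(x$significant)) {
    idx <- which(x$significant, arr.ind = TRUE)
    cat("  reliable predictors (BH-significant PLRP):\n")
    for (r in seq_len(nrow(idx))) {
      j <- idx[r, 1]; k <- idx[r, 2]
      cat(sprintf("    %s -> C%d: loading %+.2f, PLRP %.0f%%, p = %.4g\n",
                  rownames(x$plrp)[j], k,
                  x$reference$predictor_loadings[j, k],
                  x$plrp[j, k], x$p_values[j, k]))
    }
  } else if (!is.null(x$significant)) {
    cat("  no BH-significant predictor loadings\n")
  }
  invisible(x)
}

#' Critical correlation for a given sample size
#'
#' The two-tailed critical value of a Pearson correlation at level `alpha`,
#' r = t / sqrt(t^2 + n - 2) with t the alpha/2 quantile of the t
#' distribution on n - 2 degrees of freedom. Useful as a data-driven
#' alternative to a fixed split-half reliability threshold: pass the
#' half-sample size (e.g. `critical_r(99)` is about 0.198).
#'
#' @param n Sample size (>= 3).
#' @param alpha Two-sided significance level (default 0.05).
#' @return The critical |r|.
#' @export
critical_r <- function(n, alpha = 0.05) {
  stopifnot(n >= 3, alpha > 0, alpha < 1)
  tq <- stats::qt(1 - alpha / 2, df = n - 2)
  tq / sqrt(tq^2 + n - 2)
}
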