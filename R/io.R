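#' Read a subjects-by-variables CSV
#'
#' Comma-separated, UTF-8, mandatory header; first column holds subject
#' identifiers; missing cells empty or `NA`.
#'
#' @param path CSV file path.
#' @return A data.frame ready for [assemble()].
#' @export
read_sample_csv <- function(path) {
  if (!file.exists(path)) stop("data file not found: ", path)
  utils::read.csv(path, check.names = FALSE, na.strings = c("", "NA"))
}

#' Write a synthetic sample and its ground truth
#'
#' @param g Output of [generate()].
#' @param data_path CSV destination for the sample.
#' @param truth_path Optional JSON destination for the generating loadings
#'   and configuration.
#' @return `data_path`, invisibly.
#' @export
write_simulation <- function(g, data_path, truth_path = NULL) {
  utils::write.csv(g$data, data_path, row.names = FALSE)
  if (!is.null(truth_path)) {
    tr <- list(lambda_c = g$truth$lambda_c, lambda_p = g$truth$lambda_p,
               N = g$truth$spec$N, likert_levels = g$truth$spec$likert_levels,
               cutpoints = g$truth$spec$cutpoints,
               missing_rate = g$truth$spec$missing_rate,
               predictors = g$roles$predictors,
               criteria = g$roles$criteria)
    jsonlite::write_json(tr, truth_path, digits = NA, pretty = TRUE)
  }
  invisible(data_path)
}

#' Write the result bundle of a full run
#'
#' Emits `predictor_loadings.csv` (reference loadings with PLRP, p-value
#' and BH-significance star columns), `component_loadings.csv` (with
#' retained-cell flags), `scores.csv` (iteration-averaged component
#' scores), `run.json` (configuration, seed, overlap and variance
#' percentages, package version) and a plain-text `run.log`.
#'
#' @param result An `icpca_result` from [run_icpca()].
#' @param dir Output directory (created if absent).
#' @param sample Optional `sample_matrix`, used to include the provenance
#'   log.
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir, sample = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ref <- result$reference
  mm <- ncol(result$plrp)

  star <- function(sig, p) {
    ifelse(!sig, "", ifelse(p <= 0.01, "**", "*"))
  }
  pl <- data.frame(item = rownames(result$plrp), ref$predictor_loadings,
                   check.names = FALSE)
  for (k in seq_len(mm)) {
    pl[[paste0("PLRP_C", k)]] <- result$plrp[, k]
    if (!is.null(result$p_values)) {
      pl[[paste0("p_C", k)]] <- result$p_values[, k]
      pl[[paste0("sig_C", k)]] <- star(result$significant[, k],
                                       result$p_values[, k])
    }
  }
  utils::write.csv(pl, file.path(dir, "predictor_loadings.csv"),
                   row.names = FALSE)

  cl <- data.frame(measure = rownames(ref$component_loadings),
                   ref$component_loadings, check.names = FALSE)
  if (!is.null(result$retention)) {
    for (k in seq_len(mm)) {
      ret <- result$retention$components[[k]]$retained
      cl[[paste0("retained_C", k)]] <- cl$measure %in% ret
    }
  }
  utils::write.csv(cl, file.path(dir, "component_loadings.csv"),
                   row.names = FALSE)

  sc <- data.frame(subject = rownames(result$scores), result$scores,
                   check.names = FALSE)
  utils::write.csv(sc, file.path(dir, "scores.csv"), row.names = FALSE)

  meta <- list(
    package_version = as.character(utils::packageVersion("icpca")),
    config = result$config,
    overlap_pct = result$overlap_pct,
    reference_overlap_pct = result$reference_overlap_pct,
    var_pct_constrained = result$var_pct_constrained,
    n_resampled = result$split_half$n_resampled)
  jsonlite::write_json(meta, file.path(dir, "run.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  log <- c(paste0("icpca run, seed = ",
                  if (is.null(result$config$seed)) "NULL" else
                    result$config$seed),
           if (!is.null(sample)) sample$log,
           sprintf("overlap %.2f%% (half-sample mean), %.2f%% (full sample)",
                   result$overlap_pct, result$reference_overlap_pct),
           sprintf("constrained variance: %s",
                   paste(sprintf("C%d %.1f%%",
                                 seq_len(mm), result$var_pct_constrained),
                         collapse = ", ")))
  writeLines(log, file.path(dir, "run.log"))
  invisible(dir)
}
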