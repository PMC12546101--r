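#' Read a column-role configuration file
#'
#' Parses a YAML (or JSON) configuration declaring which columns of a data
#' table are predictors (symptom items), which are criteria (cognitive
#' measures), and which item names to exclude from the analysis.
#'
#' @param path Path to a YAML/JSON file with keys `predictors`, `criteria`
#'   and optionally `exclude` (each a list of column names).
#' @return A list with character vectors `predictors`, `criteria`, `exclude`.
#' @export
read_roles <- function(path) {
  if (!file.exists(path)) stop("roles file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$predictors) || is.null(cfg$criteria)) {
    stop("roles file must define 'predictors' and 'criteria' lists")
  }
  list(
    predictors = as.character(unlist(cfg$predictors)),
    criteria   = as.character(unlist(cfg$criteria)),
    exclude    = as.character(unlist(cfg$exclude))
  )
}

#' Assemble the analysis matrix
#'
#' Builds the subjects-by-variables matrix used by the constrained PCA from a
#' raw data table: selects predictor and criterion columns, drops excluded
#' items, resolves missing data and validates the result. The returned object
#' carries a provenance log recording every subject or column removed.
#'
#' Excluded items are typically symptom ratings that directly measure
#' cognitive performance (for the PANSS these are N5 Difficulty in Abstract
#' Thinking, G11 Poor Attention, and G10 Disorientation) and would trivially
#' overlap with cognitive criteria if retained.
#'
#' @param raw_table A data.frame with one row per subject. The column named
#'   by `id_col` (default the first column) holds subject identifiers; the
#'   remaining columns are numeric.
#' @param roles List with character vectors `predictors` and `criteria`
#'   naming the columns of each block (see [read_roles()]).
#' @param exclusions Character vector of item names to drop from the
#'   predictor/criterion sets; names absent from the table trigger a warning.
#' @param missing_policy Either `"listwise"` (drop subjects with any missing
#'   value in the retained columns) or `"mean_impute"` (replace each missing
#'   cell by its column mean computed over observed values).
#' @param id_col Name or index of the subject-identifier column.
#' @return A `sample_matrix` object: list with `values` (numeric matrix),
#'   `subject_ids`, `predictor_names`, `criterion_names`, `roles` (named
#'   character vector column -> role) and `log` (character provenance).
#' @export
assemble <- function(raw_table, roles,
                     exclusions = roles$exclude,
                     missing_policy = c("listwise", "mean_impute"),
                     id_col = 1L) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(is.data.frame(raw_table))
  log <- character()

  ids <- as.character(raw_table[[id_col]])
  pred <- setdiff(roles$predictors, exclusions)
  crit <- setdiff(roles$criteria, exclusions)
  if (length(exclusions)) {
    absent <- setdiff(exclusions, c(roles$predictors, roles$criteria))
    if (length(absent)) {
      warning("exclusion name(s) not present: ", paste(absent, collapse = ", "))
    }
    log <- c(log, paste0("excluded items: ", paste(exclusions, collapse = ", ")))
  }
  if (length(intersect(pred, crit))) {
    stop("predictor and criterion sets overlap: ",
         paste(intersect(pred, crit), collapse = ", "))
  }
  keep <- c(pred, crit)
  missing_cols <- setdiff(keep, names(raw_table))
  if (length(missing_cols)) {
    stop("column(s) named in roles not found in table: ",
         paste(missing_cols, collapse = ", "))
  }

  x <- as.matrix(raw_table[, keep, drop = FALSE])
  storage.mode(x) <- "double"
  rownames(x) <- ids

  if (anyNA(x)) {
    if (missing_policy == "listwise") {
      complete <- stats::complete.cases(x)
      log <- c(log, paste0("listwise deletion dropped ", sum(!complete),
                           " subject(s): ",
                           paste(ids[!complete], collapse = ", ")))
      x <- x[complete, , drop = FALSE]
      ids <- ids[complete]
    } else {
      for (j in seq_len(ncol(x))) {
        miss <- is.na(x[, j])
        if (any(miss)) {
          if (all(miss)) stop("column entirely missing: ", keep[j])
          x[miss, j] <- mean(x[!miss, j])
          log <- c(log, paste0("mean-imputed ", sum(miss), " cell(s) in ",
                               keep[j]))
        }
      }
    }
  }
  log <- c(log, paste0("missing policy: ", missing_policy))

  m <- structure(
    list(values = x,
         subject_ids = ids,
         predictor_names = pred,
         criterion_names = crit,
         roles = stats::setNames(c(rep("predictor", length(pred)),
                                   rep("criterion", length(crit))), keep),
         log = log),
    class = "sample_matrix")
  validate_sample_matrix(m)
  m
}

#' Validate a sample_matrix against its invariants
#'
#' @param m A `sample_matrix`.
#' @return `m`, invisibly; errors describe the violated invariant.
#' @keywords internal
validate_sample_matrix <- function(m) {
  x <- m$values
  p <- length(m$predictor_names)
  q <- length(m$criterion_names)
  if (anyNA(x)) stop("sample matrix contains missing values after assembly")
  if (p < 1L) stop("at least one predictor is required")
  if (q < 2L) stop("at least two criteria are required")
  if (nrow(x) <= p + 2L) {
    stop("N = ", nrow(x), " subjects is too small for p = ", p,
         " predictors (need N > p + 2)")
  }
  v <- apply(x, 2, stats::var)
  if (any(v <= 0 | !is.finite(v))) {
    stop("zero-variance column(s) after assembly: ",
         paste(colnames(x)[v <= 0 | !is.finite(v)], collapse = ", "))
  }
  invisible(m)
}

#' Standardize the columns of a sample matrix
#'
#' z-scores every column (mean 0, unit variance with the N - 1 denominator).
#' The centering and scaling parameters are retained as attributes for
#' reporting. Constrained PCA on the correlation metric requires standardized
#' blocks; within the split-half engine each half is standardized internally
#' so that half-solutions are self-contained.
#'
#' @param m A `sample_matrix` or a plain numeric matrix.
#' @return The same type of object with standardized columns; for a
#'   `sample_matrix` the transformation parameters are stored in
#'   `m$scaling`.
#' @export
standardize <- function(m) {
  if (inherits(m, "sample_matrix")) {
    s <- standardize(m$values)
    m$values <- s
    m$scaling <- list(center = attr(s, "scaled:center"),
                      scale = attr(s, "scaled:scale"))
    return(m)
  }
  v <- apply(m, 2, stats::var)
  if (any(v <= 0 | !is.finite(v))) {
    stop("cannot standardize constant column(s): ",
         paste(colnames(m)[v <= 0 | !is.finite(v)], collapse = ", "))
  }
  scale(m)
}

#' @export
print.sample_matrix <- function(x, ...) {
  cat("sample_matrix:", nrow(x$values), "subjects,",
      length(x$predictor_names), "predictors,",
      length(x$criterion_names), "criteria\n")
  for (l in x$log) cat(" -", l, "\n")
  invisible(x)
}

# Extract the predictor (G) and criterion (Z) blocks as matrices.
predictor_block <- function(m) {
  m$values[, m$predictor_names, drop = FALSE]
}
criterion_block <- function(m) {
  m$values[, m$criterion_names, drop = FALSE]
}

# Restrict a sample_matrix to a subset of subjects and/or criteria.
subset_sample_matrix <- function(m, subjects = NULL, criteria = NULL) {
  out <- m
  if (!is.null(criteria)) {
    out$criterion_names <- criteria
    out$roles <- out$roles[c(out$predictor_names, criteria)]
  }
  out$values <- out$values[
    if (is.null(subjects)) seq_along(out$subject_ids) else subjects,
    c(out$predictor_names, out$criterion_names), drop = FALSE]
  if (!is.null(subjects)) out$subject_ids <- out$subject_ids[subjects]
  out
}
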