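#' One-way ANOVA from group summary statistics
#'
#' Reconstructs the one-way fixed-effects ANOVA from per-group sample sizes,
#' means and sample standard deviations (N - 1 denominator), as printed in a
#' demographics table: SSb = sum n_i (m_i - grand)^2 with the weighted grand
#' mean, SSw = sum (n_i - 1) sd_i^2, F = MSb/MSw, eta squared =
#' SSb/(SSb + SSw).
#'
#' @param n,mean,sd Numeric vectors of equal length (>= 2 groups).
#' @return List: `F`, `df_between`, `df_within`, `p`, `eta_squared`,
#'   `grand_mean`, `ss_between`, `ss_within`, `ms_within`.
#' @export
anova_oneway_summary <- function(n, mean, sd) {
  stopifnot(length(n) >= 2, length(mean) == length(n),
            length(sd) == length(n), all(n >= 2), all(sd >= 0))
  grand <- sum(n * mean) / sum(n)
  ssb <- sum(n * (mean - grand)^2)
  ssw <- sum((n - 1) * sd^2)
  dfb <- length(n) - 1
  dfw <- sum(n) - length(n)
  if (ssw == 0) {
    if (ssb == 0) stop("all SDs zero with equal means: F undefined")
    return(list(F = Inf, df_between = dfb, df_within = dfw, p = 0,
                eta_squared = 1, grand_mean = grand, ss_between = ssb,
                ss_within = ssw, ms_within = 0))
  }
  Fv <- (ssb / dfb) / (ssw / dfw)
  list(F = Fv, df_between = dfb, df_within = dfw,
       p = stats::pf(Fv, dfb, dfw, lower.tail = FALSE),
       eta_squared = ssb / (ssb + ssw), grand_mean = grand,
       ss_between = ssb, ss_within = ssw, ms_within = ssw / dfw)
}

#' Scheffe post hoc contrast from group summaries
#'
#' Pairwise Scheffe comparison within a one-way design given per-group
#' summaries: the mean difference is significant when its squared value
#' exceeds (k - 1) F_{alpha; k-1, df_w} MSw (1/n_i + 1/n_j).
#'
#' @param n,mean,sd Group summaries as in [anova_oneway_summary()].
#' @param i,j Indices of the two groups to compare.
#' @param alpha Significance level (default 0.05).
#' @return List: `difference` (mean_i - mean_j), `critical_value` (the
#'   least significant difference magnitude), `significant`, `p` (the
#'   Scheffe-adjusted p-value).
#' @export
scheffe_summary <- function(n, mean, sd, i, j, alpha = 0.05) {
  a <- anova_oneway_summary(n, mean, sd)
  k <- length(n)
  diff <- mean[i] - mean[j]
  se2 <- a$ms_within * (1 / n[i] + 1 / n[j])
  crit <- sqrt((k - 1) * stats::qf(alpha, k - 1, a$df_within,
                                   lower.tail = FALSE) * se2)
  Fs <- diff^2 / ((k - 1) * se2)
  list(difference = diff, critical_value = crit,
       significant = abs(diff) > crit,
       p = stats::pf(Fs, k - 1, a$df_within, lower.tail = FALSE))
}

#' Chi-square test of independence for a contingency table
#'
#' Pearson's chi-square without continuity correction on an r x c table of
#' counts; df = (r - 1)(c - 1).
#'
#' @param table Matrix of non-negative counts.
#' @return List: `chi_squared`, `df`, `p`, `expected`.
#' @export
chisq_independence <- function(table) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("contingency table has a zero marginal")
  }
  ct <- stats::chisq.test(table, correct = FALSE)
  if (any(ct$expected <= 0)) stop("expected count not positive")
  list(chi_squared = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, expected = ct$expected)
}

#' Two-sample t test from group summaries
#'
#' Pooled-variance Student t (default) or Welch t from two group summaries,
#' with Cohen's d computed against the pooled standard deviation.
#'
#' @param n1,mean1,sd1 First group summary.
#' @param n2,mean2,sd2 Second group summary.
#' @param pooled Use the pooled-variance Student t (default `TRUE`); Welch
#'   otherwise.
#' @return List: `t`, `df`, `p`, `cohen_d`.
#' @export
t_from_summary <- function(n1, mean1, sd1, n2, mean2, sd2, pooled = TRUE) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (sd1 == 0 && sd2 == 0) stop("both SDs zero: t undefined")
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  d <- (mean1 - mean2) / sqrt(sp2)
  if (pooled) {
    tt <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    tt <- (mean1 - mean2) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  list(t = tt, df = df, p = 2 * stats::pt(abs(tt), df, lower.tail = FALSE),
       cohen_d = d)
}

#' Pearson correlation with a t-based two-sided p-value
#'
#' @param x,y Numeric vectors of equal length (n >= 3, finite, nonconstant).
#' @return List: `r`, `n`, `p`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero-variance input to correlation")
  }
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), n = length(x), p = ct$p.value)
}

#' Reproduce a site-comparison table from printed summaries
#'
#' Reads a long-format summary table (columns `variable`, `group`, `n`,
#' `mean`, `sd`) and computes the one-way ANOVA F, p and eta squared for
#' every variable, plus all pairwise Scheffe contrasts.
#'
#' @param summaries A data.frame or path to a CSV file in the format above.
#' @return A list with `anova` (data.frame: variable, F, df_between,
#'   df_within, p, eta_squared, grand_mean) and `scheffe` (data.frame of
#'   pairwise contrasts).
#' @export
site_comparison <- function(summaries) {
  if (is.character(summaries)) {
    summaries <- utils::read.csv(summaries, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("variable", "group", "n", "mean", "sd") %in%
                  names(summaries)))
  vars <- unique(summaries$variable)
  an <- do.call(rbind, lapply(vars, function(v) {
    s <- summaries[summaries$variable == v, ]
    a <- anova_oneway_summary(s$n, s$mean, s$sd)
    data.frame(variable = v, F = a$F, df_between = a$df_between,
               df_within = a$df_within, p = a$p,
               eta_squared = a$eta_squared, grand_mean = a$grand_mean)
  }))
  sc <- do.call(rbind, lapply(vars, function(v) {
    s <- summaries[summaries$variable == v, ]
    pairs <- utils::combn(nrow(s), 2)
    do.call(rbind, lapply(seq_len(ncol(pairs)), function(c2) {
      i <- pairs[1, c2]; j <- pairs[2, c2]
      sch <- scheffe_summary(s$n, s$mean, s$sd, i, j)
      data.frame(variable = v, group_i = s$group[i], group_j = s$group[j],
                 difference = sch$difference,
                 critical_value = sch$critical_value,
                 significant = sch$significant, p = sch$p)
    }))
  }))
  list(anova = an, scheffe = sc)
}
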