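test_that("single-iteration PLRP is Bernoulli and thresholds behave", {
  m <- generate_sample_matrix(mini_planted_spec(), seed = 41)
  sh <- split_half_iterate(m, 2, n_iter = 1, seed = 42)
  plrp <- compute_plrp(sh)
  expect_true(all(plrp %in% c(0, 100)))
  # unattainable threshold kills every cell
  expect_true(all(compute_plrp(sh, threshold = 1.01) == 0))
})

test_that("PLRP counts exceedances exactly on a hand-built record set", {
  pl <- function(a, b) list(predictor_loadings_a = matrix(a, 1, 1),
                            predictor_loadings_b = matrix(b, 1, 1),
                            exceed = matrix(abs(a) >= 0.26 & abs(b) >= 0.26,
                                            1, 1))
  records <- list(pl(0.30, 0.40), pl(0.30, 0.10), pl(-0.27, -0.30),
                  pl(0.50, 0.26), pl(0.20, 0.90))
  expect_equal(as.vector(compute_plrp(records)), 60)
  expect_equal(as.vector(compute_plrp(records, threshold = 0.05)), 100)
})

test_that("split-half records partition the sample and respect the threshold", {
  m <- generate_sample_matrix(mini_planted_spec(N = 81), seed = 43)
  sh <- split_half_iterate(m, 2, n_iter = 20, seed = 44)
  for (rec in sh$records[1:5]) {
    expect_identical(sort(c(rec$idx_a, rec$idx_b)), 1:81)
    expect_lte(abs(length(rec$idx_a) - length(rec$idx_b)), 1)
    expect_identical(rec$exceed,
                     abs(rec$predictor_loadings_a) >= 0.26 &
                       abs(rec$predictor_loadings_b) >= 0.26)
  }
})

test_that("the engine is deterministic under a fixed seed", {
  m <- generate_sample_matrix(mini_planted_spec(), seed = 45)
  sh1 <- split_half_iterate(m, 2, n_iter = 15, seed = 46)
  sh2 <- split_half_iterate(m, 2, n_iter = 15, seed = 46)
  expect_identical(compute_plrp(sh1), compute_plrp(sh2))
  expect_identical(sh1$records[[7]]$idx_a, sh2$records[[7]]$idx_a)
  expect_identical(sh1$records[[7]]$scores_b, sh2$records[[7]]$scores_b)
})

test_that("PLRP is monotonically non-increasing in the threshold", {
  m <- generate_sample_matrix(mini_planted_spec(), seed = 47)
  sh <- split_half_iterate(m, 2, n_iter = 60, seed = 48)
  thr <- c(0.1, 0.2, 0.26, 0.4, 0.6)
  mats <- lapply(thr, function(t) compute_plrp(sh, threshold = t))
  for (i in seq_len(length(thr) - 1)) {
    expect_true(all(mats[[i + 1]] <= mats[[i]]))
  }
})

test_that("PLRP is invariant to criterion column order up to relabeling", {
  spec <- mini_planted_spec()
  m <- generate_sample_matrix(spec, seed = 49)
  mrev <- m
  rev_crit <- rev(m$criterion_names)
  mrev$criterion_names <- rev_crit
  mrev$values <- m$values[, c(m$predictor_names, rev_crit)]

  sh <- split_half_iterate(m, 2, n_iter = 40, seed = 50)
  shr <- split_half_iterate(mrev, 2, n_iter = 40, seed = 50)
  # map components of the reversed run onto the original reference
  mt <- icpca:::.match_components(shr$reference$component_loadings[rev(seq_along(rev_crit)), ],
                                  sh$reference$component_loadings)
  expect_equal(compute_plrp(shr)[, order(mt$perm)], compute_plrp(sh),
               ignore_attr = TRUE)
})

test_that("planted predictors dominate the PLRP table", {
  m <- generate_sample_matrix(mini_planted_spec(N = 160), seed = 51)
  tr <- attr(m, "truth")
  sh <- split_half_iterate(m, 2, n_iter = 80, seed = 52)
  plrp <- compute_plrp(sh)
  mc <- match_components(sh$reference, tr$lambda_c)
  expect_gt(plrp["S1", mc[1]], 80)
  expect_gt(plrp["S2", mc[2]], 80)
  expect_lt(max(plrp[c("S3", "S4", "S5"), ]), 50)
})

test_that("Benjamini-Hochberg flags follow the step-up rule", {
  flags <- bh_adjust(c(0.001, 0.013, 0.04, 0.2), alpha = 0.05)
  expect_identical(flags, c(TRUE, TRUE, FALSE, FALSE))
  expect_false(any(bh_adjust(rep(1, 6))))
  expect_true(all(bh_adjust(rep(0.05 / 4, 4))))
  pm <- matrix(c(0.001, 0.5, 0.9, 0.2), 2, 2,
               dimnames = list(c("a", "b"), c("C1", "C2")))
  fm <- bh_adjust(pm)
  expect_identical(dimnames(fm), dimnames(pm))
  expect_error(bh_adjust(c(0, 0.5)))
})

test_that("permutation p-values are monotone in the observed PLRP", {
  m <- generate_sample_matrix(mini_planted_spec(N = 100), seed = 53)
  sh <- split_half_iterate(m, 2, n_iter = 40, seed = 54)
  plrp <- compute_plrp(sh)
  pn <- permutation_null_plrp(m, 2, observed = plrp, n_perm = 19,
                              n_iter = 20, seed = 55)
  expect_true(all(pn$p_values > 0 & pn$p_values <= 1))
  for (k in 1:2) {
    ord <- order(plrp[, k])
    expect_true(all(diff(pn$p_values[ord, k]) <= 1e-12))
  }
  # extreme observed value attains the add-one floor
  pool <- length(pn$null_plrp[, 1, ])
  big <- plrp; big[] <- 101
  pn2 <- permutation_null_plrp(m, 2, observed = big, n_perm = 19,
                               n_iter = 20, seed = 56)
  expect_true(all(pn2$p_values == 1 / (1 + pool)))
  # observed 0 sits at the top of the null
  zero <- plrp; zero[] <- 0
  pn3 <- permutation_null_plrp(m, 2, observed = zero, n_perm = 19,
                               n_iter = 20, seed = 57)
  expect_true(all(pn3$p_values == 1))
})

test_that("averaged scores reduce to the concatenated halves at one iteration", {
  m <- generate_sample_matrix(mini_planted_spec(), seed = 58)
  sh <- split_half_iterate(m, 2, n_iter = 1, seed = 59)
  avg <- average_component_scores(sh)
  rec <- sh$records[[1]]
  manual <- matrix(NA_real_, nrow(m$values), 2)
  manual[rec$idx_a, ] <- rec$scores_a
  manual[rec$idx_b, ] <- rec$scores_b
  manual <- scale(manual, center = TRUE, scale = FALSE)
  expect_equal(unname(avg), unname(manual), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("averaged scores of planted data track the generating latent", {
  m <- generate_sample_matrix(dense_indicator_spec(N = 200), seed = 60)
  tr <- attr(m, "truth")
  sh <- split_half_iterate(m, 2, n_iter = 60, seed = 61)
  avg <- average_component_scores(sh)
  mc <- match_components(sh$reference, tr$lambda_c)
  # ceiling: scores live in the predictor span, |cor| <= R(f|G) ~ 0.85
  expect_gt(abs(cor(avg[, mc[1]], tr$latents[, 1])), 0.75)
  expect_gt(abs(cor(avg[, mc[2]], tr$latents[, 2])), 0.75)
})

test_that("fixed-k retention honors the requested counts", {
  m <- generate_sample_matrix(mini_planted_spec(), seed = 62)
  sh <- split_half_iterate(m, 2, n_iter = 10, seed = 63)
  ret <- retain_component_loadings(m, sh, strategy = "fixed_k", k = c(3, 4))
  expect_identical(ret$components$C1$chosen, 3L)
  expect_identical(ret$components$C2$chosen, 4L)
  expect_length(ret$components$C1$retained, 3)
  expect_length(ret$components$C2$retained, 4)
  # ranked by reference loading magnitude
  r1 <- ret$components$C1$ranked_criteria
  mags <- abs(sh$reference$component_loadings[r1, 1])
  expect_true(all(diff(mags) <= 1e-12))
})

test_that("the average-PLRP retention curve is computed over all counts", {
  m <- generate_sample_matrix(mini_planted_spec(), seed = 64)
  sh <- split_half_iterate(m, 2, n_iter = 30, seed = 65)
  plrp <- compute_plrp(sh)
  ret <- retain_component_loadings(m, sh, plrp = plrp, n_iter = 20,
                                   seed = 66)
  for (comp in ret$components) {
    expect_length(comp$curve, 6)
    finite <- which(!is.na(comp$curve))
    expect_gt(length(finite), 2)
    expect_identical(comp$chosen,
                     as.integer(which.max(ifelse(is.na(comp$curve), -Inf,
                                                 comp$curve))))
  }
})

test_that("a full run is bundled coherently", {
  m <- generate_sample_matrix(mini_planted_spec(N = 100), seed = 67)
  res <- run_icpca(m, n_components = 2, n_iter = 30, n_perm = 19,
                   n_iter_perm = 15, retention = "fixed_k",
                   retain_k = c(2, 2), seed = 68)
  expect_s3_class(res, "icpca_result")
  expect_identical(dim(res$plrp), dim(res$p_values))
  expect_identical(dim(res$plrp), dim(res$significant))
  expect_equal(nrow(res$scores), 100)
  expect_gte(res$overlap_pct, 0)
  expect_lte(res$overlap_pct, 100)
  expect_length(res$var_pct_constrained, 2)
  expect_output(print(res), "iterative constrained PCA")
})

test_that("the critical correlation matches the t-test boundary", {
  for (n in c(20, 99, 198)) {
    r <- critical_r(n)
    # at exactly the critical r, the correlation t statistic sits at the
    # alpha/2 quantile
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    expect_equal(2 * pt(tstat, n - 2, lower.tail = FALSE), 0.05,
                 tolerance = 1e-10)
  }
  expect_lt(critical_r(198), critical_r(99))
})
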