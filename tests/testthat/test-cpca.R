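test_that("external analysis equals the brute-force hat-matrix projection", {
  tb <- toy_blocks()
  ext <- external_analysis(tb$Z, tb$G)
  zhat_oracle <- oracle_projection(tb$Z, tb$G)
  expect_lt(max(abs(ext$constrained - zhat_oracle)), 1e-10)
  expect_equal(ext$overlap_fraction,
               sum(zhat_oracle^2) / sum(tb$Z^2), tolerance = 1e-12)
})

test_that("overlap is 1 for self-prediction and 0 under orthogonality", {
  tb <- toy_blocks()
  self <- external_analysis(tb$Z, tb$Z)
  expect_lt(max(abs(self$constrained - tb$Z)), 1e-10)
  expect_equal(self$overlap_fraction, 1, tolerance = 1e-12)

  set.seed(2)
  x <- scale(matrix(rnorm(40 * 5), 40, 5), scale = FALSE)
  q <- qr.Q(qr(x))
  Z <- q[, 1:3]; G <- q[, 4:5]
  colnames(Z) <- paste0("z", 1:3); colnames(G) <- paste0("g", 1:2)
  orth <- external_analysis(Z, G)
  expect_lt(orth$overlap_fraction, 1e-20)
})

test_that("rank-deficient predictors are rejected, naming the culprit", {
  tb <- toy_blocks()
  G <- cbind(tb$G, g3 = tb$G[, 1] + tb$G[, 2])
  expect_error(external_analysis(tb$Z, G), "collinear")
})

test_that("internal analysis matches an independent eigendecomposition", {
  tb <- toy_blocks()
  zhat <- external_analysis(tb$Z, tb$G)$constrained
  int <- internal_analysis(zhat, 2, total_ss = sum(tb$Z^2))
  eig <- eigen(t(zhat) %*% zhat, symmetric = TRUE)$values
  expect_lt(max(abs(int$singular_values[1:2]^2 - eig[1:2])), 1e-10)
  # scores: zero mean, unit variance, uncorrelated
  expect_lt(max(abs(colMeans(int$scores))), 1e-10)
  expect_lt(max(abs(apply(int$scores, 2, var) - 1)), 1e-10)
  expect_lt(abs(cor(int$scores)[1, 2]), 1e-10)
  # full extraction accounts for all constrained variance
  full <- internal_analysis(zhat, qr(zhat)$rank)
  expect_equal(sum(full$var_frac_constrained), 1, tolerance = 1e-10)
  expect_error(internal_analysis(zhat, 4), "rank")
})

test_that("a rank-1 constrained matrix gives one component with all variance", {
  u <- scale(matrix(rnorm(20), 20, 1))
  zhat <- u %*% t(c(1, 2, 0.5))
  colnames(zhat) <- paste0("z", 1:3)
  int <- internal_analysis(zhat, 1)
  expect_equal(int$var_frac_constrained, 1, tolerance = 1e-10)
})

test_that("varimax rotation matches the planar grid-search oracle", {
  L <- matrix(c(0.8, 0.7, 0.3, 0.2,
                0.2, 0.3, 0.75, 0.8), 4, 2)
  sol <- list(loadings = L,
              scores = scale(matrix(rnorm(200 * 2), 200, 2)),
              var_frac_constrained = c(0.5, 0.5),
              var_frac_total = c(0.3, 0.3))
  rot <- varimax_rotate(sol, normalize = FALSE)
  oracle <- oracle_varimax_angle(L)
  expect_equal(varimax_criterion(rot$loadings), oracle$value,
               tolerance = 1e-6)
  # monotonicity of the criterion
  expect_gte(varimax_criterion(rot$loadings), varimax_criterion(L) - 1e-12)
})

test_that("perfect simple structure is left unchanged by varimax", {
  L <- matrix(c(0.9, 0.8, 0, 0,
                0, 0, 0.7, 0.6), 4, 2)
  sol <- list(loadings = L, scores = scale(matrix(rnorm(100 * 2), 100, 2)),
              var_frac_constrained = c(0.5, 0.5),
              var_frac_total = c(0.3, 0.3))
  rot <- varimax_rotate(sol, normalize = FALSE)
  # rotation is a signed permutation: loadings unchanged up to order/sign
  expect_equal(sort(abs(as.vector(rot$rotation))), c(0, 0, 1, 1),
               tolerance = 1e-6)
  expect_equal(sort(abs(as.vector(rot$loadings))), sort(abs(as.vector(L))),
               tolerance = 1e-6)
})

test_that("loadings are the column-wise Pearson correlations", {
  tb <- toy_blocks()
  zhat <- external_analysis(tb$Z, tb$G)$constrained
  int <- internal_analysis(zhat, 2)
  ld <- compute_loadings(int$scores, zhat, tb$G)
  for (k in 1:2) {
    for (j in 1:3) {
      expect_equal(ld$component_loadings[j, k],
                   cor(int$scores[, k], zhat[, j]), tolerance = 1e-12)
    }
    for (j in 1:2) {
      expect_equal(ld$predictor_loadings[j, k],
                   cor(int$scores[, k], tb$G[, j]), tolerance = 1e-12)
    }
  }
  # a score column identical to a predictor column correlates perfectly
  ld2 <- compute_loadings(cbind(C1 = tb$G[, 1]), zhat, tb$G)
  expect_equal(ld2$predictor_loadings["g1", 1], 1, tolerance = 1e-12)
})

test_that("zero-variance constrained column yields zero loading and warning", {
  zhat <- cbind(z1 = scale(rnorm(30))[, 1], z2 = rep(0, 30))
  scores <- cbind(C1 = scale(rnorm(30))[, 1])
  G <- cbind(g1 = scale(rnorm(30))[, 1])
  expect_warning(ld <- compute_loadings(scores, zhat, G), "zero-variance")
  expect_equal(ld$component_loadings["z2", 1], 0)
})

test_that("with criteria as their own predictors CPCA reproduces plain PCA", {
  set.seed(11)
  Z <- scale(matrix(rnorm(50 * 4), 50, 4))
  colnames(Z) <- paste0("z", 1:4)
  ext <- external_analysis(Z, Z)
  int <- internal_analysis(ext$constrained, 4)
  ld <- compute_loadings(int$scores, ext$constrained, Z)
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  pca_loadings <- cor(pc$x, Z)
  # compare up to sign
  expect_lt(max(abs(abs(ld$component_loadings) - abs(t(pca_loadings)))),
            1e-10)
})

test_that("fit_cpca is deterministic and satisfies the solution invariants", {
  spec <- mini_planted_spec(N = 100)
  m <- generate_sample_matrix(spec, seed = 21)
  f1 <- fit_cpca(m, 2)
  f2 <- fit_cpca(m, 2)
  expect_identical(f1$component_loadings, f2$component_loadings)
  expect_identical(f1$scores, f2$scores)

  expect_true(all(abs(f1$component_loadings) <= 1))
  expect_true(all(abs(f1$predictor_loadings) <= 1))
  expect_gte(f1$overlap_fraction, 0)
  expect_lte(f1$overlap_fraction, 1)
  expect_lt(abs(cor(f1$scores)[1, 2]), 1e-10)
  # sign convention: dominant criterion loads positively
  for (k in 1:2) {
    expect_gt(f1$component_loadings[which.max(abs(f1$component_loadings[, k])), k], 0)
  }
})

test_that("projection is idempotent and overlap matches per-column R-squared", {
  tb <- toy_blocks()
  ext <- external_analysis(tb$Z, tb$G)
  again <- external_analysis(ext$constrained, tb$G)
  expect_lt(max(abs(again$constrained - ext$constrained)), 1e-10)

  r2 <- vapply(1:3, function(j) {
    summary(lm(tb$Z[, j] ~ tb$G - 1))$r.squared
  }, numeric(1))
  expect_equal(ext$overlap_fraction, mean(r2), tolerance = 1e-10)
})

test_that("rotation preserves overlap, row communalities and score orthogonality", {
  spec <- mini_planted_spec(N = 150)
  m <- generate_sample_matrix(spec, seed = 5)
  unrot <- fit_cpca(m, 2, rotate = FALSE)
  rot <- fit_cpca(m, 2, rotate = TRUE)
  expect_equal(rot$overlap_fraction, unrot$overlap_fraction,
               tolerance = 1e-12)
  expect_lt(abs(cor(rot$scores)[1, 2]), 1e-10)
  expect_equal(sum(rot$var_frac_constrained),
               sum(unrot$var_frac_constrained), tolerance = 1e-10)
})

test_that("under independence the expected overlap is about p/(N-1)", {
  set.seed(33)
  n <- 200; p <- 27; q <- 15
  ov <- replicate(60, {
    G <- scale(matrix(rnorm(n * p), n, p))
    Z <- scale(matrix(rnorm(n * q), n, q))
    external_analysis(Z, G)$overlap_fraction
  })
  expect_equal(mean(ov), p / (n - 1), tolerance = 0.01)
})

test_that("constrained eigenstructure agrees with redundancy analysis", {
  skip_if_not_installed("vegan")
  tb <- toy_blocks()
  ext <- external_analysis(tb$Z, tb$G)
  ours <- scree_eigenvalues(ext$constrained)
  rda_fit <- vegan::rda(X = as.data.frame(tb$Z), Y = as.data.frame(tb$G))
  theirs <- as.numeric(rda_fit$CCA$eig)
  expect_equal(ours[seq_along(theirs)], theirs, tolerance = 1e-8,
               ignore_attr = TRUE)
})
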