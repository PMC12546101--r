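# Shared fixtures and independent oracles for the test suite.

# Small deterministic raw table: `n` subjects, symptom items on a 1-7 scale
# plus continuous criteria, optionally with missing cells.
make_raw_table <- function(n = 40, items = c("S1", "S2", "S3"),
                           crits = c("M1", "M2", "M3"), seed = 1) {
  set.seed(seed)
  d <- data.frame(id = sprintf("P%02d", seq_len(n)))
  for (s in items) d[[s]] <- sample(1:7, n, replace = TRUE)
  for (m in crits) d[[m]] <- rnorm(n)
  d
}

make_roles <- function(items, crits, exclude = character()) {
  list(predictors = items, criteria = crits, exclude = exclude)
}

# Centered deterministic toy blocks for the CPCA oracles: 6 subjects,
# 2 predictors, 3 criteria, integer-valued before centering.
toy_blocks <- function() {
  G <- matrix(c(1, 2, 3, 4, 5, 6,
                2, 1, 4, 3, 6, 5), 6, 2,
              dimnames = list(NULL, c("g1", "g2")))
  Z <- matrix(c(1, 3, 2, 5, 4, 6,
                5, 1, 4, 2, 6, 3,
                2, 2, 5, 3, 8, 4), 6, 3,
              dimnames = list(NULL, c("z1", "z2", "z3")))
  list(G = scale(G), Z = scale(Z))
}

# Brute-force projection oracle: explicit hat-matrix product with a dense
# inverse, independent of the QR route used by the package.
oracle_projection <- function(Z, G) {
  G %*% solve(t(G) %*% G) %*% t(G) %*% Z
}

# Varimax criterion (raw, no Kaiser normalization): variance of squared
# loadings per column.
varimax_criterion <- function(L) {
  sum(apply(L^2, 2, function(x) mean(x^2) - mean(x)^2))
}

# Grid + golden-section oracle for the optimal planar rotation of a
# two-column loading matrix.
oracle_varimax_angle <- function(L) {
  rot <- function(th) matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  f <- function(th) varimax_criterion(L %*% rot(th))
  grid <- seq(0, pi / 2, length.out = 2001)
  vals <- vapply(grid, f, numeric(1))
  th0 <- grid[which.max(vals)]
  opt <- stats::optimize(f, c(th0 - 0.002, th0 + 0.002), maximum = TRUE,
                         tol = 1e-10)
  list(theta = opt$maximum, value = opt$objective)
}

# Exhaustive alignment oracle for m = 2: all 2 permutations x 4 sign
# patterns, maximizing total absolute Tucker congruence.
oracle_align2 <- function(L, Lref) {
  tc <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  best <- NULL; best_val <- -Inf
  for (perm in list(c(1, 2), c(2, 1))) {
    for (s1 in c(-1, 1)) for (s2 in c(-1, 1)) {
      val <- abs(tc(s1 * L[, perm[1]], Lref[, 1])) +
        abs(tc(s2 * L[, perm[2]], Lref[, 2]))
      if (val > best_val) {
        best_val <- val
        best <- list(perm = perm, signs = c(s1, s2), value = val)
      }
    }
  }
  best
}

# A tiny planted two-latent spec for fast engine tests: strong, clean
# structure so recovery is unambiguous at modest N.
mini_planted_spec <- function(N = 120) {
  lambda_c <- matrix(c(0.75, 0.10,
                       0.70, 0.12,
                       0.10, 0.75,
                       0.12, 0.70,
                       0.10, 0.10,
                       0.12, 0.08), ncol = 2, byrow = TRUE,
                     dimnames = list(paste0("M", 1:6), c("C1", "C2")))
  lambda_p <- matrix(c(-0.70, 0.00,
                       0.00, -0.65,
                       0.05, 0.02,
                       -0.04, 0.06,
                       0.03, -0.05), ncol = 2, byrow = TRUE,
                     dimnames = list(paste0("S", 1:5), c("C1", "C2")))
  synthetic_spec(N = N, lambda_c = lambda_c, lambda_p = lambda_p)
}

# Richer design with several strong symptom indicators per latent, so the
# predictor block recovers the latents well (R(f|G) ~ 0.85); used where a
# test needs component scores to track the generating latents closely.
dense_indicator_spec <- function(N = 160) {
  lambda_c <- matrix(c(0.75, 0.10,
                       0.70, 0.10,
                       0.10, 0.75,
                       0.10, 0.70,
                       0.10, 0.10,
                       0.12, 0.08), ncol = 2, byrow = TRUE,
                     dimnames = list(paste0("M", 1:6), c("C1", "C2")))
  lambda_p <- matrix(c(0.80, 0.00,
                       0.00, 0.75,
                       0.70, 0.05,
                       0.05, 0.70,
                       0.60, 0.00,
                       0.00, 0.60,
                       0.50, 0.05,
                       0.05, 0.50), ncol = 2, byrow = TRUE,
                     dimnames = list(paste0("S", 1:8), c("C1", "C2")))
  synthetic_spec(N = N, lambda_c = lambda_c, lambda_p = lambda_p)
}

table1_summaries_path <- function() {
  system.file("extdata", "table1_site_summaries.csv", package = "icpca")
}
table1_sex_path <- function() {
  system.file("extdata", "table1_sex_counts.csv", package = "icpca")
}
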