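#' Tucker congruence between loading vectors
#'
#' @param x,y Numeric vectors (loading columns).
#' @return The congruence coefficient sum(xy)/sqrt(sum(x^2) sum(y^2)), the
#'   cosine of the angle between the two vectors; 0 if either is null.
#' @export
tucker_congruence <- function(x, y) {
  d <- sqrt(sum(x^2) * sum(y^2))
  if (d == 0) return(0)
  sum(x * y) / d
}

# All permutations of 1..n as a matrix (n! rows). n is the component count,
# small by construction.
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    out[rows, -1L] <- matrix(seq_len(n)[-i][sub], nrow(sub))
  }
  out
}

# Optimal injective assignment of the columns of `loadings` to the columns
# of `ref_loadings`, maximizing total |Tucker congruence|. Returns
# list(perm, signs, congruence): column k of the solution matches reference
# column perm[k] with sign signs[k].
.match_components <- function(loadings, ref_loadings) {
  ms <- ncol(loadings)
  mr <- ncol(ref_loadings)
  stopifnot(ms <= mr, mr <= 8L)
  cg <- matrix(0, ms, mr)
  for (i in seq_len(ms)) for (j in seq_len(mr)) {
    cg[i, j] <- tucker_congruence(loadings[, i], ref_loadings[, j])
  }
  perms <- .permutations(mr)
  best <- NULL; best_val <- -Inf
  for (r in seq_len(nrow(perms))) {
    asg <- perms[r, seq_len(ms)]
    val <- sum(abs(cg[cbind(seq_len(ms), asg)]))
    if (val > best_val) { best_val <- val; best <- asg }
  }
  signs <- ifelse(cg[cbind(seq_len(ms), best)] < 0, -1, 1)
  list(perm = best, signs = signs,
       congruence = abs(cg[cbind(seq_len(ms), best)]))
}

#' Align a CPCA solution to a reference solution
#'
#' Components fitted on different subsamples are identified only up to
#' column order and sign. This permutes and sign-flips the columns of a
#' solution to maximize the total Tucker congruence between its component
#' loadings and those of a reference solution, solved exactly by
#' enumeration over all assignments. Congruence is computed on component
#' (criterion) loadings because the criteria define each component's
#' identity.
#'
#' @param s A `cpca_solution` to align.
#' @param ref The reference `cpca_solution` with the same criterion
#'   variables and at least as many components.
#' @return `s` with columns reordered/sign-flipped to match `ref`; the
#'   attribute `alignment` records the permutation, signs and per-component
#'   congruence values.
#' @export
align_solution <- function(s, ref) {
  stopifnot(nrow(s$component_loadings) == nrow(ref$component_loadings))
  mt <- .match_components(s$component_loadings, ref$component_loadings)
  ord <- order(mt$perm)            # place column matching ref k at slot k
  sg <- mt$signs[ord]
  flip <- function(x) sweep(x[, ord, drop = FALSE], 2, sg, `*`)
  s$scores <- flip(s$scores)
  s$component_loadings <- flip(s$component_loadings)
  s$predictor_loadings <- flip(s$predictor_loadings)
  s$var_frac_constrained <- s$var_frac_constrained[ord]
  s$var_frac_total <- s$var_frac_total[ord]
  cn <- paste0("C", seq_len(s$n_components))
  colnames(s$scores) <- colnames(s$component_loadings) <-
    colnames(s$predictor_loadings) <- cn
  attr(s, "alignment") <- list(
    assignment = mt$perm,              # original column i matched ref column
    ref_component = sort(mt$perm),     # ref column matched by output column k
    signs = sg,
    congruence = mt$congruence[ord])
  s
}

#' Match fitted components to a set of target loading vectors
#'
#' Identifies which fitted component corresponds to each column of a target
#' loading matrix (for instance the generating criterion loadings of a
#' synthetic population) by maximizing total absolute Tucker congruence.
#'
#' @param solution A `cpca_solution`.
#' @param target q x k matrix of target criterion loading vectors (k <= m).
#' @return Integer vector of length k: `out[j]` is the fitted component
#'   matching target column j, with attribute `signs` giving the matched
#'   sign.
#' @export
match_components <- function(solution, target) {
  target <- as.matrix(target)
  mt <- .match_components(target, solution$component_loadings)
  structure(mt$perm, signs = mt$signs, congruence = mt$congruence)
}
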