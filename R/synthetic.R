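#' PANSS item codes and labels used by the synthetic presets
#'
#' The 27 symptom items retained after excluding the three items of the
#' PANSS cognitive factor (N5 Difficulty in Abstract Thinking, G10
#' Disorientation, G11 Poor Attention), and the 15 MCCB-derived cognitive
#' variables.
#'
#' @return Character vector of item codes.
#' @export
panss_items <- function() {
  c("P1", "P2", "P3", "P4", "P5", "P6", "P7",
    "N1", "N2", "N3", "N4", "N6", "N7",
    "G1", "G2", "G3", "G4", "G5", "G6", "G7", "G8", "G9",
    "G12", "G13", "G14", "G15", "G16")
}

#' @rdname panss_items
#' @export
mccb_measures <- function() {
  c("TMT_A", "DSC", "CPTIP_2", "CPTIP_3", "CPTIP_4",
    "SS_forward", "SS_backward", "LNS",
    "HVLT_1", "HVLT_2", "HVLT_3",
    "BVMTR_1", "BVMTR_2", "BVMTR_3", "Mazes")
}

#' Specify a synthetic symptom-cognition population
#'
#' Defines a latent factor population from which samples are drawn:
#' criteria are linear in the latents plus Gaussian noise; predictors are
#' linear in the latents plus noise and then discretized through fixed
#' Gaussian quantile cut points into an ordinal 1..levels scale (emulating
#' clinician severity ratings, where most items sit at the mild end).
#' Unit-variance columns are enforced by setting each noise SD to
#' sqrt(1 - communality) unless overridden.
#'
#' @param N Number of subjects.
#' @param lambda_c q x m criterion loading matrix (rows named).
#' @param lambda_p p x m predictor loading matrix (rows named).
#' @param criterion_noise_sd,predictor_noise_sd Optional noise SDs; default
#'   sqrt(1 - rowSums(lambda^2)).
#' @param likert_levels Number of ordinal levels for predictors (default 7).
#' @param cutpoints Increasing vector of `likert_levels - 1` latent-scale
#'   cut points; the default is skewed so low severity levels are most
#'   frequent.
#' @param missing_rate Probability that any cell is missing completely at
#'   random (default 0).
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(N, lambda_c, lambda_p,
                           criterion_noise_sd = NULL,
                           predictor_noise_sd = NULL,
                           likert_levels = 7,
                           cutpoints = stats::qnorm(
                             c(0.30, 0.55, 0.75, 0.88, 0.95, 0.985)),
                           missing_rate = 0) {
  lambda_c <- as.matrix(lambda_c)
  lambda_p <- as.matrix(lambda_p)
  stopifnot(ncol(lambda_c) == ncol(lambda_p))
  h2c <- rowSums(lambda_c^2)
  h2p <- rowSums(lambda_p^2)
  if (any(h2c > 1) || any(h2p > 1)) {
    stop("row communalities must not exceed 1")
  }
  if (is.null(criterion_noise_sd)) criterion_noise_sd <- sqrt(1 - h2c)
  if (is.null(predictor_noise_sd)) predictor_noise_sd <- sqrt(1 - h2p)
  stopifnot(all(criterion_noise_sd > 0), all(predictor_noise_sd > 0))
  if (length(cutpoints) != likert_levels - 1 ||
      any(diff(cutpoints) <= 0)) {
    stop("cutpoints must be strictly increasing, length levels - 1")
  }
  stopifnot(missing_rate >= 0, missing_rate < 1)
  structure(
    list(N = as.integer(N), n_latents = ncol(lambda_c),
         lambda_c = lambda_c, lambda_p = lambda_p,
         criterion_noise_sd = criterion_noise_sd,
         predictor_noise_sd = predictor_noise_sd,
         likert_levels = as.integer(likert_levels),
         cutpoints = cutpoints, missing_rate = missing_rate),
    class = "synthetic_spec")
}

#' Generate a synthetic sample
#'
#' Draws latent factors as iid standard normals, builds continuous criterion
#' and predictor variables from the loading matrices plus noise, discretizes
#' the predictors through the cut points, applies the optional
#' missing-completely-at-random mask, and returns the data together with the
#' generating ground truth (loadings and latent scores) for recovery
#' scoring.
#'
#' @param spec A `synthetic_spec`.
#' @param seed Optional integer seed.
#' @return List with `data` (data.frame: `subject`, predictor columns,
#'   criterion columns), `roles` (list usable by [assemble()]) and `truth`
#'   (list with `lambda_c`, `lambda_p`, `latents`, `spec`).
#' @export
generate <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$N
  m <- spec$n_latents
  p <- nrow(spec$lambda_p)
  q <- nrow(spec$lambda_c)
  f <- matrix(stats::rnorm(n * m), n, m)
  crit <- f %*% t(spec$lambda_c) +
    matrix(stats::rnorm(n * q), n, q) %*% diag(spec$criterion_noise_sd, q)
  pred_cont <- f %*% t(spec$lambda_p) +
    matrix(stats::rnorm(n * p), n, p) %*% diag(spec$predictor_noise_sd, p)
  pred <- matrix(findInterval(pred_cont, spec$cutpoints) + 1L, n, p)
  colnames(pred) <- rownames(spec$lambda_p)
  colnames(crit) <- rownames(spec$lambda_c)
  if (spec$missing_rate > 0) {
    mask_p <- matrix(stats::runif(n * p) < spec$missing_rate, n, p)
    mask_c <- matrix(stats::runif(n * q) < spec$missing_rate, n, q)
    pred[mask_p] <- NA
    crit[mask_c] <- NA
  }
  dat <- data.frame(subject = sprintf("S%03d", seq_len(n)), pred, crit,
                    check.names = FALSE)
  list(data = dat,
       roles = list(predictors = colnames(pred),
                    criteria = colnames(crit),
                    exclude = character()),
       truth = list(lambda_c = spec$lambda_c, lambda_p = spec$lambda_p,
                    latents = f, spec = spec))
}

#' Generate and assemble in one step
#'
#' @inheritParams generate
#' @param missing_policy Passed to [assemble()].
#' @return A `sample_matrix` with the ground truth attached as attribute
#'   `truth`.
#' @export
generate_sample_matrix <- function(spec, seed = NULL,
                                   missing_policy = "listwise") {
  g <- generate(spec, seed = seed)
  m <- assemble(g$data, g$roles, missing_policy = missing_policy)
  attr(m, "truth") <- g$truth
  m
}

#' Preset emulating a PANSS-by-MCCB symptom-cognition design
#'
#' A two-latent population sized like a multisite chronic-schizophrenia
#' cohort: 198 subjects, 27 ordinal symptom items, 15 continuous cognitive
#' measures. Latent 1 is a verbal memory/learning dimension carried by the
#' three HVLT trials and predicted dominantly by item N6 (lack of
#' spontaneity and flow of conversation); latent 2 is a visual
#' attention/working-memory dimension carried by the CPT-IP 3- and 4-digit
#' conditions, digit-symbol coding and backward spatial span, predicted
#' dominantly by item G7 (motor retardation). The planted latent loadings
#' (-0.62 and -0.63) are chosen so that the split-half reliability of the
#' two planted predictor-component cells is high (PLRP in the 90s and 80s)
#' despite the attenuation from ordinal discretization; because component
#' scores live in the predictor span, the observed predictor loadings for a
#' single dominant indicator come out somewhat larger in magnitude than the
#' planted values. All other symptom items carry only weak associations, so
#' the two planted cells are the only reliably recoverable
#' predictor-component links.
#'
#' @param N Number of subjects (default 198).
#' @return A `synthetic_spec`.
#' @export
preset_panss_mccb <- function(N = 198) {
  crit <- mccb_measures()
  lambda_c <- matrix(c(
    # C1 (verbal memory) C2 (attention/working memory)
    -0.30, -0.25,  # TMT_A (time score: higher is worse)
     0.20,  0.55,  # DSC
     0.12,  0.42,  # CPTIP_2
     0.15,  0.60,  # CPTIP_3
     0.15,  0.65,  # CPTIP_4
     0.18,  0.38,  # SS_forward
     0.18,  0.52,  # SS_backward
     0.32,  0.38,  # LNS
     0.62,  0.18,  # HVLT_1
     0.65,  0.15,  # HVLT_2
     0.70,  0.20,  # HVLT_3
     0.35,  0.12,  # BVMTR_1
     0.38,  0.15,  # BVMTR_2
     0.38,  0.18,  # BVMTR_3
     0.22,  0.35   # Mazes
  ), ncol = 2, byrow = TRUE, dimnames = list(crit, c("C1", "C2")))

  pred <- panss_items()
  lambda_p <- matrix(c(
     0.02,  0.08,  # P1
    -0.05, -0.10,  # P2
    -0.08,  0.04,  # P3
    -0.03,  0.02,  # P4
    -0.02,  0.07,  # P5
     0.04,  0.05,  # P6
    -0.03, -0.06,  # P7
    -0.10, -0.04,  # N1
    -0.09, -0.02,  # N2
    -0.09,  0.02,  # N3
    -0.02, -0.06,  # N4
    -0.62,  0.00,  # N6  planted: verbal memory predictor
    -0.06, -0.06,  # N7
    -0.04,  0.01,  # G1
     0.12, -0.01,  # G2
     0.07,  0.02,  # G3
     0.05,  0.03,  # G4
    -0.10, -0.05,  # G5
     0.07, -0.02,  # G6
     0.00, -0.63,  # G7  planted: attention/working memory predictor
    -0.03,  0.01,  # G8
    -0.02,  0.08,  # G9
     0.02,  0.00,  # G12
    -0.02, -0.06,  # G13
     0.01, -0.05,  # G14
    -0.05, -0.04,  # G15
     0.00, -0.01   # G16
  ), ncol = 2, byrow = TRUE, dimnames = list(pred, c("C1", "C2")))

  synthetic_spec(N = N, lambda_c = lambda_c, lambda_p = lambda_p)
}

#' Null variant: same marginals, no symptom-cognition association
#'
#' Zeroes every predictor loading of a spec, leaving the criterion structure
#' and the ordinal marginals untouched, so predictors and criteria are
#' independent.
#'
#' @param spec A `synthetic_spec` (default the PANSS-by-MCCB preset).
#' @return A `synthetic_spec`.
#' @export
preset_null <- function(spec = preset_panss_mccb()) {
  synthetic_spec(N = spec$N, lambda_c = spec$lambda_c,
                 lambda_p = spec$lambda_p * 0,
                 likert_levels = spec$likert_levels,
                 cutpoints = spec$cutpoints,
                 missing_rate = spec$missing_rate)
}
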