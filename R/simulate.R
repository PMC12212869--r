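#' Parameters for the synthetic birth-cohort generator
#'
#' Describes a registry-like singleton cohort: sex ratio, a gestational-age
#' mixture (a term component and a preterm tail), a latent
#' growth-restriction (FGR) subpopulation whose weight z-scores are shifted
#' down and whose births are preferentially preterm, multiplicative weight
#' noise at constant coefficient of variation around the region-specific
#' mean, and logistic outcome models in the latent z (and prematurity).
#'
#' Outcome models have the form
#' `logit P = logit(base) + z_slope * z + preterm_logodds * preterm`,
#' so `z_slope < 0` makes risk rise with growth deficit and `z_slope = 0`
#' gives a size-independent (null) outcome. The default stillbirth slope
#' (-0.78) is calibrated so the defaults yield an overall stillbirth rate
#' of about 0.25%.
#'
#' @param n Number of births.
#' @param seed Integer seed; the full cohort is a deterministic function of
#'   it, and record i is unchanged if `n` grows (per-record streams).
#' @param sex_male_prob Probability a birth is male (default 0.51).
#' @param ga_term_mean,ga_term_sd Term gestation component, days (278, 8).
#' @param ga_bounds Gestation window in days (default 168-300).
#' @param preterm_fraction Baseline probability of drawing from the preterm
#'   tail (< 259 days; default 0.07).
#' @param fgr_fraction Latent FGR fraction (default 0.05).
#' @param fgr_z_shift,fgr_z_sd Latent z distribution of FGR births
#'   (default Normal(-1.5, 0.5)).
#' @param fgr_preterm_multiplier Multiplier (>= 1) on the preterm
#'   probability for FGR births (default 3).
#' @param cv Coefficient of variation of weight around the gestational mean
#'   (default `NULL`: use the reference's cv).
#' @param outcome_params Named list of outcome models, each
#'   `list(base=, z_slope=, preterm_logodds=)`. See defaults in the source;
#'   `apgar5_lt4` is applied conditionally within `apgar5_lt7`.
#' @param delivery_emergency_z_slope Log-odds slope of emergency cesarean
#'   on z (default -0.4; 0 for size-independent delivery mode).
#' @return A validated list of class `simulation_params`.
#' @export
simulation_params <- function(n,
                              seed = 1L,
                              sex_male_prob = 0.51,
                              ga_term_mean = 278,
                              ga_term_sd = 8,
                              ga_bounds = c(168L, 300L),
                              preterm_fraction = 0.07,
                              fgr_fraction = 0.05,
                              fgr_z_shift = -1.5,
                              fgr_z_sd = 0.5,
                              fgr_preterm_multiplier = 3,
                              cv = NULL,
                              outcome_params = NULL,
                              delivery_emergency_z_slope = -0.4) {
  defaults <- list(
    stillbirth = list(base = 0.0015, z_slope = -0.78, preterm_logodds = 1.0),
    neonatal_death = list(base = 0.0008, z_slope = -0.60, preterm_logodds = 2.0),
    nicu = list(base = 0.02, z_slope = -0.60, preterm_logodds = 2.5),
    apgar5_lt7 = list(base = 0.012, z_slope = -0.45, preterm_logodds = 1.2),
    apgar5_lt4 = list(base = 0.0015, z_slope = -0.55, preterm_logodds = 1.2),
    induced_for_poor_growth = list(base = 0.025, z_slope = -1.1, preterm_logodds = 0),
    operative_for_fetal_distress = list(base = 0.10, z_slope = -0.35, preterm_logodds = 0.3)
  )
  if (!is.null(outcome_params)) {
    for (nm in names(outcome_params)) {
      if (!nm %in% names(defaults)) stop("unknown outcome: ", nm, call. = FALSE)
      defaults[[nm]] <- utils::modifyList(defaults[[nm]], outcome_params[[nm]])
    }
  }
  p <- list(n = as.integer(n), seed = as.integer(seed),
            sex_male_prob = sex_male_prob,
            ga_term_mean = ga_term_mean, ga_term_sd = ga_term_sd,
            ga_bounds = as.integer(ga_bounds),
            preterm_fraction = preterm_fraction,
            fgr_fraction = fgr_fraction,
            fgr_z_shift = fgr_z_shift, fgr_z_sd = fgr_z_sd,
            fgr_preterm_multiplier = fgr_preterm_multiplier,
            cv = cv, outcome_params = defaults,
            delivery_emergency_z_slope = delivery_emergency_z_slope)
  probs <- c(p$sex_male_prob, p$preterm_fraction, p$fgr_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (p$n <= 0) stop("n must be positive", call. = FALSE)
  if (p$ga_bounds[1] < 168L || p$ga_bounds[2] > 300L ||
      p$ga_bounds[1] >= p$ga_bounds[2]) {
    stop("ga_bounds must lie within 168-300 days", call. = FALSE)
  }
  if (p$fgr_preterm_multiplier < 1) stop("fgr_preterm_multiplier must be >= 1", call. = FALSE)
  if (p$fgr_fraction > 0 && p$preterm_fraction * p$fgr_preterm_multiplier > 1) {
    stop("preterm_fraction * fgr_preterm_multiplier exceeds 1", call. = FALSE)
  }
  if (p$fgr_z_sd <= 0 || p$ga_term_sd <= 0) stop("scale parameters must be positive", call. = FALSE)
  structure(p, class = "simulation_params")
}

#' Null simulation parameters
#'
#' A pure calibration cohort: no latent FGR subpopulation, all outcome
#' slopes zero (outcomes independent of size), 50/50 sex. Weights are then
#' drawn exactly from the chart's own model, so the chart classifying them
#' should flag about 10% SGA, 3% below the 3rd centile, and so on.
#'
#' @inheritParams simulation_params
#' @param ... Further arguments to [simulation_params()].
#' @return A `simulation_params` object.
#' @export
null_simulation_params <- function(n, seed = 1L, sex_male_prob = 0.5, ...) {
  zero <- list(z_slope = 0, preterm_logodds = 0)
  simulation_params(
    n = n, seed = seed, sex_male_prob = sex_male_prob,
    fgr_fraction = 0,
    outcome_params = list(
      stillbirth = zero, neonatal_death = zero, nicu = zero,
      apgar5_lt7 = zero, apgar5_lt4 = zero,
      induced_for_poor_growth = zero, operative_for_fetal_distress = zero),
    delivery_emergency_z_slope = 0,
    ...
  )
}

# fixed number of uniform variates consumed per record; record i uses
# slots (i-1)*K+1 .. i*K so earlier records are untouched when n grows
.SIM_SLOTS <- 16L

#' Generate a synthetic birth cohort
#'
#' Deterministic for a fixed seed (byte-identical cohorts), with per-record
#' random streams: increasing `n` appends records without reshuffling
#' earlier ones. Weights are `frogs_mean(ga, ref, sex) * (1 + cv * z)`
#' (floored at 150 g, rounded to the gram) with `z ~ N(0,1)` for normal
#' births and `z ~ N(fgr_z_shift, fgr_z_sd)` for the latent FGR
#' subpopulation, whose births are preferentially preterm. Binary outcomes
#' follow the logistic models in [simulation_params()]; stillbirths carry
#' no neonatal outcomes (NICU and Apgar set missing, neonatal death
#' `FALSE`).
#'
#' @param params A [simulation_params()].
#' @param ref The [population_reference()] the weights are generated around
#'   (default the standard reference).
#' @return A [as_cohort()] cohort with the usual record columns plus the
#'   simulation truth: `true_fgr`, `true_z`, `true_preterm`.
#' @export
generate_cohort <- function(params, ref = default_reference()) {
  stopifnot(inherits(params, "simulation_params"))
  n <- params$n
  cv <- params$cv %||% ref$cv
  K <- .SIM_SLOTS

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(params$seed)
  U <- matrix(stats::runif(n * K), nrow = n, ncol = K, byrow = TRUE)

  sex <- ifelse(U[, 1] < params$sex_male_prob, "male", "female")
  fgr <- U[, 2] < params$fgr_fraction
  p_pt <- pmin(1, params$preterm_fraction *
                 ifelse(fgr, params$fgr_preterm_multiplier, 1))
  preterm <- U[, 3] < p_pt

  lo <- params$ga_bounds[1]; hi <- params$ga_bounds[2]
  # term component: truncated normal via inverse CDF (stream-preserving)
  plo <- stats::pnorm(259, params$ga_term_mean, params$ga_term_sd)
  phi <- stats::pnorm(hi + 1, params$ga_term_mean, params$ga_term_sd)
  ga_term <- stats::qnorm(plo + U[, 4] * (phi - plo),
                          params$ga_term_mean, params$ga_term_sd)
  # preterm tail: right-skewed towards late preterm over [lo, 258]
  ga_pre <- lo + (259 - lo) * stats::qbeta(U[, 4], 3, 1.2)
  ga <- as.integer(pmin(hi, pmax(lo, floor(ifelse(preterm, ga_pre, ga_term)))))

  z <- ifelse(fgr,
              stats::qnorm(U[, 5], params$fgr_z_shift, params$fgr_z_sd),
              stats::qnorm(U[, 5]))
  mu <- frogs_mean(ga, ref, sex)
  weight <- round(pmax(150, mu * (1 + cv * z)))

  op <- params$outcome_params
  pmodel <- function(m) {
    stats::plogis(stats::qlogis(m$base) + m$z_slope * z +
                    m$preterm_logodds * preterm)
  }
  stillbirth <- U[, 6] < pmodel(op$stillbirth)
  neonatal_death <- !stillbirth & U[, 7] < pmodel(op$neonatal_death)
  nicu <- !stillbirth & U[, 8] < pmodel(op$nicu)
  p7 <- pmodel(op$apgar5_lt7)
  p4 <- pmodel(op$apgar5_lt4)
  lt7 <- U[, 9] < p7
  lt4 <- lt7 & (U[, 10] < pmin(1, p4 / p7))
  apgar5 <- ifelse(lt4, floor(U[, 14] * 4),
                   ifelse(lt7, 4 + floor(U[, 14] * 3),
                          8 + floor(U[, 14] * 3)))
  apgar5 <- as.integer(pmin(10L, apgar5))
  apgar5[stillbirth] <- NA_integer_
  nicu[stillbirth] <- NA

  induced <- U[, 11] < pmodel(op$induced_for_poor_growth)
  distress <- U[, 12] < pmodel(op$operative_for_fetal_distress)

  # delivery mode: emergency cesarean odds rise with growth deficit;
  # the remaining mass keeps its base proportions
  p_em <- stats::plogis(stats::qlogis(0.17) +
                          params$delivery_emergency_z_slope * z)
  rest <- c(unassisted_vaginal = 0.55, instrumental = 0.13,
            elective_cs = 0.15) / 0.83
  cut1 <- (1 - p_em) * rest[1]
  cut2 <- (1 - p_em) * (rest[1] + rest[2])
  cut3 <- 1 - p_em
  u <- U[, 13]
  delivery_mode <- ifelse(u < cut1, "unassisted_vaginal",
                          ifelse(u < cut2, "instrumental",
                                 ifelse(u < cut3, "elective_cs",
                                        "emergency_cs")))

  df <- data.frame(
    id = sprintf("b%07d", seq_len(n)),
    ga_days = ga,
    sex = sex,
    birthweight_g = weight,
    stillbirth = stillbirth,
    neonatal_death = neonatal_death,
    nicu = nicu,
    apgar5 = apgar5,
    delivery_mode = delivery_mode,
    induced_for_poor_growth = induced,
    operative_for_fetal_distress = distress,
    true_fgr = fgr,
    true_z = z,
    true_preterm = preterm,
    stringsAsFactors = FALSE
  )
  as_cohort(df)
}

#' Confusion-matrix rates of SGA against the simulation truth
#'
#' Only available for synthetic cohorts, where the latent FGR label is
#' known: sensitivity and specificity of a chart's SGA call for true
#' growth restriction, with Wilson intervals. Unclassifiable records are
#' excluded (and counted).
#'
#' @param cc A [classify_cohort()] result whose cohort carries `true_fgr`.
#' @param subset Optional logical vector restricting the evaluation (e.g.
#'   preterm births only).
#' @return A list with `sensitivity` and `specificity` (each a
#'   [wilson_ci()] `proportion_estimate`), `ppv`, `npv` (plain fractions)
#'   and `n_excluded`.
#' @export
truth_metrics <- function(cc, subset = NULL) {
  stop_if_not_classified(cc)
  if (!"true_fgr" %in% names(cc)) {
    stop("cohort has no truth labels (true_fgr); only synthetic cohorts do",
         call. = FALSE)
  }
  keep <- cc$classifiable & !is.na(cc$sga)
  if (!is.null(subset)) keep <- keep & subset
  truth <- cc$true_fgr[keep]
  call <- cc$sga[keep]
  tp <- sum(call & truth); fn <- sum(!call & truth)
  tn <- sum(!call & !truth); fp <- sum(call & !truth)
  list(
    sensitivity = if (tp + fn > 0) wilson_ci(tp, tp + fn) else NULL,
    specificity = if (tn + fp > 0) wilson_ci(tn, tn + fp) else NULL,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    n_excluded = sum(!cc$classifiable | is.na(cc$sga))
  )
}
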