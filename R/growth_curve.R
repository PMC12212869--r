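#' Hadlock fetal weight curve
#'
#' The log-quadratic ultrasound-derived fetal weight equation
#' `exp(0.578 + 0.332 g - 0.00354 g^2)` with `g` the gestational age in
#' exact weeks. This curve supplies the *shape* of the region-specific
#' standard; its absolute level is rescaled by [proportionality_ratio()].
#'
#' @param ga_weeks Gestational age in exact (possibly fractional) weeks.
#'   Must lie in 20-44 weeks.
#' @return Expected fetal weight in grams.
#' @examples
#' round(hadlock_weight(40.5))  # 3705, the term anchor
#' @export
hadlock_weight <- function(ga_weeks) {
  if (!is.numeric(ga_weeks)) stop("ga_weeks must be numeric", call. = FALSE)
  bad <- !is.na(ga_weeks) & (ga_weeks < 20 | ga_weeks > 44)
  if (any(bad)) {
    stop(sprintf(
      "gestational age %s weeks outside the supported 20-44 week window",
      paste(signif(utils::head(ga_weeks[bad], 5), 4), collapse = ", ")),
      call. = FALSE)
  }
  exp(0.578 + 0.332 * ga_weeks - 0.00354 * ga_weeks^2)
}

#' Proportionality ratio of a population to the Hadlock anchor
#'
#' The sex-appropriate term mean birthweight expressed as a proportion of
#' the 3705 g Hadlock anchor. The ratio is maintained unchanged at all
#' earlier gestations: a population whose term mean is 94% of the anchor
#' has an expected weight of 94% of Hadlock's at every gestational day.
#' Unknown sex falls back to the combined mean.
#'
#' @param ref A [population_reference()].
#' @param sex `"male"`, `"female"` or `"unknown"` (vectorised).
#' @return Dimensionless ratio(s).
#' @examples
#' proportionality_ratio(population_reference(mean_combined_g = 3500))  # 0.94...
#' @export
proportionality_ratio <- function(ref, sex = "unknown") {
  stopifnot(inherits(ref, "population_reference"))
  sex <- check_sex(sex)
  mean_g <- ifelse(sex == "male", ref$mean_male_g,
                   ifelse(sex == "female", ref$mean_female_g,
                          ref$mean_combined_g))
  mean_g / ref$hadlock_anchor_g
}

#' Expected weight of the region-specific standard at a gestational day
#'
#' `hadlock_weight(days/7)` rescaled by the proportionality ratio for the
#' given sex. Strictly increasing in gestational age over the chart window.
#'
#' @param ga Gestational age: integer days, `"W+D"` string, or a
#'   [gestational_age()] object.
#' @param ref A [population_reference()].
#' @param sex `"male"`, `"female"` or `"unknown"` (vectorised).
#' @return Expected weight(s) in grams.
#' @export
frogs_mean <- function(ga, ref = default_reference(), sex = "unknown") {
  days <- parse_ga_days(ga)
  check_chart_window(days)
  hadlock_weight(days / 7) * proportionality_ratio(ref, sex)
}

#' Standard deviation of the region-specific standard at a gestational day
#'
#' One coefficient of variation (term SD over combined term mean; 11.8% for
#' the default reference) is applied to the sex-appropriate mean at every
#' gestation, so the SD is exactly proportional to the mean.
#'
#' @inheritParams frogs_mean
#' @return Standard deviation(s) in grams.
#' @export
frogs_sd <- function(ga, ref = default_reference(), sex = "unknown") {
  ref$cv * frogs_mean(ga, ref, sex)
}
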