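#' @keywords internal
#' @noRd
clamp_centile <- function(p) pmin(pmax(p, 0.01), 99.99)

#' Convert a weight to a centile on the region-specific standard
#'
#' Computes `z = (weight - mu) / sigma` with `mu = frogs_mean()` and
#' `sigma = frogs_sd()`, then `centile = 100 * pnorm(z)`, together with the
#' measurement-error estimate range obtained by re-scoring the weight at
#' `(1 - error_fraction)` and `(1 + error_fraction)` times its value.
#'
#' The raw centile and unbounded z are always retained; `centile_display`
#' is the centile clamped to `[0.01, 99.99]` for reporting.
#'
#' @param weight_g Weight(s) in grams; must be positive.
#' @param ga Gestational age: integer days, `"W+D"`, or [gestational_age()].
#' @param sex `"male"`, `"female"` or `"unknown"` (vectorised). Unknown sex
#'   uses the combined mean and is flagged `sex_adjusted = FALSE`.
#' @param ref A [population_reference()].
#' @param error_fraction Assumed fractional measurement error for the
#'   estimate range (default 0.10, i.e. plus or minus 10%).
#' @return A data frame of class `centile_result` with columns `weight_g`,
#'   `ga_days`, `sex`, `z`, `centile`, `centile_display`,
#'   `range_low_centile`, `range_high_centile`, `sex_adjusted`.
#' @examples
#' weight_to_centile(3490, 280)   # close to the 50th centile
#' @export
weight_to_centile <- function(weight_g, ga, sex = "unknown",
                              ref = default_reference(),
                              error_fraction = 0.10) {
  if (!is.numeric(weight_g) || any(!is.na(weight_g) & weight_g <= 0)) {
    stop("weight_g must be positive", call. = FALSE)
  }
  days <- parse_ga_days(ga)
  check_chart_window(days)
  n <- max(length(weight_g), length(days), length(sex))
  weight_g <- rep_len(weight_g, n)
  days <- rep_len(days, n)
  sex <- check_sex(rep_len(check_sex(sex), n))

  mu <- frogs_mean(days, ref, sex)
  sigma <- ref$cv * mu
  z <- (weight_g - mu) / sigma
  centile <- 100 * stats::pnorm(z)
  rng <- estimate_range(weight_g, days, sex, ref, error_fraction)
  structure(
    data.frame(
      weight_g = weight_g,
      ga_days = days,
      sex = sex,
      z = z,
      centile = centile,
      centile_display = clamp_centile(centile),
      range_low_centile = rng$low,
      range_high_centile = rng$high,
      sex_adjusted = sex != "unknown",
      stringsAsFactors = FALSE
    ),
    class = c("centile_result", "data.frame")
  )
}

#' Invert the standard: weight at a given centile
#'
#' `mu + sigma * qnorm(centile/100)`; the exact inverse of
#' [weight_to_centile()] (round-trips to within 1e-9 relative error).
#'
#' @param centile Centile(s) strictly between 0 and 100.
#' @inheritParams weight_to_centile
#' @return Weight(s) in grams.
#' @export
centile_to_weight <- function(centile, ga, sex = "unknown",
                              ref = default_reference()) {
  if (!is.numeric(centile) || any(!is.na(centile) & (centile <= 0 | centile >= 100))) {
    stop("centile must lie strictly between 0 and 100", call. = FALSE)
  }
  days <- parse_ga_days(ga)
  check_chart_window(days)
  mu <- frogs_mean(days, ref, sex)
  mu + ref$cv * mu * stats::qnorm(centile / 100)
}

#' Measurement-error estimate range for a weight centile
#'
#' Re-scores the weight multiplied by `1 - error_fraction` (underestimate)
#' and `1 + error_fraction` (overestimate) on the same standard, giving the
#' centile interval within which the true centile would fall under the
#' assumed ultrasound measurement error.
#'
#' @inheritParams weight_to_centile
#' @return A list with numeric vectors `low` and `high` (centiles, raw,
#'   unclamped). `low <= point centile <= high` always holds, with equality
#'   only at `error_fraction = 0`.
#' @export
estimate_range <- function(weight_g, ga, sex = "unknown",
                           ref = default_reference(),
                           error_fraction = 0.10) {
  if (!is.numeric(error_fraction) || length(error_fraction) != 1L ||
      error_fraction < 0 || error_fraction >= 1) {
    stop("error_fraction must be a single value in [0, 1)", call. = FALSE)
  }
  days <- parse_ga_days(ga)
  check_chart_window(days)
  mu <- frogs_mean(days, ref, sex)
  sigma <- ref$cv * mu
  low <- 100 * stats::pnorm((weight_g * (1 - error_fraction) - mu) / sigma)
  high <- 100 * stats::pnorm((weight_g * (1 + error_fraction) - mu) / sigma)
  list(low = low, high = high)
}

#' @export
print.centile_result <- function(x, digits = 1, ...) {
  for (i in seq_len(nrow(x))) {
    cat(sprintf(
      "%g g at %d+%d (%s): centile %.*f (z = %.2f)\n",
      x$weight_g[i], x$ga_days[i] %/% 7L, x$ga_days[i] %% 7L, x$sex[i],
      digits, x$centile_display[i], x$z[i]))
    cat(sprintf(
      "  Assuming a 10%% measurement error, the true estimated fetal weight centile would fall between the %sth and %sth percentile.\n",
      formatC(clamp_centile(x$range_low_centile[i]), format = "f", digits = digits),
      formatC(clamp_centile(x$range_high_centile[i]), format = "f", digits = digits)))
  }
  invisible(x)
}
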