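#' Growth chart constructors
#'
#' A growth chart pairs a reference with a classification rule. Four chart
#' families are supported:
#'
#' * `frogs_chart()` -- the region-specific standard: exact centile per
#'   gestational day, optionally sex-specific.
#' * `global_week_chart()` -- a week-resolution unisex comparator: the same
#'   construction, but the mean/SD are evaluated once per completed
#'   gestational week (at the week mid-point, `completed_weeks + 0.5`) and
#'   held constant across the 7 days of that week; always the combined mean.
#' * `bracket_chart()` -- a lookup-table comparator that assigns centile
#'   *brackets* (e.g. 10th-25th) from published week-by-sex threshold
#'   tables; see [bracket_table()].
#'
#' @param ref A [population_reference()].
#' @param sex_specific Use sex-specific term means where sex is known?
#' @param table A [bracket_table()].
#' @param label Optional display label.
#' @return An object of class `growth_chart` (subclass per family).
#' @name growth_chart
NULL

#' @rdname growth_chart
#' @export
frogs_chart <- function(ref = default_reference(), sex_specific = TRUE,
                        label = NULL) {
  stopifnot(inherits(ref, "population_reference"))
  structure(
    list(kind = "frogs_day", resolution = "day",
         sex_specific = isTRUE(sex_specific), ref = ref,
         label = label %||% if (sex_specific) "frogs" else "frogs (unisex)"),
    class = c("frogs_chart", "growth_chart")
  )
}

#' @rdname growth_chart
#' @export
global_week_chart <- function(ref = default_reference(), label = NULL) {
  stopifnot(inherits(ref, "population_reference"))
  structure(
    list(kind = "global_week", resolution = "week", sex_specific = FALSE,
         ref = ref, label = label %||% "global (week)"),
    class = c("global_week_chart", "growth_chart")
  )
}

#' @rdname growth_chart
#' @export
bracket_chart <- function(table, label = NULL) {
  stopifnot(inherits(table, "bracket_table"))
  structure(
    list(kind = "lookup_bracket",
         resolution = "week",
         sex_specific = attr(table, "sex_specific"),
         table = table,
         label = label %||% "bracket lookup"),
    class = c("bracket_chart", "growth_chart")
  )
}

#' @export
print.growth_chart <- function(x, ...) {
  cat(sprintf("<growth_chart: %s> kind=%s resolution=%s sex_specific=%s\n",
              x$label, x$kind, x$resolution, x$sex_specific))
  invisible(x)
}

#' Does a chart yield exact centiles (as opposed to brackets)?
#' @param chart A `growth_chart`.
#' @return Logical scalar.
#' @export
exact_centiles <- function(chart) {
  UseMethod("exact_centiles")
}
#' @export
exact_centiles.growth_chart <- function(chart) TRUE
#' @export
exact_centiles.bracket_chart <- function(chart) FALSE

#' Week-resolution unisex centile
#'
#' Identical construction to [weight_to_centile()] except that (a) the
#' combined term mean is always used (no sex adjustment) and (b) the
#' reference mean and SD are evaluated once per completed gestational week,
#' at the week's mid-point (`completed_weeks + 0.5` weeks), and held
#' constant across all 7 days of that week. This emulates charts published
#' per completed week: a birth early in the week is scored against the same
#' threshold as one late in the week, despite being several days of growth
#' behind it.
#'
#' @inheritParams weight_to_centile
#' @return A `centile_result` data frame (see [weight_to_centile()]);
#'   `sex_adjusted` is always `FALSE`.
#' @export
global_week_centile <- function(weight_g, ga, ref = default_reference(),
                                error_fraction = 0.10) {
  if (!is.numeric(weight_g) || any(!is.na(weight_g) & weight_g <= 0)) {
    stop("weight_g must be positive", call. = FALSE)
  }
  days <- parse_ga_days(ga)
  check_chart_window(days)
  n <- max(length(weight_g), length(days))
  weight_g <- rep_len(weight_g, n)
  days <- rep_len(days, n)
  week_mid_days <- (days %/% 7L) * 7 + 3.5   # completed_weeks + 0.5 in days
  mu <- hadlock_weight(week_mid_days / 7) *
    (ref$mean_combined_g / ref$hadlock_anchor_g)
  sigma <- ref$cv * mu
  z <- (weight_g - mu) / sigma
  centile <- 100 * stats::pnorm(z)
  low <- 100 * stats::pnorm((weight_g * (1 - error_fraction) - mu) / sigma)
  high <- 100 * stats::pnorm((weight_g * (1 + error_fraction) - mu) / sigma)
  structure(
    data.frame(
      weight_g = weight_g, ga_days = days, sex = "unknown",
      z = z, centile = centile, centile_display = clamp_centile(centile),
      range_low_centile = low, range_high_centile = high,
      sex_adjusted = FALSE, stringsAsFactors = FALSE
    ),
    class = c("centile_result", "data.frame")
  )
}

#' Score weights on a chart
#'
#' The polymorphic classification entry point used by [classify_cohort()].
#' Continuous charts return exact centiles and z-scores; bracket charts
#' return centile brackets with numeric bracket bounds.
#'
#' @param chart A `growth_chart`.
#' @param weight_g Weights in grams.
#' @param ga Gestational ages (days, `"W+D"`, or [gestational_age()]).
#' @param sex Fetal sex vector (`"male"`, `"female"`, `"unknown"`).
#' @return A data frame with one row per query: always `sga`, `lga` and
#'   `classifiable`; `centile`/`z` for continuous charts;
#'   `bracket`/`bracket_low`/`bracket_high` for bracket charts. SGA is
#'   strictly centile < 10 (a weight exactly at the 10th-centile threshold
#'   is not SGA); LGA is centile > 90.
#' @export
chart_centile <- function(chart, weight_g, ga, sex = "unknown") {
  UseMethod("chart_centile")
}

#' @export
chart_centile.frogs_chart <- function(chart, weight_g, ga, sex = "unknown") {
  sex_used <- if (chart$sex_specific) sex else "unknown"
  res <- weight_to_centile(weight_g, ga, sex_used, chart$ref)
  data.frame(
    centile = res$centile,
    z = res$z,
    sga = res$centile < 10,
    lga = res$centile > 90,
    classifiable = TRUE,
    stringsAsFactors = FALSE
  )
}

#' @export
chart_centile.global_week_chart <- function(chart, weight_g, ga,
                                            sex = "unknown") {
  res <- global_week_centile(weight_g, ga, chart$ref)
  data.frame(
    centile = res$centile,
    z = res$z,
    sga = res$centile < 10,
    lga = res$centile > 90,
    classifiable = TRUE,
    stringsAsFactors = FALSE
  )
}

#' @export
chart_centile.bracket_chart <- function(chart, weight_g, ga, sex = "unknown") {
  bracket_classify(weight_g, ga, sex, chart$table)
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
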