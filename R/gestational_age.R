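#' Gestational age in exact days
#'
#' Gestational age is stored internally as an integer count of days since
#' the last menstrual period (dating per the estimated due date). Fractional
#' weeks, completed weeks and the day-of-gestational-week index are all
#' derived from the day count, never stored independently.
#'
#' @param days Integer vector of gestational days, or character vector in
#'   obstetric `"W+D"` notation (e.g. `"38+4"`). Whole-week strings such as
#'   `"38"` are read as `38+0`.
#' @return An object of class `gestational_age`: a list with integer `days`
#'   and the derived `weeks_exact` (`days/7`), `completed_weeks`
#'   (`floor(days/7)`) and `day_of_week` (`days %% 7`).
#' @examples
#' ga <- gestational_age("38+4")
#' ga$days          # 270
#' ga$day_of_week   # 4
#' @export
gestational_age <- function(days) {
  days <- parse_ga_days(days)
  structure(
    list(
      days = days,
      weeks_exact = days / 7,
      completed_weeks = days %/% 7L,
      day_of_week = days %% 7L
    ),
    class = "gestational_age"
  )
}

#' @export
print.gestational_age <- function(x, ...) {
  cat(sprintf(
    "<gestational_age> %s day(s): %s\n",
    length(x$days),
    paste0(x$completed_weeks, "+", x$day_of_week, collapse = ", ")
  ))
  invisible(x)
}

#' Parse gestational age input to integer days
#'
#' Accepts integer days, numeric whole days, `gestational_age` objects, or
#' `"W+D"` strings. Non-integer day counts are an error (days are exact).
#'
#' @param x Input vector or `gestational_age` object.
#' @return Integer vector of gestational days.
#' @export
parse_ga_days <- function(x) {
  if (inherits(x, "gestational_age")) {
    return(x$days)
  }
  if (is.character(x)) {
    x <- trimws(x)
    parts <- regmatches(x, regexec("^([0-9]+)(\\+([0-6]))?$", x))
    bad <- vapply(parts, function(p) length(p) == 0L, logical(1))
    if (any(bad)) {
      stop("cannot parse gestational age: ",
           paste(utils::head(x[bad], 5), collapse = ", "),
           " (expected integer days or \"W+D\")", call. = FALSE)
    }
    wk <- as.integer(vapply(parts, `[`, character(1), 2L))
    dy <- vapply(parts, `[`, character(1), 4L)
    dy <- ifelse(is.na(dy) | dy == "", 0L, as.integer(dy))
    # bare numbers above the plausible week range are taken as day counts
    out <- ifelse(wk > 50L & dy == 0L, wk, wk * 7L + dy)
    return(as.integer(out))
  }
  if (!is.numeric(x) || any(!is.na(x) & x != round(x))) {
    stop("gestational age must be whole days (or a \"W+D\" string)",
         call. = FALSE)
  }
  as.integer(x)
}

# internal window checks ----------------------------------------------------

#' @keywords internal
#' @noRd
check_chart_window <- function(days, low = 140L, high = 307L) {
  bad <- !is.na(days) & (days < low | days > high)
  if (any(bad)) {
    stop(sprintf(
      "gestational age %s d outside the chart window %d-%d days (%d+0 to %d+6)",
      paste(utils::head(days[bad], 5), collapse = ", "),
      low, high, low %/% 7L, high %/% 7L),
      call. = FALSE)
  }
  invisible(days)
}
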