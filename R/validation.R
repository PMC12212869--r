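#' Classify every birth in a cohort on a chart
#'
#' Step 1 of the two-step chart validation starts here: each record gets a
#' centile (or centile bracket) and SGA/LGA flags under the given chart.
#' Records a bracket chart cannot classify (missing week-by-sex cell) are
#' flagged and counted, never silently dropped; their SGA/LGA flags are
#' `NA` so they fall out of downstream denominators explicitly.
#'
#' @param cohort A [as_cohort()] cohort (or data frame with `ga_days`,
#'   `sex`, `birthweight_g`).
#' @param chart A [growth_chart][frogs_chart()].
#' @return The cohort with classification columns appended (`centile`, `z`
#'   or `bracket`, `bracket_low`, `bracket_high`; plus `sga`, `lga`,
#'   `classifiable`), class `classified_cohort`; the chart is attached as
#'   attribute `chart`.
#' @export
classify_cohort <- function(cohort, chart) {
  stopifnot(inherits(chart, "growth_chart"))
  df <- as.data.frame(cohort)
  if (nrow(df) > 0) {
    bad <- df$ga_days < 140 | df$ga_days > 307
    if (any(bad)) {
      stop("cohort contains gestations outside the chart window 140-307 days",
           call. = FALSE)
    }
    cls <- chart_centile(chart, df$birthweight_g, df$ga_days, df$sex)
    cls$sga[!cls$classifiable] <- NA
    cls$lga[!cls$classifiable] <- NA
    df <- cbind(df, cls)
  } else {
    df$sga <- logical(0); df$lga <- logical(0); df$classifiable <- logical(0)
  }
  structure(df,
            chart = chart,
            exclusion_log = attr(cohort, "exclusion_log"),
            n_input = attr(cohort, "n_input"),
            class = c("classified_cohort", "data.frame"))
}

#' @keywords internal
#' @noRd
stop_if_not_classified <- function(cc) {
  if (!inherits(cc, "classified_cohort")) {
    stop("need a classified cohort (see classify_cohort())", call. = FALSE)
  }
  invisible(cc)
}

#' Threshold proportions of a classified cohort
#'
#' Counts and percentages of births below the 3rd, 10th and 50th centile
#' and above the 90th and 97th, plus the male share of the SGA group.
#' Percentages are taken against the classifiable n. For bracket charts the
#' indicators are computed from the bracket bounds, so they are only exact
#' when the table carries the corresponding labels (3, 10, 50, 90, 97).
#'
#' @param cc A [classify_cohort()] result.
#' @return A list with `n_classifiable`, `n_unclassifiable`, a `table` data
#'   frame (threshold, count, percent) and `male_share_sga` (fraction of
#'   the SGA group that is male, `NA` if no SGA births).
#' @export
threshold_proportions <- function(cc) {
  stop_if_not_classified(cc)
  ok <- cc$classifiable
  n <- sum(ok)
  if ("centile" %in% names(cc)) {
    cent <- cc$centile[ok]
    ind <- cbind(`<3` = cent < 3, `<10` = cent < 10, `<50` = cent < 50,
                 `>90` = cent > 90, `>97` = cent > 97)
  } else {
    lo <- cc$bracket_low[ok]; hi <- cc$bracket_high[ok]
    ind <- cbind(`<3` = hi <= 3, `<10` = hi <= 10, `<50` = hi <= 50,
                 `>90` = lo >= 90, `>97` = lo >= 97)
  }
  counts <- colSums(ind)
  sga <- !is.na(cc$sga) & cc$sga
  male_share <- if (any(sga)) mean(cc$sex[sga] == "male") else NA_real_
  list(
    n_classifiable = n,
    n_unclassifiable = sum(!ok),
    table = data.frame(
      threshold = colnames(ind),
      count = as.integer(counts),
      percent = if (n > 0) 100 * counts / n else rep(NA_real_, ncol(ind)),
      row.names = NULL
    ),
    male_share_sga = male_share
  )
}

#' SGA fraction by day of the gestational week
#'
#' Diagnoses week-resolution bias: under a chart that holds its threshold
#' constant across a gestational week, births on day 0 (the youngest in
#' the week) are scored against a threshold computed for the mid-week and
#' so are classified SGA more often than births on day 6.
#'
#' @param cc A [classify_cohort()] result.
#' @return A list with `fraction` (length-7 vector of SGA fractions for
#'   days 0-6; `NA` for days with no births), `n` (births per day) and
#'   `day0_day6_ratio`.
#' @export
sga_by_day_of_week <- function(cc) {
  stop_if_not_classified(cc)
  ok <- cc$classifiable & !is.na(cc$sga)
  day <- cc$ga_days[ok] %% 7L
  sga <- cc$sga[ok]
  frac <- rep(NA_real_, 7)
  nn <- integer(7)
  for (d in 0:6) {
    idx <- day == d
    nn[d + 1] <- sum(idx)
    if (any(idx)) frac[d + 1] <- mean(sga[idx])
  }
  list(fraction = stats::setNames(frac, paste0("day", 0:6)),
       n = stats::setNames(nn, paste0("day", 0:6)),
       day0_day6_ratio = frac[1] / frac[7])
}

#' Histogram of exact centiles
#'
#' Bins the centile distribution of a classified cohort on (0, 100] with
#' summary statistics; mirrors the visual calibration check that a
#' well-calibrated chart yields a flat histogram. Bracket charts cannot be
#' histogrammed and raise an error.
#'
#' @param cc A [classify_cohort()] result from an exact-centile chart.
#' @param bin_width Bin width in centiles (must divide 100; default 5).
#' @return A list with `breaks`, `counts`, and `summary` (mean, median,
#'   q25, q75 of the centiles).
#' @export
centile_histogram <- function(cc, bin_width = 5) {
  stop_if_not_classified(cc)
  if (!"centile" %in% names(cc)) {
    stop("this chart provides centile brackets only; an exact-centile histogram is not supported",
         call. = FALSE)
  }
  if (bin_width <= 0 || 100 %% bin_width != 0) {
    stop("bin_width must be a positive divisor of 100", call. = FALSE)
  }
  cent <- clamp_centile(cc$centile[cc$classifiable])
  breaks <- seq(0, 100, by = bin_width)
  counts <- as.integer(table(cut(cent, breaks, include.lowest = FALSE)))
  list(
    breaks = breaks,
    counts = counts,
    summary = c(mean = mean(cent), median = stats::median(cent),
                q25 = unname(stats::quantile(cent, 0.25)),
                q75 = unname(stats::quantile(cent, 0.75)))
  )
}

#' SGA versus non-SGA relative risk of an outcome
#'
#' The first outcome-based validation statistic: relative risk of an
#' outcome among births classified SGA (<10th centile, the exposed group)
#' versus non-SGA (reference). Complete-case per outcome: records with a
#' missing outcome value, and records unclassifiable by the chart, are
#' excluded from both groups.
#'
#' @param cc A [classify_cohort()] result.
#' @param outcome Name of a logical outcome column (e.g. `"stillbirth"`).
#' @return A [relative_risk()] `risk_comparison`.
#' @export
sga_vs_nonsga_rr <- function(cc, outcome) {
  stop_if_not_classified(cc)
  if (!outcome %in% names(cc)) {
    stop("outcome column not present: ", outcome, call. = FALSE)
  }
  y <- outcome_indicator(cc, outcome)
  ok <- cc$classifiable & !is.na(cc$sga) & !is.na(y)
  sga <- cc$sga[ok]; y <- y[ok]
  relative_risk(sum(y[!sga]), sum(!sga), sum(y[sga]), sum(sga),
                label = outcome)
}

#' @keywords internal
#' @noRd
#' derived outcome indicators: apgar5_lt7 / apgar5_lt4 come from apgar5
outcome_indicator <- function(df, outcome) {
  if (outcome %in% names(df)) {
    x <- df[[outcome]]
    if (is.logical(x)) return(x)
    return(ifelse(is.na(x), NA, isTRUE_vec(x)))
  }
  if (outcome == "apgar5_lt7") return(ifelse(is.na(df$apgar5), NA, df$apgar5 < 7))
  if (outcome == "apgar5_lt4") return(ifelse(is.na(df$apgar5), NA, df$apgar5 < 4))
  stop("outcome column not present: ", outcome, call. = FALSE)
}

#' Outcome comparison of non-overlapping SGA populations
#'
#' Step 2 of the validation. The SGA sets of two charts are partitioned
#' into A-only, B-only and the overlap; the non-overlapping populations
#' are then compared outcome by outcome, with "SGA by chart A only" as the
#' reference group and "SGA by chart B only" as exposed. Delivery mode,
#' when present, is compared as a 4-category frequency table with a
#' chi-square test. Records unclassifiable by either chart are excluded
#' from the partition and counted.
#'
#' @param cohort A cohort.
#' @param chart_a,chart_b Two [growth_chart][frogs_chart()]s; A is the
#'   reference side.
#' @param outcomes Character vector of outcome names (columns, or derived
#'   `apgar5_lt7` / `apgar5_lt4`).
#' @return Object of class `nonoverlap_comparison`: list with `venn`
#'   (counts `a_only`, `b_only`, `both`, `a_total`, `b_total`,
#'   `unclassifiable`), `risks` (list of `risk_comparison`, one per
#'   estimable outcome), `not_estimable` (outcomes skipped because a
#'   non-overlap set is empty), and `delivery_mode` (counts + chi-square
#'   p) when available.
#' @export
nonoverlap_compare <- function(cohort, chart_a, chart_b,
                               outcomes = c("stillbirth", "perinatal_death")) {
  cc_a <- classify_cohort(cohort, chart_a)
  cc_b <- classify_cohort(cohort, chart_b)
  ok <- cc_a$classifiable & cc_b$classifiable &
    !is.na(cc_a$sga) & !is.na(cc_b$sga)
  a <- cc_a$sga & ok
  b <- cc_b$sga & ok
  venn <- list(
    a_only = sum(a & !b), b_only = sum(b & !a), both = sum(a & b),
    a_total = sum(a), b_total = sum(b), unclassifiable = sum(!ok)
  )
  df <- as.data.frame(cohort)
  sel_a <- a & !b
  sel_b <- b & !a
  risks <- list()
  not_estimable <- character()
  if (venn$a_only == 0 || venn$b_only == 0) {
    not_estimable <- outcomes
  } else {
    for (oc in outcomes) {
      y <- outcome_indicator(df, oc)
      ya <- y[sel_a]; yb <- y[sel_b]
      ya <- ya[!is.na(ya)]; yb <- yb[!is.na(yb)]
      if (length(ya) == 0 || length(yb) == 0) {
        not_estimable <- c(not_estimable, oc)
        next
      }
      risks[[oc]] <- relative_risk(sum(ya), length(ya), sum(yb), length(yb),
                                   label = oc)
    }
  }
  delivery <- NULL
  if ("delivery_mode" %in% names(df) && venn$a_only > 0 && venn$b_only > 0) {
    modes <- c("unassisted_vaginal", "instrumental", "elective_cs",
               "emergency_cs")
    ta <- table(factor(df$delivery_mode[sel_a], levels = modes))
    tb <- table(factor(df$delivery_mode[sel_b], levels = modes))
    m <- rbind(a_only = as.integer(ta), b_only = as.integer(tb))
    colnames(m) <- modes
    p <- if (all(colSums(m) > 0) && all(rowSums(m) > 0)) {
      suppressWarnings(stats::chisq.test(m)$p.value)
    } else NA_real_
    delivery <- list(counts = m, chisq_p = p)
  }
  structure(
    list(chart_a = chart_a$label, chart_b = chart_b$label,
         venn = venn, risks = risks, not_estimable = not_estimable,
         delivery_mode = delivery),
    class = "nonoverlap_comparison"
  )
}

#' @export
print.nonoverlap_comparison <- function(x, ...) {
  v <- x$venn
  cat(sprintf("Non-overlapping SGA populations: %s (A) vs %s (B)\n",
              x$chart_a, x$chart_b))
  cat(sprintf("  SGA by A only: %d; by B only: %d; by both: %d (A total %d, B total %d)\n",
              v$a_only, v$b_only, v$both, v$a_total, v$b_total))
  if (v$unclassifiable > 0) {
    cat(sprintf("  unclassifiable by at least one chart: %d\n", v$unclassifiable))
  }
  for (r in x$risks) print(r)
  if (length(x$not_estimable)) {
    cat("  not estimable:", paste(x$not_estimable, collapse = ", "), "\n")
  }
  if (!is.null(x$delivery_mode)) {
    cat(sprintf("  delivery mode chi-square p = %.4g\n", x$delivery_mode$chisq_p))
  }
  invisible(x)
}
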