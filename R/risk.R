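#' Relative risk of a 2x2 outcome comparison
#'
#' Risk ratio of group b (exposed) versus group a (reference),
#' `rr = (events_b/n_b) / (events_a/n_a)`, with the log-RR (Katz)
#' confidence interval
#' `exp(log rr +/- z * sqrt(1/events_b - 1/n_b + 1/events_a - 1/n_a))`
#' and a two-sided pooled-proportion score (z) test p-value. No continuity
#' correction is applied: zero events in the reference group yield an
#' explicit infinite RR with the CI omitted, and zero events in both
#' groups an undefined (NA) RR.
#'
#' @param events_a,n_a Events and total in the reference group.
#' @param events_b,n_b Events and total in the exposed group.
#' @param conf Confidence level (default 0.95).
#' @param label Optional outcome label carried into the result.
#' @return Object of class `risk_comparison`: list with the counts, `rr`,
#'   `ci_low`, `ci_high`, `p`, `conf`, `label` and `estimable`.
#' @examples
#' relative_risk(8, 5335, 276, 14005)   # rr 13.14, CI [6.51, 26.52]
#' @export
relative_risk <- function(events_a, n_a, events_b, n_b, conf = 0.95,
                          label = NULL) {
  counts <- c(events_a, n_a, events_b, n_b)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (n_a <= 0 || n_b <= 0) stop("group sizes must be positive", call. = FALSE)
  if (events_a > n_a || events_b > n_b) {
    stop("events cannot exceed group size", call. = FALSE)
  }
  pa <- events_a / n_a
  pb <- events_b / n_b

  if (events_a == 0 && events_b == 0) {
    rr <- NA_real_; ci <- c(NA_real_, NA_real_); estimable <- FALSE
  } else if (events_a == 0) {
    rr <- Inf; ci <- c(NA_real_, NA_real_); estimable <- FALSE
  } else {
    rr <- pb / pa
    if (events_b == 0) {
      ci <- c(NA_real_, NA_real_); estimable <- FALSE
    } else {
      z <- stats::qnorm(1 - (1 - conf) / 2)
      se <- sqrt(1 / events_b - 1 / n_b + 1 / events_a - 1 / n_a)
      ci <- exp(log(rr) + c(-1, 1) * z * se)
      estimable <- TRUE
    }
  }
  # pooled two-proportion score test
  pp <- (events_a + events_b) / (n_a + n_b)
  se0 <- sqrt(pp * (1 - pp) * (1 / n_a + 1 / n_b))
  p <- if (se0 == 0) NA_real_ else 2 * stats::pnorm(-abs((pb - pa) / se0))

  structure(
    list(label = label %||% "outcome",
         events_a = as.integer(events_a), n_a = as.integer(n_a),
         events_b = as.integer(events_b), n_b = as.integer(n_b),
         rr = rr, ci_low = ci[1], ci_high = ci[2], p = p,
         conf = conf, estimable = estimable),
    class = "risk_comparison"
  )
}

#' @export
print.risk_comparison <- function(x, ...) {
  fmt_p <- function(p) {
    if (is.na(p)) "p = NA"
    else if (p < 1e-4) "p < 0.0001"
    else sprintf("p = %.4f", p)
  }
  cat(sprintf("%s: %d/%d (%.2f%%) vs %d/%d (%.2f%%)\n",
              x$label, x$events_a, x$n_a, 100 * x$events_a / x$n_a,
              x$events_b, x$n_b, 100 * x$events_b / x$n_b))
  if (is.na(x$rr)) {
    cat("  RR not defined (no events in either group)\n")
  } else if (!is.finite(x$rr)) {
    cat("  RR infinite (no events in reference group); CI omitted\n")
  } else if (!x$estimable) {
    cat(sprintf("  RR %.2f; CI not estimable (zero events); %s\n",
                x$rr, fmt_p(x$p)))
  } else {
    cat(sprintf("  RR %.2f (%.0f%% CI %.2f-%.2f) %s\n",
                x$rr, 100 * x$conf, x$ci_low, x$ci_high, fmt_p(x$p)))
  }
  invisible(x)
}

#' Wilson score interval for a binomial proportion
#'
#' @param k Number of events (0 <= k <= n).
#' @param n Number of trials (> 0).
#' @param conf Confidence level (default 0.95).
#' @return Object of class `proportion_estimate`: list with `k`, `n`,
#'   `p_hat`, `wilson_low`, `wilson_high`, `conf`. Bounds always lie in
#'   `[0, 1]` and contain `k/n`.
#' @examples
#' wilson_ci(5, 10)   # about (0.237, 0.763)
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  if (length(k) != 1L || length(n) != 1L || n <= 0 || k < 0 || k > n ||
      k != round(k) || n != round(n)) {
    stop("need integers 0 <= k <= n with n > 0", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p_hat <- k / n
  denom <- 1 + z^2 / n
  centre <- (p_hat + z^2 / (2 * n)) / denom
  half <- z * sqrt(p_hat * (1 - p_hat) / n + z^2 / (4 * n^2)) / denom
  # algebraically the bound is exactly 0 at k = 0 (and 1 at k = n);
  # evaluate it that way rather than through the cancellation-prone form
  structure(
    list(k = as.integer(k), n = as.integer(n), p_hat = p_hat,
         wilson_low = if (k == 0) 0 else max(0, centre - half),
         wilson_high = if (k == n) 1 else min(1, centre + half),
         conf = conf),
    class = "proportion_estimate"
  )
}

#' @export
print.proportion_estimate <- function(x, ...) {
  cat(sprintf("%d/%d = %.4f (%.0f%% Wilson CI %.4f-%.4f)\n",
              x$k, x$n, x$p_hat, 100 * x$conf, x$wilson_low, x$wilson_high))
  invisible(x)
}
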