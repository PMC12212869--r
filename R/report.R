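#' Flatten analysis results to report tables
#'
#' Converts the objects produced by the validation operations into plain
#' data frames with a deterministic column order, ready to be written.
#'
#' @param x An object (`risk_comparison`, `nonoverlap_comparison`,
#'   threshold-proportion list, ...).
#' @return A data frame (or named list of data frames for composite
#'   objects).
#' @export
as_report_table <- function(x) UseMethod("as_report_table")

#' @export
as_report_table.data.frame <- function(x) x

#' @export
as_report_table.risk_comparison <- function(x) {
  data.frame(
    outcome = x$label,
    events_a = x$events_a, n_a = x$n_a,
    events_b = x$events_b, n_b = x$n_b,
    rr = x$rr, ci_low = x$ci_low, ci_high = x$ci_high, p = x$p,
    stringsAsFactors = FALSE
  )
}

#' @export
as_report_table.nonoverlap_comparison <- function(x) {
  v <- x$venn
  venn <- data.frame(
    chart_a = x$chart_a, chart_b = x$chart_b,
    a_only = v$a_only, b_only = v$b_only, both = v$both,
    a_total = v$a_total, b_total = v$b_total,
    unclassifiable = v$unclassifiable,
    stringsAsFactors = FALSE
  )
  risks <- if (length(x$risks)) {
    do.call(rbind, lapply(x$risks, as_report_table))
  } else {
    data.frame(outcome = character(), events_a = integer(), n_a = integer(),
               events_b = integer(), n_b = integer(), rr = numeric(),
               ci_low = numeric(), ci_high = numeric(), p = numeric())
  }
  rownames(risks) <- NULL
  out <- list(venn = venn, risks = risks)
  if (!is.null(x$delivery_mode)) {
    m <- x$delivery_mode$counts
    out$delivery_mode <- data.frame(
      group = rep(rownames(m), each = ncol(m)),
      mode = rep(colnames(m), times = nrow(m)),
      n = as.integer(t(m)),
      chisq_p = x$delivery_mode$chisq_p,
      stringsAsFactors = FALSE
    )
  }
  out
}

#' Write a validation report
#'
#' Writes each result as tab-separated machine output (full precision) and,
#' optionally, a human-readable text rendering (display-rounded: relative
#' risks to 2 decimal places, percentages to 1). Writing then re-reading
#' the machine files reproduces the numbers exactly.
#'
#' @param results Named list of result objects (anything with an
#'   [as_report_table()] method, including nested lists produced by it).
#' @param dir Output directory (created if needed).
#' @param format `"delimited"` (machine TSV), `"text"` (human), or both.
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(results, dir, format = c("delimited", "text")) {
  format <- match.arg(format, several.ok = TRUE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(names(results)) || any(names(results) == "")) {
    stop("results must be a fully named list", call. = FALSE)
  }
  files <- character()
  flat <- list()
  for (nm in names(results)) {
    tab <- as_report_table(results[[nm]])
    if (is.data.frame(tab)) {
      flat[[nm]] <- tab
    } else {
      for (sub in names(tab)) flat[[paste(nm, sub, sep = "_")]] <- tab[[sub]]
    }
  }
  if ("delimited" %in% format) {
    for (nm in names(flat)) {
      path <- file.path(dir, paste0(nm, ".tsv"))
      df <- flat[[nm]]
      num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
      df[num] <- lapply(df[num], function(x) sprintf("%.15g", x))
      utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
      files <- c(files, path)
    }
  }
  if ("text" %in% format) {
    path <- file.path(dir, "report.txt")
    con <- file(path, "w")
    on.exit(close(con), add = TRUE)
    for (nm in names(flat)) {
      writeLines(c(paste0("== ", nm, " =="), ""), con)
      df <- flat[[nm]]
      num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
      df[num] <- lapply(df[num], function(x) round(x, 2))
      utils::capture.output(print(df, row.names = FALSE), file = con)
      writeLines("", con)
    }
    files <- c(files, path)
  }
  invisible(files)
}
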