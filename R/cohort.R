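#' Build a validation cohort, applying the inclusion rules
#'
#' Filters a one-row-per-birth data frame down to the analysable singleton
#' cohort and keeps an accounting of every exclusion. Rules applied in
#' order (each birth is counted once, under the first matching reason):
#'
#' 1. `multiple_pregnancy` flagged (column optional)
#' 2. `congenital_anomaly` flagged (column optional)
#' 3. missing fetal sex (`NA` or `"unknown"`)
#' 4. gestation missing or outside 168-300 days (24+0 to 42+6)
#' 5. birthweight missing or implausible (outside `weight_range`)
#'
#' @param df Data frame with at least `ga_days`, `sex`, `birthweight_g`;
#'   optional outcome columns (`stillbirth`, `neonatal_death`, `nicu`,
#'   `apgar5`, `delivery_mode`, `induced_for_poor_growth`,
#'   `operative_for_fetal_distress`), exclusion flags, and an `id`.
#' @param ga_range Inclusive gestation window in days (default 168-300).
#' @param weight_range Plausible birthweight bounds in grams
#'   (default 100-7000).
#' @return The retained records, class `frogs_cohort`, with derived column
#'   `perinatal_death` (`stillbirth | neonatal_death`) when outcomes are
#'   present. Attributes: `exclusion_log` (named counts by reason,
#'   reconciling with `n_input`) and `n_input`.
#' @export
as_cohort <- function(df, ga_range = c(168L, 300L),
                      weight_range = c(100, 7000)) {
  if (inherits(df, "frogs_cohort")) return(df)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("ga_days", "sex", "birthweight_g")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("cohort is missing mandatory columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  n_input <- nrow(df)
  if (!"id" %in% names(df)) df$id <- as.character(seq_len(n_input))

  flag <- function(col) {
    if (col %in% names(df)) isTRUE_vec(df[[col]]) else rep(FALSE, nrow(df))
  }
  reason <- rep(NA_character_, n_input)
  mark <- function(cond, why) {
    cond <- !is.na(cond) & cond
    reason[is.na(reason) & cond] <<- why
  }
  mark(flag("multiple_pregnancy"), "multiple_pregnancy")
  mark(flag("congenital_anomaly"), "congenital_anomaly")
  mark(is.na(df$sex) | df$sex == "unknown", "missing_sex")
  mark(is.na(df$ga_days) | df$ga_days < ga_range[1] | df$ga_days > ga_range[2],
       "gestation_out_of_range")
  mark(is.na(df$birthweight_g) | df$birthweight_g < weight_range[1] |
         df$birthweight_g > weight_range[2], "implausible_weight")

  keep <- is.na(reason)
  log <- table(factor(reason[!keep],
                      levels = c("multiple_pregnancy", "congenital_anomaly",
                                 "missing_sex", "gestation_out_of_range",
                                 "implausible_weight", "unparseable")))
  log <- stats::setNames(as.integer(log), names(log))
  pre <- attr(df, "pre_exclusions")
  if (!is.null(pre)) {
    log["unparseable"] <- log["unparseable"] + pre
    n_input <- n_input + pre
  }

  out <- df[keep, , drop = FALSE]
  out$sex <- check_sex(out$sex)
  if (all(c("stillbirth", "neonatal_death") %in% names(out))) {
    sb <- isTRUE_vec(out$stillbirth)
    nnd <- isTRUE_vec(out$neonatal_death) & !sb   # stillbirth excludes neonatal death
    out$stillbirth <- sb
    out$neonatal_death <- nnd
    out$perinatal_death <- sb | nnd
  }
  rownames(out) <- NULL
  structure(out,
            exclusion_log = log,
            n_input = n_input,
            class = c("frogs_cohort", "data.frame"))
}

#' @keywords internal
#' @noRd
isTRUE_vec <- function(x) {
  if (is.logical(x)) return(!is.na(x) & x)
  if (is.numeric(x)) return(!is.na(x) & x != 0)
  x <- tolower(as.character(x))
  !is.na(x) & x %in% c("true", "t", "1", "yes", "y")
}

#' @export
print.frogs_cohort <- function(x, ...) {
  log <- attr(x, "exclusion_log")
  cat(sprintf("<cohort> %d births kept of %d input\n", nrow(x),
              attr(x, "n_input")))
  if (sum(log) > 0) {
    for (nm in names(log)[log > 0]) cat(sprintf("  excluded %s: %d\n", nm, log[nm]))
  }
  invisible(x)
}

#' Exclusion accounting for a cohort
#' @param cohort A `frogs_cohort`.
#' @return Named integer vector of exclusion counts by reason.
#' @export
exclusion_log <- function(cohort) {
  stopifnot(inherits(cohort, "frogs_cohort"))
  attr(cohort, "exclusion_log")
}

#' Read a cohort file
#'
#' Delimited text, one birth per row, header-named columns matching the
#' cohort data dictionary (see [as_cohort()]). `ga_days` may also be given
#' in `"W+D"` notation. Rows whose gestation cannot be parsed are logged as
#' `unparseable` with their row numbers, not silently dropped; the function
#' hard-fails only on missing mandatory columns.
#'
#' @param path File path (comma- or tab-delimited, inferred from header).
#' @param ... Passed to [as_cohort()] (e.g. `weight_range`).
#' @return A `frogs_cohort`; see [exclusion_log()] for the accounting.
#' @export
read_cohort <- function(path, ...) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("ga_days", "sex", "birthweight_g")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("cohort file is missing mandatory columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  ga <- rep(NA_integer_, nrow(df))
  bad_rows <- integer()
  for (i in seq_len(nrow(df))) {
    gi <- df$ga_days[i]
    if (is.na(gi)) next
    parsed <- tryCatch(parse_ga_days(gi), error = function(e) NULL)
    if (is.null(parsed)) bad_rows <- c(bad_rows, i) else ga[i] <- parsed
  }
  df$ga_days <- ga
  if (length(bad_rows)) {
    message("rows with unparseable gestation (excluded): ",
            paste(utils::head(bad_rows, 10), collapse = ", "))
    attr_pre <- length(bad_rows)
    df <- df[-bad_rows, , drop = FALSE]
    attr(df, "pre_exclusions") <- attr_pre
  }
  if (!is.na(match("birthweight_g", names(df)))) {
    df$birthweight_g <- suppressWarnings(as.numeric(df$birthweight_g))
  }
  as_cohort(df, ...)
}

#' Write a cohort (and its exclusion side-car)
#'
#' @param cohort A `frogs_cohort` or plain data frame of births.
#' @param path Output CSV path. If the cohort carries an exclusion log, it
#'   is written alongside as `<path>.exclusions.tsv`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   quote = FALSE, na = "")
  log <- attr(cohort, "exclusion_log")
  if (!is.null(log)) {
    side <- paste0(path, ".exclusions.tsv")
    utils::write.table(
      data.frame(reason = names(log), n = as.integer(log)),
      side, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
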