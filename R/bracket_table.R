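#' Centile-bracket lookup table
#'
#' Many published charts provide only centile *brackets* per completed
#' gestational week (and possibly sex): an ordered list of centile labels
#' with their weight thresholds. A `bracket_table` stores those rows and
#' validates that, within each (week, sex) cell, thresholds and labels are
#' strictly increasing.
#'
#' @param df Data frame with columns `week` (completed gestational weeks,
#'   integer), `sex` (`"male"`, `"female"` or `"combined"`),
#'   `centile_label` (numeric centile, e.g. 3, 10, 25, ...) and
#'   `threshold_g` (grams).
#' @return The validated data frame with class `bracket_table`. The
#'   attribute `sex_specific` records whether any non-combined rows exist.
#' @export
bracket_table <- function(df) {
  need <- c("week", "sex", "centile_label", "threshold_g")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("bracket table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- df[need]
  df$week <- as.integer(df$week)
  df$sex <- as.character(df$sex)
  df$centile_label <- as.numeric(df$centile_label)
  df$threshold_g <- as.numeric(df$threshold_g)
  if (!all(df$sex %in% c("male", "female", "combined"))) {
    stop("bracket table sex must be male/female/combined", call. = FALSE)
  }
  df <- df[order(df$week, df$sex, df$centile_label), , drop = FALSE]
  cells <- split(df, interaction(df$week, df$sex, drop = TRUE))
  for (cell in cells) {
    if (any(diff(cell$centile_label) <= 0) || any(diff(cell$threshold_g) <= 0)) {
      stop(sprintf(
        "bracket table cell (week %d, %s): labels and thresholds must be strictly increasing",
        cell$week[1], cell$sex[1]), call. = FALSE)
    }
  }
  rownames(df) <- NULL
  structure(df,
            sex_specific = any(df$sex %in% c("male", "female")),
            class = c("bracket_table", "data.frame"))
}

#' Read / write a bracket table
#'
#' Plain delimited text (tab-separated) with header columns
#' `week`, `sex`, `centile_label`, `threshold_g`; validated on load.
#'
#' @param path File path.
#' @return `read_bracket_table()`: a [bracket_table()].
#' @export
read_bracket_table <- function(path) {
  if (!file.exists(path)) stop("bracket table file not found: ", path, call. = FALSE)
  bracket_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_bracket_table
#' @param table A [bracket_table()].
#' @export
write_bracket_table <- function(table, path) {
  stopifnot(inherits(table, "bracket_table"))
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build an empirical birthweight chart from a cohort
#'
#' Emulates a published birthweight chart: per completed gestational week
#' and sex, the empirical weight quantiles of the births observed at that
#' week become the centile thresholds. Because preterm cells are built from
#' the (growth-restriction-enriched) births that happened to deliver then,
#' such charts systematically understate healthy fetal weight at preterm
#' gestations -- the defect the fetal standard exists to avoid.
#'
#' @param cohort A cohort (see [as_cohort()]) or data frame with `ga_days`,
#'   `sex`, `birthweight_g`.
#' @param quantile_levels Centile labels to tabulate (default the clinical
#'   set 3, 10, 25, 50, 75, 90, 97).
#' @param min_cell Minimum births per (week, sex) cell (default 20); cells
#'   below this are flagged unusable and omitted, never interpolated.
#' @param sex_specific Build separate male/female cells (default `TRUE`) or
#'   a single combined cell per week.
#' @return A [bracket_table()]; attribute `unusable_cells` lists omitted
#'   cells with their counts. Quantiles use the linear-interpolation
#'   convention (`type = 7`).
#' @export
build_empirical_birthweight_chart <- function(cohort,
                                              quantile_levels = c(3, 10, 25, 50, 75, 90, 97),
                                              min_cell = 20,
                                              sex_specific = TRUE) {
  df <- as.data.frame(cohort)
  if (nrow(df) == 0L) stop("cohort is empty", call. = FALSE)
  stopifnot(all(c("ga_days", "sex", "birthweight_g") %in% names(df)))
  if (is.unsorted(quantile_levels, strictly = TRUE)) {
    stop("quantile_levels must be strictly increasing", call. = FALSE)
  }
  week <- df$ga_days %/% 7L
  sex <- if (sex_specific) df$sex else "combined"
  key <- split(df$birthweight_g, list(week = week, sex = sex), drop = TRUE)
  rows <- list()
  unusable <- list()
  for (nm in names(key)) {
    w <- key[[nm]]
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    wk <- as.integer(parts[1]); sx <- parts[2]
    if (length(w) < min_cell) {
      unusable[[nm]] <- data.frame(week = wk, sex = sx, n = length(w),
                                   stringsAsFactors = FALSE)
      next
    }
    q <- stats::quantile(w, probs = quantile_levels / 100, type = 7,
                         names = FALSE)
    # a degenerate cell (ties) cannot define strictly increasing brackets;
    # nudge exact ties apart by a negligible epsilon so ordering is preserved
    q <- q + cumsum(c(0, diff(q) == 0)) * 1e-9
    rows[[nm]] <- data.frame(week = wk, sex = sx,
                             centile_label = quantile_levels,
                             threshold_g = q, stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no (week, sex) cell reaches min_cell births", call. = FALSE)
  tab <- bracket_table(do.call(rbind, rows))
  attr(tab, "unusable_cells") <-
    if (length(unusable)) do.call(rbind, unusable) else
      data.frame(week = integer(), sex = character(), n = integer())
  rownames(attr(tab, "unusable_cells")) <- NULL
  tab
}

#' Classify weights into centile brackets
#'
#' Assigns each weight to the half-open bracket of its (completed week,
#' sex) cell. Thresholds are lower-inclusive of the bracket above: a weight
#' exactly at the 10th-centile threshold falls in the 10th-25th bracket and
#' is *not* SGA. Below the lowest threshold the bracket is `"<L1"`; at or
#' above the highest it is `">=Lk"`. Records whose cell is absent from the
#' table are returned `classifiable = FALSE` (to be counted, not dropped).
#' A sex-specific table classifies unknown-sex records only if it also
#' carries `"combined"` rows for that week.
#'
#' @param weight_g Weights in grams.
#' @param ga Gestational ages (days, `"W+D"`, or [gestational_age()]).
#' @param sex Fetal sex vector.
#' @param table A [bracket_table()].
#' @return Data frame with `bracket` (label string), `bracket_low`,
#'   `bracket_high` (numeric centile bounds, 0 and 100 at the extremes),
#'   `sga` (bracket entirely below 10), `lga` (bracket entirely above 90)
#'   and `classifiable`.
#' @export
bracket_classify <- function(weight_g, ga, sex, table) {
  stopifnot(inherits(table, "bracket_table"))
  days <- parse_ga_days(ga)
  n <- max(length(weight_g), length(days), length(sex))
  weight_g <- rep_len(weight_g, n)
  days <- rep_len(days, n)
  sex <- rep_len(check_sex(sex), n)
  week <- days %/% 7L

  tab_key <- paste(table$week, table$sex, sep = "|")
  cells <- split(seq_len(nrow(table)), tab_key)

  bracket <- rep(NA_character_, n)
  lo <- rep(NA_real_, n)
  hi <- rep(NA_real_, n)
  classifiable <- rep(FALSE, n)

  sex_cell <- ifelse(sex == "unknown", "combined", sex)
  want <- paste(week, sex_cell, sep = "|")
  fallback <- paste(week, "combined", sep = "|")
  use <- ifelse(want %in% names(cells), want,
                ifelse(fallback %in% names(cells), fallback, NA))

  for (nm in unique(use[!is.na(use)])) {
    idx <- which(!is.na(use) & use == nm)
    cell <- table[cells[[nm]], , drop = FALSE]
    labels <- cell$centile_label
    thr <- cell$threshold_g
    pos <- findInterval(weight_g[idx], thr)   # t[pos] <= w < t[pos+1]
    k <- length(thr)
    bounds_low <- c(0, labels)
    bounds_high <- c(labels, 100)
    lab <- character(length(pos))
    lab[pos == 0] <- paste0("<", labels[1])
    lab[pos == k] <- paste0(">=", labels[k])
    mid <- pos > 0 & pos < k
    lab[mid] <- paste0(labels[pos[mid]], "-", labels[pos[mid] + 1])
    bracket[idx] <- lab
    lo[idx] <- bounds_low[pos + 1]
    hi[idx] <- bounds_high[pos + 1]
    classifiable[idx] <- TRUE
  }
  data.frame(
    bracket = bracket, bracket_low = lo, bracket_high = hi,
    sga = !is.na(hi) & hi <= 10,
    lga = !is.na(lo) & lo >= 90,
    classifiable = classifiable,
    stringsAsFactors = FALSE
  )
}
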