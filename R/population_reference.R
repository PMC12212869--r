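#' @keywords internal
#' @noRd
.HADLOCK_ANCHOR_G <- 3705

#' Hadlock term anchor weight
#'
#' The mean birthweight (grams) at the mid-point of week 40 in the original
#' Hadlock ultrasound cohort. All proportionality ratios are taken against
#' this fixed constant; it is not configurable.
#'
#' @return 3705 (grams).
#' @export
hadlock_anchor <- function() .HADLOCK_ANCHOR_G

#' Population reference for a region-specific growth standard
#'
#' Bundles the term (40+0 to 40+6) mean birthweights and standard deviation
#' for the population a chart is to represent. The defaults are the
#' Australian national values (singleton births 2004-2013): combined mean
#' 3573 g, male 3641 g, female 3504 g, SD 421 g. The coefficient of
#' variation `cv = sd_term_g / mean_combined_g` (default 421/3573, which
#' rounds to 11.8%) is carried at full precision and applied to all sexes.
#'
#' @param mean_combined_g Term mean birthweight, both sexes combined (g).
#' @param mean_male_g Term mean birthweight, males (g).
#' @param mean_female_g Term mean birthweight, females (g).
#' @param sd_term_g Term standard deviation of birthweight (g).
#' @return An object of class `population_reference`.
#' @examples
#' ref <- population_reference()
#' round(100 * ref$cv, 1)  # 11.8
#' @export
population_reference <- function(mean_combined_g = 3573,
                                 mean_male_g = 3641,
                                 mean_female_g = 3504,
                                 sd_term_g = 421) {
  vals <- c(mean_combined_g = mean_combined_g, mean_male_g = mean_male_g,
            mean_female_g = mean_female_g, sd_term_g = sd_term_g)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all reference means and the term SD must be positive and finite",
         call. = FALSE)
  }
  cv <- sd_term_g / mean_combined_g
  if (cv <= 0 || cv >= 1) {
    stop("coefficient of variation sd_term_g/mean_combined_g must lie in (0, 1)",
         call. = FALSE)
  }
  structure(
    list(
      mean_combined_g = as.numeric(mean_combined_g),
      mean_male_g = as.numeric(mean_male_g),
      mean_female_g = as.numeric(mean_female_g),
      sd_term_g = as.numeric(sd_term_g),
      cv = cv,
      hadlock_anchor_g = .HADLOCK_ANCHOR_G
    ),
    class = "population_reference"
  )
}

#' Default (Australian national) population reference
#'
#' @return `population_reference()` with its default values.
#' @export
default_reference <- function() population_reference()

#' @export
print.population_reference <- function(x, ...) {
  cat("<population_reference>\n")
  cat(sprintf("  term mean (combined/male/female): %g / %g / %g g\n",
              x$mean_combined_g, x$mean_male_g, x$mean_female_g))
  cat(sprintf("  term SD: %g g (cv %.1f%% of combined mean)\n",
              x$sd_term_g, 100 * x$cv))
  cat(sprintf("  Hadlock anchor: %g g\n", x$hadlock_anchor_g))
  invisible(x)
}

#' Read a population reference from a key/value config file
#'
#' The file holds one `key: value` pair per line (DCF format) with keys
#' `mean_combined_g`, `mean_male_g`, `mean_female_g`, `sd_term_g`. Missing
#' keys fall back to the defaults.
#'
#' @param path Path to the config file.
#' @return A `population_reference`.
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) stop("reference file not found: ", path, call. = FALSE)
  dcf <- read.dcf(path)
  get <- function(key, default) {
    if (key %in% colnames(dcf)) as.numeric(dcf[1L, key]) else default
  }
  population_reference(
    mean_combined_g = get("mean_combined_g", 3573),
    mean_male_g = get("mean_male_g", 3641),
    mean_female_g = get("mean_female_g", 3504),
    sd_term_g = get("sd_term_g", 421)
  )
}

#' Write a population reference to a key/value config file
#'
#' @param ref A `population_reference`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path) {
  stopifnot(inherits(ref, "population_reference"))
  m <- matrix(
    c(ref$mean_combined_g, ref$mean_male_g, ref$mean_female_g, ref$sd_term_g),
    nrow = 1,
    dimnames = list(NULL, c("mean_combined_g", "mean_male_g",
                            "mean_female_g", "sd_term_g"))
  )
  write.dcf(m, path)
  invisible(path)
}

#' @keywords internal
#' @noRd
check_sex <- function(sex, n = NULL) {
  sex <- as.character(sex)
  sex[is.na(sex)] <- "unknown"
  ok <- sex %in% c("male", "female", "unknown")
  if (!all(ok)) {
    stop("sex must be one of \"male\", \"female\", \"unknown\"; got: ",
         paste(unique(sex[!ok]), collapse = ", "), call. = FALSE)
  }
  if (!is.null(n) && length(sex) == 1L) sex <- rep(sex, n)
  sex
}
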