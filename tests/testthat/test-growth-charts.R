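# expected values below marked "frozen" were computed from an independent
# high-precision evaluation of the printed closed forms (see comments)

test_that("Hadlock curve reproduces its anchor and oracle values", {
  expect_identical(round(hadlock_weight(40.5)), 3705)
  # frozen: exp(0.578 + 0.332*g - 0.00354*g^2) evaluated independently
  expect_equal(hadlock_weight(40), 3619.170012, tolerance = 1e-8)
  expect_equal(hadlock_weight(28), 1210.319920, tolerance = 1e-8)
  expect_error(hadlock_weight(19.9), "20-44")
  expect_error(hadlock_weight(44.1), "20-44")
})

test_that("proportionality ratio follows the worked example and sex rules", {
  expect_equal(round(proportionality_ratio(
    population_reference(mean_combined_g = 3500)), 2), 0.94)
  expect_equal(proportionality_ratio(
    population_reference(3705, 3705, 3705, 421)), 1)
  ref <- default_reference()
  expect_equal(proportionality_ratio(ref), 3573 / 3705)          # ~0.9644
  expect_equal(proportionality_ratio(ref, "male"), 3641 / 3705)
  expect_equal(proportionality_ratio(ref, "female"), 3504 / 3705)
  # unknown falls back to combined
  expect_equal(proportionality_ratio(ref, "unknown"),
               proportionality_ratio(ref))
})

test_that("frogs_mean rescales the Hadlock curve and is strictly monotone", {
  ref <- default_reference()
  # frozen: 3619.170011716 * 3573/3705
  expect_equal(frogs_mean(280, ref), 3490.227922, tolerance = 1e-8)
  # the anchor identity: with the reference mean at the anchor, the curve
  # is Hadlock's own (ratio exactly 1 at the mid-point of week 40)
  anchor_ref <- population_reference(3705, 3705, 3705, 421)
  expect_identical(proportionality_ratio(anchor_ref) * hadlock_weight(40.5),
                   hadlock_weight(40.5))
  # proportionality: doubling the term mean doubles every gestation
  ref2 <- population_reference(2 * 3573, 2 * 3641, 2 * 3504, 2 * 421)
  days <- 140:307
  expect_equal(frogs_mean(days, ref2), 2 * frogs_mean(days, ref))
  for (sx in c("male", "female", "unknown")) {
    expect_true(all(diff(frogs_mean(days, ref, sx)) > 0))
  }
})

test_that("frogs_sd is one cv applied to every sex and gestation", {
  ref <- default_reference()
  expect_equal(round(100 * ref$cv, 1), 11.8)
  expect_equal(frogs_sd(280, ref), 411.247119, tolerance = 1e-6)  # frozen cv*3490.2279
  days <- c(168L, 200L, 250L, 300L)
  for (sx in c("male", "female", "unknown")) {
    expect_equal(frogs_sd(days, ref, sx), ref$cv * frogs_mean(days, ref, sx))
  }
})

test_that("weight_to_centile matches the normal model and is monotone", {
  ref <- default_reference()
  mu <- frogs_mean(280, ref, "male")
  sigma <- frogs_sd(280, ref, "male")
  expect_equal(weight_to_centile(mu, 280, "male", ref)$centile, 50)
  expect_equal(weight_to_centile(mu + 1.2816 * sigma, 280, "male", ref)$centile,
               90.0, tolerance = 1e-3)
  # frozen: 100*pnorm(-2) evaluated independently = 2.2750132
  expect_equal(weight_to_centile(mu - 2 * sigma, 280, "male", ref)$centile,
               2.2750132, tolerance = 1e-6)
  w <- seq(1500, 5500, by = 100)
  expect_true(all(diff(weight_to_centile(w, 280, "male", ref)$centile) > 0))
  expect_error(weight_to_centile(-1, 280), "positive")
  res <- weight_to_centile(3000, 280, "unknown", ref)
  expect_false(res$sex_adjusted)
})

test_that("centile_to_weight inverts weight_to_centile to 1e-9 relative error", {
  ref <- default_reference()
  expect_equal(centile_to_weight(50, 280, "unknown", ref), frogs_mean(280, ref))
  # frozen: mu + qnorm(0.9)*sigma at 280 d combined = 3490.2279 + 1.2815516*411.2471
  expect_equal(centile_to_weight(90, 280, "unknown", ref), 4017.262311,
               tolerance = 1e-6)
  set.seed(SUITE_SEED)
  cent <- runif(200, 0.1, 99.9)
  days <- sample(140:307, 200, replace = TRUE)
  sex <- sample(c("male", "female", "unknown"), 200, replace = TRUE)
  w <- centile_to_weight(cent, days, sex, ref)
  back <- weight_to_centile(w, days, sex, ref)$centile
  expect_equal(back, cent, tolerance = 1e-9)
  expect_error(centile_to_weight(0, 280), "strictly between")
  expect_error(centile_to_weight(100, 280), "strictly between")
})

test_that("estimate_range brackets the point centile and collapses at zero error", {
  ref <- default_reference()
  mu <- frogs_mean(275, ref, "female")
  r0 <- estimate_range(mu, 275, "female", ref, error_fraction = 0)
  expect_equal(r0$low, 50)
  expect_equal(r0$high, 50)
  # frozen: 100*pnorm(-/+ 0.1/(421/3573)) = 19.80259 / 80.19741
  r <- estimate_range(mu, 275, "female", ref)
  expect_equal(r$low, 100 * pnorm(-0.1 * 3573 / 421), tolerance = 1e-9)
  expect_equal(r$low, 19.8026, tolerance = 1e-4)
  expect_equal(r$high, 80.1974, tolerance = 1e-4)
  # bracketing holds everywhere; strictness holds away from the saturated
  # tails (a weight many sigma out maps to a centile of exactly 0 or 100
  # in double precision, where low == centile == high)
  set.seed(SUITE_SEED + 1)
  days <- sample(168:300, 100, replace = TRUE)
  z <- runif(100, -3.5, 3.5)
  w <- frogs_mean(days, ref) * (1 + ref$cv * z)
  res <- weight_to_centile(w, days, "unknown", ref)
  expect_true(all(res$range_low_centile < res$centile))
  expect_true(all(res$centile < res$range_high_centile))
  far <- weight_to_centile(c(500, 6500), 300, "unknown", ref)
  expect_true(all(far$range_low_centile <= far$centile))
  expect_true(all(far$centile <= far$range_high_centile))
  expect_error(estimate_range(3000, 280, error_fraction = 1.2), "error_fraction")
})

test_that("week-resolution chart agrees mid-week and diverges at the edges", {
  ref <- default_reference()
  # at day 3/4 of the week the week chart evaluates essentially at the birth
  # day, so combined-sex centiles agree closely
  for (d in c(38L * 7L + 3L, 38L * 7L + 4L, 30L * 7L + 3L)) {
    w <- centile_to_weight(30, d, "unknown", ref)
    expect_equal(global_week_centile(w, d, ref)$centile, 30, tolerance = 0.5)
  }
  # sex blindness: a male at his sex-specific 10th centile is scored against
  # the lower combined mean, so the unisex chart places him above the 10th;
  # a female at hers falls below it (this is why unisex charts under-
  # represent males among SGA)
  wm <- centile_to_weight(10, 276, "male", ref)
  expect_gt(global_week_centile(wm, 276, ref)$centile, 10)
  wf <- centile_to_weight(10, 276, "female", ref)
  expect_lt(global_week_centile(wf, 276, ref)$centile, 10)
  # week-constant thresholds: a fetus at the true (day-exact) 10th centile
  # scores lower when born on day 0 than on day 6 of the same week, because
  # the week chart judges both against the mid-week reference
  w0 <- centile_to_weight(10, 38L * 7L + 0L, "unknown", ref)
  w6 <- centile_to_weight(10, 38L * 7L + 6L, "unknown", ref)
  expect_lt(global_week_centile(w0, 38L * 7L + 0L, ref)$centile,
            global_week_centile(w6, 38L * 7L + 6L, ref)$centile)
})

test_that("centiles are calibrated: simulated fractions match p at 3/10/50/90/97", {
  ref <- default_reference()
  co <- null_cohort(100000L)
  cc <- classify_cohort(co, frogs_chart(ref))
  n <- nrow(cc)
  for (p in c(3, 10, 50, 90, 97)) {
    frac <- mean(cc$centile < p)
    band <- 3 * sqrt(p / 100 * (1 - p / 100) / n)
    expect_lt(abs(frac - p / 100), band, label = sprintf("p=%g frac=%g", p, frac))
  }
})

test_that("day chart is trend-free across the gestational week; week chart is not", {
  co <- null_cohort(100000L)
  cc_day <- classify_cohort(co, frogs_chart())
  cc_week <- classify_cohort(co, global_week_chart())
  day <- co$ga_days %% 7L
  # day-resolution: no day-of-week trend in SGA (logistic slope z-score small)
  fit <- glm(cc_day$sga ~ day, family = binomial)
  expect_lt(abs(coef(summary(fit))["day", "z value"]), 3)
  # week-resolution: strong negative trend, monotone decrease, ratio > 1.5
  dow <- sga_by_day_of_week(cc_week)
  expect_true(all(diff(dow$fraction) < 0))
  expect_gt(dow$day0_day6_ratio, 1.5)
})
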