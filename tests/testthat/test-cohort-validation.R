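test_that("classify_cohort flags SGA/LGA and handles edge cohorts", {
  ref <- default_reference()
  co <- null_cohort(50000L)
  cc <- classify_cohort(co, frogs_chart(ref))
  expect_equal(mean(cc$sga), 0.10, tolerance = 0.05)
  # a record at exactly the 50th-centile weight is neither SGA nor LGA
  w50 <- centile_to_weight(50, 280, "male", ref)
  one <- as_cohort(data.frame(id = "a", ga_days = 280L, sex = "male",
                              birthweight_g = w50))
  c1 <- classify_cohort(one, frogs_chart(ref))
  expect_false(c1$sga); expect_false(c1$lga)
  # empty cohort
  empty <- as_cohort(data.frame(id = character(), ga_days = integer(),
                                sex = character(), birthweight_g = numeric()))
  ce <- classify_cohort(empty, frogs_chart(ref))
  expect_identical(nrow(ce), 0L)
  expect_identical(threshold_proportions(ce)$n_classifiable, 0L)
})

test_that("threshold proportions partition and reflect sex-specificity", {
  co <- null_cohort(50000L)
  tp <- threshold_proportions(classify_cohort(co, frogs_chart()))
  expect_identical(tp$n_classifiable, nrow(co))
  expect_equal(tp$table$percent / 100, c(0.03, 0.10, 0.50, 0.10, 0.03),
               tolerance = 0.12)
  expect_equal(tp$male_share_sga, 0.5, tolerance = 0.06)
  # the unisex week chart under-represents males among SGA when the male
  # mean exceeds the female mean
  tpw <- threshold_proportions(classify_cohort(co, global_week_chart()))
  expect_lt(tpw$male_share_sga, 0.45)
})

test_that("SGA by day-of-week reports absent days as NA, not zero", {
  df <- data.frame(id = as.character(1:50), ga_days = 38L * 7L + 3L,
                   sex = "male", birthweight_g = seq(2000, 4500, length.out = 50),
                   stringsAsFactors = FALSE)
  cc <- classify_cohort(as_cohort(df), frogs_chart())
  dow <- sga_by_day_of_week(cc)
  expect_false(is.na(dow$fraction["day3"]))
  expect_true(all(is.na(dow$fraction[c(1, 2, 3, 5, 6, 7)])))
  expect_identical(sum(dow$n), 50L)
})

test_that("centile histograms are uniform under the null and refused for brackets", {
  co <- null_cohort(50000L)
  cc <- classify_cohort(co, frogs_chart())
  h <- centile_histogram(cc, bin_width = 10)
  expect_identical(sum(h$counts), nrow(co))
  expect_equal(h$counts / nrow(co), rep(0.1, 10), tolerance = 0.06)
  expect_equal(unname(h$summary["mean"]), 50, tolerance = 0.02)
  expect_error(centile_histogram(cc, bin_width = 7), "divisor")
  emp <- bracket_chart(build_empirical_birthweight_chart(co))
  expect_error(centile_histogram(classify_cohort(co, emp)),
               "brackets only")
})

test_that("relative_risk agrees with an independent 2x2 oracle to 10 digits", {
  # oracle: direct arithmetic written independently of the implementation
  oracle <- function(ea, na, eb, nb, conf = 0.95) {
    risk_ref <- ea / na
    risk_exp <- eb / nb
    est <- risk_exp / risk_ref
    zq <- qnorm((1 + conf) / 2)
    selog <- sqrt(1 / eb - 1 / nb + 1 / ea - 1 / na)
    pool <- (ea + eb) / (na + nb)
    zstat <- (risk_exp - risk_ref) / sqrt(pool * (1 - pool) * (1 / na + 1 / nb))
    list(rr = est,
         lo = est * exp(-zq * selog), hi = est * exp(zq * selog),
         p = 2 * pnorm(abs(zstat), lower.tail = FALSE))
  }
  set.seed(SUITE_SEED)
  for (i in 1:50) {
    na <- sample(5:400, 1); nb <- sample(5:400, 1)
    ea <- sample(1:na, 1); eb <- sample(1:nb, 1)
    got <- relative_risk(ea, na, eb, nb)
    want <- oracle(ea, na, eb, nb)
    expect_equal(got$rr, want$rr, tolerance = 1e-10)
    expect_equal(got$ci_low, want$lo, tolerance = 1e-10)
    expect_equal(got$ci_high, want$hi, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
})

test_that("relative_risk handles symmetry and degenerate counts explicitly", {
  expect_equal(relative_risk(10, 100, 10, 100)$rr, 1)
  r0 <- relative_risk(0, 50, 5, 50)
  expect_identical(r0$rr, Inf)
  expect_false(r0$estimable)
  expect_true(is.na(r0$ci_low))
  r00 <- relative_risk(0, 50, 0, 50)
  expect_true(is.na(r00$rr))
  rb0 <- relative_risk(5, 50, 0, 50)
  expect_identical(rb0$rr, 0)
  expect_false(rb0$estimable)
  expect_error(relative_risk(5, 0, 1, 10), "positive")
  expect_error(relative_risk(11, 10, 1, 10), "exceed")
  expect_error(relative_risk(-1, 10, 1, 10), "non-negative")
})

test_that("wilson_ci matches the closed form, stays in [0,1], and covers ~95%", {
  w <- wilson_ci(5, 10)
  expect_equal(w$wilson_low, 0.2365931, tolerance = 1e-6)   # frozen closed form
  expect_equal(w$wilson_high, 0.7634069, tolerance = 1e-6)
  expect_identical(wilson_ci(0, 10)$wilson_low, 0)
  expect_identical(wilson_ci(10, 10)$wilson_high, 1)
  for (k in c(0, 1, 7, 10)) {
    ww <- wilson_ci(k, 10)
    expect_true(ww$wilson_low <= ww$p_hat && ww$p_hat <= ww$wilson_high)
    expect_true(ww$wilson_low >= 0 && ww$wilson_high <= 1)
  }
  # interval width shrinks with n at fixed p
  widths <- vapply(c(10, 50, 250), function(n) {
    ww <- wilson_ci(round(0.2 * n), n); ww$wilson_high - ww$wilson_low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  # coverage by exact binomial enumeration: at any single (n, p) the true
  # coverage oscillates around the nominal level (97.0% at n = 50, p = 0.1);
  # averaged over p it sits at ~95%
  exact_cov <- function(n, p) {
    covered <- vapply(0:n, function(k) {
      ww <- wilson_ci(k, n); ww$wilson_low <= p && p <= ww$wilson_high
    }, logical(1))
    sum(dbinom(0:n, n, p) * covered)
  }
  expect_gt(exact_cov(50, 0.1), 0.93)
  expect_lt(exact_cov(50, 0.1), 0.98)
  expect_equal(mean(vapply(seq(0.05, 0.5, by = 0.01),
                           function(p) exact_cov(50, p), numeric(1))),
               0.95, tolerance = 0.01)
  expect_error(wilson_ci(5, 0), "n > 0")
})

test_that("SGA vs non-SGA relative risk recovers null and signal", {
  co_null <- null_cohort(100000L)
  cc <- classify_cohort(co_null, frogs_chart())
  rr_null <- sga_vs_nonsga_rr(cc, "stillbirth")
  expect_true(rr_null$ci_low < 1 && 1 < rr_null$ci_high)
  co_sig <- generate_cohort(simulation_params(60000, seed = SUITE_SEED))
  rr_sig <- sga_vs_nonsga_rr(classify_cohort(co_sig, frogs_chart()),
                             "stillbirth")
  expect_gt(rr_sig$rr, 1)
  expect_gt(rr_sig$ci_low, 1)
  expect_error(sga_vs_nonsga_rr(cc, "no_such_outcome"), "not present")
})

test_that("non-overlap comparison partitions correctly and matches printed tables", {
  co <- generate_cohort(simulation_params(40000, seed = SUITE_SEED))
  cmp <- nonoverlap_compare(co, global_week_chart(), frogs_chart(),
                            outcomes = c("stillbirth", "apgar5_lt7"))
  v <- cmp$venn
  expect_identical(v$a_only + v$both, v$a_total)
  expect_identical(v$b_only + v$both, v$b_total)
  # identical charts: both non-overlap sets empty, nothing estimable
  same <- nonoverlap_compare(co, frogs_chart(), frogs_chart(), "stillbirth")
  expect_identical(same$venn$a_only, 0L + 0L)
  expect_identical(same$venn$b_only, 0L + 0L)
  expect_length(same$risks, 0)
  expect_true("stillbirth" %in% same$not_estimable)
  # births flagged only by the day-resolution sex-specific chart are
  # enriched for males (the unisex chart misses small males) and for
  # late-in-week deliveries (the week chart's constant threshold
  # over-diagnoses day-0 births, so its misses concentrate late in the week)
  cc_a <- classify_cohort(co, global_week_chart())
  cc_b <- classify_cohort(co, frogs_chart())
  b_only <- cc_b$sga & !cc_a$sga
  a_only <- cc_a$sga & !cc_b$sga
  expect_gt(mean(co$sex[b_only] == "male"), mean(co$sex[a_only] == "male"))
  expect_gt(mean(co$ga_days[b_only] %% 7L), mean(co$ga_days[a_only] %% 7L))
  # delivery-mode frequency comparison is present with a chi-square p
  expect_false(is.null(cmp$delivery_mode))
  expect_true(is.finite(cmp$delivery_mode$chisq_p))
})

test_that("non-overlap RRs are null when outcomes are independent of size", {
  co <- null_cohort(100000L)
  cmp <- nonoverlap_compare(co, global_week_chart(), frogs_chart(),
                            outcomes = c("nicu", "apgar5_lt7",
                                         "operative_for_fetal_distress"))
  for (r in cmp$risks) {
    if (r$estimable) {
      expect_true(r$ci_low < 1 && 1 < r$ci_high,
                  label = sprintf("%s rr=%.2f", r$label, r$rr))
    }
  }
})
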