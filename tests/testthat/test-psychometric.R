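test_that("comparison levels scale a fixed 0.2-3.0 geometric ladder", {
  lv <- comparison_levels(1)
  expect_length(lv, 7)
  expect_equal(lv[1], 0.2)
  expect_equal(lv[7], 3.0)
  # constant ratio 15^(1/6)
  expect_equal(diff(log(lv)), rep(log(15) / 6, 6))
  expect_equal(comparison_levels(0.05), 0.05 * lv)
  expect_error(comparison_levels(0), "positive|> 0")
})

test_that("the psychometric function hits chance, 75% at threshold, and the ceiling", {
  p0 <- psychometric_params(0.04, 0.04, 0)
  expect_equal(psych_fun(0, p0), 0.5)
  expect_equal(psych_fun(0.04, p0), 0.75)
  p2 <- psychometric_params(0.04, 0.04, 0.02)
  expect_equal(psych_fun(1e3, p2), 0.98, tolerance = 1e-9)
  # width parameterization: inner function spans 0.05..0.95 over `width`
  inner <- function(d, p) (psych_fun(d, p) - 0.5) / 0.5
  x95 <- uniroot(function(d) inner(d, p0) - 0.95, c(1e-6, 1))$root
  x05 <- uniroot(function(d) inner(d, p0) - 0.05, c(1e-6, 1))$root
  expect_equal(x95 - x05, 0.04, tolerance = 1e-3)
  # non-decreasing for valid params
  d <- seq(0, 0.5, length.out = 300)
  expect_true(all(diff(psych_fun(d, p2)) >= -1e-12))
  expect_error(psychometric_params(0.04, 0.04, 0.6), "lapse")
})

test_that("the reported 75% point accounts for the lapse rate", {
  p0 <- psychometric_params(0.04, 0.04, 0)
  expect_equal(threshold_75(p0), 0.04)
  p2 <- psychometric_params(0.04, 0.04, 0.1)
  t75 <- threshold_75(p2)
  expect_gt(t75, 0.04)
  expect_equal(psych_fun(t75, p2), 0.75, tolerance = 1e-9)
})

test_that("simulated constant-stimuli counts match the design and observer", {
  des <- cs_design(4, comparison_levels(0.04))
  sure <- make_observer(1e-9, width = 1e-9)   # p ~ 1 at all levels
  counts <- simulate_cs_run(sure, des, seed = 1)
  expect_equal(counts$n_correct, rep(30, 7))
  guesser <- make_observer(10, width = 50)    # p ~ 0.5 at all levels
  counts2 <- simulate_cs_run(guesser, des, seed = 2)
  expect_equal(mean(counts2$n_correct), 15, tolerance = 0.25)
  expect_identical(simulate_cs_run(sure, des, seed = 3),
                   simulate_cs_run(sure, des, seed = 3))
  expect_error(cs_design(4, 1:5), "7 levels")
})

test_that("fitting recovers simulated parameters and flags degenerate data", {
  truth <- make_observer(0.04, width = 0.04, lapse = 0.02)
  des <- cs_design(4, comparison_levels(0.04))
  ths <- vapply(1:60, function(i) {
    fit_psychometric(simulate_cs_run(truth, des, seed = i), des)$threshold_75
  }, numeric(1))
  expect_equal(median(ths), threshold_75(truth$params), tolerance = 0.1)
  # all-correct data: threshold collapses below the lowest level, flagged
  ac <- data.frame(level = des$levels, n_correct = 30, n_total = 30)
  f <- fit_psychometric(ac, des)
  expect_lt(f$params$threshold, min(des$levels))
  expect_true("all_correct" %in% f$boundary)
  # simulated lapse 0 -> fitted lapse near 0
  f0 <- fit_psychometric(
    simulate_cs_run(make_observer(0.04, 0.04, 0), des, seed = 2), des)
  expect_lt(f0$params$lapse, 0.02)
  expect_error(fit_psychometric(data.frame(level = 1, n_correct = 1,
                                           n_total = 2)), "2 distinct")
})

test_that("round-trip fit covers the generating threshold", {
  truth <- make_observer(0.04, width = 0.04, lapse = 0.02)
  des <- cs_design(4, comparison_levels(0.04))
  covered <- vapply(1:30, function(i) {
    f <- fit_psychometric(simulate_cs_run(truth, des, seed = 400 + i), des)
    f$ci["lower", "threshold"] <= 0.04 && f$ci["upper", "threshold"] >= 0.04
  }, logical(1))
  expect_gt(mean(covered), 0.75)
})

test_that("bootstrap goodness-of-fit passes well-specified data and rejects gross misfit", {
  truth <- make_observer(0.04, width = 0.04, lapse = 0.02)
  des <- cs_design(4, comparison_levels(0.04))
  counts <- simulate_cs_run(truth, des, seed = 5)
  fit <- fit_psychometric(counts, des)
  gof <- goodness_of_fit(fit, counts, n_boot = 500, seed = 1)
  expect_true(gof$pass)
  expect_gte(gof$observed_deviance, 0)
  # grossly non-monotone fake data
  bad <- data.frame(level = des$levels,
                    n_correct = c(30, 2, 28, 1, 30, 3, 29), n_total = 30)
  fbad <- fit_psychometric(bad, des)
  gbad <- goodness_of_fit(fbad, bad, n_boot = 500, seed = 2)
  expect_false(gbad$pass)
  # saturated (perfect) agreement has deviance 0
  perf <- data.frame(level = des$levels,
                     n_correct = round(30 * psych_fun(des$levels, fit$params)),
                     n_total = 30)
  expect_equal(
    ratesync:::binom_deviance(perf$n_correct, perf$n_total,
                              perf$n_correct / perf$n_total), 0)
  expect_warning(goodness_of_fit(fit, counts, n_boot = 50, seed = 1),
                 "unstable")
})
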