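test_that("generative spec validates its parameters", {
  expect_error(generative_spec(mu_high = -0.01, mu_low = -0.01), "mu_high")
  expect_error(generative_spec(onset_high = 1), "onset_high")
  expect_error(generative_spec(onset_low = 9), "onset_low")
  expect_error(generative_spec("null", beta_high = 0.01, beta_low = 0.01),
               "beta")
  expect_error(generative_spec("increase", mu_high = 0.05, mu_low = 0.09),
               "equal")
  expect_error(generative_spec("increase", beta_high = 0.01, beta_low = 0.02),
               "equal")
  # slope family allows distinct slopes but not distinct baselines
  s <- generative_spec("increase_group_slope", mu_high = 0.05, mu_low = 0.05,
                       beta_high = 0.01, beta_low = 0.03)
  expect_s3_class(s, "generative_spec")
})

test_that("degenerate variance collapses thresholds onto the group medians", {
  spec <- generative_spec("null", mu_high = 0.05, mu_low = 0.05,
                          beta_high = 0, beta_low = 0, onset_high = NA,
                          onset_low = NA, sigma2 = 1e-12,
                          n_high = 5, n_low = 5)
  tab <- draw_threshold_dataset(spec, seed = 1)
  expect_equal(nrow(tab), 10 * 8)
  expect_equal(tab$threshold, rep(0.05, 80), tolerance = 1e-4)
})

test_that("large-sample cell medians converge to mu + x * beta", {
  # one cell examined at scale: low group, rate 8, onset_low = 4
  spec <- generative_spec("increase", mu_high = 0.0448, beta_high = 0.0144,
                          onset_high = 6, onset_low = 4, sigma2 = 0.05,
                          n_high = 0, n_low = 12500)
  tab <- draw_threshold_dataset(spec, seed = 3)
  med8 <- median(tab$threshold[tab$rate_index == 8])
  expect_equal(med8, 0.0448 + 5 * 0.0144, tolerance = 0.01)
  med1 <- median(tab$threshold[tab$rate_index == 1])
  expect_equal(med1, 0.0448, tolerance = 0.01)
})

test_that("cohort draws are reproducible under a seed", {
  spec <- generative_spec(n_high = 4, n_low = 3)
  expect_identical(draw_threshold_dataset(spec, seed = 11),
                   draw_threshold_dataset(spec, seed = 11))
  t2 <- draw_threshold_dataset(spec, seed = 12)
  expect_false(identical(draw_threshold_dataset(spec, seed = 11)$threshold,
                         t2$threshold))
})

test_that("observer hits chance, the defining point, and the lapse ceiling", {
  obs <- make_observer(0.05, width = 0.05, lapse = 0)
  expect_equal(observer_p_correct(obs, 0), 0.5)
  expect_equal(observer_p_correct(obs, 0.05), 0.75)
  obs2 <- make_observer(0.05, width = 0.05, lapse = 0.02)
  expect_equal(observer_p_correct(obs2, 10), 0.98, tolerance = 1e-6)
  # monotone non-decreasing in d, bounded in [0.5, 1 - lapse]
  d <- seq(0, 0.5, length.out = 200)
  p <- observer_p_correct(obs2, d)
  expect_true(all(diff(p) >= -1e-12))
  expect_true(all(p >= 0.5 - 1e-12 & p <= 0.98 + 1e-12))
  expect_error(make_observer(0.05, width = 0), "width")
})

test_that("tone sequences have the prescribed onset arithmetic", {
  w <- render_tone_sequence(4, 5)
  expect_equal(attr(w, "duration_s"), 4 * 0.25 + 0.015)
  expect_equal(max(abs(w)), 1)
  w7 <- render_tone_sequence(15, 7)
  expect_equal(attr(w7, "duration_s"), 6 / 15 + 0.015)
  expect_error(render_tone_sequence(80, 5), "overlap")
})

test_that("envelope pairs lock perfectly at zero jitter and degrade monotonically", {
  pair <- synth_sync_pair(30, 4.5, 0, seed = 1)
  expect_equal(length(pair$stimulus_envelope), length(pair$produced_envelope))
  expect_true(all(pair$stimulus_envelope >= 0))
  res0 <- windowed_plv(phase_series(pair$stimulus_envelope, pair$sample_rate),
                       phase_series(pair$produced_envelope, pair$sample_rate))
  expect_equal(res0$mean_plv, 1, tolerance = 1e-6)
  mean_plv_at <- function(j) {
    mean(sapply(1:3, function(s) {
      p <- synth_sync_pair(40, 4.5, j, seed = 100 + s)
      windowed_plv(phase_series(p$stimulus_envelope, p$sample_rate),
                   phase_series(p$produced_envelope, p$sample_rate))$mean_plv
    }))
  }
  expect_gt(mean_plv_at(0.3), mean_plv_at(1.5))
  expect_warning(synth_sync_pair(20, 8, 0, seed = 1), "band")
  expect_error(synth_sync_pair(10, 4.5, 0, seed = 1), "duration")
})
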