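test_that("the rate grid is 8 rates linearly spaced from 4 to 15 Hz", {
  g <- rate_grid()
  expect_equal(round(g$rates, 2),
               c(4, 5.57, 7.14, 8.71, 10.29, 11.86, 13.43, 15))
  expect_equal(unique(round(diff(g$rates), 4)), round(11 / 7, 4))
})

test_that("onset indicators count grid steps from the onset, first rate always zero", {
  expect_equal(indicator_vector(2), 0:7)
  expect_equal(indicator_vector(8), c(rep(0L, 7), 1L))
  expect_equal(indicator_vector(5), c(0, 0, 0, 0, 1, 2, 3, 4))
  expect_true(all(vapply(2:8, function(o) indicator_vector(o)[1] == 0,
                         logical(1))))
  expect_error(indicator_vector(1), "2..8")
  expect_error(indicator_vector(9), "2..8")
})

test_that("the battery enumerates 149 models in the documented order", {
  models <- enumerate_models()
  expect_length(models, 149)
  fams <- vapply(models, `[[`, character(1), "family")
  expect_equal(sum(fams == "increase"), 49)
  expect_equal(sum(fams == "increase_group_baseline"), 49)
  expect_equal(sum(fams == "increase_group_slope"), 49)
  expect_equal(models[[1]]$family, "null")
  expect_equal(models[[2]]$family, "group_baseline")
  expect_equal(length(model_parameters(models[[1]])), 2)
  expect_equal(length(model_parameters(models[[2]])), 3)
  expect_equal(length(model_parameters(models[[52]])), 4)
  expect_equal(length(model_parameters(models[[101]])), 4)
  # M33: increase starting at 11.86 Hz (idx 6) in high, 8.71 Hz (idx 4) in low
  expect_equal(models[[33]]$onset_high, 6L)
  expect_equal(models[[33]]$onset_low, 4L)
})

test_that("prior constants reproduce their defining formulas and integrate to one", {
  pr <- prior_spec()
  expect_equal(pr$var_mu0, 2 * (0.5 - 0.001)^2 / 4)
  expect_equal(pr$sigma2_bounds[2], (log(0.5) - log(0.001))^2 / 4)
  m1 <- model_spec("null")
  # sigma2 uniform density
  expect_equal(log_prior(m1, c(mu = 0.05, sigma2 = 5)) -
                 log_prior(m1, c(mu = 0.05, sigma2 = 1)), 0)
  expect_identical(log_prior(m1, c(mu = -0.01, sigma2 = 5)), -Inf)
  expect_identical(log_prior(m1, c(mu = 0.05, sigma2 = 11)), -Inf)
  # truncated normal renormalized over [0, Inf): numerical integral = 1
  f <- function(x) exp(ratesync:::dtruncnorm0_log(x, 0.05, sqrt(pr$var_mu0)))
  expect_equal(integrate(f, 0, Inf)$value, 1, tolerance = 1e-6)
})

test_that("the log-likelihood matches a record-wise density oracle", {
  t1 <- data.frame(group = "high", rate_index = 1, threshold = 1)
  m1 <- model_spec("null")
  expect_equal(log_likelihood(t1, m1, c(mu = 1, sigma2 = 1)),
               -0.5 * log(2 * pi))
  tab <- small_increase_table(seed = 3, n_high = 2, n_low = 1)
  m33 <- model_spec("increase", 6, 4)
  pars <- c(mu = 0.0448, beta = 0.0144, sigma2 = 0.25)
  # independent brute-force summation over records
  x <- list(high = indicator_vector(6), low = indicator_vector(4))
  oracle <- sum(vapply(seq_len(nrow(tab)), function(i) {
    med <- 0.0448 + x[[tab$group[i]]][tab$rate_index[i]] * 0.0144
    dlnorm(tab$threshold[i], log(med), 0.5, log = TRUE)
  }, numeric(1)))
  expect_equal(log_likelihood(tab, m33, pars), oracle)
  # additivity: doubling the dataset doubles the log-likelihood
  expect_equal(log_likelihood(rbind(tab, tab), m33, pars),
               2 * log_likelihood(tab, m33, pars))
  expect_error(log_likelihood(transform(tab, threshold = -threshold),
                              m33, pars))
})

test_that("increase with beta = 0 nests the null model exactly", {
  tab <- tiny_null_table()
  m1 <- model_spec("null")
  m33 <- model_spec("increase", 6, 4)
  expect_equal(log_likelihood(tab, m33, c(mu = 0.06, beta = 0, sigma2 = 0.3)),
               log_likelihood(tab, m1, c(mu = 0.06, sigma2 = 0.3)))
  for (r in 1:8)
    expect_equal(model_location(m33, c(mu = 0.05, beta = 0, sigma2 = 1),
                                r, "low"), log(0.05))
})

test_that("quadrature marginal likelihood matches a dense full-support grid oracle", {
  tab <- tiny_null_table()
  q <- marginal_likelihood(tab, model_spec("null"))
  expect_true(q$converged)
  expect_equal(q$log_ml, brute_force_ml_null(tab), tolerance = 0.01)
})

test_that("irrelevant slope parameters pay an Occam penalty on null data", {
  deltas <- vapply(1:6, function(s) {
    tab <- tiny_null_table(seed = 20 + s, n_keep = 40)
    marginal_likelihood(tab, model_spec("increase", 6, 4))$log_ml -
      marginal_likelihood(tab, model_spec("null"))$log_ml
  }, numeric(1))
  expect_lt(mean(deltas), 0)
})

test_that("posterior model probabilities are a stable softmax with uniform prior", {
  p <- posterior_model_probabilities(rep(-1000, 149))
  expect_equal(p, rep(1 / 149, 149))
  expect_equal(sum(p), 1, tolerance = 1e-12)
  p2 <- posterior_model_probabilities(c(0, -50, -50))
  expect_gt(p2[1], 0.999999)
  # invariance to adding a constant
  lml <- rnorm(10)
  expect_equal(posterior_model_probabilities(lml),
               posterior_model_probabilities(lml + 123.4))
  expect_error(posterior_model_probabilities(rep(-Inf, 3)), "-Inf")
})

test_that("Bayes factors are posterior odds", {
  expect_equal(round(bayes_factor(0.7453), 2), 2.93)
  expect_equal(round(bayes_factor(0.8797), 2), 7.31)
  expect_equal(round(bayes_factor(0.2861), 1), 0.4)
  expect_equal(bayes_factor(0.5), 1)
  expect_error(bayes_factor(1), "\\[0, 1\\)")
})

test_that("event probabilities marginalize correctly over the model set", {
  df <- data.frame(id = 1:149)
  models <- enumerate_models()
  post <- list(models = data.frame(
    id = vapply(models, `[[`, integer(1), "id"),
    family = vapply(models, `[[`, character(1), "family"),
    onset_high = vapply(models, `[[`, integer(1), "onset_high"),
    onset_low = vapply(models, `[[`, integer(1), "onset_low"),
    posterior_prob = rep(1 / 149, 149)))
  expect_equal(marginal_event_probability(post, function(m) rep(TRUE, 149)), 1)
  expect_equal(marginal_event_probability(post, "increase"), 49 / 149)
  p_lo <- marginal_event_probability(post, "onset_low_earlier")
  p_hi <- marginal_event_probability(post, "onset_high_earlier")
  ties <- marginal_event_probability(post, function(m)
    !is.na(m$onset_low) & m$onset_low == m$onset_high)
  no_onset <- marginal_event_probability(post, function(m) is.na(m$onset_low))
  expect_equal(p_lo + p_hi + ties + no_onset, 1)
  expect_equal(p_lo, p_hi)   # symmetry under the uniform posterior
  expect_warning(p0 <- marginal_event_probability(post, function(m)
    rep(FALSE, 149)), "no models")
  expect_equal(p0, 0)
})

test_that("MCMC plus bridge sampling agrees with quadrature on small models", {
  tab <- tiny_null_table()
  m1 <- model_spec("null")
  q <- marginal_likelihood(tab, m1)
  b <- marginal_likelihood(tab, m1, method = "mcmc", seed = 3)
  expect_lt(abs(q$log_ml - b$log_ml), 0.1)
  expect_true(all(b$rhat < 1.1))
  tab2 <- small_increase_table()
  m33 <- model_spec("increase", 6, 4)
  expect_lt(abs(marginal_likelihood(tab2, m33)$log_ml -
                  marginal_likelihood(tab2, m33, method = "mcmc",
                                      seed = 5)$log_ml), 0.1)
})

test_that("parameter posteriors recover generating values on a large cohort", {
  tab <- draw_threshold_dataset(generative_spec(), seed = 11)
  ms <- model_spec("increase", 6, 4)
  fp <- fit_parameters(tab, ms)
  expect_equal(fp$parameter, c("mu", "beta", "sigma2"))
  expect_true(all(fp$lower <= fp$mean & fp$mean <= fp$upper))
  expect_true(fp$lower[1] <= 0.0448 && 0.0448 <= fp$upper[1])
  expect_true(fp$lower[2] <= 0.0144 && 0.0144 <= fp$upper[2])
  expect_true(fp$lower[3] <= 0.25 && 0.25 <= fp$upper[3])
  # MCMC and quadrature agree in posterior means
  fm <- fit_parameters(small_increase_table(), ms, method = "mcmc", seed = 2)
  fq <- fit_parameters(small_increase_table(), ms)
  expect_equal(fm$mean, fq$mean, tolerance = 0.05)
})

test_that("the truncated-Gaussian control likelihood is a proper alternative", {
  tab <- small_increase_table()
  m33 <- model_spec("increase", 6, 4)
  pars <- c(mu = 0.0448, beta = 0.0144, sigma2 = 0.01)
  x <- list(high = indicator_vector(6), low = indicator_vector(4))
  oracle <- sum(vapply(seq_len(nrow(tab)), function(i) {
    med <- 0.0448 + x[[tab$group[i]]][tab$rate_index[i]] * 0.0144
    dnorm(tab$threshold[i], med, 0.1, log = TRUE) -
      pnorm(med / 0.1, log.p = TRUE)
  }, numeric(1)))
  expect_equal(log_likelihood(tab, m33, pars,
                              likelihood = "truncated_normal"), oracle)
})
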