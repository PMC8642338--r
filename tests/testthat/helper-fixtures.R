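# Small fixtures shared across test files; everything is generated in code.

tiny_null_table <- function(seed = 7, n_keep = 10) {
  spec <- generative_spec("null", mu_high = 0.05, mu_low = 0.05,
                          beta_high = 0, beta_low = 0,
                          onset_high = NA, onset_low = NA,
                          sigma2 = 0.2, n_high = 4, n_low = 3)
  tab <- draw_threshold_dataset(spec, seed = seed)
  set.seed(seed)
  tab[sample(nrow(tab), n_keep), ]
}

small_increase_table <- function(seed = 9, n_high = 6, n_low = 4) {
  spec <- generative_spec("increase", mu_high = 0.0448, beta_high = 0.0144,
                          onset_high = 6, onset_low = 4, sigma2 = 0.25,
                          n_high = n_high, n_low = n_low)
  draw_threshold_dataset(spec, seed = seed)
}

# dense brute-force marginal likelihood for the 2-parameter null model,
# integrating over the full prior support (independent oracle)
brute_force_ml_null <- function(tab, n_grid = 2000) {
  pr <- prior_spec()
  mu_g <- seq(1e-5, 1.2, length.out = n_grid)
  s2_g <- seq(1e-5, pr$sigma2_bounds[2] - 1e-6, length.out = n_grid)
  lp_mu <- dnorm(mu_g, pr$mu0, sqrt(pr$var_mu0), log = TRUE) -
    pnorm(pr$mu0 / sqrt(pr$var_mu0), log.p = TRUE)
  lt <- log(tab$threshold)
  n <- length(lt)
  M <- matrix(0, n_grid, n_grid)
  for (j in seq_len(n_grid)) {
    s2 <- s2_g[j]
    M[, j] <- -n / 2 * log(2 * pi * s2) - sum(lt) -
      sapply(mu_g, function(m) sum((lt - log(m))^2)) / (2 * s2)
  }
  lpost <- sweep(M, 1, lp_mu, "+") - log(diff(pr$sigma2_bounds))
  w <- log(mean(diff(mu_g))) + log(mean(diff(s2_g)))
  mx <- max(lpost)
  log(sum(exp(lpost - mx))) + mx + w
}
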