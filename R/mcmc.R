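# Sampling-based marginal likelihoods: adaptive random-walk Metropolis over
# an unconstrained reparameterization, followed by iterative (Meng-Wong)
# bridge sampling with a moment-matched Gaussian proposal. Mirrors the
# workflow settings of the reference analysis (5 chains, 2000 iterations of
# which 1000 warm-up); the quadrature path remains the deterministic default
# and the two must agree within tight tolerance on low-dimensional models.

# transforms between natural parameters and unconstrained z
.to_z <- function(theta, nm, priors) {
  z <- log(theta)
  if ("sigma2" %in% nm) {
    g <- priors$sigma2_bounds[2]
    z[nm == "sigma2"] <- qlogis(theta[nm == "sigma2"] / g)
  }
  z
}

.from_z <- function(z, nm, priors) {
  th <- exp(z)
  if ("sigma2" %in% nm) {
    g <- priors$sigma2_bounds[2]
    th[, nm == "sigma2"] <- g * plogis(z[, nm == "sigma2"])
  }
  th
}

# log |Jacobian| of z -> theta, rowwise over a z matrix
.log_jac <- function(z, nm, priors) {
  lj <- rowSums(z[, nm != "sigma2", drop = FALSE])
  if ("sigma2" %in% nm) {
    g <- priors$sigma2_bounds[2]
    zs <- z[, nm == "sigma2"]
    lj <- lj + log(g) + plogis(zs, log.p = TRUE) +
      plogis(-zs, log.p = TRUE)
  }
  lj
}

# unnormalized log posterior in z-space (matrix rows = points)
.logpost_z <- function(z, stats, spec, priors, likelihood) {
  nm <- model_parameters(spec)
  th <- .from_z(z, nm, priors)
  colnames(th) <- nm
  .loglik_points(stats, spec, th, likelihood) +
    log_prior(spec, th, priors) + .log_jac(z, nm, priors)
}

# Adaptive random-walk Metropolis. Warm-up adapts a global scale on a
# diagonal proposal, then switches to the empirical covariance of the
# warm-up draws (scaled 2.38^2/d). Returns kept draws on the natural scale.
.sample_posterior <- function(stats, spec, priors, seed = 1L,
                              n_chains = 5, iter = 2000, warmup = 1000,
                              likelihood = "lognormal") {
  set.seed(seed)
  nm <- model_parameters(spec)
  d <- length(nm)
  base_mu <- exp(mean(stats$mean_log[stats$rate_index <= 2]))
  s2_0 <- max(sum(stats$ss_log) / max(stats$N - 1, 1), 1e-3)
  th0 <- ifelse(nm == "sigma2", s2_0,
         ifelse(grepl("^beta", nm), 0.01, max(base_mu, 1e-3)))
  z0 <- .to_z(th0, nm, priors)
  kept <- vector("list", n_chains)
  kept_z <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    z <- z0 + rnorm(d, 0, 0.2)
    lp <- .logpost_z(matrix(z, 1), stats, spec, priors, likelihood)
    scale <- 0.5
    S <- diag(d)
    L <- diag(d)
    warm <- matrix(NA_real_, warmup, d)
    acc_win <- 0
    draws_z <- matrix(NA_real_, iter - warmup, d)
    for (t in seq_len(iter)) {
      prop <- z + scale * as.numeric(L %*% rnorm(d))
      lp_p <- .logpost_z(matrix(prop, 1), stats, spec, priors, likelihood)
      if (is.finite(lp_p) && log(runif(1)) < lp_p - lp) {
        z <- prop; lp <- lp_p; acc_win <- acc_win + 1
      }
      if (t <= warmup) {
        warm[t, ] <- z
        if (t %% 50 == 0) {
          rate <- acc_win / 50
          scale <- scale * exp(rate - 0.3)
          acc_win <- 0
          if (t == floor(warmup / 2)) {
            C <- cov(warm[seq_len(t), , drop = FALSE]) + 1e-8 * diag(d)
            L <- t(chol(2.38^2 / d * C))
            scale <- 1
          }
        }
      } else {
        draws_z[t - warmup, ] <- z
      }
    }
    kept_z[[ch]] <- draws_z
    th <- .from_z(draws_z, nm, priors)
    colnames(th) <- nm
    kept[[ch]] <- th
  }
  draws <- do.call(rbind, kept)
  colnames(draws) <- nm
  list(draws = draws, draws_z = do.call(rbind, kept_z),
       chains_z = kept_z, rhat = .split_rhat(kept_z), parameters = nm)
}

# split-Rhat over a list of per-chain draw matrices
.split_rhat <- function(chains) {
  d <- ncol(chains[[1]])
  vapply(seq_len(d), function(k) {
    halves <- unlist(lapply(chains, function(m) {
      n <- nrow(m); h <- floor(n / 2)
      list(m[seq_len(h), k], m[(n - h + 1):n, k])
    }), recursive = FALSE)
    mns <- vapply(halves, mean, numeric(1))
    vrs <- vapply(halves, var, numeric(1))
    n <- length(halves[[1]]); m <- length(halves)
    W <- mean(vrs); B <- n * var(mns)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
}

# Gaussian log-density with mean m and covariance factor (cholesky of cov)
.dmvnorm_log <- function(x, m, chol_cov) {
  d <- length(m)
  z <- backsolve(chol_cov, t(x) - m, transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(chol_cov))) - 0.5 * colSums(z^2)
}

# Iterative bridge-sampling estimate of the log marginal likelihood from
# posterior draws in z-space and a moment-matched Gaussian proposal.
.bridge_ml <- function(stats, spec, priors, seed = 1L,
                       n_chains = 5, iter = 2000, warmup = 1000,
                       likelihood = "lognormal") {
  fit <- .sample_posterior(stats, spec, priors, seed = seed,
                           n_chains = n_chains, iter = iter,
                           warmup = warmup, likelihood = likelihood)
  z <- fit$draws_z
  n1 <- nrow(z)
  m <- colMeans(z)
  Cz <- cov(z) + 1e-10 * diag(ncol(z))
  R <- chol(Cz)
  set.seed(seed + 1L)
  n2 <- n1
  g <- matrix(rnorm(n2 * ncol(z)), n2) %*% R
  g <- sweep(g, 2, m, `+`)
  l1 <- .logpost_z(z, stats, spec, priors, likelihood) -
    .dmvnorm_log(z, m, R)
  l2 <- .logpost_z(g, stats, spec, priors, likelihood) -
    .dmvnorm_log(g, m, R)
  l2[!is.finite(l2)] <- -Inf
  C <- stats::median(l1)
  e1 <- exp(l1 - C); e2 <- exp(l2 - C)
  s1 <- n1 / (n1 + n2); s2 <- n2 / (n1 + n2)
  r <- 1
  for (it in seq_len(1000)) {
    num <- mean(e2 / (s1 * e2 + s2 * r))
    den <- mean(1 / (s1 * e1 + s2 * r))
    r_new <- num / den
    if (abs(r_new - r) < 1e-12 * abs(r)) { r <- r_new; break }
    r <- r_new
  }
  list(log_ml = log(r) + C, rhat = fit$rhat, n_draws = n1,
       parameters = fit$parameters)
}
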