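#' Bayesian comparison of 149 threshold-vs-rate models
#'
#' The observations D are per-participant relative difference thresholds at
#' 8 standard rates, modelled as log-normal:
#'
#'   D ~ LogNormal(log(mu_j + x_kj * beta_j), sigma2)
#'
#' Five model families: a constant threshold (null), a group baseline
#' difference (high vs low synchronizers), a linear threshold increase with a
#' group-specific onset point, an increase plus a group baseline difference,
#' and an increase with a group-specific slope. The onset of the increase can
#' sit at any of grid indices 2..8 independently per group (49 combinations
#' per increase family), giving 1 + 1 + 3 * 49 = 149 models with uniform
#' prior probability 1/149. Model evidence is the marginal likelihood, by
#' deterministic mode-centred quadrature (default) or MCMC plus bridge
#' sampling.
#'
#' All location/slope parameters carry zero-truncated normal priors
#' (renormalized over `[0, Inf)`); the shared variance carries a uniform
#' prior on `(0, (log 0.5 - log 0.001)^2 / 4)`.
#'
#' @name model_comparison
NULL

#' Standard-rate grid
#'
#' Eight rates linearly spaced from 4 to 15 Hz (spacing 11/7 Hz).
#' @return list of class `rate_grid` with `rates` and `index`.
#' @export
rate_grid <- function() {
  structure(list(rates = seq(4, 15, length.out = 8), index = 1:8),
            class = "rate_grid")
}

#' Onset indicator vector
#'
#' For an increase with onset at grid index `onset_idx` (2..8), element m is
#' `max(0, m - onset_idx + 1)`: zero up to the rate before the onset, then
#' counting grid steps 1, 2, ... from the onset rate on. Index 1 (4 Hz) is
#' always zero.
#'
#' @param onset_idx integer in 2..8.
#' @return integer vector of length 8.
#' @export
indicator_vector <- function(onset_idx) {
  if (length(onset_idx) != 1 || is.na(onset_idx) || onset_idx < 2 ||
      onset_idx > 8 || onset_idx != round(onset_idx))
    stop("onset_idx must be an integer in 2..8")
  pmax(0L, 1:8 - as.integer(onset_idx) + 1L)
}

#' Specification of a single threshold model
#'
#' @param family model family (see [model_comparison]).
#' @param onset_high,onset_low onset grid indices (2..8) for the high and low
#'   group; required for increase families, forbidden otherwise.
#' @param id optional model index (1..149).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(family, onset_high = NA_integer_,
                       onset_low = NA_integer_, id = NA_integer_) {
  family <- match.arg(family, MODEL_FAMILIES)
  inc <- family %in% c("increase", "increase_group_baseline",
                       "increase_group_slope")
  if (inc) {
    if (is.na(onset_high) || is.na(onset_low))
      stop("increase families require both onset indices")
    for (v in c(onset_high, onset_low))
      if (v < 2 || v > 8 || v != round(v))
        stop("onset indices must be integers in 2..8")
  } else if (!is.na(onset_high) || !is.na(onset_low)) {
    stop("family '", family, "' carries no onset indices")
  }
  structure(list(id = as.integer(id), family = family,
                 onset_high = as.integer(onset_high),
                 onset_low = as.integer(onset_low)),
            class = "model_spec")
}

#' Free parameters of a model
#' @param spec a [model_spec()].
#' @return character vector of parameter names (sigma2 last).
#' @export
model_parameters <- function(spec) {
  switch(spec$family,
    null = c("mu", "sigma2"),
    group_baseline = c("mu_high", "mu_low", "sigma2"),
    increase = c("mu", "beta", "sigma2"),
    increase_group_baseline = c("mu_high", "mu_low", "beta", "sigma2"),
    increase_group_slope = c("mu", "beta_high", "beta_low", "sigma2"))
}

#' Enumerate the full 149-model battery
#'
#' M1 null; M2 group baseline; M3-M51 increase; M52-M100 increase + group
#' baseline; M101-M149 increase + group slope. Within each 49-block the
#' outer loop runs over the high-group onset (ascending), the inner loop
#' over the low-group onset, so e.g. M33 carries onset_high = 6 (11.86 Hz)
#' and onset_low = 4 (8.71 Hz).
#'
#' @return list of 149 [model_spec()] objects.
#' @export
enumerate_models <- function() {
  models <- list(model_spec("null", id = 1L),
                 model_spec("group_baseline", id = 2L))
  id <- 2L
  for (family in c("increase", "increase_group_baseline",
                   "increase_group_slope")) {
    for (oh in 2:8) for (ol in 2:8) {
      id <- id + 1L
      models[[id]] <- model_spec(family, onset_high = oh, onset_low = ol,
                                 id = id)
    }
  }
  models
}

#' Prior specification
#'
#' Constants from the analysis design: prior mean 5% for baseline thresholds
#' (9% for the low-group baseline where a separate one exists), prior mean 2%
#' for slopes, shared prior variance `2 (0.5 - 0.001)^2 / 4 ~ 0.125` for all
#' location/slope parameters, and a uniform prior on the log-scale variance
#' over `(0, (log 0.5 - log 0.001)^2 / 4 ~ 9.66)`. All parameters truncated
#' at 0 (renormalized).
#'
#' @export
prior_spec <- function() {
  structure(list(mu0 = 0.05, mu0_low = 0.09,
                 var_mu0 = 2 * (0.5 - 0.001)^2 / 4,
                 beta0 = 0.02, var_beta0 = 2 * (0.5 - 0.001)^2 / 4,
                 sigma2_bounds = c(0, (log(0.5) - log(0.001))^2 / 4)),
            class = "prior_spec")
}

# prior mean/sd per parameter name
.prior_moments <- function(names, priors) {
  mean <- ifelse(names == "mu_low", priors$mu0_low,
          ifelse(grepl("^mu", names), priors$mu0, priors$beta0))
  sd <- ifelse(grepl("^mu", names), sqrt(priors$var_mu0),
               sqrt(priors$var_beta0))
  mean[names == "sigma2"] <- NA
  sd[names == "sigma2"] <- NA
  list(mean = mean, sd = sd)
}

# per-group parameter extraction; params may be a named vector or a matrix
# with named columns (one row per evaluation point)
.group_params <- function(spec, params) {
  get <- function(nm, alt) {
    if (is.matrix(params)) {
      if (nm %in% colnames(params)) params[, nm] else params[, alt]
    } else {
      if (nm %in% names(params)) params[[nm]] else params[[alt]]
    }
  }
  list(mu_high = get("mu_high", "mu"), mu_low = get("mu_low", "mu"),
       beta_high = if (spec$family %in% c("null", "group_baseline")) 0
                   else get("beta_high", "beta"),
       beta_low = if (spec$family %in% c("null", "group_baseline")) 0
                  else get("beta_low", "beta"),
       sigma2 = get("sigma2", "sigma2"))
}

.onset_x <- function(spec) {
  list(high = if (is.na(spec$onset_high)) rep(0L, 8)
              else indicator_vector(spec$onset_high),
       low = if (is.na(spec$onset_low)) rep(0L, 8)
             else indicator_vector(spec$onset_low))
}

#' Log-scale location of a model at one design cell
#'
#' `log(mu_j + x_j[rate_idx] * beta_j)`, degenerating to `log(mu)` for
#' families without increase or group terms.
#'
#' @param spec a [model_spec()].
#' @param params named numeric vector of the model's parameters.
#' @param rate_idx grid index 1..8.
#' @param group `"high"` (j = 1) or `"low"` (j = 2).
#' @export
model_location <- function(spec, params, rate_idx, group = c("high", "low")) {
  group <- match.arg(group)
  gp <- .group_params(spec, params)
  x <- .onset_x(spec)[[group]]
  med <- if (group == "high") gp$mu_high + x[rate_idx] * gp$beta_high
         else gp$mu_low + x[rate_idx] * gp$beta_low
  if (any(med <= 0)) stop("mu + x * beta must be positive")
  log(med)
}

# Sufficient statistics of a threshold table for the shared-variance
# likelihood: per (group, rate) cell counts, means and centred sums of
# squares of log(threshold) (and of raw thresholds, for the
# truncated-Gaussian control likelihood).
threshold_suffstats <- function(table) {
  stopifnot(all(c("group", "rate_index", "threshold") %in% names(table)),
            all(table$threshold > 0))
  cell <- interaction(table$group, table$rate_index, drop = TRUE)
  stat <- function(v) {
    n <- tapply(v, cell, length)
    m <- tapply(v, cell, mean)
    ss <- tapply(v, cell, function(z) sum((z - mean(z))^2))
    list(n = as.numeric(n), mean = as.numeric(m), ss = as.numeric(ss))
  }
  lv <- stat(log(table$threshold))
  rv <- stat(table$threshold)
  key <- do.call(rbind, strsplit(levels(cell), ".", fixed = TRUE))
  list(group = key[, 1], rate_index = as.integer(key[, 2]),
       n = lv$n, mean_log = lv$mean, ss_log = lv$ss,
       mean_raw = rv$mean, ss_raw = rv$ss,
       N = nrow(table), sum_log = sum(log(table$threshold)))
}

# vectorized log-likelihood over a parameter matrix (rows = points)
.loglik_points <- function(stats, spec, pmat,
                           likelihood = c("lognormal", "truncated_normal")) {
  likelihood <- match.arg(likelihood)
  gp <- .group_params(spec, pmat)
  x <- .onset_x(spec)
  npts <- nrow(pmat)
  s2 <- gp$sigma2
  quad <- numeric(npts)
  extra <- numeric(npts)
  for (c_i in seq_along(stats$n)) {
    g <- stats$group[c_i]; r <- stats$rate_index[c_i]
    med <- if (g == "high") gp$mu_high + x$high[r] * gp$beta_high
           else gp$mu_low + x$low[r] * gp$beta_low
    if (likelihood == "lognormal") {
      loc <- log(med)
      quad <- quad + stats$ss_log[c_i] +
        stats$n[c_i] * (stats$mean_log[c_i] - loc)^2
    } else {
      quad <- quad + stats$ss_raw[c_i] +
        stats$n[c_i] * (stats$mean_raw[c_i] - med)^2
      # renormalization of the zero-truncated Gaussian
      extra <- extra - stats$n[c_i] *
        pnorm(med / sqrt(s2), log.p = TRUE)
    }
  }
  jac <- if (likelihood == "lognormal") stats$sum_log else 0
  -stats$N / 2 * log(2 * pi) - stats$N / 2 * log(s2) - quad / (2 * s2) -
    jac + extra
}

#' Log-likelihood of a threshold table under one model
#'
#' Sum over records of the log-normal log-density with the record's cell
#' location and the shared variance (or, for the control analysis, a
#' zero-truncated Gaussian on the natural scale).
#'
#' @param table a ThresholdTable (see [draw_threshold_dataset()]).
#' @param spec a [model_spec()].
#' @param params named numeric vector of the model's parameters.
#' @param likelihood `"lognormal"` (default) or `"truncated_normal"`.
#' @export
log_likelihood <- function(table, spec, params,
                           likelihood = c("lognormal", "truncated_normal")) {
  stats <- threshold_suffstats(table)
  pmat <- matrix(unlist(params[model_parameters(spec)]), nrow = 1,
                 dimnames = list(NULL, model_parameters(spec)))
  as.numeric(.loglik_points(stats, spec, pmat, likelihood))
}

# zero-truncated normal log-density, renormalized over [0, Inf)
dtruncnorm0_log <- function(x, mean, sd) {
  ifelse(x < 0, -Inf,
         dnorm(x, mean, sd, log = TRUE) -
           pnorm(mean / sd, log.p = TRUE))
}

#' Log prior density of a model's parameters
#'
#' Renormalized zero-truncated normal densities for location/slope
#' parameters plus the uniform density for sigma2; `-Inf` outside support.
#'
#' @param spec a [model_spec()].
#' @param params named numeric vector (or matrix with named columns).
#' @param priors a [prior_spec()].
#' @export
log_prior <- function(spec, params, priors = prior_spec()) {
  nm <- model_parameters(spec)
  pmat <- if (is.matrix(params)) params[, nm, drop = FALSE] else
    matrix(unlist(params[nm]), nrow = 1, dimnames = list(NULL, nm))
  mom <- .prior_moments(nm, priors)
  lp <- numeric(nrow(pmat))
  for (k in seq_along(nm)) {
    if (nm[k] == "sigma2") {
      lo <- priors$sigma2_bounds[1]; hi <- priors$sigma2_bounds[2]
      lp <- lp + ifelse(pmat[, k] > lo & pmat[, k] < hi, -log(hi - lo), -Inf)
    } else {
      lp <- lp + dtruncnorm0_log(pmat[, k], mom$mean[k], mom$sd[k])
    }
  }
  if (!is.matrix(params)) as.numeric(lp) else lp
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Mode-centred trapezoid quadrature of the unnormalized posterior.
# Returns the log marginal likelihood plus grid diagnostics, optionally
# with per-parameter posterior summaries from the same grid.
.quadrature_ml <- function(stats, spec, priors, npts = NULL,
                           half_width = 7, summaries = FALSE,
                           likelihood = "lognormal") {
  nm <- model_parameters(spec)
  d <- length(nm)
  if (is.null(npts)) npts <- c(61, 41, 31, 17)[d]
  mom <- .prior_moments(nm, priors)
  lo <- ifelse(nm == "sigma2", 1e-6, 0)
  hi <- ifelse(nm == "sigma2", priors$sigma2_bounds[2] - 1e-9, 2)
  negpost <- function(p) {
    pm <- matrix(p, nrow = 1, dimnames = list(NULL, nm))
    v <- .loglik_points(stats, spec, pm, likelihood) +
      log_prior(spec, pm, priors)
    if (!is.finite(v)) 1e10 else -v
  }
  # start from cell-level moments
  base_mu <- exp(mean(stats$mean_log[stats$rate_index <= 2]))
  s2_0 <- max(sum(stats$ss_log) / max(stats$N - 1, 1), 1e-3)
  start <- ifelse(nm == "sigma2", s2_0,
           ifelse(grepl("^beta", nm), 0.01, max(base_mu, 1e-3)))
  start <- pmin(pmax(start, lo + 1e-5), hi - 1e-5)
  opt <- optim(start, negpost, method = "L-BFGS-B", lower = lo, upper = hi,
               control = list(maxit = 500))
  mode <- opt$par
  H <- tryCatch(optimHess(mode, negpost), error = function(e) NULL)
  sd <- rep(NA_real_, d)
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V)) sd <- sqrt(pmax(diag(V), 0))
  }
  fallback <- ifelse(nm == "sigma2",
                     max(0.5, mode[nm == "sigma2"] / 2), 0.2)
  sd[!is.finite(sd) | sd <= 0] <- fallback[!is.finite(sd) | sd <= 0]
  grids <- weights <- vector("list", d)
  for (k in seq_len(d)) {
    if (nm[k] == "sigma2") {
      # integrate the variance on the log scale (its small-sample posterior
      # is strongly right-skewed); Jacobian e^u folded into the weights
      u0 <- log(mode[k])
      sd_u <- max(sd[k] / mode[k], 1e-3)
      span <- half_width * sd_u
      g_u <- seq(max(log(1e-8), u0 - span),
                 min(log(hi[k]), u0 + span), length.out = npts)
      h <- g_u[2] - g_u[1]
      w <- rep(h, npts); w[c(1, npts)] <- h / 2
      grids[[k]] <- exp(g_u); weights[[k]] <- log(w) + g_u
    } else {
      span <- max(half_width * sd[k], 1e-4)
      g <- seq(max(lo[k], mode[k] - span), min(hi[k], mode[k] + span),
               length.out = npts)
      h <- g[2] - g[1]
      w <- rep(h, npts); w[c(1, npts)] <- h / 2
      grids[[k]] <- g; weights[[k]] <- log(w)
    }
  }
  IG <- as.matrix(do.call(expand.grid, lapply(seq_len(d), function(k)
    seq_len(npts))))
  G <- vapply(seq_len(d), function(k) grids[[k]][IG[, k]],
              numeric(nrow(IG)))
  colnames(G) <- nm
  lp <- .loglik_points(stats, spec, G, likelihood) + log_prior(spec, G, priors)
  lw <- rowSums(vapply(seq_len(d), function(k) weights[[k]][IG[, k]],
                       numeric(nrow(IG))))
  log_ml <- logsumexp(lp + lw)
  out <- list(log_ml = log_ml, mode = setNames(mode, nm),
              mode_sd = setNames(sd, nm), npts = npts,
              converged = opt$convergence == 0)
  if (summaries) {
    w <- exp(lp + lw - log_ml)
    summ <- lapply(seq_len(d), function(k) {
      mw <- rowsum(w, IG[, k])[, 1]
      g <- grids[[k]]
      cdf <- cumsum(mw) / sum(mw)
      q <- function(p) g[which(cdf >= p)[1]]
      c(mean = sum(g * mw) / sum(mw), lower = q(0.025), upper = q(0.975))
    })
    out$summaries <- do.call(rbind, summ)
    rownames(out$summaries) <- nm
  }
  out
}

#' Marginal likelihood of one model
#'
#' `log integral of likelihood x prior` over the model's 2-4 free
#' parameters. The default is deterministic mode-centred trapezoid
#' quadrature; `method = "mcmc"` runs the adaptive-Metropolis + bridge
#' sampling path (5 chains, 2000 iterations, 1000 warm-up) and reports the
#' estimator's uncertainty.
#'
#' @param table a ThresholdTable.
#' @param spec a [model_spec()].
#' @param priors a [prior_spec()].
#' @param method `"quadrature"` or `"mcmc"`.
#' @param seed integer seed (used by the MCMC path).
#' @param likelihood `"lognormal"` (default) or `"truncated_normal"`.
#' @param ... further arguments to the backend (`npts`, `half_width`;
#'   `n_chains`, `iter`, `warmup`).
#' @return list with `log_ml` plus backend diagnostics.
#' @export
marginal_likelihood <- function(table, spec, priors = prior_spec(),
                                method = c("quadrature", "mcmc"), seed = 1L,
                                likelihood = c("lognormal",
                                               "truncated_normal"), ...) {
  method <- match.arg(method)
  likelihood <- match.arg(likelihood)
  if (nrow(table) == 0) stop("empty threshold table")
  stats <- threshold_suffstats(table)
  if (method == "quadrature") {
    .quadrature_ml(stats, spec, priors, likelihood = likelihood, ...)
  } else {
    .bridge_ml(stats, spec, priors, seed = seed, likelihood = likelihood, ...)
  }
}

#' Evaluate the full model battery on a threshold table
#'
#' Computes the log marginal likelihood of all 149 models and the derived
#' posterior quantities (uniform model prior).
#'
#' @inheritParams marginal_likelihood
#' @param models optional model list (default [enumerate_models()]).
#' @return object of class `model_posterior`: data.frame `models` (id,
#'   family, onsets, log_ml, posterior_prob, bayes_factor), `family_probs`,
#'   `onset_event_probs` (`P(onset_low < onset_high)` and the onset-pair
#'   posterior matrix marginalized over increase families), `best`.
#' @export
compare_models <- function(table, priors = prior_spec(),
                           method = c("quadrature", "mcmc"), seed = 1L,
                           models = enumerate_models(),
                           likelihood = c("lognormal", "truncated_normal"),
                           ...) {
  method <- match.arg(method)
  likelihood <- match.arg(likelihood)
  stats <- threshold_suffstats(table)
  log_ml <- vapply(seq_along(models), function(i) {
    spec <- models[[i]]
    if (method == "quadrature")
      .quadrature_ml(stats, spec, priors, likelihood = likelihood, ...)$log_ml
    else
      .bridge_ml(stats, spec, priors, seed = seed + models[[i]]$id,
                 likelihood = likelihood, ...)$log_ml
  }, numeric(1))
  df <- data.frame(
    id = vapply(models, `[[`, integer(1), "id"),
    family = vapply(models, `[[`, character(1), "family"),
    onset_high = vapply(models, `[[`, integer(1), "onset_high"),
    onset_low = vapply(models, `[[`, integer(1), "onset_low"),
    log_ml = log_ml)
  df$posterior_prob <- posterior_model_probabilities(df$log_ml)
  df$bayes_factor <- bayes_factor(df$posterior_prob)
  fam <- tapply(df$posterior_prob, df$family, sum)
  inc <- df[!is.na(df$onset_high), ]
  p_lo_early <- sum(inc$posterior_prob[inc$onset_low < inc$onset_high])
  onset_mat <- with(inc, tapply(posterior_prob,
                                list(onset_high = onset_high,
                                     onset_low = onset_low), sum))
  structure(list(models = df,
                 family_probs = fam[MODEL_FAMILIES[MODEL_FAMILIES %in% names(fam)]],
                 onset_event_probs = list(
                   p_onset_low_earlier = p_lo_early,
                   onset_pair_matrix = onset_mat),
                 best = df[which.max(df$posterior_prob), ]),
            class = "model_posterior")
}

#' Posterior model probabilities from log marginal likelihoods
#'
#' Softmax in log space; with the uniform model prior the prior cancels, but
#' a non-uniform `prior_probs` is accepted.
#'
#' @param log_mls numeric vector of log marginal likelihoods (`-Inf` allowed
#'   for empty-support models, but not for all of them).
#' @param prior_probs optional prior probabilities (default uniform).
#' @return probabilities summing to 1.
#' @export
posterior_model_probabilities <- function(log_mls, prior_probs = NULL) {
  if (all(!is.finite(log_mls)))
    stop("all log marginal likelihoods are -Inf")
  lp <- log_mls + if (is.null(prior_probs)) 0 else log(prior_probs)
  exp(lp - logsumexp(lp))
}

#' Posterior-odds Bayes factor
#'
#' Evidence for a model (or model set) as the ratio of its posterior
#' probability to the summed posterior probability of all remaining models:
#' `p / (1 - p)`.
#'
#' @param p posterior probability in `[0, 1)`.
#' @export
bayes_factor <- function(p) {
  if (any(p < 0 | p >= 1)) stop("p must lie in [0, 1)")
  p / (1 - p)
}

#' Posterior probability of a model event
#'
#' Sums posterior probabilities over the models satisfying a predicate —
#' either a function of the models data.frame returning a logical vector, or
#' one of the named events `"onset_low_earlier"`, `"onset_high_earlier"`, or
#' a family name.
#'
#' @param posterior a [compare_models()] result.
#' @param event predicate function or event name.
#' @export
marginal_event_probability <- function(posterior, event) {
  df <- posterior$models
  sel <- if (is.function(event)) event(df)
  else switch(event,
    onset_low_earlier = !is.na(df$onset_low) & df$onset_low < df$onset_high,
    onset_high_earlier = !is.na(df$onset_low) & df$onset_high < df$onset_low,
    df$family == event)
  sel[is.na(sel)] <- FALSE
  if (!any(sel)) {
    warning("event matches no models")
    return(0)
  }
  sum(df$posterior_prob[sel])
}

#' Posterior parameter summaries for one model
#'
#' Posterior mean and central 95% interval per parameter, from the
#' quadrature-normalized posterior (default) or from MCMC draws (with
#' split-Rhat convergence diagnostics).
#'
#' @inheritParams marginal_likelihood
#' @return data.frame with columns parameter, mean, lower, upper (and rhat
#'   for the MCMC path).
#' @export
fit_parameters <- function(table, spec, priors = prior_spec(),
                           method = c("quadrature", "mcmc"), seed = 1L,
                           likelihood = c("lognormal", "truncated_normal"),
                           ...) {
  method <- match.arg(method)
  likelihood <- match.arg(likelihood)
  stats <- threshold_suffstats(table)
  nm <- model_parameters(spec)
  if (method == "quadrature") {
    q <- .quadrature_ml(stats, spec, priors, summaries = TRUE,
                        likelihood = likelihood, ...)
    data.frame(parameter = nm, mean = q$summaries[, "mean"],
               lower = q$summaries[, "lower"], upper = q$summaries[, "upper"],
               row.names = NULL)
  } else {
    fit <- .sample_posterior(stats, spec, priors, seed = seed,
                             likelihood = likelihood, ...)
    draws <- fit$draws
    data.frame(parameter = nm,
               mean = colMeans(draws),
               lower = apply(draws, 2, quantile, 0.025),
               upper = apply(draws, 2, quantile, 0.975),
               rhat = fit$rhat, row.names = NULL)
  }
}
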