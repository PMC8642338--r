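#' Weibull psychometric function machinery for 2IFC rate discrimination
#'
#' The task is two-interval forced choice, so the guess rate is fixed at 0.5
#' and performance runs from chance to a lapse-limited ceiling:
#'
#'   p(correct | d) = 0.5 + (0.5 - lapse) * F(d; threshold, width)
#'
#' where `d` is the relative rate difference (comparison - standard)/standard
#' and F is a Weibull cumulative form parameterized so that F(threshold) = 0.5
#' and `width` is the stimulus-axis distance between the 0.05 and 0.95 points
#' of F. The reported "75% correct threshold" is the level where the full
#' curve crosses 0.75; it coincides with the `threshold` parameter when the
#' lapse rate is zero.
#'
#' @name psychometric
NULL

# Weibull shape k such that F(x) = 1 - 2^-(x/m)^k has width w between its
# 0.05 and 0.95 points. The width is strictly decreasing in k.
weibull_shape_from_width <- function(threshold, width) {
  stopifnot(threshold > 0, width > 0)
  q95 <- log2(1 / 0.05)   # (x/m)^k at F = 0.95
  q05 <- log2(1 / 0.95)   # (x/m)^k at F = 0.05
  f <- function(k) threshold * (q95^(1 / k) - q05^(1 / k)) - width
  uniroot(f, lower = 1e-3, upper = 1e3, tol = 1e-12)$root
}

#' Psychometric parameter bundle
#'
#' @param threshold level at which the inner Weibull reaches 0.5 (proportion).
#' @param width distance between the inner function's 0.05 and 0.95 points.
#' @param lapse lapse probability in `[0, 0.5)`.
#' @return object of class `psychometric_params`.
#' @export
psychometric_params <- function(threshold, width, lapse = 0) {
  if (!is.numeric(threshold) || threshold <= 0) stop("threshold must be > 0")
  if (!is.numeric(width) || width <= 0) stop("width must be > 0")
  if (!is.numeric(lapse) || lapse < 0 || lapse >= 0.5)
    stop("lapse must lie in [0, 0.5)")
  structure(
    list(threshold = threshold, width = width, lapse = lapse, guess = 0.5,
         shape = weibull_shape_from_width(threshold, width)),
    class = "psychometric_params")
}

#' Probability of a correct 2IFC response
#'
#' @param d relative rate difference(s), `>= 0`.
#' @param params a [psychometric_params()] object.
#' @return probabilities in `[0.5, 1 - lapse]`.
#' @export
psych_fun <- function(d, params) {
  stopifnot(inherits(params, "psychometric_params"), all(d >= 0))
  inner <- 1 - 2^(-(d / params$threshold)^params$shape)
  params$guess + (0.5 - params$lapse) * inner
}

#' Level at which the full psychometric curve crosses 75% correct
#'
#' Accounts for the lapse rate: solves 0.5 + (0.5 - lapse) F(d) = 0.75.
#' Equals the `threshold` parameter when lapse = 0; undefined (NA) when the
#' ceiling 1 - lapse does not reach 0.75.
#'
#' @param params a [psychometric_params()] object.
#' @export
threshold_75 <- function(params) {
  target <- (0.25) / (0.5 - params$lapse)  # required F value
  if (target >= 1) return(NA_real_)
  # invert F(x) = 1 - 2^-(x/m)^k
  params$threshold * log2(1 / (1 - target))^(1 / params$shape)
}

#' Comparison levels for the method of constant stimuli
#'
#' Seven levels: the individual weighted up-down threshold multiplied by a
#' geometric seven-point scale from 0.2 to 3, spanning the psychometric
#' function from near chance to saturation.
#'
#' @param wud_threshold individual adaptive-staircase threshold (> 0).
#' @return numeric vector of 7 strictly increasing levels.
#' @export
comparison_levels <- function(wud_threshold) {
  if (!is.numeric(wud_threshold) || wud_threshold <= 0)
    stop("wud_threshold must be > 0")
  wud_threshold * 0.2 * (3 / 0.2)^((0:6) / 6)
}

#' Constant-stimuli design
#'
#' @param standard_rate standard rate in Hz.
#' @param levels 7 strictly increasing comparison levels (relative differences).
#' @param trials_per_level trials measured at each level (default 30).
#' @export
cs_design <- function(standard_rate, levels, trials_per_level = 30) {
  if (length(levels) != 7) stop("design requires exactly 7 levels")
  if (any(diff(levels) <= 0)) stop("levels must be strictly increasing")
  structure(list(standard_rate = standard_rate, levels = levels,
                 trials_per_level = trials_per_level),
            class = "cs_design")
}

#' Simulate a constant-stimuli session for an observer
#'
#' Bernoulli responses at each design level from the observer's psychometric
#' function; `trials_per_level` trials per level (the real procedure presents
#' them as interleaved runs, which does not affect the per-level counts).
#'
#' @param observer an [make_observer()] object.
#' @param design a [cs_design()] object.
#' @param seed integer seed.
#' @return data.frame with columns level, n_correct, n_total.
#' @export
simulate_cs_run <- function(observer, design, seed = 1L) {
  stopifnot(inherits(observer, "observer_model"), inherits(design, "cs_design"))
  set.seed(seed)
  p <- observer_p_correct(observer, design$levels)
  n_correct <- rbinom(length(design$levels), design$trials_per_level, p)
  data.frame(level = design$levels, n_correct = n_correct,
             n_total = design$trials_per_level)
}

# binomial deviance of counts against predicted probabilities
# (saturated-vs-model log-likelihood ratio form)
binom_deviance <- function(n_correct, n_total, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  phat <- n_correct / n_total
  ll_sat <- ifelse(n_correct > 0, n_correct * log(phat), 0) +
    ifelse(n_total - n_correct > 0, (n_total - n_correct) * log(1 - phat), 0)
  ll_mod <- n_correct * log(p) + (n_total - n_correct) * log(1 - p)
  2 * sum(ll_sat - ll_mod)
}

# negative log posterior for the MAP fit, parameterized as
# (log threshold, log width, lapse); weak Beta(1, 20) prior keeps the lapse
# near 0 as in typical 2AFC fits, other parameters are unpenalized.
.psy_negll <- function(par, counts, lapse_prior = c(1, 20)) {
  m <- exp(par[1]); w <- exp(par[2]); lam <- par[3]
  if (lam < 0 || lam >= 0.5) return(1e10)
  params <- tryCatch(psychometric_params(m, w, lam), error = function(e) NULL)
  if (is.null(params)) return(1e10)
  p <- psych_fun(counts$level, params)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  nll <- -sum(counts$n_correct * log(p) +
                (counts$n_total - counts$n_correct) * log(1 - p))
  nll - dbeta(min(lam / 0.5, 1 - 1e-12), lapse_prior[1], lapse_prior[2], log = TRUE)
}

#' Fit the Weibull psychometric function to per-level counts
#'
#' Maximum a-posteriori fit with the guess rate fixed at 0.5; three free
#' parameters (75%-point threshold of the inner function, width, lapse).
#' Interval estimates are Wald intervals from the numerical Hessian on the
#' (log threshold, log width, lapse) scale; boundary solutions (e.g. lapse
#' pinned at 0, or all-correct data) are flagged in `$boundary`.
#'
#' @param counts data.frame with columns level, n_correct, n_total.
#' @param design optional [cs_design()] the counts came from (metadata only).
#' @return list of class `psychometric_fit` with elements `params`
#'   ([psychometric_params()]), `threshold_75`, `ci` (2x3 matrix), `deviance`,
#'   `converged`, `boundary`.
#' @export
fit_psychometric <- function(counts, design = NULL) {
  stopifnot(all(c("level", "n_correct", "n_total") %in% names(counts)))
  counts <- counts[counts$n_total > 0, , drop = FALSE]
  if (length(unique(counts$level)) < 2)
    stop("need data at >= 2 distinct levels")
  med <- stats::median(counts$level)
  starts <- list(c(log(med), log(med), 0.02),
                 c(log(med / 2), log(med), 0.01),
                 c(log(med * 1.5), log(med * 2), 0.05))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      optim(s, .psy_negll, counts = counts, method = "L-BFGS-B",
            lower = c(log(min(counts$level)) - 6, log(min(counts$level)) - 4, 0),
            upper = c(log(max(counts$level)) + 4, log(max(counts$level)) + 4, 0.49),
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("psychometric fit failed from all starting points")
  par <- best$par
  params <- psychometric_params(exp(par[1]), exp(par[2]), max(par[3], 0))
  p_hat <- psych_fun(counts$level, params)
  dev <- binom_deviance(counts$n_correct, counts$n_total, p_hat)
  boundary <- character(0)
  if (par[3] < 1e-6) boundary <- c(boundary, "lapse_at_zero")
  if (all(counts$n_correct == counts$n_total))
    boundary <- c(boundary, "all_correct")
  if (all(counts$n_correct == 0)) boundary <- c(boundary, "all_incorrect")
  if (params$threshold < min(counts$level))
    boundary <- c(boundary, "threshold_below_levels")
  # Wald intervals on the optimization scale
  H <- tryCatch(optimHess(par, .psy_negll, counts = counts),
                error = function(e) NULL)
  se <- rep(NA_real_, 3)
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V) && all(diag(V) > 0)) se <- sqrt(diag(V))
  }
  z <- qnorm(0.975)
  ci <- rbind(
    lower = c(exp(par[1] - z * se[1]), exp(par[2] - z * se[2]),
              max(0, par[3] - z * se[3])),
    upper = c(exp(par[1] + z * se[1]), exp(par[2] + z * se[2]),
              min(0.5, par[3] + z * se[3])))
  colnames(ci) <- c("threshold", "width", "lapse")
  structure(list(params = params, threshold_75 = threshold_75(params),
                 ci = ci, deviance = dev, converged = best$convergence == 0,
                 boundary = boundary, design = design, counts = counts),
            class = "psychometric_fit")
}

#' Parametric-bootstrap goodness-of-fit
#'
#' Compares the observed binomial deviance to the distribution of deviances
#' of `n_boot` datasets simulated from the fitted curve (each scored against
#' that same curve); the fit passes when the observed deviance does not
#' exceed the 95th percentile of the bootstrap distribution.
#'
#' @param fit a [fit_psychometric()] result.
#' @param counts the observed counts the fit was computed from.
#' @param n_boot bootstrap sample size (default 10000).
#' @param seed integer seed.
#' @param percentile pass criterion percentile (default 0.95).
#' @return list with `pass`, `observed_deviance`, `critical`, `boot_deviances`.
#' @export
goodness_of_fit <- function(fit, counts = fit$counts, n_boot = 10000,
                            seed = 1L, percentile = 0.95) {
  stopifnot(inherits(fit, "psychometric_fit"))
  if (n_boot < 100)
    warning("n_boot < 100: bootstrap percentile will be unstable")
  set.seed(seed)
  p_hat <- psych_fun(counts$level, fit$params)
  obs <- binom_deviance(counts$n_correct, counts$n_total, p_hat)
  L <- length(counts$level)
  sims <- matrix(rbinom(L * n_boot, rep(counts$n_total, n_boot),
                        rep(p_hat, n_boot)), nrow = L)
  boot <- vapply(seq_len(n_boot), function(i)
    binom_deviance(sims[, i], counts$n_total, p_hat), numeric(1))
  crit <- as.numeric(quantile(boot, percentile, type = 7))
  list(pass = obs <= crit, observed_deviance = obs, critical = crit,
       boot_deviances = boot)
}
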