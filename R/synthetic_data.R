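#' Synthetic cohorts, observers, and envelope pairs
#'
#' Generators that reproduce the statistical structure the downstream
#' analysis assumes: per-participant relative difference thresholds that are
#' log-normal around a group-level location (constant up to a group-specific
#' onset rate, then increasing linearly per grid step), simulated 2IFC
#' observers with Weibull psychometric functions, and stimulus/produced
#' envelope pairs at the syllable rate whose phase-locking degrades with a
#' controllable per-cycle phase jitter.
#'
#' @name synthetic_data
NULL

MODEL_FAMILIES <- c("null", "group_baseline", "increase",
                    "increase_group_baseline", "increase_group_slope")

#' Generative specification for a synthetic threshold cohort
#'
#' @param family one of `"null"`, `"group_baseline"`, `"increase"`,
#'   `"increase_group_baseline"`, `"increase_group_slope"`.
#' @param mu_high,mu_low baseline relative thresholds (proportions) for high
#'   (group 1) and low (group 2) synchronizers. Families without a group
#'   baseline difference require them equal.
#' @param beta_high,beta_low per-grid-step slope of the threshold increase;
#'   families without a slope difference require them equal, non-increase
#'   families require 0.
#' @param onset_high,onset_low rate-grid index (2..8) of the first elevated
#'   rate, or `NA` for non-increase families. Index 1 (4 Hz) can never be
#'   elevated.
#' @param sigma2 log-scale variance of the thresholds.
#' @param n_high,n_low participant counts (defaults 35 and 20, the cohort the
#'   analysis was designed around).
#' @return object of class `generative_spec`.
#' @export
generative_spec <- function(family = "increase",
                            mu_high = 0.0448, mu_low = mu_high,
                            beta_high = 0.0144, beta_low = beta_high,
                            onset_high = 6L, onset_low = 4L,
                            sigma2 = 0.25, n_high = 35L, n_low = 20L) {
  family <- match.arg(family, MODEL_FAMILIES)
  has_increase <- family %in% c("increase", "increase_group_baseline",
                                "increase_group_slope")
  num <- c(mu_high = mu_high, mu_low = mu_low, beta_high = beta_high,
           beta_low = beta_low, sigma2 = sigma2)
  for (nm in names(num)) {
    if (!is.numeric(num[[nm]]) || is.na(num[[nm]]) || num[[nm]] < 0)
      stop(sprintf("'%s' must be a non-negative number", nm))
  }
  if (!has_increase) {
    if (beta_high != 0 || beta_low != 0)
      stop("'beta_high'/'beta_low' must be 0 for non-increase families")
    onset_high <- onset_low <- NA_integer_
  } else {
    for (nm in c("onset_high", "onset_low")) {
      v <- get(nm)
      if (is.na(v) || v < 2 || v > 8 || v != round(v))
        stop(sprintf("'%s' must be an integer in 2..8", nm))
    }
  }
  if (family %in% c("null", "increase", "increase_group_slope") &&
      mu_high != mu_low)
    stop("'mu_high' and 'mu_low' must be equal for families without a group baseline difference")
  if (family != "increase_group_slope" && beta_high != beta_low)
    stop("'beta_high' and 'beta_low' must be equal for families without a group slope difference")
  structure(list(family = family, mu_high = mu_high, mu_low = mu_low,
                 beta_high = beta_high, beta_low = beta_low,
                 onset_high = as.integer(onset_high),
                 onset_low = as.integer(onset_low),
                 sigma2 = sigma2, n_high = as.integer(n_high),
                 n_low = as.integer(n_low)),
            class = "generative_spec")
}

#' Draw a synthetic threshold cohort
#'
#' One record per participant x standard rate. The threshold of a participant
#' in group j at rate index r is LogNormal with location
#' `log(mu_j + x_j[r] * beta_j)` (x_j the group's onset indicator vector) and
#' log-scale variance `sigma2`.
#'
#' @param spec a [generative_spec()].
#' @param seed integer seed.
#' @return data.frame (a `ThresholdTable`) with columns participant_id,
#'   group (`"high"`/`"low"`), rate_hz, rate_index, threshold.
#' @export
draw_threshold_dataset <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "generative_spec"))
  set.seed(seed)
  grid <- rate_grid()
  x_high <- if (is.na(spec$onset_high)) rep(0, 8) else indicator_vector(spec$onset_high)
  x_low <- if (is.na(spec$onset_low)) rep(0, 8) else indicator_vector(spec$onset_low)
  med_high <- spec$mu_high + x_high * spec$beta_high
  med_low <- spec$mu_low + x_low * spec$beta_low
  sdlog <- sqrt(spec$sigma2)
  one_group <- function(n, med, group, id0) {
    if (n == 0) return(NULL)
    data.frame(
      participant_id = rep(sprintf("P%03d", id0 + seq_len(n)), each = 8),
      group = group,
      rate_hz = rep(grid$rates, n),
      rate_index = rep(1:8, n),
      threshold = rlnorm(8 * n, meanlog = rep(log(med), n), sdlog = sdlog))
  }
  out <- rbind(one_group(spec$n_high, med_high, "high", 0L),
               one_group(spec$n_low, med_low, "low", spec$n_high))
  rownames(out) <- NULL
  out
}

#' Simulated 2IFC observer
#'
#' An observer whose probability of a correct response at relative difference
#' d follows the package's Weibull psychometric function; with `lapse = 0`
#' the probability equals 0.75 exactly at `d = true_threshold_75`.
#'
#' @param true_threshold_75 relative difference producing 75% correct when
#'   lapse = 0 (proportion, > 0).
#' @param width psychometric width (> 0); defaults to the threshold itself,
#'   a realistically shallow slope.
#' @param lapse lapse probability in `[0, 0.5)`.
#' @return object of class `observer_model`.
#' @export
make_observer <- function(true_threshold_75, width = true_threshold_75,
                          lapse = 0) {
  params <- psychometric_params(true_threshold_75, width, lapse)
  structure(list(true_threshold_75 = true_threshold_75, params = params),
            class = "observer_model")
}

#' Observer response probability
#' @param observer an [make_observer()] object.
#' @param d relative difference(s), `>= 0`.
#' @export
observer_p_correct <- function(observer, d) {
  stopifnot(inherits(observer, "observer_model"))
  psych_fun(d, observer$params)
}

#' Render an isochronous pure-tone sequence
#'
#' Concatenates 15-ms 440-Hz pure tones with 5-ms linear rise/fall ramps at
#' inter-onset interval 1/rate; the waveform is peak-normalized.
#'
#' @param rate presentation rate in Hz; must leave the inter-onset interval
#'   at least one tone duration (rate <= ~66.7 Hz).
#' @param n_tones number of tones (5 or 7 in the discrimination task).
#' @param fs sampling rate in Hz (default 44100).
#' @return numeric waveform with attributes `fs` and `duration_s`.
#' @export
render_tone_sequence <- function(rate, n_tones, fs = 44100) {
  tone_dur <- 0.015
  if (1 / rate < tone_dur)
    stop("rate too high: tones would overlap (inter-onset interval < 15 ms)")
  ramp <- 0.005
  n_tone <- round(tone_dur * fs)
  t <- (seq_len(n_tone) - 1) / fs
  env <- pmin(1, pmin(t / ramp, (tone_dur - t) / ramp))
  tone <- sin(2 * pi * 440 * t) * env
  dur <- (n_tones - 1) / rate + tone_dur
  wave <- numeric(ceiling(dur * fs))
  for (i in seq_len(n_tones)) {
    i0 <- round((i - 1) / rate * fs)
    wave[i0 + seq_len(n_tone)] <- wave[i0 + seq_len(n_tone)] + tone
  }
  wave <- wave / max(abs(wave))
  attr(wave, "fs") <- fs
  attr(wave, "duration_s") <- dur
  wave
}

#' Synthetic stimulus/produced envelope pair
#'
#' The stimulus envelope is a smoothed periodic pulse train (one Gaussian
#' bump per syllable) at `syllable_rate`; the produced envelope is the same
#' train with independent per-cycle phase perturbations (standard deviation
#' `phase_jitter_sd` radians, non-cumulative, so the mean PLV decreases
#' monotonically with the jitter). With `progressive_rate = TRUE` the rate
#' sweeps 4.3-4.7 Hz in 0.1-Hz steps every 60 syllables instead of staying
#' fixed, mirroring the real syllable train.
#'
#' @param duration_s signal duration in seconds (>= 15, i.e. at least two
#'   analysis windows).
#' @param syllable_rate mean syllable rate in Hz; rates outside the 3.5-5.5
#'   Hz analysis band trigger a warning (the PLV band-pass would remove the
#'   signal).
#' @param phase_jitter_sd per-cycle phase jitter SD in radians (>= 0).
#' @param seed integer seed.
#' @param fs envelope sampling rate in Hz (default 200).
#' @param progressive_rate logical, default FALSE.
#' @return object of class `sync_signal_pair` with elements
#'   `stimulus_envelope`, `produced_envelope`, `sample_rate`,
#'   `true_phase_jitter_sd`.
#' @export
synth_sync_pair <- function(duration_s = 70, syllable_rate = 4.5,
                            phase_jitter_sd = 0, seed = 1L, fs = 200,
                            progressive_rate = FALSE) {
  if (duration_s < 15)
    stop("duration_s must be >= 15 s (at least two analysis windows)")
  if (syllable_rate < 3.5 || syllable_rate > 5.5)
    warning("syllable_rate outside the 3.5-5.5 Hz analysis band; PLV will be meaningless")
  if (phase_jitter_sd < 0) stop("phase_jitter_sd must be >= 0")
  set.seed(seed)
  if (progressive_rate) {
    rates <- rep(seq(syllable_rate - 0.2, syllable_rate + 0.2, by = 0.1),
                 each = 60)
    iois <- 1 / rates
    onsets <- cumsum(c(0, iois))
    onsets <- onsets[onsets < duration_s - 0.1]
  } else {
    onsets <- seq(0, duration_s - 0.1, by = 1 / syllable_rate)
  }
  jitter_t <- rnorm(length(onsets), 0, phase_jitter_sd) / (2 * pi * syllable_rate)
  bump_sd <- 0.025
  n <- round(duration_s * fs)
  tt <- (seq_len(n) - 1) / fs
  train <- function(on) {
    env <- numeric(n)
    for (o in on) env <- env + exp(-0.5 * ((tt - o) / bump_sd)^2)
    env
  }
  structure(list(stimulus_envelope = train(onsets),
                 produced_envelope = train(onsets + jitter_t),
                 sample_rate = fs,
                 true_phase_jitter_sd = phase_jitter_sd),
            class = "sync_signal_pair")
}

# Calibration table mapping per-cycle phase jitter (radians) to the mean
# windowed PLV of synth_sync_pair at the default 70 s / 4.5 Hz settings,
# measured once by simulation (10 seeds per point) and frozen; see the
# methods vignette. Monotone decreasing, interpolated linearly.
.jitter_plv_table <- function() {
  data.frame(
    jitter = c(0, 0.25, 0.5, 0.75, 1, 1.25, 1.5, 2, 2.5),
    plv = c(1, 0.989, 0.957, 0.903, 0.803, 0.659, 0.505, 0.317, 0.275))
}

#' Per-cycle jitter needed to reach a target mean PLV
#'
#' Inverts the generator's frozen jitter-to-PLV calibration curve by linear
#' interpolation. Targets above the achievable maximum map to 0 jitter;
#' targets at or below the chance floor of the windowed PLV map to the
#' largest calibrated jitter.
#'
#' @param target_plv desired mean PLV in (0, 1].
#' @return jitter SD in radians.
#' @export
jitter_for_plv <- function(target_plv) {
  tab <- .jitter_plv_table()
  target_plv <- pmin(pmax(target_plv, min(tab$plv) + 1e-6), max(tab$plv))
  approx(rev(tab$plv), rev(tab$jitter), xout = target_plv)$y
}

#' Simulate a cohort of synchronization measurements
#'
#' Draws a per-participant target PLV from the group's normal distribution
#' (defaults: high synchronizers 0.74, SD 0.10; low synchronizers 0.34, SD
#' 0.12), converts it to a per-cycle jitter through the generator's
#' calibration curve, and synthesizes one envelope pair per run.
#'
#' @param n_high,n_low participants per group.
#' @param plv_high,plv_low group mean target PLVs.
#' @param sd_high,sd_low group SDs of the target PLVs.
#' @param n_runs runs (blocks) per participant, default 2.
#' @param duration_s,syllable_rate passed to [synth_sync_pair()].
#' @param seed integer seed.
#' @return data.frame with participant_id, group, run, jitter_sd, plv, and
#'   the per-participant mean PLV across runs in `mean_plv`.
#' @export
simulate_sync_cohort <- function(n_high = 35, n_low = 20,
                                 plv_high = 0.74, plv_low = 0.34,
                                 sd_high = 0.10, sd_low = 0.12,
                                 n_runs = 2, duration_s = 70,
                                 syllable_rate = 4.5, seed = 1L) {
  set.seed(seed)
  n <- n_high + n_low
  group <- rep(c("high", "low"), c(n_high, n_low))
  target <- c(rnorm(n_high, plv_high, sd_high), rnorm(n_low, plv_low, sd_low))
  target <- pmin(pmax(target, 0.05), 0.999)
  jit <- jitter_for_plv(target)
  seeds <- sample.int(2^30, n * n_runs)
  rows <- vector("list", n * n_runs)
  k <- 0
  for (i in seq_len(n)) {
    for (r in seq_len(n_runs)) {
      k <- k + 1
      pair <- synth_sync_pair(duration_s, syllable_rate, jit[i],
                              seed = seeds[k])
      res <- windowed_plv(
        phase_series(pair$stimulus_envelope, pair$sample_rate),
        phase_series(pair$produced_envelope, pair$sample_rate))
      rows[[k]] <- data.frame(participant_id = sprintf("P%03d", i),
                              group = group[i], run = r,
                              jitter_sd = jit[i], plv = res$mean_plv)
    }
  }
  out <- do.call(rbind, rows)
  mp <- tapply(out$plv, out$participant_id, mean)
  out$mean_plv <- as.numeric(mp[out$participant_id])
  out
}
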