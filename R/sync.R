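#' Envelope phase-locking and synchronizer clustering
#'
#' Quantifies auditory-motor speech synchronization as the phase-locking
#' value (PLV) between the phase series of the stimulus envelope and of the
#' produced-speech envelope. Phases are obtained by resampling both envelopes
#' to 100 Hz, zero-phase band-pass filtering at 3.5-5.5 Hz around the
#' syllable rate, and taking the analytic-signal angle. PLVs are computed in
#' 5-s windows with 2-s overlap and averaged; participants are split into
#' high and low synchronizers by 2-means clustering of their mean PLVs.
#'
#' @name sync
NULL

# analytic signal via the FFT construction (doubled positive frequencies)
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase series of an envelope
#'
#' Resamples to `resample_rate`, band-pass filters (zero-phase 4th-order
#' Butterworth applied forward-backward), and takes the analytic-signal
#' angle. One `edge_trim_s` of samples at each end (filter settling) is
#' excluded from the returned phases. Inputs whose in-band power is a
#' negligible fraction of total power trigger a low-power warning (the
#' phases are then meaningless).
#'
#' @param envelope non-negative amplitude series.
#' @param fs sampling rate of `envelope` in Hz.
#' @param band band-pass edges in Hz (default `c(3.5, 5.5)`).
#' @param resample_rate target rate in Hz (default 100).
#' @param edge_trim_s seconds discarded at each end (default 1).
#' @return object of class `phase_series`: list with `phases` (radians in
#'   (-pi, pi]), `sample_rate`, `band`.
#' @export
phase_series <- function(envelope, fs, band = c(3.5, 5.5),
                         resample_rate = 100, edge_trim_s = 1) {
  if (length(envelope) / fs < 5 + 2 * edge_trim_s)
    stop("envelope too short: need at least one 5-s window after edge trimming")
  x <- as.numeric(envelope)
  unmodulated <- stats::var(x) <= 1e-12 * (mean(x)^2 + 1e-12)
  if (fs != resample_rate) {
    # mirror-pad 1 s per side: resample assumes zeros outside the signal
    # and would otherwise inject large edge transients
    pad <- round(fs)
    xp <- c(rev(x[seq_len(pad) + 1]), x, rev(x[length(x) - seq_len(pad)]))
    xp <- signal::resample(xp, p = resample_rate, q = fs)
    cut <- round(pad * resample_rate / fs)
    x <- xp[(cut + 1):(length(xp) - cut)]
  }
  x <- x - mean(x)
  bf <- signal::butter(4, band / (resample_rate / 2), type = "pass")
  xf <- signal::filtfilt(bf, x)
  if (unmodulated || stats::var(xf) <= 1e-8 * max(stats::var(x), 1e-12))
    warning("negligible power in the analysis band: phases are meaningless")
  ph <- Arg(analytic_signal(xf))
  trim <- round(edge_trim_s * resample_rate)
  if (trim > 0) ph <- ph[(trim + 1):(length(ph) - trim)]
  structure(list(phases = ph, sample_rate = resample_rate, band = band),
            class = "phase_series")
}

phases_of <- function(x) {
  if (inherits(x, "phase_series")) x$phases else as.numeric(x)
}

#' Phase-locking value of two phase series
#'
#' `|mean(exp(i (phi_a - phi_b)))|`: 1 for perfectly locked series (invariant
#' under any constant phase offset), near 0 for independent phases.
#'
#' @param a,b phase series (`phase_series` objects or numeric radians) of
#'   equal length.
#' @return scalar in `[0, 1]`.
#' @export
plv <- function(a, b) {
  pa <- phases_of(a); pb <- phases_of(b)
  if (length(pa) != length(pb)) stop("phase series lengths differ")
  Mod(mean(exp(1i * (pa - pb))))
}

#' Windowed PLV between two phase series
#'
#' PLV per 5-s window with consecutive windows sharing 2 s (hop 3 s), plus
#' their arithmetic mean.
#'
#' @param a,b phase series of equal length.
#' @param window_s window length in seconds (default 5).
#' @param overlap_s overlap between consecutive windows (default 2).
#' @param sample_rate sampling rate; taken from `a` when it is a
#'   `phase_series`.
#' @return object of class `plv_result`: list with `window_plvs`, `mean_plv`,
#'   `window_s`, `overlap_s`.
#' @export
windowed_plv <- function(a, b, window_s = 5, overlap_s = 2,
                         sample_rate = NULL) {
  if (is.null(sample_rate)) {
    if (!inherits(a, "phase_series"))
      stop("sample_rate required when 'a' is a bare numeric series")
    sample_rate <- a$sample_rate
  }
  pa <- phases_of(a); pb <- phases_of(b)
  if (length(pa) != length(pb)) stop("phase series lengths differ")
  wl <- round(window_s * sample_rate)
  hop <- round((window_s - overlap_s) * sample_rate)
  if (length(pa) < wl) stop("series shorter than one window")
  starts <- seq(1, length(pa) - wl + 1, by = hop)
  wp <- vapply(starts, function(s) {
    idx <- s:(s + wl - 1)
    Mod(mean(exp(1i * (pa[idx] - pb[idx]))))
  }, numeric(1))
  structure(list(window_plvs = wp, mean_plv = mean(wp),
                 window_s = window_s, overlap_s = overlap_s),
            class = "plv_result")
}

#' Cluster participants into high and low synchronizers
#'
#' 2-means clustering of scalar mean PLVs with many random restarts; the
#' cluster with the larger centroid is labelled "high". Participants whose
#' assignment varies across independent restarts (an inherent instability of
#' k-means for points near the midpoint) are reported in `unstable`.
#'
#' @param mean_plvs numeric vector, one mean PLV per participant.
#' @param seed integer seed.
#' @param nstart random restarts for the final fit (default 50).
#' @param n_stability independent single-start refits used to probe
#'   assignment stability (default 100).
#' @return object of class `cluster_result`: list with `labels`
#'   (`"high"`/`"low"`), `centroids` (named, high then low), `unstable`
#'   (indices), `sizes`.
#' @export
cluster_synchronizers <- function(mean_plvs, seed = 1L, nstart = 50,
                                  n_stability = 100) {
  x <- as.numeric(mean_plvs)
  if (length(x) < 2) stop("need at least 2 participants")
  if (length(unique(x)) < 2) stop("all mean PLVs identical: clustering undefined")
  set.seed(seed)
  km <- stats::kmeans(x, centers = 2, nstart = nstart)
  hi <- which.max(km$centers)
  labels <- ifelse(km$cluster == hi, "high", "low")
  # stability probe: single-start refits from random seeds
  base <- labels
  varies <- rep(FALSE, length(x))
  for (i in seq_len(n_stability)) {
    km_i <- stats::kmeans(x, centers = 2, nstart = 1)
    lab_i <- ifelse(km_i$cluster == which.max(km_i$centers), "high", "low")
    varies <- varies | (lab_i != base)
  }
  structure(list(labels = labels,
                 centroids = c(high = max(km$centers), low = min(km$centers)),
                 unstable = which(varies),
                 sizes = c(high = sum(labels == "high"),
                           low = sum(labels == "low"))),
            class = "cluster_result")
}

#' Flag run-inconsistent participants
#'
#' A participant's two runs are flagged as inconsistent when their run PLVs
#' straddle the midpoint between the two cluster centroids (a declared
#' convention; flagged, never auto-excluded).
#'
#' @param run_plvs data.frame with columns participant_id and plv (two rows
#'   per participant).
#' @param clusters a [cluster_synchronizers()] result.
#' @return character vector of flagged participant ids.
#' @export
flag_inconsistent_runs <- function(run_plvs, clusters) {
  mid <- mean(clusters$centroids)
  split_ids <- tapply(run_plvs$plv, run_plvs$participant_id, function(v)
    length(v) >= 2 && min(v) < mid && max(v) > mid)
  names(split_ids)[which(split_ids)]
}
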