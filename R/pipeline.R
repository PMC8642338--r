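#' End-to-end cohort pipeline
#'
#' Orchestrates simulate -> measure -> cluster -> compare: draws a synthetic
#' cohort of true thresholds, measures each with the weighted up-down
#' staircase, optionally validates two rates with the constant-stimuli
#' procedure, computes synchronization PLVs and clusters participants,
#' applies the median +/- 3 MAD exclusion rule, runs the 149-model Bayesian
#' comparison, and reports group-demeaned correlations.
#'
#' @name pipeline
NULL

#' Median absolute deviation outlier filter
#'
#' Excludes a value iff |value - median| > 3 MAD, with the MAD scaled by the
#' 1.4826 normal-consistency constant. The inequality is strict: a value at
#' exactly median + 3 MAD is kept. When all values are identical (MAD = 0)
#' nothing is excluded and a warning is issued.
#'
#' @param values per-participant mean thresholds (length >= 3).
#' @return list with logical `keep`, `median`, `mad` (scaled), `mad_raw`.
#' @export
mad_outlier_filter <- function(values) {
  if (length(values) < 3) stop("need at least 3 values")
  med <- stats::median(values)
  mad_scaled <- stats::mad(values)           # constant = 1.4826
  mad_raw <- stats::mad(values, constant = 1)
  if (mad_scaled == 0)
    warning("MAD is zero (majority of values identical): ",
            "any deviation from the median is flagged")
  keep <- abs(values - med) <= 3 * mad_scaled
  list(keep = keep, median = med, mad = mad_scaled, mad_raw = mad_raw)
}

#' Express a relative threshold as a fraction of the oscillatory cycle
#'
#' A relative rate difference d (faster comparison) corresponds to a period
#' difference of d/(1+d) of the standard period; in milliseconds that is
#' `d/(1+d) * 1000/rate`.
#'
#' @param d relative difference threshold(s), `>= 0`.
#' @param rate standard rate(s) in Hz, `> 0`.
#' @return data.frame with `fraction` and `ms`.
#' @export
cycle_fraction <- function(d, rate) {
  stopifnot(all(d >= 0), all(rate > 0))
  frac <- d / (1 + d)
  data.frame(fraction = frac, ms = frac * 1000 / rate)
}

#' Group-demeaned Spearman correlation
#'
#' Subtracts each cluster's mean from both variables before rank correlation,
#' controlling for the spurious correlation induced by a bimodal grouping.
#' With a covariate, computes the partial rank correlation by correlating the
#' residuals of the (demeaned) ranks after regressing out the covariate's
#' ranks. p-values use the large-sample t approximation; for fewer than
#' `exact_below` pairs an exact permutation p is computed instead.
#'
#' @param x,y numeric vectors.
#' @param group_labels cluster labels, same length.
#' @param covariate optional numeric covariate (e.g. musical sophistication).
#' @param exact_below sample size below which a permutation p-value is used
#'   (default 30; permutations are Monte-Carlo with 20000 draws).
#' @param seed seed for the permutation p-value.
#' @return list with `rho`, `p`, `n`, `method`.
#' @export
demeaned_spearman <- function(x, y, group_labels, covariate = NULL,
                              exact_below = 30, seed = 1L) {
  ok <- stats::complete.cases(x, y, group_labels,
                              if (is.null(covariate)) x else covariate)
  x <- x[ok]; y <- y[ok]; g <- group_labels[ok]
  if (!is.null(covariate)) covariate <- covariate[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 paired observations")
  dm <- function(v) v - ave(v, g)
  xd <- dm(x); yd <- dm(y)
  if (sd(xd) == 0 || sd(yd) == 0)
    stop("a variable is constant after group demeaning")
  rho_of <- function(a, b) {
    ra <- rank(a); rb <- rank(b)
    if (!is.null(covariate)) {
      rc <- rank(dm(covariate))
      ra <- resid(lm(ra ~ rc)); rb <- resid(lm(rb ~ rc))
    }
    suppressWarnings(cor(ra, rb))
  }
  rho <- rho_of(xd, yd)
  if (n < exact_below) {
    set.seed(seed)
    perm <- replicate(20000, rho_of(xd, sample(yd)))
    p <- (sum(abs(perm) >= abs(rho) - 1e-12) + 1) / (length(perm) + 1)
    method <- "permutation"
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tt), n - 2)
    method <- "t-approximation"
  }
  list(rho = rho, p = p, n = n, method = method)
}

#' Default full-pipeline configuration
#'
#' @param seed master seed; every random stage derives its own seed from it.
#' @param cohort a [generative_spec()].
#' @param observer_width_factor width of each simulated observer's
#'   psychometric function as a multiple of its true threshold (default 1).
#' @param observer_lapse constant lapse rate of simulated observers.
#' @param run_cs run the constant-stimuli validation at 4 and 11.86 Hz.
#' @param cs_n_boot bootstrap samples for the CS goodness-of-fit.
#' @param sync_duration_s duration of the synthetic syllable trains.
#' @param model_method marginal-likelihood backend for the comparison.
#' @export
pipeline_config <- function(seed = 1L, cohort = generative_spec(),
                            observer_width_factor = 1,
                            observer_lapse = 0.02,
                            run_cs = FALSE, cs_n_boot = 1000,
                            sync_duration_s = 70,
                            model_method = "quadrature") {
  list(seed = as.integer(seed), cohort = cohort,
       observer_width_factor = observer_width_factor,
       observer_lapse = observer_lapse, run_cs = run_cs,
       cs_n_boot = cs_n_boot, sync_duration_s = sync_duration_s,
       model_method = model_method)
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror [pipeline_config()] arguments; the `cohort` key
#' holds [generative_spec()] arguments.
#'
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort <- do.call(generative_spec, y$cohort %||% list())
  y$cohort <- NULL
  do.call(pipeline_config, c(y, list(cohort = cohort)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Measure a cohort's thresholds with the staircase procedure
#'
#' Turns each true threshold into a simulated Weibull observer and runs one
#' weighted up-down staircase per participant x rate, using the rate's
#' prescribed start value.
#'
#' @param truth a ThresholdTable of true 75%-correct thresholds.
#' @param seed integer seed.
#' @param width_factor,lapse observer parameters (see [pipeline_config()]).
#' @return the table with a `measured_threshold` column appended.
#' @export
measure_cohort_staircase <- function(truth, seed = 1L, width_factor = 1,
                                     lapse = 0.02) {
  sv <- start_values()
  set.seed(seed)
  seeds <- sample.int(2^30, nrow(truth))
  truth$measured_threshold <- vapply(seq_len(nrow(truth)), function(i) {
    obs <- make_observer(truth$threshold[i],
                         width = width_factor * truth$threshold[i],
                         lapse = lapse)
    cfg <- staircase_config(start_value = sv[truth$rate_index[i]])
    run_staircase(obs, cfg, seed = seeds[i],
                  rate_hz = truth$rate_hz[i])$threshold
  }, numeric(1))
  truth
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' @param config a [pipeline_config()] list.
#' @return object of class `cohort_report`: list with `thresholds` (true and
#'   measured), `sync` (per-run PLVs), `clusters`, `exclusions`,
#'   `model_comparison`, `best_model_parameters`, `correlations`, `seeds`.
#' @export
run_full_pipeline <- function(config = pipeline_config()) {
  set.seed(config$seed)
  seeds <- setNames(as.list(sample.int(2^30, 6)),
                    c("cohort", "staircase", "cs", "sync", "cluster", "model"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  truth <- stage("simulate", draw_threshold_dataset(config$cohort,
                                                    seed = seeds$cohort))
  meas <- stage("staircase", measure_cohort_staircase(
    truth, seed = seeds$staircase,
    width_factor = config$observer_width_factor,
    lapse = config$observer_lapse))

  cs <- NULL
  if (isTRUE(config$run_cs)) {
    cs <- stage("constant_stimuli", {
      rates <- c(1L, 6L)   # 4 and 11.86 Hz
      sub <- meas[meas$rate_index %in% rates, ]
      set.seed(seeds$cs)
      cs_seeds <- sample.int(2^30, nrow(sub))
      rows <- lapply(seq_len(nrow(sub)), function(i) {
        obs <- make_observer(sub$threshold[i],
                             width = config$observer_width_factor *
                               sub$threshold[i],
                             lapse = config$observer_lapse)
        des <- cs_design(sub$rate_hz[i],
                         comparison_levels(sub$measured_threshold[i]))
        counts <- simulate_cs_run(obs, des, seed = cs_seeds[i])
        fit <- fit_psychometric(counts, des)
        gof <- goodness_of_fit(fit, counts, n_boot = config$cs_n_boot,
                               seed = cs_seeds[i])
        data.frame(participant_id = sub$participant_id[i],
                   rate_hz = sub$rate_hz[i],
                   cs_threshold = fit$threshold_75,
                   lapse = fit$params$lapse, gof_pass = gof$pass)
      })
      do.call(rbind, rows)
    })
  }

  sync <- stage("sync", simulate_sync_cohort(
    n_high = config$cohort$n_high, n_low = config$cohort$n_low,
    duration_s = config$sync_duration_s, seed = seeds$sync))
  per_part <- unique(sync[, c("participant_id", "group", "mean_plv")])
  clusters <- stage("cluster", cluster_synchronizers(per_part$mean_plv,
                                                     seed = seeds$cluster))
  per_part$cluster <- clusters$labels
  inconsistent <- flag_inconsistent_runs(sync, clusters)

  # exclusion: per-participant mean measured threshold, median +/- 3 MAD
  part_mean <- tapply(meas$measured_threshold, meas$participant_id, mean)
  filt <- mad_outlier_filter(as.numeric(part_mean))
  excl <- data.frame(participant_id = names(part_mean),
                     mean_threshold = as.numeric(part_mean),
                     keep = filt$keep,
                     reason = ifelse(filt$keep, "",
                                     "threshold_outlier_3mad"))
  keep_ids <- excl$participant_id[excl$keep]

  table_in <- meas[meas$participant_id %in% keep_ids, ]
  # analysis grouping comes from the recovered clusters, as in the protocol
  cl_map <- setNames(per_part$cluster, per_part$participant_id)
  table_in$group <- unname(cl_map[table_in$participant_id])
  table_in$threshold_true <- table_in$threshold
  table_in$threshold <- table_in$measured_threshold

  comp <- stage("model_comparison", compare_models(
    table_in, method = config$model_method, seed = seeds$model))
  best_spec <- model_spec(comp$best$family, comp$best$onset_high,
                          comp$best$onset_low, id = comp$best$id)
  pars <- stage("parameters", fit_parameters(table_in, best_spec,
                                             method = config$model_method,
                                             seed = seeds$model))

  wud_mean <- tapply(table_in$threshold, table_in$participant_id, mean)
  pp <- per_part[match(names(wud_mean), per_part$participant_id), ]
  correlations <- list(
    wud_vs_plv = demeaned_spearman(as.numeric(wud_mean), pp$mean_plv,
                                   pp$cluster))

  structure(list(thresholds = meas, constant_stimuli = cs, sync = sync,
                 clusters = clusters, inconsistent_runs = inconsistent,
                 exclusions = excl, model_comparison = comp,
                 best_model_parameters = pars, correlations = correlations,
                 seeds = seeds, config = config),
            class = "cohort_report")
}
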