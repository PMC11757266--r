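#' Configuration for the synthetic intraoperative cohort generator
#'
#' Defines the study conditions emulated by the generator: a cohort of
#' patients whose mean arterial pressure follows a baseline plus a
#' mean-reverting (discretized Ornstein-Uhlenbeck) fluctuation, an optional
#' slow oscillatory component, and episodic hypotensive/hypertensive
#' excursions; SBP/DBP are reconstructed around MAP with a physiologic
#' pulse pressure, HR and pulse are correlated channels, points drop out
#' independently (never more than two in a row, so no gap exceeds 10
#' minutes), and the prolonged-length-of-stay outcome follows a logistic
#' model on standardized true feature values with known coefficients.
#'
#' @param n_patients cohort size (>= 2).
#' @param series_len_range integer range of grid points per surgery.
#' @param grid_minutes sampling interval, minutes.
#' @param baseline_map_mean,baseline_map_sd baseline MAP distribution, mmHg.
#' @param ou_theta mean-reversion rate of the MAP fluctuation, 1/min.
#' @param theta_logsd log-scale SD of per-patient heterogeneity in
#'   `ou_theta`; 0 disables heterogeneity. Larger values spread the
#'   autocorrelation (hence entropy/complexity) of traces across patients
#'   while the per-step innovation scale — which drives ARV — stays fixed.
#' @param ou_sigma innovation scale, mmHg per sqrt(min).
#' @param osc_amp_mean mean of the exponentially distributed per-patient
#'   amplitude of a slow MAP oscillation, mmHg; 0 disables it.
#' @param osc_period_min period of the slow oscillation, minutes.
#' @param episode_rate excursion episodes per hour.
#' @param episode_depth_mean,episode_depth_sd episode depth, mmHg.
#' @param p_hyper probability an episode is hypertensive (upward).
#' @param missing_prob per-point dropout probability.
#' @param pulse_pressure_mean mean pulse pressure, mmHg.
#' @param effect_sizes named numeric vector of log-odds coefficients on
#'   standardized true feature values. Names may be manual metric names
#'   (`tw_hypotension`, ...), quantified feature names
#'   (`"map__fft__abs_9"`, ...), or clinical covariate names.
#' @param outcome_intercept log-odds intercept.
#' @param los_median anchor for the length-of-stay distribution, days.
#' @param covariate_specs named list of functions `n -> vector` drawing the
#'   clinical covariates.
#' @param seed master seed; per-patient seeds are derived from it
#'   counter-style, so cohorts are reproducible.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 200L,
                       series_len_range = c(88L, 92L),
                       grid_minutes = 5,
                       baseline_map_mean = 85, baseline_map_sd = 10,
                       ou_theta = 0.05, theta_logsd = 0,
                       ou_sigma = 1.8,
                       osc_amp_mean = 4, osc_period_min = 50,
                       episode_rate = 0.6,
                       episode_depth_mean = 30, episode_depth_sd = 8,
                       p_hyper = 0.25,
                       missing_prob = 0.02,
                       pulse_pressure_mean = 40,
                       effect_sizes = c(tw_hypotension = 1.5,
                                        map__fft__abs_9 = 1.5,
                                        albumin_pre = -0.4,
                                        rbc_units = 0.4),
                       outcome_intercept = 0,
                       los_median = 10,
                       covariate_specs = default_covariate_specs(),
                       seed = 1L) {
  stopifnot(n_patients >= 2, grid_minutes > 0,
            length(series_len_range) == 2L,
            series_len_range[1] >= 4, series_len_range[2] >= series_len_range[1],
            missing_prob >= 0, missing_prob <= 1,
            p_hyper >= 0, p_hyper <= 1,
            episode_depth_mean >= 0, episode_rate >= 0,
            ou_theta > 0, ou_sigma >= 0, osc_amp_mean >= 0,
            baseline_map_mean > 0, los_median >= 1)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Default clinical covariate distributions
#'
#' Age, sex, smoking, pre-operative albumin, post-operative hemoglobin,
#' transfused red-cell units and reoperation flags, with locations chosen
#' to resemble a head-and-neck free-flap surgical population.
#'
#' @return Named list of generator functions, each taking `n`.
#' @export
default_covariate_specs <- function() {
  list(
    age = function(n) round(pmin(85, pmax(18, stats::rnorm(n, 55, 12)))),
    sex = function(n) stats::rbinom(n, 1, 0.7),
    smoking = function(n) stats::rbinom(n, 1, 0.45),
    albumin_pre = function(n) round(stats::rnorm(n, 30.4, 4.5), 1),
    hb_post = function(n) round(stats::rnorm(n, 111, 15)),
    rbc_units = function(n) stats::rpois(n, 0.8),
    reoperation = function(n) stats::rbinom(n, 1, 0.08)
  )
}

patient_seed <- function(master, i) {
  as.integer((as.double(master) * 1000003 + i) %% 2147483629)
}

#' Simulate one patient's intraoperative circulation series
#'
#' @param config a [sim_config()].
#' @param pseed integer seed for this patient.
#' @param patient_id identifier for the series.
#' @return A [circulation_series] with `NA` at dropped points. The
#'   attribute `complete` holds the pre-dropout channel data frame;
#'   `episodes` records the inserted excursions (start, duration, depth,
#'   direction); `latent` records the per-patient latent draws.
#' @export
simulate_series <- function(config, pseed, patient_id = "p1") {
  set.seed(pseed)
  gm <- config$grid_minutes
  n <- if (config$series_len_range[1] == config$series_len_range[2]) {
    config$series_len_range[1]
  } else {
    sample(seq(config$series_len_range[1], config$series_len_range[2]), 1L)
  }
  t <- (seq_len(n) - 1) * gm
  baseline <- stats::rnorm(1, config$baseline_map_mean, config$baseline_map_sd)
  theta <- config$ou_theta * exp(stats::rnorm(1, 0, config$theta_logsd))
  phi <- exp(-theta * gm)
  innov <- stats::rnorm(n - 1, 0, config$ou_sigma * sqrt(gm))
  dev <- numeric(n)
  for (k in 2:n) dev[k] <- phi * dev[k - 1] + innov[k - 1]

  amp <- if (config$osc_amp_mean > 0) stats::rexp(1, 1 / config$osc_amp_mean) else 0
  phase <- stats::runif(1, 0, 2 * pi)
  osc <- amp * sin(2 * pi * t / config$osc_period_min + phase)

  t_total <- t[n]
  n_ep <- if (config$episode_rate > 0) {
    stats::rpois(1, config$episode_rate * t_total / 60)
  } else 0L
  ep <- numeric(n)
  episodes <- data.frame(start = numeric(0), duration = numeric(0),
                         depth = numeric(0), direction = character(0))
  if (n_ep > 0) {
    for (e in seq_len(n_ep)) {
      start <- stats::runif(1, 0, max(t_total - 10, 0))
      dur <- stats::runif(1, 10, 30)
      depth <- abs(stats::rnorm(1, config$episode_depth_mean, config$episode_depth_sd))
      up <- stats::runif(1) < config$p_hyper
      # boxcar with 5-min linear ramps
      prof <- pmax(0, pmin(1, pmin((t - start) / 5, (start + dur - t) / 5)))
      ep <- ep + (if (up) depth else -depth) * prof
      episodes <- rbind(episodes,
                        data.frame(start = start, duration = dur, depth = depth,
                                   direction = if (up) "hyper" else "hypo"))
    }
  }

  map <- pmax(30, baseline + dev + osc + ep)
  pp_i <- stats::rnorm(1, config$pulse_pressure_mean, 6)
  pp <- pmax(15, pp_i + stats::rnorm(n, 0, 3))
  pp <- pmin(pp, 2.9 * map)
  sbp <- map + (2 / 3) * pp
  dbp <- map - (1 / 3) * pp
  hr_base <- stats::rnorm(1, 75, 10)
  hdev <- numeric(n)
  hinnov <- stats::rnorm(n - 1, 0, 2)
  for (k in 2:n) hdev[k] <- 0.8 * hdev[k - 1] + hinnov[k - 1]
  hr <- pmax(30, hr_base + hdev)
  pulse <- hr + stats::rnorm(n, 0, 1)

  complete <- data.frame(t = t, sbp = sbp, dbp = dbp, hr = hr, pulse = pulse)

  drop <- rep(FALSE, n)
  if (config$missing_prob > 0 && n > 2) {
    drop[2:(n - 1)] <- stats::runif(n - 2) < config$missing_prob
    # cap runs at 2 consecutive so no gap exceeds 10 minutes
    run <- 0L
    for (k in seq_len(n)) {
      if (drop[k]) {
        run <- run + 1L
        if (run > 2L) { drop[k] <- FALSE; run <- 0L }
      } else run <- 0L
    }
  }
  ch <- complete
  ch[drop, c("sbp", "dbp", "hr", "pulse")] <- NA_real_
  out <- circulation_series(ch$t, ch$sbp, ch$dbp, ch$hr, ch$pulse,
                            patient_id = patient_id, grid_minutes = gm)
  attr(out, "complete") <- complete
  attr(out, "episodes") <- episodes
  attr(out, "latent") <- list(baseline = baseline, theta = theta, osc_amp = amp)
  out
}

#' Simulate a synthetic cohort with known ground truth
#'
#' Generates covariates, circulation series and a prolonged-length-of-stay
#' (PLOS) outcome whose log-odds are
#' `intercept + sum(effect_sizes * standardized true feature values)`,
#' where true feature values are computed on the complete (pre-dropout)
#' series. Length of stay is anchored at `los_median` days with geometric
#' jitter consistent with the generative label (PLOS = 1 implies
#' `los_days > los_median`).
#'
#' @param config a [sim_config()].
#' @return An object of class `plos_cohort`: a list with `series` (named
#'   list of [circulation_series]), `covariates` (data frame with
#'   `patient_id`, the clinical covariates and `los_days`), `truth` (the
#'   generative ground truth: linear predictor, raw true feature values,
#'   standardization constants, effect sizes, generative labels) and
#'   `config`. Any generation warnings are kept in the `log` attribute.
#' @export
simulate_cohort <- function(config) {
  n <- config$n_patients
  ids <- sprintf("p%04d", seq_len(n))
  run_log <- character(0)

  set.seed(patient_seed(config$seed, 0L))
  cov <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
  for (nm in names(config$covariate_specs)) {
    cov[[nm]] <- config$covariate_specs[[nm]](n)
  }

  series <- lapply(seq_len(n), function(i) {
    simulate_series(config, patient_seed(config$seed, i), patient_id = ids[i])
  })
  names(series) <- ids

  beta <- config$effect_sizes
  truth_raw <- matrix(NA_real_, n, length(beta),
                      dimnames = list(ids, names(beta)))
  for (nm in names(beta)) {
    truth_raw[, nm] <- true_feature_values(nm, series, cov)
  }
  mu <- colMeans(truth_raw)
  sg <- apply(truth_raw, 2L, stats::sd)
  if (any(sg == 0)) {
    run_log <- c(run_log, sprintf("constant true feature(s) dropped from outcome: %s",
                                  paste(names(beta)[sg == 0], collapse = ", ")))
  }
  z <- sweep(sweep(truth_raw, 2L, mu, `-`), 2L, ifelse(sg > 0, sg, 1), `/`)
  z[, sg == 0] <- 0
  lp <- config$outcome_intercept + as.vector(z %*% beta)

  set.seed(patient_seed(config$seed, n + 1L))
  plos <- stats::rbinom(n, 1L, stats::plogis(lp))
  if (n >= 50 && length(unique(plos)) == 1L) {
    run_log <- c(run_log, "degenerate outcome: single PLOS class generated")
    warning("degenerate configuration: single-class PLOS outcome", call. = FALSE)
  }
  med <- config$los_median
  jitter_hi <- stats::rgeom(n, 0.35)
  jitter_lo <- stats::rgeom(n, 0.35)
  cov$los_days <- ifelse(plos == 1L, med + 1 + jitter_hi,
                         pmax(1, med - pmin(jitter_lo, med - 1)))

  truth <- list(lp = stats::setNames(lp, ids),
                features = truth_raw, mean = mu, sd = sg,
                effect_sizes = beta, intercept = config$outcome_intercept,
                plos = stats::setNames(plos, ids))
  structure(list(series = series, covariates = cov, truth = truth,
                 config = config),
            class = "plos_cohort", log = run_log)
}

true_feature_values <- function(nm, series, cov) {
  if (nm %in% names(cov)) return(as.numeric(cov[[nm]]))
  manual <- c("tw_hypotension", "tw_hypertension", "arv_map", "arvs_map")
  vapply(series, function(s) {
    cmp <- attr(s, "complete")
    cs <- circulation_series(cmp$t, cmp$sbp, cmp$dbp, cmp$hr, cmp$pulse,
                             patient_id = attr(s, "patient_id"),
                             grid_minutes = attr(s, "grid_minutes"))
    if (nm %in% manual) {
      manual_metrics(cs)[[nm]]
    } else {
      ch <- sub("__.*$", "", nm)
      if (!ch %in% c("sbp", "dbp", "hr", "pulse", "map")) {
        stop("unknown effect feature: ", nm, call. = FALSE)
      }
      key <- sub("^[a-z]+__", "", nm)
      fam <- sub("__.*$", "", key)
      fn <- switch(fam,
                   fft = fft_features, cwt = ricker_cwt_features,
                   lz = lempel_ziv_complexity, apen = approximate_entropy,
                   pe = permutation_entropy, alt = agg_linear_trend,
                   dup = duplicate_fractions,
                   stop("unknown effect feature: ", nm, call. = FALSE))
      v <- fn(cs[[ch]])
      if (!key %in% names(v)) stop("unknown effect feature: ", nm, call. = FALSE)
      v[[key]]
    }
  }, numeric(1))
}

#' @export
print.plos_cohort <- function(x, ...) {
  n <- length(x$series)
  cat(sprintf("<plos_cohort> %d patients, %d covariates, generative PLOS prevalence %.2f\n",
              n, ncol(x$covariates) - 2L, mean(x$truth$plos)))
  if (length(attr(x, "log"))) cat("  log:", paste(attr(x, "log"), collapse = "; "), "\n")
  invisible(x)
}

#' Write a cohort to plain-text files
#'
#' Series go to `series.csv` in long format (`patient_id, t_min, sbp, dbp,
#' hr, pulse`; missing points as empty cells), covariates and length of
#' stay to `covariates.csv`, and the generative ground truth to
#' `truth.json`.
#'
#' @param cohort a `plos_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  long <- do.call(rbind, lapply(cohort$series, function(s) {
    data.frame(patient_id = attr(s, "patient_id"), t_min = s$t,
               sbp = s$sbp, dbp = s$dbp, hr = s$hr, pulse = s$pulse)
  }))
  utils::write.csv(long, file.path(dir, "series.csv"), row.names = FALSE, na = "")
  utils::write.csv(cohort$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  tr <- cohort$truth
  jsonlite::write_json(
    list(lp = as.list(tr$lp), effect_sizes = as.list(tr$effect_sizes),
         intercept = tr$intercept, mean = as.list(tr$mean),
         sd = as.list(tr$sd), plos = as.list(tr$plos)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read circulation series from a long-format CSV
#'
#' @param path CSV with columns `patient_id, t_min, sbp, dbp, hr, pulse`.
#' @param grid_minutes grid spacing.
#' @return Named list of [circulation_series].
#' @export
read_series_csv <- function(path, grid_minutes = 5) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(long, long$patient_id), function(d) {
    d <- d[order(d$t_min), ]
    circulation_series(d$t_min, d$sbp, d$dbp, d$hr, d$pulse,
                       patient_id = d$patient_id[1L], grid_minutes = grid_minutes)
  })
}
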