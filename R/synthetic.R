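#' Generate a randomized MSIT trial schedule
#'
#' Produces the ordered trial table for one synthetic participant: per run,
#' exactly the specified numbers of congruent, incongruent and fixation
#' trials in a seeded random order, with onsets at consecutive multiples of
#' the trial duration starting at 0 within each run. Fixation trials carry
#' no RT or accuracy.
#'
#' @param spec a [schedule_spec()].
#' @param seed integer seed; the same seed yields a bit-identical schedule.
#' @return a trial table (tibble) with columns `trial_id`, `run`, `onset`
#'   (s, within run), `duration` (s), `condition`, `rt` (ms, `NA` here) and
#'   `accuracy` (`NA` here).
#' @export
generate_schedule <- function(spec = schedule_spec(), seed = 1) {
  stopifnot(inherits(spec, "schedule_spec"))
  withr::with_seed(seed, {
    runs <- lapply(seq_len(spec$n_runs), function(r) {
      types <- c(rep("congruent", spec$n_congruent),
                 rep("incongruent", spec$n_incongruent),
                 rep("fixation", spec$n_fixation))
      n <- length(types)
      if (n > 0) types <- types[sample.int(n)]
      tibble::tibble(
        trial_id = sprintf("r%02d_t%03d", r, seq_len(n)),
        run = rep(as.integer(r), n),
        onset = (seq_len(n) - 1) * spec$trial_duration,
        duration = ifelse(types == "fixation", spec$trial_duration,
                          spec$stimulus_duration),
        condition = types,
        rt = rep(NA_real_, n),
        accuracy = rep(NA_integer_, n))
    })
    if (length(runs) == 0)
      return(tibble::tibble(trial_id = character(), run = integer(),
                            onset = numeric(), duration = numeric(),
                            condition = character(), rt = numeric(),
                            accuracy = integer()))
    tibble::as_tibble(do.call(rbind, runs))
  })
}

# ex-Gaussian draw truncated to positive values
rexgauss <- function(n, mu, sigma, tau) {
  x <- rnorm(n, mu, sigma) + if (tau > 0) rexp(n, 1 / tau) else 0
  bad <- which(x <= 0)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mu, sigma) +
      if (tau > 0) rexp(length(bad), 1 / tau) else 0
    bad <- bad[x[bad] <= 0]
  }
  x
}

#' Sample reaction times and accuracies for a schedule
#'
#' Each non-fixation trial gains an ex-Gaussian RT (truncated at 0) and an
#' accuracy flag drawn from the per-condition error probability; omitted
#' trials (per-condition omission probability) get no RT and no accuracy.
#' Fixation trials are unchanged. Error trials keep an RT draw from the
#' same conditional distribution.
#'
#' @param table a trial table from [generate_schedule()].
#' @param model an [rt_model()].
#' @param seed integer seed.
#' @return the trial table with `rt` (ms) and `accuracy` filled in.
#' @export
sample_behavior <- function(table, model = rt_model(), seed = 1) {
  stopifnot(inherits(model, "rt_model"))
  withr::with_seed(seed, {
    for (cond in CONDITIONS) {
      idx <- which(table$condition == cond)
      if (length(idx) == 0) next
      n <- length(idx)
      rt <- rexgauss(n, model$mu[cond], model$sigma[cond], model$tau[cond])
      omitted <- runif(n) < model$p_omission[cond]
      errs <- runif(n) < model$p_error[cond]
      table$rt[idx] <- ifelse(omitted, NA_real_, rt)
      table$accuracy[idx] <- ifelse(omitted, NA_integer_,
                                    ifelse(errs, 0L, 1L))
    }
    table
  })
}

# stationary AR(1) noise with marginal sd `sd` and lag-1 autocorrelation phi
ar1_noise <- function(n, sd, phi) {
  if (n == 0) return(numeric(0))
  if (sd == 0) return(numeric(n))
  e <- numeric(n)
  e[1] <- rnorm(1, 0, sd)
  if (n > 1) {
    w <- rnorm(n - 1, 0, sd * sqrt(1 - phi^2))
    for (t in 2:n) e[t] <- phi * e[t - 1] + w[t - 1]
  }
  e
}

# within-run cosine drift evaluated at volume times
drift_signal <- function(times, run_dur, amplitudes) {
  d <- numeric(length(times))
  for (k in seq_along(amplitudes))
    d <- d + amplitudes[k] * cos(pi * k * times / run_dur)
  d
}

# ground-truth response amplitude per trial; NA rt on a correct trial is a
# data error, omissions contribute the baseline alone
trial_amplitudes <- function(table, truth) {
  amp <- numeric(nrow(table))
  task <- table$condition != "fixation"
  if (any(task & !is.na(table$accuracy) & table$accuracy == 1L &
          is.na(table$rt)))
    stop_rtbold("correct trials must carry an RT",
                class = "rtbold_data_error")
  for (i in which(task)) {
    cond <- table$condition[i]
    a <- truth$baseline[[cond]]
    if (!is.na(table$rt[i])) a <- a + truth$rt_slope * table$rt[i]
    if (cond == "incongruent") a <- a + truth$increment
    amp[i] <- a
  }
  amp
}

# convolve per-run impulse streams with the HRF kernel and sample at the TR
# grid; onsets/weights are within-run, returns one value per volume
convolve_run <- function(onsets, weights, kernel, dt, run_dur, tr, n_vols) {
  n_micro <- max(ceiling(run_dur / dt), 1)
  pos <- if (length(onsets) > 0) pmin(round(onsets / dt) + 1, n_micro)
         else integer(0)
  # sparse direct convolution: impulses are few, the kernel is short
  klen <- length(kernel)
  conv <- numeric(n_micro + klen)
  if (length(onsets) > 0) {
    for (j in seq_along(pos)) {
      if (weights[j] == 0) next
      idx <- pos[j]:(pos[j] + klen - 1)
      conv[idx] <- conv[idx] + weights[j] * kernel
    }
  }
  vol_idx <- pmin(round((0:(n_vols - 1)) * tr / dt) + 1, n_micro)
  conv[vol_idx]
}

#' Synthesize an ROI BOLD time series for a trial table
#'
#' Each task trial contributes a neural impulse at its onset whose
#' amplitude follows the generative model in [bold_truth()]; impulses are
#' convolved with the canonical HRF on a microtime grid, sampled at the TR,
#' and summed with cosine drift and AR(1) noise. Ground truth (per-trial
#' amplitudes and the truth object) is recorded alongside the series.
#'
#' @param table a behaviour-complete trial table.
#' @param truth a [bold_truth()].
#' @param hrf an [hrf_spec()].
#' @param spec the [schedule_spec()] used (provides run duration and TR).
#' @param seed integer seed for noise.
#' @param n_signals number of independent noisy realizations (columns).
#' @return an object of class `bold_series`: list with `data` (volumes x
#'   signals matrix), `run`, `times` (within-run volume onsets, s), `tr`,
#'   `run_duration`, `truth` and `amplitudes`.
#' @export
synthesize_bold <- function(table, truth = bold_truth(), hrf = hrf_spec(),
                            spec = schedule_spec(), seed = 1, n_signals = 1) {
  stopifnot(inherits(truth, "bold_truth"), inherits(hrf, "hrf_spec"))
  kernel <- canonical_hrf(hrf)
  run_dur <- run_duration(spec)
  n_vols <- ceiling(run_dur / spec$tr)
  amp <- trial_amplitudes(table, truth)
  runs <- sort(unique(table$run))
  clean <- unlist(lapply(runs, function(r) {
    rows <- which(table$run == r & table$condition != "fixation" & amp != 0)
    convolve_run(table$onset[rows], amp[rows], kernel, hrf$microtime_dt,
                 run_dur, spec$tr, n_vols)
  }))
  if (length(runs) == 0) clean <- numeric(0)
  times <- rep((0:(n_vols - 1)) * spec$tr, times = length(runs))
  run_col <- rep(runs, each = n_vols)
  drift <- drift_signal(times, run_dur, truth$drift_amplitudes)
  withr::with_seed(seed, {
    data <- vapply(seq_len(n_signals), function(s) {
      noise <- unlist(lapply(runs, function(r)
        ar1_noise(n_vols, truth$noise_sd, truth$ar1)))
      clean + drift + noise
    }, numeric(length(clean)))
  })
  if (!is.matrix(data)) data <- matrix(data, ncol = n_signals)
  colnames(data) <- sprintf("sig%02d", seq_len(n_signals))
  structure(list(data = data, run = run_col, times = times, tr = spec$tr,
                 run_duration = run_dur, truth = truth, amplitudes = amp),
            class = "bold_series")
}

#' Simulate one synthetic participant (events + ROI BOLD series)
#'
#' @inheritParams synthesize_bold
#' @param rt a [rt_model()].
#' @param seed integer seed controlling schedule, behaviour and noise.
#' @return list with `events` (trial table) and `series` ([synthesize_bold()]).
#' @export
simulate_participant <- function(spec = schedule_spec(), rt = rt_model(),
                                 truth = bold_truth(), hrf = hrf_spec(),
                                 seed = 1) {
  events <- generate_schedule(spec, seed = seed)
  events <- sample_behavior(events, rt, seed = seed + 1L)
  series <- synthesize_bold(events, truth, hrf, spec, seed = seed + 2L)
  list(events = events, series = series)
}

#' Synthesize smooth random-walk head-motion series
#'
#' Six rigid-body motion parameter series (smoothed cumulative Gaussian
#' steps, one per run), suitable for exercising the 24-parameter motion
#' nuisance expansion.
#'
#' @param n_vols volumes per run.
#' @param n_runs number of runs.
#' @param step step SD of the random walk.
#' @param seed integer seed.
#' @return numeric matrix, `n_vols * n_runs` rows by 6 columns.
#' @export
synthesize_motion <- function(n_vols, n_runs = 1, step = 0.02, seed = 1) {
  withr::with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(n_runs), function(r) {
      m <- vapply(1:6, function(j) cumsum(rnorm(n_vols, 0, step)),
                  numeric(n_vols))
      # light smoothing keeps the walk slow, like real head drift
      apply(m, 2, function(x) stats::filter(x, rep(1 / 5, 5), sides = 2,
                                            circular = TRUE))
    }))
    colnames(out) <- c("tx", "ty", "tz", "rx", "ry", "rz")
    out
  })
}

#' Synthesize a volumetric (4-D) BOLD dataset
#'
#' Places the generative trial signal (plus drift) in every voxel of a
#' spherical ROI on a small world-aligned grid, with independent AR(1)
#' noise in every voxel of the grid, so that sphere-ROI extraction and
#' averaging can be exercised end to end. Voxels outside the ROI carry
#' drift and noise only.
#'
#' @inheritParams synthesize_bold
#' @param grid a [grid_spec()].
#' @param roi a [roi_spec()]; the signal-bearing sphere.
#' @return an object of class `bold_series` whose `data` is a 4-D array
#'   (x, y, z, time); `run`, `times`, `tr`, `truth` as in
#'   [synthesize_bold()].
#' @export
synthesize_bold_volume <- function(table, truth = bold_truth(),
                                   hrf = hrf_spec(), spec = schedule_spec(),
                                   grid = grid_spec(), roi = roi_spec(),
                                   seed = 1) {
  base <- synthesize_bold(table, bold_truth(
    baseline = truth$baseline, rt_slope = truth$rt_slope,
    increment = truth$increment, noise_sd = 0, ar1 = truth$ar1,
    drift_amplitudes = numeric(0)), hrf, spec, seed = seed)
  clean <- base$data[, 1]          # event signal only, noise- and drift-free
  drift <- drift_signal(base$times, base$run_duration,
                        truth$drift_amplitudes)
  nt <- length(clean)
  nvox <- prod(grid$dim)
  vox <- sphere_voxels(roi, grid)
  withr::with_seed(seed, {
    phi <- truth$ar1
    noise <- matrix(rnorm(nt * nvox, 0, truth$noise_sd), nt, nvox)
    if (truth$noise_sd > 0 && phi != 0) {
      runs <- base$run
      for (r in unique(runs)) {
        rows <- which(runs == r)
        if (length(rows) < 2) next
        sub <- noise[rows, , drop = FALSE]
        sub[-1, ] <- sub[-1, ] * sqrt(1 - phi^2)
        for (t in 2:nrow(sub)) sub[t, ] <- phi * sub[t - 1, ] + sub[t, ]
        noise[rows, ] <- sub
      }
    }
  })
  flat <- t(noise + drift)                  # voxels x time
  flat[vox$linear, ] <- flat[vox$linear, , drop = FALSE] +
    matrix(clean, nrow = nrow(vox), ncol = nt, byrow = TRUE)
  arr <- array(flat, dim = c(grid$dim, nt))
  structure(list(data = arr, run = base$run, times = base$times,
                 tr = base$tr, run_duration = base$run_duration,
                 truth = truth, amplitudes = base$amplitudes,
                 grid = grid, roi = roi),
            class = "bold_series")
}
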