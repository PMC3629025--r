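#' Trial-schedule specification
#'
#' Describes the per-run trial composition and timing of an event-related
#' MSIT session. Defaults correspond to five 3-minute runs of 24 congruent,
#' 24 incongruent and 12 fixation trials, each trial occupying 3 s
#' (500 ms stimulus followed by 2500 ms fixation), scanned at TR = 2 s.
#'
#' @param n_runs number of runs.
#' @param n_congruent,n_incongruent,n_fixation trials of each type per run.
#' @param trial_duration trial length in seconds.
#' @param stimulus_duration stimulus presentation in seconds (must not
#'   exceed `trial_duration`); fixation trials show the cross for the full
#'   trial.
#' @param tr repetition time of the scanner, seconds.
#' @return an object of class `schedule_spec`.
#' @export
schedule_spec <- function(n_runs = 5, n_congruent = 24, n_incongruent = 24,
                          n_fixation = 12, trial_duration = 3,
                          stimulus_duration = 0.5, tr = 2) {
  counts <- c(n_runs, n_congruent, n_incongruent, n_fixation)
  if (any(counts < 0) || any(counts != round(counts)))
    stop_rtbold("trial and run counts must be non-negative integers",
                class = "rtbold_config_error")
  if (trial_duration <= 0 || tr <= 0 || stimulus_duration <= 0)
    stop_rtbold("trial_duration, stimulus_duration and tr must be positive",
                class = "rtbold_config_error")
  if (stimulus_duration > trial_duration)
    stop_rtbold("stimulus_duration cannot exceed trial_duration",
                class = "rtbold_config_error")
  structure(list(n_runs = as.integer(n_runs),
                 n_congruent = as.integer(n_congruent),
                 n_incongruent = as.integer(n_incongruent),
                 n_fixation = as.integer(n_fixation),
                 trial_duration = trial_duration,
                 stimulus_duration = stimulus_duration,
                 tr = tr),
            class = "schedule_spec")
}

#' Run duration implied by a schedule
#' @param spec a [schedule_spec()].
#' @return seconds spanned by one run.
#' @export
run_duration <- function(spec) {
  with(spec, (n_congruent + n_incongruent + n_fixation) * trial_duration)
}

#' Behavioural (reaction-time and accuracy) model
#'
#' RTs are ex-Gaussian: the sum of a Gaussian (`mu`, `sigma`) and an
#' exponential (`tau`) component, the standard descriptive model for RT
#' distributions; the condition mean is `mu + tau` and the SD is
#' `sqrt(sigma^2 + tau^2)`. The default calibration gives mean RTs of
#' 686.9 ms (congruent) and 969.8 ms (incongruent) with conditional SDs of
#' roughly 150-190 ms, and error rates of 0.1% and 8.2%.
#'
#' @param mu,sigma,tau named numeric vectors (conditions `congruent`,
#'   `incongruent`), in ms. `sigma > 0`, `tau >= 0`.
#' @param p_error per-condition probability of an incorrect response.
#' @param p_omission per-condition probability of no response (no RT).
#' @return an object of class `rt_model`.
#' @export
rt_model <- function(mu = c(congruent = 556.9, incongruent = 799.8),
                     sigma = c(congruent = 80, incongruent = 90),
                     tau = c(congruent = 130, incongruent = 170),
                     p_error = c(congruent = 0.001, incongruent = 0.082),
                     p_omission = c(congruent = 0.005, incongruent = 0.005)) {
  for (v in list(mu, sigma, tau, p_error, p_omission))
    if (!all(CONDITIONS %in% names(v)))
      stop_rtbold("rt_model parameters must be named for both conditions",
                  class = "rtbold_config_error")
  if (any(sigma <= 0) || any(tau < 0))
    stop_rtbold("sigma must be > 0 and tau >= 0",
                class = "rtbold_config_error")
  if (any(c(p_error, p_omission) < 0) || any(c(p_error, p_omission) > 1))
    stop_rtbold("probabilities must lie in [0, 1]",
                class = "rtbold_config_error")
  structure(list(mu = mu[CONDITIONS], sigma = sigma[CONDITIONS],
                 tau = tau[CONDITIONS], p_error = p_error[CONDITIONS],
                 p_omission = p_omission[CONDITIONS]),
            class = "rt_model")
}

#' Mean RT per condition implied by an rt_model
#' @param model an [rt_model()].
#' @return named numeric vector of condition means, ms.
#' @export
rt_model_means <- function(model) model$mu + model$tau

#' Generative ground truth for the BOLD signal
#'
#' Each correct trial contributes a haemodynamic response of amplitude
#' `baseline[condition] + rt_slope * RT + increment * (incongruent)`,
#' so with `increment = 0` the two conditions differ only through RT.
#' The series additionally carries slow cosine drift (within-run periods
#' `2 * run_duration / k` for the k-th amplitude) and stationary AR(1)
#' Gaussian noise with marginal standard deviation `noise_sd` and lag-1
#' autocorrelation `ar1`.
#'
#' @param baseline named condition baselines, signal units.
#' @param rt_slope signal units per ms of RT.
#' @param increment genuine congruency increment added to incongruent
#'   trials, signal units.
#' @param noise_sd marginal SD of the AR(1) noise; `>= 0`.
#' @param ar1 lag-1 autocorrelation, in (-1, 1).
#' @param drift_amplitudes amplitudes of the within-run cosine drifts.
#' @return an object of class `bold_truth`.
#' @export
bold_truth <- function(baseline = c(congruent = 0, incongruent = 0),
                       rt_slope = 0.002, increment = 0, noise_sd = 1,
                       ar1 = 0.3, drift_amplitudes = c(0.3, 0.2)) {
  if (!all(CONDITIONS %in% names(baseline)))
    stop_rtbold("baseline must be named for both conditions",
                class = "rtbold_config_error")
  if (noise_sd < 0) stop_rtbold("noise_sd must be >= 0",
                                class = "rtbold_config_error")
  if (abs(ar1) >= 1) stop_rtbold("ar1 must lie strictly in (-1, 1)",
                                 class = "rtbold_config_error")
  structure(list(baseline = baseline[CONDITIONS], rt_slope = rt_slope,
                 increment = increment, noise_sd = noise_sd, ar1 = ar1,
                 drift_amplitudes = drift_amplitudes),
            class = "bold_truth")
}

#' Canonical haemodynamic response specification
#'
#' Parameters of the double-gamma HRF (difference of two gamma densities):
#' response peak and undershoot delays/dispersions in seconds, the relative
#' undershoot amplitude, and the microtime resolution at which event
#' streams are convolved before resampling to the TR grid.
#'
#' @param peak_delay,undershoot_delay,peak_dispersion,undershoot_dispersion
#'   gamma timing parameters, seconds; all positive.
#' @param undershoot_ratio relative amplitude of the undershoot; `>= 0`.
#' @param microtime_dt convolution grid step, seconds.
#' @param duration kernel support, seconds.
#' @return an object of class `hrf_spec`.
#' @export
hrf_spec <- function(peak_delay = 6, undershoot_delay = 16,
                     peak_dispersion = 1, undershoot_dispersion = 1,
                     undershoot_ratio = 1 / 6, microtime_dt = 0.1,
                     duration = 32) {
  if (any(c(peak_delay, undershoot_delay, peak_dispersion,
            undershoot_dispersion, microtime_dt, duration) <= 0))
    stop_rtbold("HRF timing parameters must be positive",
                class = "rtbold_config_error")
  if (undershoot_ratio < 0)
    stop_rtbold("undershoot_ratio must be >= 0",
                class = "rtbold_config_error")
  structure(list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
                 peak_dispersion = peak_dispersion,
                 undershoot_dispersion = undershoot_dispersion,
                 undershoot_ratio = undershoot_ratio,
                 microtime_dt = microtime_dt, duration = duration),
            class = "hrf_spec")
}

#' Voxel-grid specification
#'
#' An axis-aligned voxel grid in world (MNI-style) mm coordinates. The
#' default 20 x 20 x 16 grid at 3.75 x 3.75 x 3.0 mm is centred on the
#' posterior medial frontal cortex coordinate (2, 16, 46) so that
#' sphere-ROI extraction is exercised without whole-brain cost.
#'
#' @param dim integer grid dimensions (nx, ny, nz).
#' @param voxel_size voxel edge lengths, mm.
#' @param origin world coordinate of the centre of voxel (1, 1, 1); by
#'   default chosen so the grid is centred on `centre_on`.
#' @param centre_on world point the default grid is centred on.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(dim = c(20, 20, 16), voxel_size = c(3.75, 3.75, 3),
                      origin = NULL, centre_on = c(2, 16, 46)) {
  if (length(dim) != 3 || any(dim < 1))
    stop_rtbold("grid dim must be three positive integers",
                class = "rtbold_config_error")
  if (length(voxel_size) != 3 || any(voxel_size <= 0))
    stop_rtbold("voxel_size must be three positive lengths",
                class = "rtbold_config_error")
  if (is.null(origin)) origin <- centre_on - (dim - 1) / 2 * voxel_size
  structure(list(dim = as.integer(dim), voxel_size = voxel_size,
                 origin = origin),
            class = "grid_spec")
}

#' Spherical region-of-interest specification
#'
#' @param center world mm coordinates of the sphere centre. The default,
#'   (2, 16, 46), is a posterior medial frontal cortex peak implicated in
#'   interference processing by meta-analysis.
#' @param radius sphere radius, mm; `>= 0`.
#' @return an object of class `roi_spec`.
#' @export
roi_spec <- function(center = c(2, 16, 46), radius = 8) {
  if (length(center) != 3)
    stop_rtbold("center must be (x, y, z)", class = "rtbold_config_error")
  if (radius < 0)
    stop_rtbold("radius must be >= 0", class = "rtbold_config_error")
  structure(list(center = center, radius = radius), class = "roi_spec")
}
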