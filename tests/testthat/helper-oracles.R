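# Small fixtures and independent oracles used across the suite.

tiny_spec <- function(...) {
  schedule_spec(n_runs = 2, n_congruent = 8, n_incongruent = 8,
                n_fixation = 4, ...)
}

quick_participant <- function(seed = 1, spec = tiny_spec(),
                              truth = bold_truth(), rt = rt_model()) {
  simulate_participant(spec, rt, truth, seed = seed)
}

# brute-force maximum-cardinality matching by exhaustive recursion
bf_match_count <- function(crt, irt, window) {
  best <- 0L
  n_i <- length(irt)
  rec <- function(ci, used, count) {
    if (count + (length(crt) - ci + 1) <= best) return()
    if (ci > length(crt)) { best <<- max(best, count); return() }
    for (j in seq_len(n_i)) {
      if (!used[j] && abs(crt[ci] - irt[j]) <= window) {
        used[j] <- TRUE
        rec(ci + 1L, used, count + 1L)
        used[j] <- FALSE
      }
    }
    rec(ci + 1L, used, count)   # leave congruent trial ci unmatched
  }
  if (length(crt) == 0 || n_i == 0) return(0L)
  rec(1L, logical(n_i), 0L)
  best
}

# double-gamma HRF evaluated from the closed form, independent of
# canonical_hrf()'s construction
oracle_hrf <- function(t, peak_delay = 6, undershoot_delay = 16,
                       peak_disp = 1, undershoot_disp = 1, ratio = 1 / 6) {
  dgamma(t, shape = peak_delay / peak_disp, rate = 1 / peak_disp) -
    ratio * dgamma(t, shape = undershoot_delay / undershoot_disp,
                   rate = 1 / undershoot_disp)
}

# direct sum-of-shifted-kernels regressor column (independent of the
# package's convolution path): evaluate at volume times on a microtime grid
oracle_column <- function(onsets, weights, run_dur, tr, n_vols,
                          dt = 0.1, duration = 32) {
  tk <- seq(0, duration, by = dt)
  kern <- oracle_hrf(tk)
  kern <- kern / max(kern)
  vol_t <- (0:(n_vols - 1)) * tr
  out <- numeric(n_vols)
  for (j in seq_along(onsets)) {
    # impulse snapped to the microtime grid, like the builder
    o <- round(onsets[j] / dt) * dt
    lag <- vol_t - o
    inside <- lag >= 0 & lag <= duration
    idx <- round(lag[inside] / dt) + 1
    out[inside] <- out[inside] + weights[j] * kern[idx]
  }
  out
}

# AR(1) series for simulation oracles
oracle_ar1 <- function(n, sd, phi) {
  e <- numeric(n)
  e[1] <- rnorm(1, 0, sd)
  for (t in seq_len(n)[-1])
    e[t] <- phi * e[t - 1] + rnorm(1, 0, sd * sqrt(1 - phi^2))
  e
}
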