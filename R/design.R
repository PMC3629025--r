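#' Canonical double-gamma haemodynamic response kernel
#'
#' The difference of two gamma densities (response peak minus undershoot),
#' sampled on the microtime grid and peak-normalized to 1. With the default
#' parameters (peak delay 6 s, undershoot delay 16 s, unit dispersions,
#' undershoot ratio 1/6) this is the canonical HRF of the SPM family.
#'
#' @param spec an [hrf_spec()].
#' @return numeric kernel sampled at `spec$microtime_dt`, with attribute
#'   `times`.
#' @export
canonical_hrf <- function(spec = hrf_spec()) {
  stopifnot(inherits(spec, "hrf_spec"))
  t <- seq(0, spec$duration, by = spec$microtime_dt)
  h <- dgamma(t, shape = spec$peak_delay / spec$peak_dispersion,
              rate = 1 / spec$peak_dispersion) -
    spec$undershoot_ratio *
    dgamma(t, shape = spec$undershoot_delay / spec$undershoot_dispersion,
           rate = 1 / spec$undershoot_dispersion)
  h <- h / max(h)
  attr(h, "times") <- t
  h
}

# discrete cosine high-pass basis: K components with periods 2*T/k > cutoff
dct_basis <- function(n_vols, tr, hp_cutoff) {
  T_run <- n_vols * tr
  K <- floor(2 * T_run / hp_cutoff)
  if (2 * T_run / max(K, 1) <= hp_cutoff) K <- K - 1
  if (K < 1) return(matrix(numeric(0), nrow = n_vols, ncol = 0))
  t <- 0:(n_vols - 1)
  vapply(seq_len(K),
         function(k) sqrt(2 / n_vols) * cos(pi * (2 * t + 1) * k /
                                              (2 * n_vols)),
         numeric(n_vols))
}

# expand 6 rigid-body motion series to the 24-parameter set:
# linear, squared, within-run derivative, squared derivative
expand_motion <- function(motion, run) {
  stopifnot(ncol(motion) == 6)
  d <- motion
  for (r in unique(run)) {
    rows <- which(run == r)
    d[rows, ] <- rbind(0, diff(as.matrix(motion[rows, , drop = FALSE])))
  }
  out <- cbind(motion, motion^2, d, d^2)
  colnames(out) <- paste0("mot", sprintf("%02d", 1:24))
  out
}

# timing block shared by all design builders
design_timing <- function(table, series, tr, run_dur) {
  if (!is.null(series)) {
    tr <- series$tr; run_dur <- series$run_duration
    runs <- sort(unique(series$run))
  } else {
    if (is.null(tr) || is.null(run_dur))
      stop_rtbold("supply a bold series or tr + run_dur",
                  class = "rtbold_design_error")
    runs <- sort(unique(table$run))
  }
  n_vols <- ceiling(run_dur / tr)
  list(tr = tr, run_dur = run_dur, runs = runs, n_vols = n_vols)
}

# core builder: `cols` is a list of regressor specs
# (name, ids, weights, role, condition, order, orth_group)
build_design_core <- function(table, cols, timing, hrf, hp_cutoff, motion,
                              orthogonalize) {
  kernel <- canonical_hrf(hrf)
  dt <- hrf$microtime_dt
  runs <- timing$runs
  n_total <- timing$n_vols * length(runs)
  onset_of <- setNames(table$onset, table$trial_id)
  run_of <- setNames(table$run, table$trial_id)
  col_for <- function(ids, weights) {
    w <- setNames(weights, ids)
    unlist(lapply(runs, function(r) {
      sel <- ids[run_of[ids] == r]
      convolve_run(onset_of[sel], unname(w[sel]), kernel, dt,
                   timing$run_dur, timing$tr, timing$n_vols)
    }))
  }
  omitted <- character(0)
  X <- NULL; info <- NULL
  for (cs in cols) {
    missing <- setdiff(cs$ids, table$trial_id)
    if (length(missing) > 0)
      stop_rtbold("trial ids not present in table: ",
                  paste(head(missing, 3), collapse = ", "),
                  class = "rtbold_design_error")
    if (length(cs$ids) == 0) { omitted <- c(omitted, cs$name); next }
    X <- cbind(X, col_for(cs$ids, cs$weights))
    info <- rbind(info,
                  data.frame(name = cs$name, role = cs$role,
                             condition = cs$condition %||% NA_character_,
                             order = cs$order %||% NA_integer_,
                             orth_group = cs$orth_group %||% NA_character_))
  }
  if (is.null(X)) X <- matrix(numeric(0), nrow = n_total, ncol = 0)
  colnames(X) <- info$name
  # sequential orthogonalization of polynomial modulators within condition
  if (orthogonalize && !is.null(info)) {
    for (g in unique(stats::na.omit(info$orth_group))) {
      grp <- which(info$orth_group == g)
      grp <- grp[order(ifelse(is.na(info$order[grp]), -1, info$order[grp]))]
      if (length(grp) < 2) next
      for (j in 2:length(grp)) {
        prev <- X[, grp[1:(j - 1)], drop = FALSE]
        y <- X[, grp[j]]
        if (all(y == 0)) next
        qrp <- qr(prev)
        X[, grp[j]] <- y - prev %*% qr.coef(qrp, y)
      }
    }
  }
  # nuisance: motion expansion, per-run cosine drift basis, per-run constant
  if (!is.null(motion)) {
    run_col <- rep(runs, each = timing$n_vols)
    if (nrow(motion) != n_total)
      stop_rtbold("motion series must have one row per volume",
                  class = "rtbold_design_error")
    X <- cbind(X, expand_motion(motion, run_col))
    info <- rbind(info, data.frame(name = paste0("mot", sprintf("%02d", 1:24)),
                                   role = "motion", condition = NA, order = NA,
                                   orth_group = NA))
  }
  hp <- dct_basis(timing$n_vols, timing$tr, hp_cutoff)
  for (ri in seq_along(runs)) {
    rows <- (ri - 1) * timing$n_vols + seq_len(timing$n_vols)
    if (ncol(hp) > 0) {
      block <- matrix(0, n_total, ncol(hp))
      block[rows, ] <- hp
      nm <- sprintf("run%02d_cos%02d", runs[ri], seq_len(ncol(hp)))
      colnames(block) <- nm
      X <- cbind(X, block)
      info <- rbind(info, data.frame(name = nm, role = "drift",
                                     condition = NA, order = NA,
                                     orth_group = NA))
    }
    cst <- numeric(n_total); cst[rows] <- 1
    nm <- sprintf("run%02d_constant", runs[ri])
    X <- cbind(X, setNames(data.frame(cst), nm)[[1]])
    colnames(X)[ncol(X)] <- nm
    info <- rbind(info, data.frame(name = nm, role = "constant",
                                   condition = NA, order = NA,
                                   orth_group = NA))
  }
  structure(list(X = X, col_info = tibble::as_tibble(info),
                 run = rep(runs, each = timing$n_vols),
                 times = rep((0:(timing$n_vols - 1)) * timing$tr,
                             length(runs)),
                 tr = timing$tr, n_vols = timing$n_vols,
                 run_duration = timing$run_dur, hp_cutoff = hp_cutoff,
                 meta = list(omitted = omitted,
                             orthogonalize = orthogonalize)),
            class = "design_matrix")
}

#' Build the full first-level design matrix
#'
#' For each condition of interest (correct congruent, correct incongruent)
#' the design carries a main column (unit impulses at trial onsets
#' convolved with the HRF) plus polynomial RT-modulator columns of orders
#' 1..`rt_orders`, whose impulse weights are powers of the mean-centred RT
#' (centred on the retained conditional mean, in ms, so the order-1
#' coefficient has units signal per ms). Higher orders are sequentially
#' orthogonalized against the main column and lower orders within their
#' condition (switchable). Error trials and excluded/omitted trials get
#' their own unmodulated columns; a per-run discrete-cosine basis spanning
#' periods above `hp_cutoff` seconds implements the high-pass filter, and
#' an optional 6-column motion series is expanded to the 24-parameter
#' nuisance set.
#'
#' @param table a trial table.
#' @param filt the matching [filter_trials()] result.
#' @param series a `bold_series` supplying the time grid (or give `tr` and
#'   `run_dur`).
#' @param hrf an [hrf_spec()].
#' @param hp_cutoff high-pass cutoff period, seconds.
#' @param rt_orders highest polynomial RT order (0 for none; default 4).
#' @param orthogonalize sequentially orthogonalize modulators (default TRUE).
#' @param motion optional volumes x 6 motion parameter matrix.
#' @param tr,run_dur timing when no `series` is given.
#' @return an object of class `design_matrix` (fields `X`, `col_info`,
#'   `run`, `times`, `meta`).
#' @export
build_design <- function(table, filt, series = NULL, hrf = hrf_spec(),
                         hp_cutoff = 128, rt_orders = 4,
                         orthogonalize = TRUE, motion = NULL, tr = NULL,
                         run_dur = NULL) {
  stopifnot(inherits(filt, "filter_result"))
  timing <- design_timing(table, series, tr, run_dur)
  rt_of <- setNames(table$rt, table$trial_id)
  cols <- list()
  for (cond in CONDITIONS) {
    ids <- filt$retained$trial_id[filt$retained$class ==
                                    paste0("correct_", cond)]
    center <- filt$summaries$mean_rt[filt$summaries$condition == cond]
    cols <- c(cols, list(list(name = paste0(cond, "_main"), ids = ids,
                              weights = rep(1, length(ids)),
                              role = "condition_main", condition = cond,
                              order = 0L, orth_group = cond)))
    if (rt_orders >= 1 && length(ids) > 0) {
      dev <- rt_of[ids] - center
      for (p in seq_len(rt_orders))
        cols <- c(cols, list(list(name = sprintf("%s_rt%d", cond, p),
                                  ids = ids, weights = unname(dev)^p,
                                  role = "rt_modulator", condition = cond,
                                  order = as.integer(p),
                                  orth_group = cond)))
    }
  }
  err_ids <- filt$excluded$trial_id[filt$excluded$reason == "error"]
  exc_ids <- filt$excluded$trial_id[filt$excluded$reason %in%
                                      c("omission", "rt_outlier")]
  cols <- c(cols,
            list(list(name = "error", ids = err_ids,
                      weights = rep(1, length(err_ids)), role = "error",
                      condition = NA, order = NA, orth_group = NA),
                 list(name = "excluded", ids = exc_ids,
                      weights = rep(1, length(exc_ids)), role = "excluded",
                      condition = NA, order = NA, orth_group = NA)))
  build_design_core(table, cols, timing, hrf, hp_cutoff, motion,
                    orthogonalize)
}

# shared builder for the matched / subsampled categorical models
build_class_design <- function(table, filt, class_ids, series, hrf,
                               hp_cutoff, motion, tr, run_dur) {
  timing <- design_timing(table, series, tr, run_dur)
  cols <- lapply(names(class_ids), function(nm)
    list(name = nm, ids = class_ids[[nm]],
         weights = rep(1, length(class_ids[[nm]])), role = "class",
         condition = NA, order = NA, orth_group = NA))
  build_design_core(table, cols, timing, hrf, hp_cutoff, motion,
                    orthogonalize = FALSE)
}

#' First-level design for the RT-matched model
#'
#' Regroups trials into four categorical classes — (a) RT-matched congruent,
#' (b) RT-matched incongruent, (c) non-matched correct trials of either
#' condition, (d) error trials — plus the excluded-trial column, with no RT
#' modulators.
#'
#' @inheritParams build_design
#' @param matched a [match_trials()] result.
#' @return a `design_matrix`.
#' @export
build_matched_design <- function(table, filt, matched, series = NULL,
                                 hrf = hrf_spec(), hp_cutoff = 128,
                                 motion = NULL, tr = NULL, run_dur = NULL) {
  stopifnot(inherits(matched, "matched_set"))
  mc <- matched$pairs$congruent_id
  mi <- matched$pairs$incongruent_id
  other <- setdiff(filt$retained$trial_id, c(mc, mi))
  class_ids <- list(
    matched_congruent = mc, matched_incongruent = mi,
    other_correct = other,
    error = filt$excluded$trial_id[filt$excluded$reason == "error"],
    excluded = filt$excluded$trial_id[filt$excluded$reason %in%
                                        c("omission", "rt_outlier")])
  build_class_design(table, filt, class_ids, series, hrf, hp_cutoff,
                     motion, tr, run_dur)
}

#' First-level design for the RT-subsampled model
#'
#' Classes: (a) RT-subsampled congruent, (b) RT-subsampled incongruent,
#' (c) all other correct trials, (d) errors, plus the excluded-trial
#' column; no RT modulators.
#'
#' @inheritParams build_design
#' @param sub a [subsample_trials()] result.
#' @return a `design_matrix`.
#' @export
build_subsampled_design <- function(table, filt, sub, series = NULL,
                                    hrf = hrf_spec(), hp_cutoff = 128,
                                    motion = NULL, tr = NULL,
                                    run_dur = NULL) {
  stopifnot(inherits(sub, "subsampled_set"))
  sc <- sub$selected$congruent
  si <- sub$selected$incongruent
  other <- setdiff(filt$retained$trial_id, c(sc, si))
  class_ids <- list(
    subsampled_congruent = sc, subsampled_incongruent = si,
    other_correct = other,
    error = filt$excluded$trial_id[filt$excluded$reason == "error"],
    excluded = filt$excluded$trial_id[filt$excluded$reason %in%
                                        c("omission", "rt_outlier")])
  build_class_design(table, filt, class_ids, series, hrf, hp_cutoff,
                     motion, tr, run_dur)
}

#' Export a design matrix as TSV
#' @param design a `design_matrix`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_design <- function(design, path) {
  out <- cbind(tibble::tibble(run = design$run, time = design$times),
               tibble::as_tibble(as.data.frame(design$X)))
  readr::write_tsv(tibble::as_tibble(out), path)
  invisible(path)
}
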