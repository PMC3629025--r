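#' Write a synthetic dataset to disk
#'
#' Emits one BIDS-style events TSV per run (`run-XX_events.tsv`, columns
#' `onset`, `duration`, `trial_type`, `response_time`, `accuracy`, `run`,
#' `trial_id`; missing values encoded as `n/a`) plus the BOLD series as a
#' plain time-by-signal TSV (`bold_roi.tsv`) or, when `series$data` is a
#' 4-D array, a NIfTI volume (`bold.nii.gz`). Round-trips losslessly
#' through [read_events()].
#'
#' @param table a trial table.
#' @param series a `bold_series` (or `NULL` to write events only).
#' @param path output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(table, series = NULL, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path))
    stop_rtbold("cannot create output directory ", path,
                class = "rtbold_io_error")
  paths <- character(0)
  runs <- if (nrow(table) > 0) sort(unique(table$run)) else integer(0)
  if (length(runs) == 0) runs <- 1L   # emit a header-only file
  for (r in runs) {
    sub <- table[!is.na(table$run) & table$run == r, , drop = FALSE]
    out <- tibble::tibble(onset = sub$onset, duration = sub$duration,
                          trial_type = sub$condition,
                          response_time = sub$rt, accuracy = sub$accuracy,
                          run = sub$run, trial_id = sub$trial_id)
    f <- file.path(path, sprintf("run-%02d_events.tsv", r))
    readr::write_tsv(out, f, na = "n/a")
    paths <- c(paths, f)
  }
  if (!is.null(series)) {
    if (is.array(series$data) && length(dim(series$data)) == 4) {
      f <- file.path(path, "bold.nii.gz")
      RNifti::writeNifti(RNifti::asNifti(series$data), f)
    } else {
      f <- file.path(path, "bold_roi.tsv")
      out <- tibble::as_tibble(as.data.frame(series$data))
      out <- cbind(tibble::tibble(run = series$run, time = series$times), out)
      readr::write_tsv(tibble::as_tibble(out), f)
    }
    paths <- c(paths, f)
  }
  invisible(paths)
}

EVENT_COLUMNS <- c("onset", "duration", "trial_type", "response_time",
                   "accuracy", "run")

#' Read BIDS-style events TSV file(s) into a trial table
#'
#' @param path a directory containing `*_events.tsv` files, or a character
#'   vector of file paths.
#' @return a trial table as produced by [generate_schedule()] (with `rt`
#'   and `accuracy` populated from the file).
#' @export
read_events <- function(path) {
  files <- if (length(path) == 1 && dir.exists(path)) {
    sort(list.files(path, pattern = "_events\\.tsv$", full.names = TRUE))
  } else path
  if (length(files) == 0 || !all(file.exists(files)))
    stop_rtbold("no events files found at ", paste(path, collapse = ", "),
                class = "rtbold_io_error")
  tabs <- lapply(files, function(f) {
    tab <- tryCatch(
      readr::read_tsv(f, na = c("n/a", "NA", ""), show_col_types = FALSE,
                      progress = FALSE),
      error = function(e) stop_rtbold("cannot parse ", f, ": ",
                                      conditionMessage(e),
                                      class = "rtbold_parse_error"))
    missing <- setdiff(EVENT_COLUMNS, names(tab))
    if (length(missing) > 0)
      stop_rtbold(f, ": missing required columns ",
                  paste(missing, collapse = ", "),
                  class = "rtbold_parse_error")
    prob <- readr::problems(tab)
    if (nrow(prob) > 0)
      stop_rtbold(f, ": malformed value at line ", prob$row[1] + 1,
                  " (", prob$expected[1], ")", class = "rtbold_parse_error")
    if (!"trial_id" %in% names(tab))
      tab$trial_id <- sprintf("r%02d_t%03d", tab$run, seq_len(nrow(tab)))
    tibble::tibble(trial_id = as.character(tab$trial_id),
                   run = as.integer(tab$run),
                   onset = as.numeric(tab$onset),
                   duration = as.numeric(tab$duration),
                   condition = as.character(tab$trial_type),
                   rt = as.numeric(tab$response_time),
                   accuracy = as.integer(tab$accuracy))
  })
  tibble::as_tibble(do.call(rbind, tabs))
}

#' Validate a trial table
#'
#' Checks structural invariants: known condition labels, non-negative
#' onsets, unique trial ids, positive RTs where present, no RT/accuracy on
#' fixation trials, and flags non-fixation trials without an RT as
#' omissions.
#'
#' @param table a trial table.
#' @param strict error (rather than report) on violations.
#' @return a list with `ok` (logical), `issues` (character vector) and
#'   `omissions` (trial ids lacking an RT).
#' @export
validate_events <- function(table, strict = FALSE) {
  issues <- character(0)
  bad_cond <- setdiff(unique(table$condition),
                      c(CONDITIONS, "fixation"))
  if (length(bad_cond) > 0)
    issues <- c(issues, paste0("unknown condition labels: ",
                               paste(bad_cond, collapse = ", ")))
  if (any(table$onset < 0, na.rm = TRUE))
    issues <- c(issues, "negative onsets present")
  if (anyDuplicated(table$trial_id))
    issues <- c(issues, paste0("duplicate trial_id: ",
                               table$trial_id[duplicated(table$trial_id)][1]))
  if (any(!is.na(table$rt) & table$rt <= 0))
    issues <- c(issues, "non-positive RTs present")
  fix <- table$condition == "fixation"
  if (any(fix & (!is.na(table$rt) | !is.na(table$accuracy))))
    issues <- c(issues, "fixation trials must not carry rt/accuracy")
  omissions <- table$trial_id[!fix & is.na(table$rt)]
  if (strict && length(issues) > 0)
    stop_rtbold(paste(issues, collapse = "; "),
                class = "rtbold_validation_error")
  list(ok = length(issues) == 0, issues = issues, omissions = omissions)
}

#' Classify and filter trials for first-level modelling
#'
#' Implements the trial-exclusion rule for correct-trial analyses:
#' response omissions and error trials are excluded with their own
#' reasons; among the remaining correct trials, per condition, trials
#' whose RT lies strictly more than `sd_threshold` conditional (sample)
#' standard deviations from the conditional mean are excluded as RT
#' outliers. Bounds are computed once from the pre-exclusion correct-trial
#' set (single pass); trials exactly at the bound are retained. A
#' condition with fewer than two correct trials has an undefined SD, so no
#' outlier exclusion is applied there (with a warning).
#'
#' @param table a trial table with behaviour.
#' @param sd_threshold outlier cut in conditional SD units (default 3).
#' @return an object of class `filter_result`: list with `retained`
#'   (tibble `trial_id`, `class` in `correct_congruent` /
#'   `correct_incongruent`), `excluded` (tibble `trial_id`, `reason` in
#'   `error` / `omission` / `rt_outlier`), `summaries` (per-condition `n`,
#'   `mean_rt`, `sd_rt` of the retained trials) and `bounds` (the
#'   pre-exclusion mean/SD used for the cut).
#' @export
filter_trials <- function(table, sd_threshold = 3) {
  task <- table[table$condition != "fixation", , drop = FALSE]
  omitted <- is.na(task$rt)
  errors <- !omitted & !is.na(task$accuracy) & task$accuracy == 0L
  correct <- !omitted & !errors
  excluded <- tibble::tibble(
    trial_id = c(task$trial_id[omitted], task$trial_id[errors]),
    reason = c(rep("omission", sum(omitted)), rep("error", sum(errors))))
  keep <- rep(FALSE, nrow(task))
  bounds <- NULL
  for (cond in CONDITIONS) {
    idx <- which(correct & task$condition == cond)
    rts <- task$rt[idx]
    m <- mean(rts)
    s <- if (length(rts) >= 2) sd(rts) else NA_real_
    bounds <- rbind(bounds,
                    data.frame(condition = cond, n_correct = length(idx),
                               mean_rt = m, sd_rt = s))
    if (length(idx) == 0) next
    if (is.na(s)) {
      warning("condition '", cond, "' has fewer than 2 correct trials; ",
              "no RT-outlier exclusion applied", call. = FALSE)
      keep[idx] <- TRUE
      next
    }
    out <- abs(rts - m) > sd_threshold * s
    keep[idx[!out]] <- TRUE
    if (any(out))
      excluded <- rbind(excluded,
                        tibble::tibble(trial_id = task$trial_id[idx[out]],
                                       reason = "rt_outlier"))
  }
  retained <- tibble::tibble(
    trial_id = task$trial_id[keep],
    class = paste0("correct_", task$condition[keep]))
  kept_rt <- task$rt[keep]
  kept_cond <- task$condition[keep]
  summaries <- do.call(rbind, lapply(CONDITIONS, function(cond) {
    rts <- kept_rt[kept_cond == cond]
    tibble::tibble(condition = cond, n = length(rts),
                   mean_rt = if (length(rts)) mean(rts) else NA_real_,
                   sd_rt = if (length(rts) >= 2) sd(rts) else NA_real_)
  }))
  structure(list(retained = retained, excluded = excluded,
                 summaries = tibble::as_tibble(summaries),
                 bounds = tibble::as_tibble(bounds),
                 sd_threshold = sd_threshold),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat("Trial filter result\n")
  cat("  retained:", nrow(x$retained), "trials (",
      sum(x$retained$class == "correct_congruent"), "congruent /",
      sum(x$retained$class == "correct_incongruent"), "incongruent )\n")
  if (nrow(x$excluded) > 0) {
    tab <- table(x$excluded$reason)
    cat("  excluded:", nrow(x$excluded), "trials (",
        paste(names(tab), tab, sep = "=", collapse = ", "), ")\n")
  } else cat("  excluded: none\n")
  invisible(x)
}

#' Write a filter report as TSV
#'
#' One row per non-fixation trial with its class (retained) or exclusion
#' reason, for auditability.
#'
#' @param filt a [filter_trials()] result.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_filter_report <- function(filt, path) {
  rep_tab <- rbind(
    tibble::tibble(trial_id = filt$retained$trial_id, status = "retained",
                   detail = filt$retained$class),
    tibble::tibble(trial_id = filt$excluded$trial_id, status = "excluded",
                   detail = filt$excluded$reason))
  readr::write_tsv(rep_tab, path)
  invisible(path)
}
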