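#' RT-equating contrast from a fitted GLM
#'
#' Estimates congruent-trial activity at the incongruent condition's mean
#' RT by extrapolating along the within-congruent RT-BOLD slope:
#' `congruent_eq = beta_cong_main + slope_cong * (mean_rt_incong -
#' mean_rt_cong)`, and contrasts incongruent activity against it,
#' `contrast = beta_incong_main - congruent_eq`. The uncorrected
#' congruency effect (`beta_incong_main - beta_cong_main`) is returned for
#' comparison. With a zero slope the two coincide.
#'
#' @param fit a [fit_glm()] result for the full (modulated) model.
#' @param summaries per-condition RT summaries, e.g.
#'   `filter_trials()$summaries` (needs `condition` and `mean_rt`).
#' @param signal signal column, default 1.
#' @return an object of class `rt_equated_contrast` with fields
#'   `beta_cong_main`, `beta_incong_main`, `slope_cong`, `mean_rt_cong`,
#'   `mean_rt_incong`, `congruent_eq`, `contrast`, `uncorrected`.
#' @export
rt_equate <- function(fit, summaries, signal = 1) {
  b_c <- coef_of(fit, "congruent_main", signal)
  b_i <- coef_of(fit, "incongruent_main", signal)
  slope <- coef_of(fit, "congruent_rt1", signal)
  m_c <- summaries$mean_rt[summaries$condition == "congruent"]
  m_i <- summaries$mean_rt[summaries$condition == "incongruent"]
  if (length(m_c) != 1 || length(m_i) != 1 || any(is.na(c(m_c, m_i))))
    stop_rtbold("summaries must provide mean RTs for both conditions",
                class = "rtbold_contrast_error")
  eq <- b_c + slope * (m_i - m_c)
  structure(list(beta_cong_main = b_c, beta_incong_main = b_i,
                 slope_cong = slope, mean_rt_cong = m_c, mean_rt_incong = m_i,
                 congruent_eq = eq, contrast = b_i - eq,
                 uncorrected = b_i - b_c),
            class = "rt_equated_contrast")
}

#' @export
print.rt_equated_contrast <- function(x, ...) {
  cat("RT-equated congruency contrast\n")
  cat(sprintf("  uncorrected incong - cong : %.4f\n", x$uncorrected))
  cat(sprintf("  RT-BOLD slope (congruent) : %.6f / ms\n", x$slope_cong))
  cat(sprintf("  congruent_eq at %.1f ms   : %.4f\n",
              x$mean_rt_incong, x$congruent_eq))
  cat(sprintf("  RT-equated contrast       : %.4f\n", x$contrast))
  invisible(x)
}

#' Tolerance-window RT matching of congruent to incongruent trials
#'
#' Finds a maximum-cardinality pairing of congruent with incongruent
#' trials such that the two RTs in every pair differ by at most `window`
#' ms and no trial is used twice. The deterministic algorithm sorts both
#' lists by RT (ties by trial id) and sweeps them with two pointers,
#' pairing the current heads when they are within the window and otherwise
#' discarding the smaller head; for this interval structure the greedy
#' sweep attains the brute-force maximum cardinality.
#'
#' @param cong,incong data frames (or tibbles) with columns `trial_id` and
#'   `rt` (ms, finite and positive).
#' @param window tolerance in ms (default 10).
#' @return an object of class `matched_set`: `pairs` (tibble
#'   `congruent_id`, `incongruent_id`, `rt_c`, `rt_i`), `window`,
#'   `n_pairs`.
#' @export
match_trials <- function(cong, incong, window = 10) {
  for (d in list(cong, incong))
    if (!all(c("trial_id", "rt") %in% names(d)))
      stop_rtbold("inputs need trial_id and rt columns",
                  class = "rtbold_match_error")
  if (any(!is.finite(cong$rt)) || any(!is.finite(incong$rt)) ||
      any(cong$rt <= 0) || any(incong$rt <= 0))
    stop_rtbold("RTs must be finite and positive",
                class = "rtbold_match_error")
  co <- cong[order(cong$rt, cong$trial_id), , drop = FALSE]
  io <- incong[order(incong$rt, incong$trial_id), , drop = FALSE]
  i <- 1L; j <- 1L
  ci <- character(0); ii <- character(0); rc <- numeric(0); ri <- numeric(0)
  while (i <= nrow(co) && j <= nrow(io)) {
    d <- co$rt[i] - io$rt[j]
    if (abs(d) <= window) {
      ci <- c(ci, co$trial_id[i]); ii <- c(ii, io$trial_id[j])
      rc <- c(rc, co$rt[i]); ri <- c(ri, io$rt[j])
      i <- i + 1L; j <- j + 1L
    } else if (d < 0) i <- i + 1L else j <- j + 1L
  }
  structure(list(pairs = tibble::tibble(congruent_id = ci,
                                        incongruent_id = ii,
                                        rt_c = rc, rt_i = ri),
                 window = window, n_pairs = length(ci)),
            class = "matched_set")
}

#' @export
print.matched_set <- function(x, ...) {
  cat("RT-matched set:", x$n_pairs, "pairs within", x$window, "ms\n")
  if (x$n_pairs > 0)
    cat(sprintf("  mean RT congruent %.1f ms, incongruent %.1f ms\n",
                mean(x$pairs$rt_c), mean(x$pairs$rt_i)))
  invisible(x)
}

#' Uniform-stride RT subsampling
#'
#' Selects `k` trials per condition from the RT-sorted lists at uniform
#' intervals: on a list of `n` trials the 0-based indices are
#' `floor(j * n / k)` for `j = 0..k-1`. This equates trial counts across
#' conditions (and with the RT-matched set) while preserving each
#' condition's native RT distribution. A centred variant
#' (`floor((j + 0.5) * n / k)`) is available.
#'
#' @param cong,incong data frames with `trial_id` and `rt`.
#' @param k number of trials to select per condition;
#'   `k <= min(nrow(cong), nrow(incong))`.
#' @param centered use the centred stride rule.
#' @return an object of class `subsampled_set`: `selected` (list of
#'   trial-id vectors per condition), `rts`, `target_k`.
#' @export
subsample_trials <- function(cong, incong, k, centered = FALSE) {
  if (k > min(nrow(cong), nrow(incong)) || k < 0)
    stop_rtbold("k must satisfy 0 <= k <= available trials per condition",
                class = "rtbold_subsample_error")
  pick <- function(d) {
    o <- d[order(d$rt, d$trial_id), , drop = FALSE]
    n <- nrow(o)
    if (k == 0) return(list(ids = character(0), rts = numeric(0)))
    j <- 0:(k - 1)
    idx <- floor((j + if (centered) 0.5 else 0) * n / k) + 1
    list(ids = o$trial_id[idx], rts = o$rt[idx])
  }
  pc <- pick(cong); pi_ <- pick(incong)
  structure(list(selected = list(congruent = pc$ids,
                                 incongruent = pi_$ids),
                 rts = list(congruent = pc$rts, incongruent = pi_$rts),
                 target_k = as.integer(k), centered = centered),
            class = "subsampled_set")
}

#' @export
print.subsampled_set <- function(x, ...) {
  cat("RT-subsampled set:", x$target_k, "trials per condition\n")
  invisible(x)
}

#' Serialize matched / subsampled sets as TSV
#' @param x a `matched_set` or `subsampled_set`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_selection <- function(x, path) {
  tab <- if (inherits(x, "matched_set")) {
    x$pairs
  } else if (inherits(x, "subsampled_set")) {
    rbind(tibble::tibble(condition = "congruent",
                         trial_id = x$selected$congruent,
                         rt = x$rts$congruent),
          tibble::tibble(condition = "incongruent",
                         trial_id = x$selected$incongruent,
                         rt = x$rts$incongruent))
  } else stop_rtbold("unsupported selection object",
                     class = "rtbold_io_error")
  readr::write_tsv(tab, path)
  invisible(path)
}

# retained correct trials of one condition as (trial_id, rt)
retained_rts <- function(table, filt, cond) {
  ids <- filt$retained$trial_id[filt$retained$class ==
                                  paste0("correct_", cond)]
  rows <- match(ids, table$trial_id)
  tibble::tibble(trial_id = ids, rt = table$rt[rows])
}
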