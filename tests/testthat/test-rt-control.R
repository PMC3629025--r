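fake_fit <- function(b_cong, b_incong, slope) {
  co <- matrix(c(b_cong, b_incong, slope), ncol = 1,
               dimnames = list(c("congruent_main", "incongruent_main",
                                 "congruent_rt1"), "sig01"))
  structure(list(coefficients = co), class = "glm_fit")
}
summ <- function(m_c, m_i) {
  tibble::tibble(condition = c("congruent", "incongruent"),
                 mean_rt = c(m_c, m_i))
}

test_that("RT-equating arithmetic follows the extrapolation formula", {
  # worked example: slope 0.002 over a 282.9 ms gap lifts 1.0 to 1.5658
  eq <- rt_equate(fake_fit(1.0, 2.0, 0.002), summ(687, 687 + 282.9))
  expect_equal(eq$congruent_eq, 1.5658, tolerance = 1e-12)
  expect_equal(eq$contrast, 2.0 - 1.5658, tolerance = 1e-12)
  expect_equal(eq$uncorrected, 1.0)
  # zero slope collapses to the uncorrected congruency effect
  eq0 <- rt_equate(fake_fit(1.0, 2.0, 0), summ(687, 970))
  expect_equal(eq0$contrast, eq0$uncorrected)
  # invariant restated: congruent_eq = beta + slope * dRT
  expect_equal(eq$congruent_eq,
               eq$beta_cong_main + eq$slope_cong *
                 (eq$mean_rt_incong - eq$mean_rt_cong))
  expect_error(rt_equate(fake_fit(1, 2, 0.002), summ(NA, 900)),
               class = "rtbold_contrast_error")
})

trials <- function(rts, prefix = "t") {
  tibble::tibble(trial_id = sprintf("%s%03d", prefix, seq_along(rts)),
                 rt = rts)
}

test_that("matching solves the worked example and trivial cases", {
  ms <- match_trials(trials(c(700, 710, 905), "c"),
                     trials(c(705, 712, 950), "i"), window = 10)
  expect_equal(ms$n_pairs, 2)
  expect_equal(ms$pairs$rt_c, c(700, 710))
  expect_equal(ms$pairs$rt_i, c(705, 712))
  expect_equal(bf_match_count(c(700, 710, 905), c(705, 712, 950), 10), 2)
  # disjoint ranges: nothing matches
  expect_equal(match_trials(trials(c(600, 620), "c"),
                            trials(c(900, 950), "i"))$n_pairs, 0)
  # identical lists: perfect matching
  expect_equal(match_trials(trials(1:6 * 100, "c"),
                            trials(1:6 * 100, "i"))$n_pairs, 6)
  expect_error(match_trials(trials(c(700, -5), "c"), trials(700, "i")),
               class = "rtbold_match_error")
})

test_that("greedy matching attains the brute-force maximum", {
  set.seed(202)
  for (rep in 1:120) {
    nc <- sample(0:8, 1); ni <- sample(0:8, 1)
    crt <- round(runif(nc, 600, 1100))
    irt <- round(runif(ni, 600, 1100))
    w <- sample(c(5, 10, 25, 60), 1)
    ms <- match_trials(trials(crt, "c"), trials(irt, "i"), window = w)
    expect_equal(ms$n_pairs, bf_match_count(crt, irt, w))
    if (ms$n_pairs > 0) {
      expect_true(all(abs(ms$pairs$rt_c - ms$pairs$rt_i) <= w))
      expect_equal(anyDuplicated(ms$pairs$congruent_id), 0)
      expect_equal(anyDuplicated(ms$pairs$incongruent_id), 0)
      expect_lte(abs(mean(ms$pairs$rt_i) - mean(ms$pairs$rt_c)), w)
    }
  }
})

test_that("uniform-stride subsampling follows the floor rule", {
  # 110 and 100 trials cut to 50: ~every 2.2nd congruent, every 2nd incongruent
  set.seed(5)
  cong <- trials(sort(runif(110, 500, 1200)), "c")
  incong <- trials(sort(runif(100, 700, 1500)), "i")
  ss <- subsample_trials(cong, incong, 50)
  expect_length(ss$selected$congruent, 50)
  expect_length(ss$selected$incongruent, 50)
  expect_equal(ss$selected$congruent,
               cong$trial_id[floor((0:49) * 110 / 50) + 1])
  expect_equal(ss$selected$incongruent,
               incong$trial_id[floor((0:49) * 100 / 50) + 1])
  expect_equal(ss$selected$incongruent, incong$trial_id[seq(1, 99, by = 2)])
  # n = 10, k = 3 selects 0-based indices 0, 3, 6
  s2 <- subsample_trials(trials(1:10 * 50 + 400, "c"),
                         trials(1:10 * 50 + 400, "i"), 3)
  expect_equal(s2$selected$congruent, sprintf("c%03d", c(1, 4, 7)))
  # k = n keeps everything; k > n errors
  s3 <- subsample_trials(trials(1:4 * 100, "c"), trials(1:4 * 100, "i"), 4)
  expect_setequal(s3$selected$congruent, sprintf("c%03d", 1:4))
  expect_error(subsample_trials(trials(1:4 * 100, "c"),
                                trials(1:4 * 100, "i"), 5),
               class = "rtbold_subsample_error")
})

test_that("subsampling preserves the behavioural congruency effect", {
  dat <- simulate_participant(seed = 77)
  filt <- filter_trials(dat$events)
  cong <- rtbold:::retained_rts(dat$events, filt, "congruent")
  incong <- rtbold:::retained_rts(dat$events, filt, "incongruent")
  ms <- match_trials(cong, incong)
  ss <- subsample_trials(cong, incong, ms$n_pairs)
  full_eff <- mean(incong$rt) - mean(cong$rt)
  sub_eff <- mean(ss$rts$incongruent) - mean(ss$rts$congruent)
  expect_equal(sub_eff, full_eff, tolerance = 0.15)
  # count equality between the two RT-control sets
  expect_equal(length(ss$selected$congruent), ms$n_pairs)
  expect_equal(length(ss$selected$incongruent), ms$n_pairs)
})

test_that("matched and subsampled designs regroup trials correctly", {
  dat <- quick_participant(seed = 21)
  filt <- filter_trials(dat$events)
  cong <- rtbold:::retained_rts(dat$events, filt, "congruent")
  incong <- rtbold:::retained_rts(dat$events, filt, "incongruent")
  ms <- match_trials(cong, incong, window = 50)
  des <- build_matched_design(dat$events, filt, ms, dat$series)
  expect_true(all(c("matched_congruent", "matched_incongruent",
                    "other_correct") %in% colnames(des$X)))
  expect_false(any(grepl("_rt[0-9]", colnames(des$X))))
  # the matched-congruent column is the sum of its per-trial responses
  ids <- ms$pairs$congruent_id
  rows <- match(ids, dat$events$trial_id)
  for (r in 1:2) {
    inr <- dat$events$run[rows] == r
    seg <- (r - 1) * des$n_vols + seq_len(des$n_vols)
    expect_equal(des$X[seg, "matched_congruent"],
                 oracle_column(dat$events$onset[rows][inr],
                               rep(1, sum(inr)), des$run_duration, des$tr,
                               des$n_vols),
                 tolerance = 1e-10)
  }
  # empty matched set degenerates to the remaining classes
  ms0 <- match_trials(trials(numeric(0), "c"), trials(numeric(0), "i"))
  des0 <- build_matched_design(dat$events, filt, ms0, dat$series)
  expect_true(all(c("matched_congruent", "matched_incongruent") %in%
                    des0$meta$omitted))
  expect_true("other_correct" %in% colnames(des0$X))
  # all trials matched: no other_correct column, recorded in metadata
  msall <- match_trials(cong, incong, window = 1e6)
  if (length(setdiff(filt$retained$trial_id,
                     c(msall$pairs$congruent_id,
                       msall$pairs$incongruent_id))) == 0) {
    desall <- build_matched_design(dat$events, filt, msall, dat$series)
    expect_true("other_correct" %in% desall$meta$omitted)
  }
  # subsampled design mirrors the matched one
  ss <- subsample_trials(cong, incong, 5)
  dss <- build_subsampled_design(dat$events, filt, ss, dat$series)
  expect_true(all(c("subsampled_congruent", "subsampled_incongruent",
                    "other_correct") %in% colnames(dss$X)))
  # unknown trial ids are rejected
  ms$pairs$congruent_id[1] <- "nonexistent"
  expect_error(build_matched_design(dat$events, filt, ms, dat$series),
               class = "rtbold_design_error")
})

test_that("selections serialize to TSV", {
  dat <- quick_participant(seed = 22)
  filt <- filter_trials(dat$events)
  cong <- rtbold:::retained_rts(dat$events, filt, "congruent")
  incong <- rtbold:::retained_rts(dat$events, filt, "incongruent")
  ms <- match_trials(cong, incong, window = 100)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_selection(ms, f)
  expect_equal(nrow(readr::read_tsv(f, show_col_types = FALSE)), ms$n_pairs)
  ss <- subsample_trials(cong, incong, 3)
  write_selection(ss, f)
  expect_equal(nrow(readr::read_tsv(f, show_col_types = FALSE)), 6)
})
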