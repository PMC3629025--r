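test_that("schedules have exact per-run composition for any seed", {
  spec <- schedule_spec()
  for (seed in c(1, 7, 99, 1234)) {
    tab <- generate_schedule(spec, seed = seed)
    for (r in 1:5) {
      sub <- tab[tab$run == r, ]
      expect_equal(nrow(sub), 60)
      expect_equal(sum(sub$condition == "congruent"), 24)
      expect_equal(sum(sub$condition == "incongruent"), 24)
      expect_equal(sum(sub$condition == "fixation"), 12)
      expect_equal(sub$onset, (0:59) * 3)
    }
    expect_true(all(is.na(tab$rt[tab$condition == "fixation"])))
  }
})

test_that("degenerate schedules: empty and single-trial cases", {
  empty <- generate_schedule(schedule_spec(n_congruent = 0,
                                           n_incongruent = 0,
                                           n_fixation = 0))
  expect_equal(nrow(empty), 0)
  expect_named(empty, c("trial_id", "run", "onset", "duration",
                        "condition", "rt", "accuracy"))
  one <- generate_schedule(schedule_spec(n_runs = 1, n_congruent = 1,
                                         n_incongruent = 0, n_fixation = 0))
  expect_equal(nrow(one), 1)
  expect_equal(one$onset, 0)
  expect_equal(one$condition, "congruent")
  expect_error(schedule_spec(trial_duration = -1), class = "rtbold_config_error")
})

test_that("same seed gives a bit-identical dataset", {
  a <- simulate_participant(tiny_spec(), seed = 42)
  b <- simulate_participant(tiny_spec(), seed = 42)
  expect_identical(a$events, b$events)
  expect_identical(a$series$data, b$series$data)
  c <- simulate_participant(tiny_spec(), seed = 43)
  expect_false(identical(a$series$data, c$series$data))
})

test_that("behaviour sampling respects the RT model", {
  tab <- generate_schedule(tiny_spec(), seed = 1)
  # degenerate distribution: all RTs collapse to mu
  m0 <- rt_model(sigma = c(congruent = 1e-9, incongruent = 1e-9),
                 tau = c(congruent = 0, incongruent = 0),
                 p_error = c(congruent = 0, incongruent = 0),
                 p_omission = c(congruent = 0, incongruent = 0))
  beh <- sample_behavior(tab, m0, seed = 2)
  expect_equal(beh$rt[beh$condition == "congruent"],
               rep(unname(m0$mu["congruent"]), 16), tolerance = 1e-6)
  # certain errors: everything flagged incorrect
  m1 <- rt_model(p_error = c(congruent = 1, incongruent = 1),
                 p_omission = c(congruent = 0, incongruent = 0))
  beh1 <- sample_behavior(tab, m1, seed = 2)
  expect_true(all(beh1$accuracy[beh1$condition != "fixation"] == 0))
  expect_true(all(is.na(beh1$accuracy[beh1$condition == "fixation"])))
})

test_that("default calibration reproduces the condition means", {
  means <- rt_model_means(rt_model())
  expect_equal(unname(means["congruent"]), 686.9)
  expect_equal(unname(means["incongruent"]), 969.8)
  # large-sample check of the sampler against the calibration
  rts <- rtbold:::rexgauss(20000, 556.9, 80, 130)
  expect_equal(mean(rts), 686.9, tolerance = 5)
  expect_equal(sd(rts), sqrt(80^2 + 130^2), tolerance = 5)
})

test_that("trial amplitudes follow the generative equation", {
  tab <- tibble::tibble(
    trial_id = c("a", "b"), run = c(1L, 1L), onset = c(0, 3),
    duration = c(0.5, 0.5), condition = c("congruent", "incongruent"),
    rt = c(600, 882.9), accuracy = c(1L, 1L))
  truth <- bold_truth(rt_slope = 0.002, increment = 0)
  amp <- rtbold:::trial_amplitudes(tab, truth)
  # RT difference of 282.9 ms at slope 0.002 forces a 0.5658 amplitude gap
  expect_equal(amp[2] - amp[1], 0.5658, tolerance = 1e-12)
  # missing RT on a correct trial is a data error
  tab$rt[1] <- NA
  expect_error(rtbold:::trial_amplitudes(tab, truth),
               class = "rtbold_data_error")
})

test_that("conditions are exchangeable when the truth says so", {
  # one congruent and one incongruent trial at the same within-run onset in
  # separate runs; no RT dependence, equal baselines, no increment, no noise
  tab <- tibble::tibble(
    trial_id = c("c1", "i1"), run = c(1L, 2L), onset = c(6, 6),
    duration = 0.5, condition = c("congruent", "incongruent"),
    rt = c(700, 950), accuracy = 1L)
  spec <- schedule_spec(n_runs = 2, n_congruent = 10, n_incongruent = 0,
                        n_fixation = 0)
  truth <- bold_truth(rt_slope = 0, increment = 0, noise_sd = 0,
                      drift_amplitudes = numeric(0),
                      baseline = c(congruent = 1, incongruent = 1))
  ser <- synthesize_bold(tab, truth, spec = spec, seed = 1)
  r1 <- ser$data[ser$run == 1, 1]
  r2 <- ser$data[ser$run == 2, 1]
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("pure-noise series matches the AR(1) recursion", {
  spec <- schedule_spec(n_runs = 1, n_congruent = 0, n_incongruent = 0,
                        n_fixation = 3000)
  tab <- generate_schedule(spec, seed = 3)
  truth <- bold_truth(noise_sd = 1, ar1 = 0.45,
                      drift_amplitudes = numeric(0))
  ser <- synthesize_bold(tab, truth, spec = spec, seed = 9)
  x <- ser$data[, 1]
  expect_equal(mean(x), 0, tolerance = 0.1)
  expect_equal(sd(x), 1, tolerance = 0.1)
  r1 <- cor(x[-1], x[-length(x)])
  expect_equal(r1, 0.45, tolerance = 0.05)
})

test_that("datasets round-trip through the events writer/reader", {
  dat <- quick_participant(seed = 5)
  dir <- withr::local_tempdir()
  write_dataset(dat$events, dat$series, dir)
  expect_length(list.files(dir, pattern = "_events"), 2)
  back <- read_events(dir)
  expect_equal(as.data.frame(back), as.data.frame(dat$events))
  # full default design: 5 event files, onsets within one 3-minute run
  dat5 <- simulate_participant(seed = 6)
  dir5 <- withr::local_tempdir()
  write_dataset(dat5$events, NULL, dir5)
  files <- list.files(dir5, pattern = "_events")
  expect_length(files, 5)
  expect_true(all(dat5$events$onset >= 0 & dat5$events$onset < 180))
  # empty table still yields a valid header-only TSV
  empty <- generate_schedule(schedule_spec(n_congruent = 0,
                                           n_incongruent = 0,
                                           n_fixation = 0))
  dir0 <- withr::local_tempdir()
  write_dataset(empty, NULL, dir0)
  f <- list.files(dir0, full.names = TRUE)[1]
  expect_equal(length(readLines(f)), 1)
})

test_that("motion synthesis returns six slow series per run", {
  m <- synthesize_motion(50, n_runs = 2, seed = 4)
  expect_equal(dim(m), c(100, 6))
  expect_false(anyNA(m))
})
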