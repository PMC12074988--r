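sched_fmri <- generate_schedule("study1_fmri", seed = 501)
choices_fmri <- simulate_choices(sched_fmri, n_participants = 1, n_sims = 1,
                                 seed = 502,
                                 decisions = c("self", "partner", "group"))
timing_fmri <- trial_timing(sched_fmri, seed = 503)

test_that("event tables match the regressor manifests exactly", {
  for (g in c("GLM1", "GLM2", "GLM3", "ROI_GLM1", "ROI_GLM2")) {
    d <- build_design(g, sched_fmri, choices = choices_fmri,
                      timing = timing_fmri)
    expect_setequal(unique(d$events$regressor), d$manifest$name)
    # durations and modulation kinds agree with the manifest
    ev <- d$events %>%
      dplyr::distinct(.data$regressor, .data$duration, .data$modulation)
    m <- d$manifest[match(ev$regressor, d$manifest$name), ]
    expect_equal(ev$duration, m$duration)
    expect_equal(ev$modulation, m$modulation)
  }
  # printed inventory sizes
  expect_equal(nrow(design_manifest("ROI_GLM1")), 9)
  expect_equal(nrow(design_manifest("ROI_GLM2")), 6)
  expect_error(build_design("GLM2", sched_fmri, timing = timing_fmri),
               "choice")
  expect_error(build_design("GLM9", sched_fmri))
})

test_that("parametric regressors are standardised and keyed to the right values", {
  d <- build_design("GLM2", sched_fmri, choices = choices_fmri,
                    timing = timing_fmri)
  par <- d$events[d$events$modulation == "parametric", ]
  for (stats_ in split(par$value, par$regressor)) {
    expect_lt(abs(mean(stats_)), 1e-12)
    expect_lt(abs(stats::sd(stats_) - 1), 1e-12)
  }
  # raw b-projections equal the schedule's projections, trial by trial
  aug <- add_decision_variables(sched_fmri)
  tr <- aug[!duplicated(aug$trial), ]
  expect_equal(par$value_raw[par$regressor == "b2"], tr$b2)
  expect_equal(par$value_raw[par$regressor == "S_position"], tr$s_position)
  # the GLM2 average-basis contrast is constructible by name
  expect_true(all(c("b1", "b2", "b3", "S_position") %in% par$regressor))

  # null vector equals the sum of all performances
  d2 <- build_design("ROI_GLM2", sched_fmri, timing = timing_fmri)
  nv <- d2$events[d2$events$regressor == "null_vector", ]
  expect_equal(nv$value_raw, tr$S + tr$P + tr$O1 + tr$O2)
})

test_that("the combined inverted projections equal twice the relevant-player difference", {
  d <- build_design("GLM3", sched_fmri, choices = choices_fmri,
                    timing = timing_fmri)
  ev <- d$events
  aug <- add_decision_variables(sched_fmri)
  for (dbin in c("DY1", "DY2")) {
    dy <- aug[aug$dtype != "group" &
                aug$decision == as.integer(substr(dbin, 3, 3)), ]
    ip <- ev$value_raw[ev$regressor == paste0(dbin, "_inv_primary")]
    is <- ev$value_raw[ev$regressor == paste0(dbin, "_inv_secondary")]
    expect_equal(ip + is, 2 * dy$social_dv)
    # the inversion flag is binary
    flag <- ev$value_raw[ev$regressor == paste0(dbin, "_sec_inversion")]
    expect_true(all(flag %in% c(0, 1)))
  }
})

test_that("HRF convolution is linear and reproduces the kernel for an impulse", {
  ev <- tibble::tibble(regressor = "imp", onset = 10, duration = 0,
                       value_raw = 1, modulation = "parametric", value = 1)
  d <- structure(list(glm_id = "custom", events = ev,
                      timing = tibble::tibble(trial_end = 40)),
                 class = "bf_design")
  dm <- convolve_hrf(d, TR = 0.1, dt_grid = 0.1, total_duration = 60)
  col <- dm$X[, "imp"]
  kern <- double_gamma_hrf(seq(0, 32, by = 0.1))
  on_idx <- which(dm$frame_times >= 10 & dm$frame_times < 42)
  expect_gt(stats::cor(col[on_idx], kern[seq_along(on_idx)]), 0.999)

  # zero values give a zero column; doubling values doubles the column
  ev2 <- ev; ev2$value <- 0
  d2 <- d; d2$events <- ev2
  expect_true(all(convolve_hrf(d2, TR = 0.1, total_duration = 60)$X == 0))
  ev3 <- ev; ev3$value <- 2
  d3 <- d; d3$events <- ev3
  expect_equal(convolve_hrf(d3, TR = 0.1, total_duration = 60)$X[, 1],
               2 * col)
})

test_that("known injected effects are recovered from synthetic BOLD", {
  d <- convolve_hrf(build_design("ROI_GLM1", sched_fmri,
                                 timing = timing_fmri))
  # noiseless: exact reconstruction
  y0 <- simulate_bold(d, c(b2 = 1.5, S_perf = -1), noise_sd = 0, seed = 1)
  est0 <- stats::coef(stats::lm(y0 ~ d$X))[-1]
  expect_equal(unname(est0[c("d$Xb2", "d$XS_perf")]), c(1.5, -1),
               tolerance = 1e-8)
  expect_lt(max(abs(est0[setdiff(names(est0), c("d$Xb2", "d$XS_perf"))]),
                na.rm = TRUE), 1e-8)

  # noisy: within the confidence interval; null effect centred on zero
  # (stick regressors have small amplitude, so noise is scaled accordingly)
  y <- simulate_bold(d, c(b2 = 1.5), noise_sd = 0.02, seed = 2, ar1 = 0.3)
  fit <- stats::lm(y ~ d$X)
  ci <- stats::confint(fit)["d$Xb2", ]
  expect_gt(1.5, ci[1]); expect_lt(1.5, ci[2])
  ci0 <- stats::confint(fit)["d$Xb3", ]
  expect_gt(0, ci0[1]); expect_lt(0, ci0[2])
  expect_error(simulate_bold(d, c(nope = 1)), "Unknown")
})

test_that("ROI time courses recover a transient injected effect at its latency", {
  TR <- 1.2
  n_vol <- ceiling((max(timing_fmri$trial_end) + 20) / TR)
  t_vol <- (seq_len(n_vol) - 1) * TR
  aug <- add_decision_variables(sched_fmri)
  tr <- aug[!duplicated(aug$trial), ]
  b3z <- socialbasis:::zscore(tr$b3)
  series <- withr::with_seed(9, stats::rnorm(n_vol))
  for (i in seq_len(nrow(timing_fmri))) {
    series <- series + 1.5 * b3z[i] *
      exp(-((t_vol - (timing_fmri$obs_offset[i] + 5))^2) / (2 * 1.5^2))
  }
  rtc <- roi_timecourse_glm(series, sched_fmri, "ROI_GLM1", timing_fmri)
  # ten times finer sampling than the TR grid
  expect_equal(length(rtc$time), length(seq(-2, 12, by = TR / 10)))
  expect_equal(diff(rtc$time)[1], TR / 10)
  pk <- rtc$time[which.max(abs(rtc$betas["b3", ]))]
  expect_lt(abs(pk - 5), 1.5)
  # a regressor orthogonal to the injected signal stays flat
  expect_lt(max(abs(rtc$betas["P_position", ])),
            max(abs(rtc$betas["b3", ])) / 2)
})

test_that("the leave-one-out peak test is calibrated and detects real effects", {
  time <- seq(-2, 12, by = 0.12)
  smooth_noise <- function(n_subj, amp = 1) {
    t(sapply(seq_len(n_subj), function(i) {
      stats::filter(stats::rnorm(length(time) + 20, sd = amp), rep(1/6, 6),
                    sides = 1)[-(1:20)]
    }))
  }
  # identical time courses: the LOO peak equals the global peak everywhere
  tc1 <- matrix(rep(sin(time), 5), 5, byrow = TRUE)
  res1 <- loo_peak_test(tc1, time, c(4, 10))
  gm <- colMeans(tc1)
  in_win <- which(time >= 4 & time <= 10)
  expect_true(all(res1$peak_times == time[in_win[which.max(abs(gm[in_win]))]]))

  # the leave-one-out read-out is unbiased under the null: each subject's
  # value is read at a latency chosen without that subject's data, so the
  # mean estimate across null cohorts is centred on zero
  ests <- withr::with_seed(11, replicate(300, {
    loo_peak_test(smooth_noise(12), time)$estimate
  }))
  expect_lt(abs(mean(ests)), 3 * stats::sd(ests) / sqrt(length(ests)) + 0.02)

  # power: a genuine positive effect is detected with the right sign
  hits <- withr::with_seed(12, sum(replicate(50, {
    tc <- smooth_noise(12) + rep(0.8 * exp(-(time - 6)^2 / 4), each = 12)
    r <- loo_peak_test(tc, time)
    r$p.value < 0.05 && r$estimate > 0
  })))
  expect_gte(hits / 50, 0.9)

  expect_error(loo_peak_test(tc1[1:2, ], time), "3 subjects")
  expect_error(loo_peak_test(tc1, time, c(20, 30)), "window")
})

test_that("event tables export to three-column text plus a manifest", {
  d <- build_design("ROI_GLM2", sched_fmri, timing = timing_fmri)
  dir <- tempfile()
  files <- write_design_events(d, dir)
  expect_length(files, 6)
  one <- utils::read.table(files[1])
  expect_equal(ncol(one), 3)
  expect_equal(nrow(one), 144)
  man <- jsonlite::read_json(file.path(dir, "ROI_GLM2_manifest.json"),
                             simplifyVector = TRUE)
  expect_setequal(man$name, design_manifest("ROI_GLM2")$name)
})
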