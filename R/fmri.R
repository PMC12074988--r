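#' Regressor manifests for the fMRI designs
#'
#' Machine-readable inventory of every regressor of the whole-brain designs
#' (GLM1-GLM3) and the ROI time-course designs: name, lock event, duration in
#' seconds and whether the regressor is a constant (boxcar) or a parametric
#' modulator. This manifest is the single source of truth for
#' [build_design()] and is asserted against the built event tables.
#'
#' @param glm_id One of `"GLM1"`, `"GLM2"`, `"GLM3"`, `"ROI_GLM1"`,
#'   `"ROI_GLM2"`.
#' @return A tibble with columns `name`, `lock`, `duration`, `modulation`.
#' @export
design_manifest <- function(glm_id = c("GLM1", "GLM2", "GLM3", "ROI_GLM1",
                                       "ROI_GLM2")) {
  glm_id <- match.arg(glm_id)
  man <- function(name, lock, duration, modulation) {
    tibble(name = name, lock = lock, duration = duration,
           modulation = modulation)
  }
  dec_par <- function(prefix, players) {
    man(paste0(prefix, "_", c(players, "bonus")), prefix, 2, "parametric")
  }
  switch(glm_id,
    GLM1 = bind_rows(
      man("rdk", "rdk_onset", 2, "constant"),
      man(paste0(c("S", "P", "O1", "O2"), "_perf"), "player_rdk_onset", 2,
          "parametric"),
      man(c("S1", "S2", "P1", "P2", "G1", "G2"), "decision_onset", 2,
          "constant"),
      dec_par("S1", c("S", "P", "Or", "Oi")),
      dec_par("S2", c("S", "P", "Or", "Oi")),
      dec_par("P1", c("S", "P", "Or", "Oi")),
      dec_par("P2", c("S", "P", "Or", "Oi")),
      dec_par("G1", c("S", "P", "O1", "O2")),
      dec_par("G2", c("S", "P", "O1", "O2")),
      man("button_press", "response", 0.1, "constant")
    ),
    GLM2 = bind_rows(
      man("obs_stick", "obs_offset_plus2", 0.1, "constant"),
      man(c("b1", "b2", "b3", "S_perf", "P_perf", "O1_perf", "O2_perf"),
          "obs_offset_plus2", 0.1, "parametric"),
      man(c("S_position", "P_position"), "obs_offset", 0.1, "parametric"),
      man(c("S_dec", "P_dec", "G_dec"), "decision_onset", 2, "constant"),
      man(paste0(rep(c("S", "P"), each = 5), "_dec_",
                 c("DV", "DVxC", "choice", "DVi", "DVixC")),
          "decision_onset", 2, "parametric"),
      man(paste0("G_dec_", c("DV", "DVxC", "choice")), "decision_onset", 2,
          "parametric"),
      man("button_press", "response", 0.1, "constant")
    ),
    GLM3 = bind_rows(
      man("rdk", "rdk_onset", 2, "constant"),
      man(c("DY1", "DY2"), "decision_onset", 2, "constant"),
      man(paste0(rep(c("DY1", "DY2"), each = 10), "_",
                 c("primary", "secondary", "tertiary", "inv_primary",
                   "sec_inversion", "inv_primary_x_choice",
                   "inv_secondary_x_choice", "bonus", "bonus_x_choice",
                   "inv_secondary")),
          "decision_onset", 2, "parametric"),
      man("G", "decision_onset", 2, "constant"),
      man(paste0("G_", c("primary", "inv_primary", "inv_primary_x_choice",
                         "bonus", "bonus_x_choice")),
          "decision_onset", 2, "parametric"),
      man("button_press", "response", 0.1, "constant")
    ),
    ROI_GLM1 = man(c("b1", "b2", "b3", "S_perf", "P_perf", "O1_perf",
                     "O2_perf", "S_position", "P_position"),
                   "obs_offset", 0, "parametric"),
    ROI_GLM2 = man(c("b1", "b2", "b3", "null_vector", "S_position",
                     "P_position"), "obs_offset", 0, "parametric")
  )
}

# clipped-Poisson jitter on a discrete grid (the printed ranges and means)
rpois_clipped <- function(n, mean, lo, hi) {
  pmin(pmax(stats::rpois(n, mean), lo), hi)
}

#' Trial timing for a schedule
#'
#' Generates onsets for the observation phase (four player RDK events of
#' 2.1 s each: 0.4 s identity cue plus six 0.2-s performance cues with 0.1-s
#' gaps), the two decisions and the responses, with the jitter structure of
#' the scanner task: a 1-5-s Poisson jitter (mean 2 s) between observation
#' offset and the first decision, 2-8 s (mean 3.5 s) between decisions, and a
#' 1-5-s (mean 2 s) intertrial interval.
#'
#' @inheritParams add_decision_variables
#' @param seed Integer seed for the jitters.
#' @param decision_duration Modelled decision duration, seconds (default 2,
#'   the average response time).
#' @return A tibble with one row per trial: RDK onsets (`rdk_onset1..4`),
#'   `obs_offset`, `dec1_onset`, `dec2_onset`, `response1`, `response2`,
#'   `trial_end`.
#' @export
trial_timing <- function(schedule, seed = 1L, decision_duration = 2) {
  trials <- unique(as_tibble(schedule)[, "trial", drop = FALSE])
  n <- nrow(trials)
  rdk_len <- 2.1
  with_rng_seed(seed, {
    j1 <- rpois_clipped(n, 2, 1, 5)
    j2 <- rpois_clipped(n, 3.5, 2, 8)
    iti <- rpois_clipped(n, 2, 1, 5)
    t0 <- 0
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      rdk <- t0 + rdk_len * 0:3
      obs_off <- t0 + 4 * rdk_len
      d1 <- obs_off + j1[i]
      r1 <- d1 + decision_duration
      d2 <- r1 + 0.5 + j2[i]
      r2 <- d2 + decision_duration
      t_end <- r2 + 0.5 + iti[i]
      rows[[i]] <- tibble(trial = trials$trial[i],
                          rdk_onset1 = rdk[1], rdk_onset2 = rdk[2],
                          rdk_onset3 = rdk[3], rdk_onset4 = rdk[4],
                          obs_offset = obs_off, dec1_onset = d1,
                          dec2_onset = d2, response1 = r1, response2 = r2,
                          trial_end = t_end)
      t0 <- t_end
    }
    bind_rows(rows)
  })
}

std_or_zero <- function(x) {
  if (stats::sd(x) == 0) rep(0, length(x)) else zscore(x)
}

add_events <- function(acc, name, onset, duration, value, modulation) {
  acc[[length(acc) + 1L]] <- tibble(regressor = name, onset = onset,
                                    duration = duration, value_raw = value,
                                    modulation = modulation)
  acc
}

#' Build an fMRI first-level event table
#'
#' Constructs the event table (onsets, durations, parametric values) for one
#' of the designs in [design_manifest()], from a schedule, simulated choices
#' (needed for the choice-dependent regressors of GLM2 and GLM3) and a
#' [trial_timing()] table. All parametric regressors are standardised to
#' mean 0 / sd 1 across their events; interaction regressors are built by
#' standardising both components first and multiplying.
#'
#' @inheritParams design_manifest
#' @inheritParams add_decision_variables
#' @param choices Simulated choices of a single participant/simulation (one
#'   row per decision), or `NULL` for choice-free designs (GLM1, ROI GLMs).
#' @param timing Output of [trial_timing()]; generated with `seed` if `NULL`.
#' @param seed Seed for generated timing.
#' @return A `bf_design` object: the event table (`$events`, with raw and
#'   standardised values), `$manifest`, `$timing` and `$glm_id`.
#' @export
build_design <- function(glm_id, schedule, choices = NULL, timing = NULL,
                         seed = 1L) {
  glm_id <- match.arg(glm_id, c("GLM1", "GLM2", "GLM3", "ROI_GLM1",
                                "ROI_GLM2"))
  manifest <- design_manifest(glm_id)
  aug <- add_decision_variables(schedule)
  if (is.null(timing)) timing <- trial_timing(schedule, seed = seed)
  tr <- aug %>% dplyr::distinct(.data$trial, .keep_all = TRUE) %>%
    left_join(timing, by = "trial")
  dec <- aug %>% left_join(timing, by = "trial") %>%
    mutate(onset = ifelse(.data$decision == 1, .data$dec1_onset,
                          .data$dec2_onset),
           response = ifelse(.data$decision == 1, .data$response1,
                             .data$response2))
  needs_choices <- glm_id %in% c("GLM2", "GLM3")
  if (needs_choices) {
    if (is.null(choices)) {
      stop(glm_id, " includes choice-dependent regressors; supply `choices`.",
           call. = FALSE)
    }
    dec <- dec %>%
      dplyr::inner_join(choices[, c("trial", "decision", "choice")],
                        by = c("trial", "decision"))
  }
  rdk_on <- as.matrix(tr[, paste0("rdk_onset", 1:4)])
  # identity -> sequence position per trial, for player-locked regressors
  ords <- do.call(rbind, strsplit(tr$order, "-", fixed = TRUE))
  ev <- list()

  if (glm_id == "GLM1") {
    ev <- add_events(ev, "rdk", as.vector(t(rdk_on)), 2, 1, "constant")
    for (id in player_labels()) {
      pos_of_id <- apply(ords == id, 1, which)
      ev <- add_events(ev, paste0(id, "_perf"),
                       rdk_on[cbind(seq_len(nrow(tr)), pos_of_id)], 2,
                       tr[[id]], "parametric")
    }
    bin <- paste0(toupper(substr(dec$dtype, 1, 1)), dec$decision)
    for (b in c("S1", "S2", "P1", "P2", "G1", "G2")) {
      rows <- dec[bin == b, ]
      ev <- add_events(ev, b, rows$onset, 2, 1, "constant")
      players <- if (substr(b, 1, 1) == "G") c("S", "P", "O1", "O2") else
        c("S", "P", "Or", "Oi")
      for (pl in players) {
        v <- switch(pl,
          S = rows$S, P = rows$P, O1 = rows$O1, O2 = rows$O2,
          Or = ifelse(rows$relevant_opponent == "O2", rows$O2, rows$O1),
          Oi = ifelse(rows$relevant_opponent == "O2", rows$O1, rows$O2))
        ev <- add_events(ev, paste0(b, "_", pl), rows$onset, 2, v,
                         "parametric")
      }
      ev <- add_events(ev, paste0(b, "_bonus"), rows$onset, 2, rows$bonus,
                       "parametric")
    }
    ev <- add_events(ev, "button_press", dec$response, 0.1, 1, "constant")
  }

  if (glm_id == "GLM2") {
    stick_t <- tr$obs_offset + 2
    ev <- add_events(ev, "obs_stick", stick_t, 0.1, 1, "constant")
    for (nm in c("b1", "b2", "b3")) {
      ev <- add_events(ev, nm, stick_t, 0.1, tr[[nm]], "parametric")
    }
    for (id in player_labels()) {
      ev <- add_events(ev, paste0(id, "_perf"), stick_t, 0.1, tr[[id]],
                       "parametric")
    }
    ev <- add_events(ev, "S_position", tr$obs_offset, 0.1, tr$s_position,
                     "parametric")
    ev <- add_events(ev, "P_position", tr$obs_offset, 0.1, tr$p_position,
                     "parametric")
    for (tp in c("self", "partner", "group")) {
      rows <- dec[dec$dtype == tp, ]
      pref <- c(self = "S_dec", partner = "P_dec", group = "G_dec")[[tp]]
      ev <- add_events(ev, pref, rows$onset, 2, 1, "constant")
      ch_sgn <- std_or_zero(rows$choice)
      ev <- add_events(ev, paste0(pref, "_DV"), rows$onset, 2, rows$dv,
                       "parametric")
      ev <- add_events(ev, paste0(pref, "_DVxC"), rows$onset, 2,
                       std_or_zero(rows$dv) * ch_sgn, "parametric")
      ev <- add_events(ev, paste0(pref, "_choice"), rows$onset, 2,
                       rows$choice, "parametric")
      if (tp != "group") {
        own_irr <- if (tp == "self") rows$P else rows$S
        opp_irr <- ifelse(rows$relevant_opponent == "O2", rows$O1, rows$O2)
        dvi <- own_irr - opp_irr
        ev <- add_events(ev, paste0(pref, "_DVi"), rows$onset, 2, dvi,
                         "parametric")
        ev <- add_events(ev, paste0(pref, "_DVixC"), rows$onset, 2,
                         std_or_zero(dvi) * ch_sgn, "parametric")
      }
    }
    ev <- add_events(ev, "button_press", dec$response, 0.1, 1, "constant")
  }

  if (glm_id == "GLM3") {
    ev <- add_events(ev, "rdk", as.vector(t(rdk_on)), 2, 1, "constant")
    B <- as.matrix(dec[, c("b1", "b2", "b3")])
    prim <- B[cbind(seq_len(nrow(dec)), dec$primary_idx)]
    sec <- ifelse(is.na(dec$secondary_idx), NA_real_,
                  B[cbind(seq_len(nrow(dec)),
                          ifelse(is.na(dec$secondary_idx), 1L,
                                 dec$secondary_idx))])
    ter <- ifelse(is.na(dec$tertiary_idx), NA_real_,
                  B[cbind(seq_len(nrow(dec)),
                          ifelse(is.na(dec$tertiary_idx), 1L,
                                 dec$tertiary_idx))])
    for (dbin in c("DY1", "DY2")) {
      rows_i <- dec$dtype != "group" & dec$decision == as.integer(substr(
        dbin, 3, 3))
      rows <- dec[rows_i, ]
      ev <- add_events(ev, dbin, rows$onset, 2, 1, "constant")
      ch_sgn <- std_or_zero(rows$choice)
      vals <- list(
        primary = prim[rows_i], secondary = sec[rows_i],
        tertiary = ter[rows_i], inv_primary = rows$inv_primary,
        sec_inversion = as.numeric(rows$secondary_sign < 0),
        inv_primary_x_choice = std_or_zero(rows$inv_primary) * ch_sgn,
        inv_secondary_x_choice = std_or_zero(rows$inv_secondary) * ch_sgn,
        bonus = rows$bonus,
        bonus_x_choice = std_or_zero(rows$bonus) * ch_sgn,
        inv_secondary = rows$inv_secondary
      )
      for (nm in names(vals)) {
        ev <- add_events(ev, paste0(dbin, "_", nm), rows$onset, 2,
                         vals[[nm]], "parametric")
      }
    }
    rows_g <- dec$dtype == "group"
    rows <- dec[rows_g, ]
    ev <- add_events(ev, "G", rows$onset, 2, 1, "constant")
    ch_sgn <- std_or_zero(rows$choice)
    gvals <- list(
      primary = prim[rows_g], inv_primary = rows$inv_primary,
      inv_primary_x_choice = std_or_zero(rows$inv_primary) * ch_sgn,
      bonus = rows$bonus,
      bonus_x_choice = std_or_zero(rows$bonus) * ch_sgn
    )
    for (nm in names(gvals)) {
      ev <- add_events(ev, paste0("G_", nm), rows$onset, 2, gvals[[nm]],
                       "parametric")
    }
    ev <- add_events(ev, "button_press", dec$response, 0.1, 1, "constant")
  }

  if (glm_id %in% c("ROI_GLM1", "ROI_GLM2")) {
    vals <- list(b1 = tr$b1, b2 = tr$b2, b3 = tr$b3)
    if (glm_id == "ROI_GLM1") {
      vals <- c(vals, list(S_perf = tr$S, P_perf = tr$P, O1_perf = tr$O1,
                           O2_perf = tr$O2))
    } else {
      vals <- c(vals, list(null_vector = tr$S + tr$P + tr$O1 + tr$O2))
    }
    vals <- c(vals, list(S_position = tr$s_position,
                         P_position = tr$p_position))
    for (nm in names(vals)) {
      ev <- add_events(ev, nm, tr$obs_offset, 0, vals[[nm]], "parametric")
    }
  }

  events <- bind_rows(ev)
  events <- events %>%
    group_by(.data$regressor) %>%
    mutate(value = ifelse(.data$modulation == "parametric",
                          std_or_zero(.data$value_raw), .data$value_raw)) %>%
    ungroup()

  built <- sort(unique(events$regressor))
  expected <- sort(manifest$name)
  stopifnot(identical(built, expected))
  structure(list(glm_id = glm_id, events = events, manifest = manifest,
                 timing = timing),
            class = "bf_design")
}

#' @export
print.bf_design <- function(x, ...) {
  cat("<bf_design>", x$glm_id, "-", length(unique(x$events$regressor)),
      "regressors,", nrow(x$events), "events\n")
  invisible(x)
}

#' Double-gamma haemodynamic response function
#'
#' Canonical double-gamma HRF: peak at 6 s, undershoot at 16 s,
#' peak-to-undershoot ratio 6, 32-s kernel.
#'
#' @param t Time points, seconds.
#' @param peak,undershoot,ratio Shape parameters.
#' @return HRF values (unit peak mass convention of the gamma densities).
#' @export
double_gamma_hrf <- function(t, peak = 6, undershoot = 16, ratio = 6) {
  h <- stats::dgamma(t, shape = peak, rate = 1) -
    stats::dgamma(t, shape = undershoot, rate = 1) / ratio
  h[t < 0] <- 0
  h
}

#' Convolve an event table into a design matrix
#'
#' Each regressor's events are placed on a fine time grid as a boxcar of its
#' duration (impulse for zero durations) scaled by the event value, convolved
#' with the double-gamma HRF and sampled at the TR grid. Temporal derivative
#' columns can be appended.
#'
#' @param design A `bf_design` from [build_design()].
#' @param TR Repetition time, seconds (default 1.2).
#' @param dt_grid Fine grid step for convolution (default 0.1 s).
#' @param total_duration Scan duration, seconds; defaults to the end of the
#'   last trial plus 20 s.
#' @param derivatives Append temporal derivatives? Default `FALSE`.
#' @param hrf HRF function taking a time vector (default
#'   [double_gamma_hrf()]).
#' @return A `bf_design_matrix`: list with the numeric matrix `$X`
#'   (volumes x regressors), `$frame_times`, `$TR` and `$glm_id`.
#' @export
convolve_hrf <- function(design, TR = 1.2, dt_grid = 0.1,
                         total_duration = NULL, derivatives = FALSE,
                         hrf = double_gamma_hrf) {
  events <- design$events
  if (is.null(total_duration)) {
    total_duration <- max(design$timing$trial_end) + 20
  }
  grid <- seq(0, total_duration, by = dt_grid)
  kernel <- hrf(seq(0, 32, by = dt_grid))
  frame_times <- seq(0, total_duration, by = TR)
  regs <- unique(events$regressor)
  X <- matrix(0, length(frame_times), length(regs),
              dimnames = list(NULL, regs))
  for (j in seq_along(regs)) {
    e <- events[events$regressor == regs[j], ]
    stim <- numeric(length(grid))
    for (i in seq_len(nrow(e))) {
      i0 <- findInterval(e$onset[i], grid)
      i1 <- findInterval(e$onset[i] + max(e$duration[i], dt_grid / 2), grid)
      i1 <- max(i1, i0)
      stim[i0:i1] <- stim[i0:i1] + e$value[i]
    }
    conv <- stats::convolve(stim, rev(kernel), type = "open")[
      seq_along(grid)] * dt_grid
    X[, j] <- stats::approx(grid, conv, xout = frame_times, rule = 2)$y
  }
  if (derivatives) {
    D <- apply(X, 2, function(col) c(0, diff(col)) / TR)
    colnames(D) <- paste0(colnames(X), "_deriv")
    X <- cbind(X, D)
  }
  structure(list(X = X, frame_times = frame_times, TR = TR,
                 glm_id = design$glm_id),
            class = "bf_design_matrix")
}

#' @export
print.bf_design_matrix <- function(x, ...) {
  cat("<bf_design_matrix>", x$glm_id, "-", nrow(x$X), "volumes x",
      ncol(x$X), "columns (TR =", x$TR, "s)\n")
  invisible(x)
}

#' Simulate a BOLD time series with known effects
#'
#' Linear combination of design-matrix columns plus Gaussian noise with
#' optional AR(1) structure: a synthetic validation surrogate for a real ROI
#' or voxel time course.
#'
#' @param design_matrix A `bf_design_matrix`.
#' @param true_betas Named vector of effects; columns not named get beta 0.
#' @param noise_sd Noise standard deviation.
#' @param seed Integer seed.
#' @param ar1 AR(1) coefficient of the noise (default 0.3).
#' @return Numeric BOLD vector, one value per volume.
#' @export
simulate_bold <- function(design_matrix, true_betas = NULL, noise_sd = 1,
                          seed = 1L, ar1 = 0.3) {
  X <- design_matrix$X
  beta <- setNames(numeric(ncol(X)), colnames(X))
  if (!is.null(true_betas)) {
    unknown <- setdiff(names(true_betas), names(beta))
    if (length(unknown)) stop("Unknown regressors: ",
                              paste(unknown, collapse = ", "), call. = FALSE)
    beta[names(true_betas)] <- true_betas
  }
  signal <- drop(X %*% beta)
  noise <- with_rng_seed(seed, {
    if (noise_sd == 0) numeric(length(signal)) else if (ar1 == 0) {
      stats::rnorm(length(signal), sd = noise_sd)
    } else {
      as.numeric(stats::arima.sim(list(ar = ar1), length(signal),
                                  sd = noise_sd * sqrt(1 - ar1^2)))
    }
  })
  signal + noise
}

#' ROI time-course GLM
#'
#' Normalises the BOLD series (z-scoring, the per-session convention),
#' oversamples it tenfold by cubic-spline interpolation, epochs it trialwise
#' around the lock event (observation-phase offset) and fits, at every epoch
#' time point, a GLM of the per-trial BOLD values on the standardised
#' regressors of the requested ROI design, yielding one beta time course per
#' regressor.
#'
#' @param series Numeric BOLD vector sampled at `TR`.
#' @param schedule The schedule the series was generated from.
#' @param regressor_set `"ROI_GLM1"` or `"ROI_GLM2"`.
#' @param timing A [trial_timing()] table (must match the series).
#' @param TR Repetition time (default 1.2 s).
#' @param window Epoch window around the lock event, seconds (default
#'   `c(-2, 12)`); epochs exceeding the series are trimmed with a warning.
#' @param oversample Oversampling factor (default 10).
#' @return A `bf_roi_timecourse`: matrix `$betas` (regressors x time points),
#'   `$time` (seconds relative to lock), `$n_trials`.
#' @export
roi_timecourse_glm <- function(series, schedule,
                               regressor_set = c("ROI_GLM1", "ROI_GLM2"),
                               timing, TR = 1.2, window = c(-2, 12),
                               oversample = 10L) {
  regressor_set <- match.arg(regressor_set)
  design <- build_design(regressor_set, schedule, timing = timing)
  ev <- design$events
  Z <- do.call(cbind, lapply(split(ev$value, ev$regressor)[
    unique(ev$regressor)], identity))
  lock <- design$timing$obs_offset

  t_orig <- (seq_along(series) - 1) * TR
  t_fine <- seq(0, max(t_orig), by = TR / oversample)
  z <- zscore(series)
  fine <- stats::spline(t_orig, z, xout = t_fine)$y

  rel_time <- seq(window[1], window[2], by = TR / oversample)
  epochs <- matrix(NA_real_, length(lock), length(rel_time))
  for (i in seq_along(lock)) {
    tt <- lock[i] + rel_time
    ok <- tt >= 0 & tt <= max(t_fine)
    idx <- round(tt[ok] / (TR / oversample)) + 1L
    epochs[i, ok] <- fine[idx]
  }
  if (anyNA(epochs)) {
    warning("Some epochs exceed the series bounds and were trimmed.")
  }
  betas <- matrix(NA_real_, ncol(Z), length(rel_time),
                  dimnames = list(colnames(Z), NULL))
  Xd <- cbind(1, Z)
  for (tp in seq_along(rel_time)) {
    y <- epochs[, tp]
    ok <- !is.na(y)
    if (sum(ok) > ncol(Xd)) {
      fit <- stats::lm.fit(Xd[ok, , drop = FALSE], y[ok])
      betas[, tp] <- fit$coefficients[-1]
    }
  }
  structure(list(betas = betas, time = rel_time,
                 n_trials = length(lock), regressor_set = regressor_set,
                 oversample = oversample),
            class = "bf_roi_timecourse")
}

#' @export
print.bf_roi_timecourse <- function(x, ...) {
  cat("<bf_roi_timecourse>", x$regressor_set, "-", nrow(x$betas),
      "regressors,", length(x$time), "time points,", x$n_trials, "trials\n")
  invisible(x)
}

#' Plot ROI beta time courses
#'
#' @param object A `bf_roi_timecourse`.
#' @param regressors Subset of regressor names (default all).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bf_roi_timecourse <- function(object, regressors = NULL, ...) {
  regs <- if (is.null(regressors)) rownames(object$betas) else regressors
  df <- bind_rows(lapply(regs, function(r) {
    tibble(regressor = r, time = object$time, beta = object$betas[r, ])
  }))
  ggplot(df, aes(x = .data$time, y = .data$beta, colour = .data$regressor)) +
    geom_line() +
    geom_hline(yintercept = 0, linewidth = 0.2) +
    labs(x = "time from observation offset (s)", y = "beta (a.u.)") +
    theme_minimal()
}

#' Leave-one-out peak test on beta time courses
#'
#' For each subject, the peak latency is the time of the maximal absolute
#' deviation from zero of the remaining subjects' mean time course within the
#' analysis window; the left-out subject's beta is read at that latency,
#' which keeps the read-out independent of the subject's own data. The
#' resulting per-subject betas are tested against zero with a two-sided
#' one-sample t-test.
#'
#' @param betas Subjects x time points matrix of beta time courses for one
#'   regressor.
#' @param time Time vector (seconds relative to the lock event).
#' @param window Analysis window, seconds (default `c(4, 10)`; an early
#'   window such as `c(0, 6)` suits fast position effects).
#' @return A list: per-subject `values` and `peak_times`, `estimate` (mean
#'   beta), `statistic`, `p.value`, `df`.
#' @export
loo_peak_test <- function(betas, time, window = c(4, 10)) {
  betas <- as.matrix(betas)
  n <- nrow(betas)
  if (n < 3) stop("At least 3 subjects are required.", call. = FALSE)
  in_win <- which(time >= window[1] & time <= window[2])
  if (length(in_win) == 0) {
    stop("The analysis window lies outside the epoch.", call. = FALSE)
  }
  values <- numeric(n)
  peaks <- numeric(n)
  for (i in seq_len(n)) {
    gm <- colMeans(betas[-i, , drop = FALSE])
    pk <- in_win[which.max(abs(gm[in_win]))]
    peaks[i] <- time[pk]
    values[i] <- betas[i, pk]
  }
  tt <- tryCatch(stats::t.test(values), error = function(e) NULL)
  list(values = values, peak_times = peaks,
       estimate = mean(values),
       statistic = if (is.null(tt)) NA_real_ else unname(tt$statistic),
       p.value = if (is.null(tt)) NA_real_ else tt$p.value,
       df = if (is.null(tt)) NA_real_ else unname(tt$parameter))
}

#' Export an event table in onset/duration/value text format
#'
#' Writes one three-column whitespace-delimited text file per regressor (the
#' de-facto standard for first-level fMRI events) plus a JSON manifest.
#'
#' @param design A `bf_design`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_design_events <- function(design, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- vapply(unique(design$events$regressor), function(r) {
    e <- design$events[design$events$regressor == r, ]
    f <- file.path(dir, paste0(design$glm_id, "_", r, ".txt"))
    utils::write.table(data.frame(e$onset, e$duration, e$value), f,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
    f
  }, character(1))
  jsonlite::write_json(design$manifest,
                       file.path(dir, paste0(design$glm_id,
                                             "_manifest.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(unname(files))
}
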