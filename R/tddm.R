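#' @useDynLib socialbasis, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

tddm_param_names <- function() {
  c("w_primary", "w_secondary", "w_bonus", "onset_asynchrony", "threshold",
    "start_bias", "non_decision_time")
}

#' Time-varying drift-diffusion model parameters
#'
#' The seven free parameters of the tDDM: drift weights of the inverted
#' primary projection, the inverted secondary projection and the bonus; the
#' onset asynchrony of the secondary attribute relative to the primary
#' (seconds; negative values mean the secondary enters evidence accumulation
#' first); the decision threshold; the starting-point bias (fraction of the
#' threshold span, 0.5 = unbiased); and the non-decision time (seconds). The
#' bonus always enters the accumulation at the earlier of the two attribute
#' onsets.
#'
#' @param w_primary,w_secondary,w_bonus Drift weights.
#' @param onset_asynchrony Secondary-minus-primary onset difference, seconds.
#' @param threshold Decision threshold (> 0).
#' @param start_bias Starting point as a fraction of the threshold (0..1).
#' @param non_decision_time Non-decision time, seconds (>= 0).
#' @return A named list of class `bf_tddm_params`.
#' @export
tddm_params <- function(w_primary = 0.15, w_secondary = 0.15, w_bonus = 0.1,
                        onset_asynchrony = 0, threshold = 0.2,
                        start_bias = 0.5, non_decision_time = 0.3) {
  p <- list(w_primary = w_primary, w_secondary = w_secondary,
            w_bonus = w_bonus, onset_asynchrony = onset_asynchrony,
            threshold = threshold, start_bias = start_bias,
            non_decision_time = non_decision_time)
  if (!all(vapply(p, function(z) is.numeric(z) && length(z) == 1 &&
                    is.finite(z), logical(1)))) {
    stop("All tDDM parameters must be finite scalars.", call. = FALSE)
  }
  if (p$threshold <= 0) stop("`threshold` must be positive.", call. = FALSE)
  if (p$start_bias <= 0 || p$start_bias >= 1) {
    stop("`start_bias` must lie strictly between 0 and 1.", call. = FALSE)
  }
  if (p$non_decision_time < 0) {
    stop("`non_decision_time` must be non-negative.", call. = FALSE)
  }
  structure(p, class = "bf_tddm_params")
}

# two-stage drift for one attribute combination: the attribute with the
# earlier onset (plus the bonus) drives the first stage, the other attribute
# joins after |onset_asynchrony| seconds
tddm_drifts <- function(params, primary, secondary, bonus) {
  a <- params$onset_asynchrony
  if (a >= 0) {
    early <- params$w_primary * primary + params$w_bonus * bonus
    late <- early + params$w_secondary * secondary
    switch_time <- a
  } else {
    early <- params$w_secondary * secondary + params$w_bonus * bonus
    late <- early + params$w_primary * primary
    switch_time <- -a
  }
  list(early = early, late = late, switch_time = switch_time)
}

#' Simulate choices and reaction times from the tDDM
#'
#' Euler-Maruyama simulation of the two-stage accumulation process for a
#' single attribute combination: evidence starts at `start_bias * threshold`
#' and drifts with the early-onset attribute (plus bonus) until the onset
#' asynchrony has elapsed, after which the second attribute joins. Absorption
#' at the upper bound is an engage choice, at zero an avoid choice; the
#' reaction time is the first-passage time plus the non-decision time.
#'
#' @param params A [tddm_params()] object.
#' @param primary,secondary,bonus Standardised attribute values of the
#'   decision.
#' @param n Number of simulated decisions.
#' @param seed Integer seed.
#' @param dt Euler step, seconds (default 0.001).
#' @param noise_sd Diffusion noise standard deviation per sqrt-second
#'   (fixed scale 0.1 by convention for identifiability).
#' @param max_t Maximal accumulation duration, seconds; walks still alive are
#'   truncated, classified by the nearer boundary and flagged.
#' @return A tibble with `choice` (1 engage / 0 avoid), `rt` and `truncated`.
#' @export
simulate_tddm <- function(params, primary, secondary, bonus, n = 3000L,
                          seed = 1L, dt = 0.001, noise_sd = 0.1, max_t = 10) {
  if (!inherits(params, "bf_tddm_params")) params <- do.call(tddm_params,
                                                             params)
  if (dt <= 0) stop("`dt` must be positive.", call. = FALSE)
  if (n < 1) stop("`n` must be at least 1.", call. = FALSE)
  dr <- tddm_drifts(params, primary, secondary, bonus)
  res <- with_rng_seed(seed, {
    tddm_simulate_cpp(as.integer(n), dr$early, dr$late, dr$switch_time,
                      params$threshold, params$start_bias,
                      params$non_decision_time, dt, noise_sd, max_t)
  })
  as_tibble(res)
}

#' Simulate a tDDM dataset over a schedule's attribute combinations
#'
#' Builds the standardised attribute triples (inverted primary, inverted
#' secondary, bonus) of a schedule's dyadic decisions and simulates one
#' choice/RT pair per decision.
#'
#' @inheritParams add_decision_variables
#' @inheritParams simulate_tddm
#' @param decisions Decision types to include (default dyadic).
#' @return An RT dataset tibble: `trial`, `decision`, `primary`, `secondary`,
#'   `bonus`, `choice`, `rt`.
#' @export
simulate_tddm_dataset <- function(schedule, params, seed = 1L,
                                  decisions = c("self", "partner"),
                                  dt = 0.001, noise_sd = 0.1, max_t = 10) {
  aug <- add_decision_variables(schedule)
  aug <- aug[aug$dtype %in% decisions, ]
  if (any(aug$dtype == "group")) {
    stop("The tDDM is defined for dyadic decisions (primary and secondary ",
         "attributes).", call. = FALSE)
  }
  dat <- tibble(
    trial = aug$trial, decision = aug$decision,
    primary = zscore(aug$inv_primary), secondary = zscore(aug$inv_secondary),
    bonus = zscore(aug$bonus)
  )
  sim <- simulate_tddm_trials(params, dat, n_per = 1L, seed = seed, dt = dt,
                              noise_sd = noise_sd, max_t = max_t)
  dplyr::bind_cols(dat, sim[, c("choice", "rt")])
}

#' Simulate an RT dataset from a table of attribute combinations
#'
#' Generates `n_per` simulated decisions for every row of `attrs` (columns
#' `primary`, `secondary`, `bonus`), sharing one forward simulation per
#' unique attribute combination. Useful for building repeated-measures
#' recovery designs in which the same combinations recur.
#'
#' @inheritParams simulate_tddm
#' @param attrs Tibble of attribute triples.
#' @param n_per Simulated decisions per row of `attrs`.
#' @return A tibble: `primary`, `secondary`, `bonus`, `choice`, `rt`.
#' @export
simulate_tddm_trials <- function(params, attrs, n_per = 1L, seed = 1L,
                                 dt = 0.001, noise_sd = 0.1, max_t = 10) {
  if (!inherits(params, "bf_tddm_params")) params <- do.call(tddm_params,
                                                             params)
  idx <- rep(seq_len(nrow(attrs)), each = n_per)
  out_choice <- integer(length(idx))
  out_rt <- numeric(length(idx))
  keys <- tddm_group_key(attrs)
  for (gi in seq_along(sort(unique(keys)))) {
    key <- sort(unique(keys))[gi]
    rows <- which(keys[idx] == key)
    i0 <- which(keys == key)[1]
    dr <- tddm_drifts(params, attrs$primary[i0], attrs$secondary[i0],
                      attrs$bonus[i0])
    sim <- with_rng_seed(seed + gi, {
      tddm_simulate_cpp(length(rows), dr$early, dr$late, dr$switch_time,
                        params$threshold, params$start_bias,
                        params$non_decision_time, dt, noise_sd, max_t)
    })
    out_choice[rows] <- sim$choice
    out_rt[rows] <- sim$rt
  }
  tibble(primary = attrs$primary[idx], secondary = attrs$secondary[idx],
         bonus = attrs$bonus[idx], choice = out_choice, rt = out_rt)
}

tddm_group_key <- function(data) {
  paste(round(data$primary, 6), round(data$secondary, 6),
        round(data$bonus, 6))
}

#' Simulation-based log-likelihood of an RT dataset under the tDDM
#'
#' For each unique combination of primary attribute, secondary attribute and
#' bonus present in the data, a forward simulation generates the joint
#' choice-by-RT distribution, discretised into fixed-width RT bins per choice
#' with add-one smoothing (so observed cells never have zero probability).
#' The log-likelihood is the sum of the log probabilities of the observed
#' (choice, RT) pairs. Simulation seeds are derived deterministically per
#' attribute combination, so the likelihood surface is fixed given `seed`.
#'
#' @param params A [tddm_params()] object (or coercible list).
#' @param data RT dataset with columns `choice`, `rt`, `primary`,
#'   `secondary`, `bonus`.
#' @param n_sims Simulated decisions per unique attribute combination
#'   (default 3000).
#' @param seed Integer seed.
#' @param bin_width RT histogram bin width, seconds (default 0.05).
#' @inheritParams simulate_tddm
#' @return The log-likelihood (scalar).
#' @export
tddm_loglik <- function(params, data, n_sims = 3000L, seed = 1L,
                        bin_width = 0.05, dt = 0.001, noise_sd = 0.1,
                        max_t = 10) {
  if (nrow(data) == 0) stop("Empty RT dataset.", call. = FALSE)
  if (!inherits(params, "bf_tddm_params")) params <- do.call(tddm_params,
                                                             params)
  keys <- tddm_group_key(data)
  groups <- split(seq_len(nrow(data)), keys)
  groups <- groups[order(names(groups))]  # deterministic, order-invariant
  breaks <- seq(0, max_t + ceiling(params$non_decision_time) + 1, bin_width)
  n_bins <- length(breaks) - 1L
  ll <- 0
  for (gi in seq_along(groups)) {
    rows <- groups[[gi]]
    i0 <- rows[1]
    dr <- tddm_drifts(params, data$primary[i0], data$secondary[i0],
                      data$bonus[i0])
    sim <- with_rng_seed(seed + gi, {
      tddm_simulate_cpp(as.integer(n_sims), dr$early, dr$late,
                        dr$switch_time, params$threshold, params$start_bias,
                        params$non_decision_time, dt, noise_sd, max_t)
    })
    bin_sim <- pmin(pmax(findInterval(sim$rt, breaks), 1L), n_bins)
    # cells indexed choice-major: add-one smoothing over choice x bin
    counts <- tabulate(bin_sim + sim$choice * n_bins, nbins = 2L * n_bins)
    log_probs <- log(counts + 1) - log(n_sims + 2 * n_bins)
    bin_obs <- pmin(pmax(findInterval(data$rt[rows], breaks), 1L), n_bins)
    ll <- ll + sum(log_probs[bin_obs + data$choice[rows] * n_bins])
  }
  ll
}

# bounds on the sigma = 0.1 diffusion-noise convention: drift weights and
# thresholds live on the same 0.1 scale
default_tddm_bounds <- function() {
  list(w_primary = c(0, 0.6), w_secondary = c(0, 0.6), w_bonus = c(0, 0.6),
       onset_asynchrony = c(-1, 1), threshold = c(0.05, 0.6),
       start_bias = c(0.15, 0.85), non_decision_time = c(0.05, 1.5))
}

#' Fit the tDDM by differential evolution
#'
#' Maximises the simulation-based likelihood of the choice and reaction-time
#' data over the seven tDDM parameters (or fewer, if some are held fixed via
#' `fixed`, e.g. `fixed = list(onset_asynchrony = 0)` for the no-asynchrony
#' model of the likelihood-ratio test). The optimiser is a seeded best/1/bin
#' differential-evolution scheme; simulation random numbers are frozen across
#' evaluations so the noisy likelihood surface is internally consistent.
#'
#' @inheritParams tddm_loglik
#' @param bounds Named list of `c(lower, upper)` for each free parameter;
#'   defaults cover the plausible ranges of all seven.
#' @param fixed Named list of parameters to hold constant.
#' @param n_iterations Differential-evolution iterations (default 150).
#' @param pop_size Population size (default 10 per free parameter).
#' @param seed Integer seed governing both the optimiser and the simulations.
#' @return A `bf_tddm_fit`: fitted [tddm_params()], `loglik`, optimisation
#'   `trace` and settings.
#' @export
fit_tddm <- function(data, bounds = default_tddm_bounds(), fixed = list(),
                     seed = 1L, n_iterations = 150L, n_sims = 3000L,
                     pop_size = NULL, bin_width = 0.05, dt = 0.001,
                     noise_sd = 0.1, max_t = 10) {
  free <- setdiff(tddm_param_names(), names(fixed))
  if (!all(free %in% names(bounds))) {
    stop("`bounds` must cover every free parameter.", call. = FALSE)
  }
  bad <- !vapply(bounds[free], function(b) length(b) == 2 &&
                   all(is.finite(b)) && b[2] >= b[1], logical(1))
  if (any(bad)) stop("Invalid bounds for: ", paste(free[bad], collapse = ", "),
                     call. = FALSE)
  if (is.null(pop_size)) pop_size <- 10L * length(free)
  lower <- vapply(bounds[free], `[`, numeric(1), 1)
  upper <- vapply(bounds[free], `[`, numeric(1), 2)

  as_params <- function(x) {
    p <- as.list(x)
    names(p) <- free
    do.call(tddm_params, c(p, fixed))
  }
  objective <- function(x) {
    -tddm_loglik(as_params(x), data, n_sims = n_sims, seed = seed,
                 bin_width = bin_width, dt = dt, noise_sd = noise_sd,
                 max_t = max_t)
  }
  opt <- de_optimize(objective, lower, upper, pop_size = pop_size,
                     n_iterations = n_iterations, seed = seed + 1000L)
  structure(list(
    params = as_params(opt$par), loglik = -opt$value, trace = -opt$trace,
    free = free, fixed = fixed, n_trials = nrow(data),
    settings = list(n_sims = n_sims, n_iterations = n_iterations,
                    pop_size = pop_size, seed = seed, dt = dt,
                    noise_sd = noise_sd, bin_width = bin_width,
                    max_t = max_t)
  ), class = "bf_tddm_fit")
}

#' @export
print.bf_tddm_fit <- function(x, ...) {
  cat("<bf_tddm_fit>", x$n_trials, "trials, logLik =", round(x$loglik, 2),
      "\n")
  print(unlist(x$params))
  invisible(x)
}

#' @export
tidy.bf_tddm_fit <- function(x, ...) {
  tibble(term = tddm_param_names(),
         estimate = unlist(x$params)[tddm_param_names()],
         fixed = tddm_param_names() %in% names(x$fixed))
}

#' @export
glance.bf_tddm_fit <- function(x, ...) {
  tibble(logLik = x$loglik, n_trials = x$n_trials,
         n_free = length(x$free),
         n_iterations = x$settings$n_iterations, n_sims = x$settings$n_sims)
}

#' Plot the RT distribution implied by a tDDM fit
#'
#' Overlays the observed reaction-time distribution (sign-flipped for avoid
#' choices, the usual defective-distribution display) with the distribution
#' simulated from the fitted parameters.
#'
#' @param object A `bf_tddm_fit`.
#' @param data The RT dataset the model was fitted to.
#' @param n_sims Simulated decisions per attribute combination.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bf_tddm_fit <- function(object, data, n_sims = 1000L, ...) {
  keys <- unique(data[, c("primary", "secondary", "bonus")])
  sims <- bind_rows(lapply(seq_len(nrow(keys)), function(i) {
    simulate_tddm(object$params, keys$primary[i], keys$secondary[i],
                  keys$bonus[i], n = n_sims, seed = object$settings$seed + i,
                  dt = object$settings$dt,
                  noise_sd = object$settings$noise_sd)
  }))
  df <- bind_rows(
    tibble(source = "observed", rt = ifelse(data$choice == 1, 1, -1) *
             data$rt),
    tibble(source = "model", rt = ifelse(sims$choice == 1, 1, -1) * sims$rt)
  )
  ggplot(df, aes(x = .data$rt, colour = .data$source)) +
    ggplot2::geom_density() +
    geom_hline(yintercept = 0, linewidth = 0.2) +
    labs(x = "signed RT (s; engage > 0, avoid < 0)", y = "density") +
    theme_minimal()
}

#' Likelihood-ratio test for the onset asynchrony
#'
#' Compares, per participant, the full tDDM against the constrained refit
#' with `onset_asynchrony` fixed at zero: the statistic is
#' `2 * (logLik_full - logLik_constrained)`, referenced against a chi-squared
#' distribution with one degree of freedom. When `data` is supplied, both
#' parameter sets are re-evaluated on a common simulation seed so that the
#' two log-likelihoods are directly comparable; otherwise the stored fit
#' likelihoods are used.
#'
#' @param fits_full,fits_constrained Named lists of `bf_tddm_fit` objects
#'   (same participant names), or single fits.
#' @param data Optional named list of RT datasets for common-seed
#'   re-evaluation.
#' @param n_sims,seed Re-evaluation settings (defaults: the full fit's).
#' @return A tibble with one row per participant: the two log-likelihoods,
#'   `statistic`, `df` and `p.value`.
#' @export
asynchrony_test <- function(fits_full, fits_constrained, data = NULL,
                            n_sims = NULL, seed = NULL) {
  if (inherits(fits_full, "bf_tddm_fit")) fits_full <- list(`1` = fits_full)
  if (inherits(fits_constrained, "bf_tddm_fit")) {
    fits_constrained <- list(`1` = fits_constrained)
  }
  if (!setequal(names(fits_full), names(fits_constrained))) {
    stop("Participant sets of the full and constrained fits differ.",
         call. = FALSE)
  }
  if (!is.null(data) && inherits(data, "data.frame")) data <- list(`1` = data)
  rows <- lapply(names(fits_full), function(pp) {
    ff <- fits_full[[pp]]
    fc <- fits_constrained[[pp]]
    if (is.null(data)) {
      ll_f <- ff$loglik
      ll_c <- fc$loglik
    } else {
      ns <- if (is.null(n_sims)) ff$settings$n_sims else n_sims
      sd_ <- if (is.null(seed)) ff$settings$seed else seed
      ll_f <- tddm_loglik(ff$params, data[[pp]], n_sims = ns, seed = sd_,
                          bin_width = ff$settings$bin_width,
                          dt = ff$settings$dt,
                          noise_sd = ff$settings$noise_sd,
                          max_t = ff$settings$max_t)
      ll_c <- tddm_loglik(fc$params, data[[pp]], n_sims = ns, seed = sd_,
                          bin_width = ff$settings$bin_width,
                          dt = ff$settings$dt,
                          noise_sd = ff$settings$noise_sd,
                          max_t = ff$settings$max_t)
    }
    stat <- 2 * (ll_f - ll_c)
    tibble(participant = pp, loglik_full = ll_f, loglik_constrained = ll_c,
           statistic = stat, df = 1,
           p.value = stats::pchisq(pmax(stat, 0), df = 1,
                                   lower.tail = FALSE))
  })
  bind_rows(rows)
}
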