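#' Choice-weight regimes for the logistic simulator
#'
#' The balanced regime weights the inverted primary and secondary basis
#' projections identically, as an ideal observer deriving the agent-centric
#' decision variable would; the overweighting regime tilts weight towards the
#' primary (team-level) projection, the behavioural consequence of its earlier
#' entry into the decision process.
#'
#' @param name `"balanced"` (1.5, 1.5, 1.5) or `"overweighting"`
#'   (1.7, 1.3, 1.5).
#' @param w_prim,w_sec,w_bonus Optional custom weights overriding the named
#'   regime.
#' @return A named list with `w_prim`, `w_sec`, `w_bonus`.
#' @export
choice_regime <- function(name = c("balanced", "overweighting"),
                          w_prim = NULL, w_sec = NULL, w_bonus = NULL) {
  name <- match.arg(name)
  w <- switch(name,
    balanced = list(w_prim = 1.5, w_sec = 1.5, w_bonus = 1.5),
    overweighting = list(w_prim = 1.7, w_sec = 1.3, w_bonus = 1.5)
  )
  if (!is.null(w_prim)) w$w_prim <- w_prim
  if (!is.null(w_sec)) w$w_sec <- w_sec
  if (!is.null(w_bonus)) w$w_bonus <- w_bonus
  stopifnot(all(vapply(w, is.finite, logical(1))))
  w
}

zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Simulate engage/avoid choices on a schedule
#'
#' For every selected decision the engage probability is a logistic function
#' of the inverted primary basis projection, the inverted secondary basis
#' projection and the bonus (standardised within decision type across the
#' schedule, so the stated weight magnitudes translate into comparable
#' regression effects). Choices are drawn independently per synthetic
#' participant and per simulation replicate; group decisions, for which no
#' secondary basis function exists, use the primary projection and bonus only.
#'
#' @inheritParams add_decision_variables
#' @param weights A [choice_regime()] list.
#' @param n_participants Number of synthetic participants (default 56, the
#'   fMRI sample size); each participant has an own seeded RNG stream.
#' @param n_sims Simulation replicates per participant (default 200).
#' @param seed Integer seed.
#' @param decisions Decision types to simulate; default `"self"`. Use
#'   `c("self", "partner")` for all dyadic decisions or include `"group"`.
#' @param standardize Standardise the predictors before applying weights
#'   (default `TRUE`); `FALSE` applies the weights on the raw scale.
#' @return A tibble with one row per participant x simulation x decision:
#'   schedule columns, predictors, `p_engage`, 0/1 `choice` and `payoff`.
#' @export
simulate_choices <- function(schedule, weights = choice_regime("balanced"),
                             n_participants = 56L, n_sims = 200L, seed = 1L,
                             decisions = "self", standardize = TRUE) {
  if (!is.numeric(n_sims) || n_sims < 1) {
    stop("`n_sims` must be a positive integer.", call. = FALSE)
  }
  decisions <- match.arg(decisions, c("self", "partner", "group"),
                         several.ok = TRUE)
  aug <- add_decision_variables(schedule)
  aug <- aug[aug$dtype %in% decisions, , drop = FALSE]
  if (nrow(aug) == 0) stop("No decisions of the requested types.",
                           call. = FALSE)

  z_prim <- stats::ave(aug$inv_primary, aug$dtype,
                       FUN = if (standardize) zscore else identity)
  z_sec <- ifelse(aug$dtype == "group", 0, aug$inv_secondary)
  z_sec[aug$dtype != "group"] <- stats::ave(
    aug$inv_secondary[aug$dtype != "group"], aug$dtype[aug$dtype != "group"],
    FUN = if (standardize) zscore else identity)
  z_bonus <- stats::ave(aug$bonus, aug$dtype,
                        FUN = if (standardize) zscore else identity)

  eta <- weights$w_prim * z_prim + weights$w_sec * z_sec +
    weights$w_bonus * z_bonus
  p_engage <- stats::plogis(eta)

  opp_rel <- ifelse(aug$relevant_opponent == "O2", aug$O2, aug$O1)
  opp_irr <- ifelse(aug$relevant_opponent == "O2", aug$O1, aug$O2)

  base <- tibble(
    trial = aug$trial, decision = aug$decision, dtype = aug$dtype,
    relevant_opponent = aug$relevant_opponent, order = aug$order,
    S = aug$S, P = aug$P, O1 = aug$O1, O2 = aug$O2,
    Or = ifelse(aug$dtype == "group", NA_real_, opp_rel),
    Oi = ifelse(aug$dtype == "group", NA_real_, opp_irr),
    bonus = aug$bonus, inv_primary = aug$inv_primary,
    inv_secondary = aug$inv_secondary,
    z_prim = z_prim, z_sec = ifelse(aug$dtype == "group", NA_real_, z_sec),
    z_bonus = z_bonus, dv = aug$dv, p_engage = p_engage
  )

  n_dec <- nrow(base)
  out <- vector("list", n_participants)
  for (pp in seq_len(n_participants)) {
    draws <- with_rng_seed(seed + pp, {
      matrix(stats::runif(n_sims * n_dec), n_sims, n_dec)
    })
    sims <- base[rep(seq_len(n_dec), n_sims), ]
    sims$participant <- pp
    sims$sim <- rep(seq_len(n_sims), each = n_dec)
    sims$choice <- as.integer(as.vector(t(draws)) < sims$p_engage)
    out[[pp]] <- sims
  }
  res <- bind_rows(out)
  res$payoff <- payoff(res$choice, res$dv)
  dplyr::relocate(res, "participant", "sim")
}
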