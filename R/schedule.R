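#' @importFrom dplyr %>% mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join n across all_of row_number
#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

# evaluate `expr` under a temporary RNG state seeded with `seed`
with_rng_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Enumerate all player orders
#'
#' All 4! = 24 permutations of the labels S, P, O1, O2, in deterministic
#' lexicographic order of the label sequence.
#'
#' @return Character vector of 24 order strings such as `"O1-O2-P-S"`.
#' @export
enumerate_player_orders <- function() {
  labs <- sort(player_labels())
  out <- character(0)
  for (a in labs) for (b in setdiff(labs, a)) for (c in setdiff(labs, c(a, b))) {
    out <- c(out, paste(c(a, b, c, setdiff(labs, c(a, b, c))), collapse = "-"))
  }
  out
}

#' Build a counterbalanced player-order sequence
#'
#' Orders are arranged in complete blocks of the 24 permutations (each block
#' internally shuffled) with any remainder trials drawn uniformly at random.
#' Following the original scheduling procedure, 1,000 candidate sequences are
#' generated and one of them is selected uniformly.
#'
#' @param n_trials Number of trials (at least 24).
#' @param seed Integer seed.
#' @param n_candidates Number of candidate sequences generated before one is
#'   picked (default 1000).
#' @return Character vector of `n_trials` order strings.
#' @export
build_order_sequence <- function(n_trials, seed = 1L, n_candidates = 1000L) {
  if (n_trials < 24) {
    stop("`n_trials` must be at least 24 to counterbalance all 24 player ",
         "orders.", call. = FALSE)
  }
  orders <- enumerate_player_orders()
  n_blocks <- n_trials %/% 24L
  remainder <- n_trials %% 24L
  with_rng_seed(seed, {
    candidates <- replicate(n_candidates, {
      blocks <- unlist(lapply(seq_len(n_blocks), function(i) sample(orders)))
      c(blocks, if (remainder > 0) sample(orders, remainder, replace = TRUE))
    }, simplify = FALSE)
    candidates[[sample.int(n_candidates, 1L)]]
  })
}

#' Generate a per-player performance pool
#'
#' Emulates the pre-experiment stage: each player contributes an oversampled
#' pool of integer scores in 0..6 (binomial over six binary cues, success
#' probability `prob`), re-drawn until the per-player pool means agree within
#' `mean_tolerance` so that all four players have approximately similar
#' performance.
#'
#' @param n_trials Number of trials the schedule will use.
#' @param prob Per-cue success probability (default 0.5).
#' @param pool_factor Oversampling factor: each pool holds
#'   `pool_factor * n_trials` scores (default 3), allowing repeated
#'   subsampling during schedule generation.
#' @param mean_tolerance Maximal allowed spread of per-player pool means
#'   (default 0.25).
#' @param max_attempts Attempts before giving up (default 100).
#' @param seed Integer seed.
#' @return Named list of integer score vectors, one per player identity.
#' @export
generate_performance_pool <- function(n_trials, prob = 0.5, pool_factor = 3,
                                      mean_tolerance = 0.25,
                                      max_attempts = 100L, seed = 1L) {
  stopifnot(prob >= 0, prob <= 1, pool_factor >= 1)
  n_pool <- ceiling(pool_factor * n_trials)
  with_rng_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      pool <- lapply(player_labels(), function(id) {
        stats::rbinom(n_pool, size = 6L, prob = prob)
      })
      names(pool) <- player_labels()
      mu <- vapply(pool, mean, numeric(1))
      if (diff(range(mu)) <= mean_tolerance) return(pool)
    }
    stop("Could not draw performance pools with matched means within ",
         max_attempts, " attempts; relax `mean_tolerance`.", call. = FALSE)
  })
}

# random length-6 binary cue string with `score` successes
cue_strings <- function(scores) {
  vapply(scores, function(s) {
    cues <- integer(6)
    cues[sample.int(6L, s)] <- 1L
    paste(cues, collapse = "")
  }, character(1))
}

new_schedule <- function(decisions, variant, seed, pre = NULL, post = NULL) {
  out <- as_tibble(decisions)
  attr(out, "variant") <- variant
  attr(out, "seed") <- as.integer(seed)
  attr(out, "pre") <- pre
  attr(out, "post") <- post
  class(out) <- c("bf_schedule", class(out))
  out
}

#' @export
print.bf_schedule <- function(x, ...) {
  cat("<bf_schedule> variant:", attr(x, "variant"),
      " seed:", attr(x, "seed"),
      " trials:", length(unique(x$trial)),
      " decisions:", nrow(x), "\n")
  NextMethod()
}

schedule_variant <- function(schedule) attr(schedule, "variant")

# ---- per-variant decision plans -------------------------------------------

# decision pair plan for the balanced designs: rows = trials, columns =
# dtype1/dtype2; "S","P","G" codes; pair order randomised but counts exact
pair_plan_balanced <- function(n_sp, n_sg, n_pg) {
  pairs <- c(rep("SP", n_sp), rep("SG", n_sg), rep("PG", n_pg))
  pairs <- sample(pairs)
  d1 <- d2 <- character(length(pairs))
  for (p in c("SP", "SG", "PG")) {
    idx <- which(pairs == p)
    flip <- rep(c(TRUE, FALSE), length.out = length(idx))[sample.int(length(idx))]
    a <- substr(p, 1, 1); b <- substr(p, 2, 2)
    d1[idx] <- ifelse(flip, a, b)
    d2[idx] <- ifelse(flip, b, a)
  }
  tibble(dtype1 = d1, dtype2 = d2)
}

# balanced assignment of a set of values to n slots (equal counts, shuffled)
balanced_assign <- function(values, n) {
  stopifnot(n %% length(values) == 0)
  sample(rep(values, each = n / length(values)))
}

expand_code <- function(code) {
  unname(c(S = "self", P = "partner", G = "group")[code])
}

# build the decisions table for study 1 / study 2 style designs
build_decisions_balanced <- function(n_trials, bonus_set) {
  n_each <- n_trials / 3  # trials per pair type
  plan <- pair_plan_balanced(n_each, n_each, n_each)
  dec <- tibble(
    trial = rep(seq_len(n_trials), each = 2L),
    decision = rep(1:2, n_trials),
    dtype = expand_code(as.vector(rbind(plan$dtype1, plan$dtype2)))
  )
  dec$relevant_opponent <- "both"
  for (tp in c("self", "partner")) {
    idx <- which(dec$dtype == tp)
    dec$relevant_opponent[idx] <- balanced_assign(c("O1", "O2"), length(idx))
  }
  dec$bonus <- NA_real_
  for (tp in c("self", "partner", "group")) {
    idx <- which(dec$dtype == tp)
    dec$bonus[idx] <- balanced_assign(bonus_set, length(idx))
  }
  # the two decisions of a trial must not compare the same player pair; with
  # pair types SP/SG/PG the only possible clash is impossible by construction,
  # but assert anyway
  stopifnot(!any(tapply(paste(dec$dtype, dec$relevant_opponent), dec$trial,
                        function(z) z[1] == z[2])))
  dec
}

# study 4: one group + one dyadic decision per trial, with the dyadic
# comparison tied to fixed sequence positions in training vs test
build_decisions_study4 <- function() {
  n_train <- 64L; n_test <- 32L
  phase <- c(rep("training", n_train), rep("test", n_test))
  n <- n_train + n_test
  dy_type <- c(balanced_assign(c("self", "partner"), n_train),
               balanced_assign(c("self", "partner"), n_test))
  dy_first <- c(balanced_assign(c(TRUE, FALSE), n_train),
                balanced_assign(c(TRUE, FALSE), n_test))
  opp <- character(n)
  for (ph in c("training", "test")) for (tp in c("self", "partner")) {
    idx <- which(phase == ph & dy_type == tp)
    opp[idx] <- balanced_assign(c("O1", "O2"), length(idx))
  }
  dec <- tibble(
    trial = rep(seq_len(n), each = 2L),
    decision = rep(1:2, n),
    phase = rep(phase, each = 2L),
    dtype = as.vector(rbind(ifelse(dy_first, dy_type, "group"),
                            ifelse(dy_first, "group", dy_type))),
    relevant_opponent = as.vector(rbind(ifelse(dy_first, opp, "both"),
                                        ifelse(dy_first, "both", opp)))
  )
  dec$bonus <- NA_real_
  for (tp in c("self", "partner", "group")) {
    idx <- which(dec$dtype == tp)
    dec$bonus[idx] <- balanced_assign(c(-0.5, 0.5), length(idx))
  }
  dec
}

# study-4 orders: place the dyadic relevant own player and opponent at the
# phase-contingent positions, remaining identities random (vectorised; one
# row per trial, entries are the identity labels at positions 1..4)
study4_order_matrix <- function(dec, pre, post) {
  per_trial <- as.data.frame(dec[dec$dtype != "group", ])
  n <- nrow(per_trial)
  train <- per_trial$phase == "training"
  q1 <- ifelse(train, 2L, 1L)
  q2 <- ifelse(train, pre, post)
  rel_own <- ifelse(per_trial$dtype == "self", "S", "P")
  irr_own <- ifelse(rel_own == "S", "P", "S")
  rel_opp <- per_trial$relevant_opponent
  irr_opp <- ifelse(rel_opp == "O1", "O2", "O1")
  flip1 <- sample(c(TRUE, FALSE), n, replace = TRUE)
  flip2 <- sample(c(TRUE, FALSE), n, replace = TRUE)
  ord <- matrix(NA_character_, n, 4)
  i <- seq_len(n)
  ord[cbind(i, ifelse(flip1, q1, q2))] <- rel_own
  ord[cbind(i, ifelse(flip1, q2, q1))] <- rel_opp
  rem <- t(apply(is.na(ord), 1, which))  # two free positions per trial
  ord[cbind(i, ifelse(flip2, rem[, 1], rem[, 2]))] <- irr_own
  ord[cbind(i, ifelse(flip2, rem[, 2], rem[, 1]))] <- irr_opp
  ord
}

study4_orders <- function(dec, pre, post) {
  apply(study4_order_matrix(dec, pre, post), 1, paste, collapse = "-")
}

# ---- decision-variable augmentation ---------------------------------------

relevance_lookup <- function() {
  orders <- enumerate_player_orders()
  combos <- rbind(
    expand.grid(order = orders, dtype = c("self", "partner"),
                relevant_opponent = c("O1", "O2"), stringsAsFactors = FALSE),
    expand.grid(order = orders, dtype = "group", relevant_opponent = "both",
                stringsAsFactors = FALSE)
  )
  res <- lapply(seq_len(nrow(combos)), function(i) {
    s <- sort_relevance(combos$order[i], combos$dtype[i],
                        if (combos$dtype[i] == "group") NULL else
                          combos$relevant_opponent[i])
    tibble(primary_idx = s$primary_idx, primary_sign = s$primary_sign,
           secondary_idx = s$secondary_idx, secondary_sign = s$secondary_sign,
           tertiary_idx = s$tertiary_idx)
  })
  dplyr::bind_cols(as_tibble(combos), bind_rows(res))
}

the_relevance_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- relevance_lookup()
    tab
  }
})

#' Add basis projections and decision variables to a schedule
#'
#' Computes, per decision row: the projections `b1`, `b2`, `b3` of the
#' trial's performance sequence, the relevance sorting (primary / secondary /
#' tertiary index and signs), the inverted (agent-centric) primary and
#' secondary projections, the social DV (relevant own minus relevant opponent
#' performance, no bonus), the overall team difference, the bonus-inclusive
#' decision variable `dv`, choice difficulty (`1 / |dv|`), and the sequence
#' positions of self and partner.
#'
#' @param schedule A [generate_schedule()] tibble (or any tibble with columns
#'   `order`, `S`, `P`, `O1`, `O2`, `dtype`, `relevant_opponent`, `bonus`).
#' @return The input with the derived columns appended.
#' @export
add_decision_variables <- function(schedule) {
  n <- nrow(schedule)
  ord_mat <- do.call(rbind, strsplit(schedule$order, "-", fixed = TRUE))
  score_mat <- as.matrix(schedule[, player_labels()])
  idx <- matrix(match(ord_mat, player_labels()), n, 4)
  pos <- matrix(score_mat[cbind(rep(seq_len(n), 4), as.vector(idx))], n, 4)
  B <- pos %*% t(basis_matrix())
  colnames(B) <- c("b1", "b2", "b3")

  rel <- the_relevance_table()
  key_sched <- paste(schedule$order, schedule$dtype, schedule$relevant_opponent)
  key_tab <- paste(rel$order, rel$dtype, rel$relevant_opponent)
  rel <- rel[match(key_sched, key_tab), ]

  inv_primary <- rel$primary_sign * B[cbind(seq_len(n), rel$primary_idx)]
  inv_secondary <- ifelse(
    is.na(rel$secondary_idx), NA_real_,
    rel$secondary_sign * B[cbind(seq_len(n),
                                 ifelse(is.na(rel$secondary_idx), 1L,
                                        rel$secondary_idx))]
  )

  rel_own_score <- ifelse(schedule$dtype == "partner", score_mat[, "P"],
                          score_mat[, "S"])
  rel_opp_score <- ifelse(schedule$relevant_opponent == "O2",
                          score_mat[, "O2"], score_mat[, "O1"])
  team_diff <- score_mat[, "S"] + score_mat[, "P"] -
    score_mat[, "O1"] - score_mat[, "O2"]
  social_dv <- ifelse(schedule$dtype == "group", team_diff,
                      rel_own_score - rel_opp_score)
  dv <- social_dv + schedule$bonus

  dplyr::bind_cols(
    as_tibble(schedule),
    as_tibble(B),
    rel[, c("primary_idx", "primary_sign", "secondary_idx", "secondary_sign",
            "tertiary_idx")],
    tibble(
      inv_primary = inv_primary,
      inv_secondary = inv_secondary,
      social_dv = social_dv,
      team_diff = team_diff,
      dv = dv,
      difficulty = 1 / abs(dv),
      s_position = apply(ord_mat == "S", 1, which),
      p_position = apply(ord_mat == "P", 1, which)
    )
  )
}

#' Squared correlations of basis projections with control variables
#'
#' Computes the matrix of squared Pearson correlations between each basis
#' projection (`b1`, `b2`, `b3`) and the agent-centric / decision-related
#' control variables: the four per-player performances, the social DV, the
#' overall team difference and choice difficulty. When `choices` are supplied
#' (a tibble with `trial`, `decision` and 0/1 `choice`, e.g. from
#' [simulate_choices()]), the choice and the chosen-minus-unchosen DV are
#' appended to the control set.
#'
#' @inheritParams add_decision_variables
#' @param choices Optional tibble of simulated or observed choices.
#' @return A 3 x k matrix of squared correlations.
#' @export
fig_rsq_matrix <- function(schedule, choices = NULL) {
  aug <- if ("b1" %in% names(schedule)) schedule else
    add_decision_variables(schedule)
  ctrl <- aug %>%
    select(all_of(c("S", "P", "O1", "O2")), social_dv = "social_dv",
           team_diff = "team_diff", difficulty = "difficulty")
  if (!is.null(choices)) {
    ch <- choices %>%
      dplyr::inner_join(aug[, c("trial", "decision", "dv")],
                        by = c("trial", "decision"))
    b_rep <- ch %>%
      dplyr::inner_join(aug[, c("trial", "decision", "b1", "b2", "b3")],
                        by = c("trial", "decision"))
    B <- as.matrix(b_rep[, c("b1", "b2", "b3")])
    ctrl_rep <- ch %>%
      dplyr::inner_join(
        aug[, c("trial", "decision", "S", "P", "O1", "O2", "social_dv",
                "team_diff", "difficulty")], by = c("trial", "decision")) %>%
      mutate(choice = .data$choice,
             dv_chosen_unchosen = (2 * .data$choice - 1) * .data$dv) %>%
      select(all_of(c("S", "P", "O1", "O2", "social_dv", "team_diff",
                      "difficulty", "choice", "dv_chosen_unchosen")))
    m <- stats::cor(B, as.matrix(ctrl_rep))^2
  } else {
    B <- as.matrix(aug[, c("b1", "b2", "b3")])
    m <- stats::cor(B, as.matrix(ctrl))^2
  }
  rownames(m) <- c("b1", "b2", "b3")
  m
}

# ---- the generator ---------------------------------------------------------

#' Generate an experimental schedule
#'
#' Builds a complete, counterbalanced trial/decision schedule for one of the
#' study designs and resamples the score-to-trial assignment until the basis
#' projections share at most `decorrelation_threshold` of variance with every
#' choice-independent control variable (per-player performances, social DV,
#' team difference, difficulty).
#'
#' Variants:
#' \describe{
#'   \item{`study1_fmri`}{144 trials / 288 decisions, evenly split between
#'     self, partner and group decisions; bonuses from
#'     (-1.5, -0.5, 0.5, 1.5).}
#'   \item{`study2_group`}{108 trials / 216 decisions, 72 self + 72 partner +
#'     72 group; bonuses from (-0.5, 0.5); all dyadic decisions flagged as
#'     matched.}
#'   \item{`study2_nogroup`}{derived from the matching `study2_group`
#'     schedule via [derive_nogroup_from_group()].}
#'   \item{`study4`}{96 trials (64 training + 32 test) / 192 decisions; every
#'     trial pairs one group with one dyadic decision, and the dyadic
#'     comparison is tied to sequence positions 2 and `pre` (training) or
#'     1 and `post` (test).}
#' }
#'
#' @param variant One of `"study1_fmri"`, `"study2_group"`,
#'   `"study2_nogroup"`, `"study4"`.
#' @param seed Integer seed; the same seed reproduces the schedule exactly.
#' @param pre,post Study-4 position contingencies (3 or 4).
#' @param decorrelation_threshold Maximal allowed squared correlation
#'   (default 0.01).
#' @param max_resamples Resampling budget (default 10000).
#' @param score_prob Per-cue success probability for the performance pool.
#' @param mean_tolerance Pool mean-matching tolerance (see
#'   [generate_performance_pool()]).
#' @return A `bf_schedule` tibble, one row per decision, with the achieved
#'   maximal squared correlation in `attr(, "max_rsq")`.
#' @export
generate_schedule <- function(variant = c("study1_fmri", "study2_group",
                                          "study2_nogroup", "study4"),
                              seed = 1L, pre = 3L, post = 4L,
                              decorrelation_threshold = 0.01,
                              max_resamples = 10000L,
                              score_prob = 0.5, mean_tolerance = 0.25) {
  variant <- match.arg(variant)
  if (variant == "study2_nogroup") {
    grp <- generate_schedule("study2_group", seed = seed,
                             decorrelation_threshold = decorrelation_threshold,
                             max_resamples = max_resamples,
                             score_prob = score_prob,
                             mean_tolerance = mean_tolerance)
    return(derive_nogroup_from_group(grp, seed = seed + 1L))
  }
  if (variant == "study4") {
    stopifnot(pre %in% c(3L, 4L), post %in% c(3L, 4L))
  }

  n_trials <- switch(variant, study1_fmri = 144L, study2_group = 108L,
                     study4 = 96L)
  pool <- generate_performance_pool(n_trials, prob = score_prob,
                                    mean_tolerance = mean_tolerance,
                                    seed = seed)

  with_rng_seed(seed + 7L, {
    dec <- switch(variant,
      study1_fmri = build_decisions_balanced(n_trials, c(-1.5, -0.5, 0.5, 1.5)),
      study2_group = build_decisions_balanced(n_trials, c(-0.5, 0.5)),
      study4 = build_decisions_study4()
    )
    if (variant != "study4") {
      orders <- build_order_sequence(n_trials,
                                     seed = sample.int(.Machine$integer.max, 1))
    }

    # lean per-attempt decorrelation check (vectorised, no tibble overhead)
    tr_of_dec <- dec$trial
    is_group <- dec$dtype == "group"
    own_col <- ifelse(dec$dtype == "partner", 2L, 1L)  # S=1, P=2
    opp_col <- ifelse(dec$relevant_opponent == "O2", 4L, 3L)
    Wt <- t(basis_matrix())
    attempt_rsq <- function(score_mat, idx) {
      pos <- matrix(score_mat[cbind(rep(seq_len(n_trials), 4),
                                    as.vector(idx))], n_trials, 4)
      B <- (pos %*% Wt)[tr_of_dec, , drop = FALSE]
      sm <- score_mat[tr_of_dec, , drop = FALSE]
      team_diff <- sm[, 1] + sm[, 2] - sm[, 3] - sm[, 4]
      social_dv <- ifelse(is_group, team_diff,
                          sm[cbind(seq_len(nrow(sm)), own_col)] -
                            sm[cbind(seq_len(nrow(sm)), opp_col)])
      dv <- social_dv + dec$bonus
      ctrl <- cbind(sm, social_dv, team_diff, 1 / abs(dv))
      max(stats::cor(B, ctrl)^2)
    }

    if (variant != "study4") {
      ord_idx <- matrix(match(do.call(rbind,
                                      strsplit(orders, "-", fixed = TRUE)),
                              player_labels()), n_trials, 4)
    }
    best_rsq <- Inf
    for (attempt in seq_len(max_resamples)) {
      scores <- lapply(pool, sample, size = n_trials)  # subsample the pool
      if (variant == "study4") {
        ord_mat <- study4_order_matrix(dec, pre = pre, post = post)
        ord_idx <- matrix(match(ord_mat, player_labels()), n_trials, 4)
      }
      score_mat <- cbind(S = scores$S, P = scores$P,
                         O1 = scores$O1, O2 = scores$O2)
      max_rsq <- attempt_rsq(score_mat, ord_idx)
      if (max_rsq <= decorrelation_threshold) {
        if (variant == "study4") {
          orders <- apply(ord_mat, 1, paste, collapse = "-")
        }
        trials <- tibble(
          trial = seq_len(n_trials),
          order = orders,
          S = scores$S, P = scores$P, O1 = scores$O1, O2 = scores$O2
        )
        trials$cues_S <- cue_strings(trials$S)
        trials$cues_P <- cue_strings(trials$P)
        trials$cues_O1 <- cue_strings(trials$O1)
        trials$cues_O2 <- cue_strings(trials$O2)
        sched <- dec %>%
          left_join(trials, by = "trial") %>%
          mutate(matched = variant == "study2_group" &
                   .data$dtype %in% c("self", "partner"))
        out <- new_schedule(sched, variant, seed,
                            pre = if (variant == "study4") pre,
                            post = if (variant == "study4") post)
        attr(out, "max_rsq") <- max_rsq
        attr(out, "n_resamples") <- attempt
        return(out)
      }
      best_rsq <- min(best_rsq, max_rsq)
    }
    stop("Decorrelation threshold ", decorrelation_threshold,
         " not reached within ", max_resamples,
         " resamples (best max r^2 = ", signif(best_rsq, 3), ").",
         call. = FALSE)
  })
}

#' Derive a no-group schedule from a group schedule
#'
#' Replaces the 72 group decisions of a `study2_group` schedule by 36 self and
#' 36 partner decisions with identical bonuses, leaving the observation phases
#' and all matched dyadic decisions untouched. The replacement decisions are
#' flagged as unmatched.
#'
#' @param group_schedule A `study2_group` schedule.
#' @param seed Integer seed for the replacement opponent assignment.
#' @return A `bf_schedule` with variant `study2_nogroup`.
#' @export
derive_nogroup_from_group <- function(group_schedule, seed = 1L) {
  if (!identical(schedule_variant(group_schedule), "study2_group")) {
    stop("`group_schedule` must be a study2_group schedule.", call. = FALSE)
  }
  sched <- as_tibble(group_schedule)
  grp_idx <- which(sched$dtype == "group")
  # in a trial pairing group with a self decision, replace group by partner,
  # and vice versa, so no trial compares the same player pair twice
  other_type <- vapply(grp_idx, function(i) {
    tr <- sched$trial[i]
    setdiff(sched$dtype[sched$trial == tr], "group")
  }, character(1))
  repl_type <- ifelse(other_type == "self", "partner", "self")
  with_rng_seed(seed, {
    for (tp in c("self", "partner")) {
      idx <- grp_idx[repl_type == tp]
      sched$dtype[idx] <- tp
      sched$relevant_opponent[idx] <- balanced_assign(c("O1", "O2"),
                                                      length(idx))
      sched$matched[idx] <- FALSE
    }
  })
  out <- new_schedule(sched, "study2_nogroup", attr(group_schedule, "seed"))
  attr(out, "max_rsq") <- attr(group_schedule, "max_rsq")
  out
}

#' Balance and decorrelation report for a schedule
#'
#' Recomputes, from the schedule alone, the structural balance quantities and
#' the basis-projection decorrelation matrix: trial/decision counts by type,
#' first-position counts per player, the histogram over the 24 player orders,
#' opponent-relevance counts within self and partner decisions, bonus counts,
#' the squared-correlation matrix from [fig_rsq_matrix()] and its maximum.
#'
#' @inheritParams add_decision_variables
#' @param choices Optional simulated choices to extend the decorrelation
#'   matrix with choice-dependent variables.
#' @return A list of class `bf_balance_report`.
#' @export
validate_schedule <- function(schedule, choices = NULL) {
  aug <- add_decision_variables(schedule)
  trials <- aug %>% dplyr::distinct(.data$trial, .keep_all = TRUE)
  first_pos <- table(factor(vapply(strsplit(trials$order, "-"), `[`,
                                   character(1), 1),
                            levels = player_labels()))
  rsq <- fig_rsq_matrix(aug, choices = choices)
  rep <- list(
    variant = schedule_variant(schedule),
    n_trials = nrow(trials),
    n_decisions = nrow(aug),
    type_counts = table(factor(aug$dtype,
                               levels = c("self", "partner", "group"))),
    first_position_counts = first_pos,
    order_histogram = table(factor(trials$order,
                                   levels = enumerate_player_orders())),
    opponent_relevance = with(
      subset(aug, aug$dtype != "group"),
      table(dtype, relevant_opponent)
    ),
    bonus_counts = table(aug$dtype, aug$bonus),
    matched_counts = if ("matched" %in% names(aug))
      table(aug$dtype[aug$matched]) else NULL,
    rsq_matrix = rsq,
    max_rsq = max(rsq)
  )
  class(rep) <- "bf_balance_report"
  rep
}

#' @export
print.bf_balance_report <- function(x, ...) {
  cat("<bf_balance_report>", x$variant, "-", x$n_trials, "trials,",
      x$n_decisions, "decisions\n")
  cat("decision types:",
      paste(names(x$type_counts), x$type_counts, sep = "=", collapse = " "),
      "\nmax r^2:", signif(x$max_rsq, 3), "\n")
  invisible(x)
}

#' Per-player decision relevance of a schedule
#'
#' Irrelevant players score 0 for a decision; the two relevant players of a
#' dyadic decision score 0.5 each; in group decisions all four players score
#' 0.25. Scores are summed over the schedule and divided by the number of
#' decisions (default) or trials.
#'
#' @inheritParams add_decision_variables
#' @param per Normalise by `"decision"` (default; relevance across players
#'   sums to 1) or `"trial"`.
#' @return A tibble with one row per player and its relevance score.
#' @export
decision_relevance <- function(schedule, per = c("decision", "trial")) {
  per <- match.arg(per)
  sched <- as_tibble(schedule)
  rel <- vapply(player_labels(), function(id) {
    r <- numeric(nrow(sched))
    grp <- sched$dtype == "group"
    r[grp] <- 0.25
    rel_own <- ifelse(sched$dtype == "self", "S",
                      ifelse(sched$dtype == "partner", "P", NA))
    r[!grp & (rel_own == id | sched$relevant_opponent == id)] <- 0.5
    sum(r)
  }, numeric(1))
  denom <- if (per == "decision") nrow(sched) else length(unique(sched$trial))
  tibble(player = player_labels(), relevance = unname(rel) / denom)
}

# ---- serialization ---------------------------------------------------------

#' Read and write schedules
#'
#' Schedules are serialised as a long-format CSV (one row per decision) plus a
#' JSON sidecar (`<file>.json`) holding the variant, seed and balance report
#' summary. The same seed always produces a byte-identical CSV.
#'
#' @param schedule A `bf_schedule`.
#' @param file Path to the CSV file.
#' @return `write_schedule()` returns `file` invisibly; `read_schedule()`
#'   returns the `bf_schedule`.
#' @export
write_schedule <- function(schedule, file) {
  utils::write.csv(as.data.frame(schedule), file, row.names = FALSE,
                   quote = FALSE)
  rep <- validate_schedule(schedule)
  side <- list(
    variant = schedule_variant(schedule),
    seed = attr(schedule, "seed"),
    n_trials = rep$n_trials,
    n_decisions = rep$n_decisions,
    max_rsq = rep$max_rsq,
    type_counts = as.list(rep$type_counts)
  )
  jsonlite::write_json(side, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE,
                        colClasses = c(cues_S = "character",
                                       cues_P = "character",
                                       cues_O1 = "character",
                                       cues_O2 = "character"))
  side <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  new_schedule(df, side$variant, side$seed)
}
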