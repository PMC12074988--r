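# synthetic agent-centric choice data with known standardised betas
make_agent_data <- function(n, betas, seed, participant = 1L) {
  withr::with_seed(seed, {
    df <- tibble::tibble(
      participant = participant,
      dtype = "self",
      S = stats::rbinom(n, 6, 0.5), P = stats::rbinom(n, 6, 0.5),
      Or = stats::rbinom(n, 6, 0.5), Oi = stats::rbinom(n, 6, 0.5),
      bonus = sample(c(-1.5, -0.5, 0.5, 1.5), n, replace = TRUE)
    )
    X <- scale(as.matrix(df[, c("S", "P", "Or", "Oi", "bonus")]))
    df$choice <- stats::rbinom(n, 1, stats::plogis(drop(X %*% betas)))
    df
  })
}

test_that("the agent-centric GLM recovers known decision weights", {
  truth <- c(2, 0, -2, 0, 1)
  est <- sapply(1:3, function(s) {
    fit <- agent_centric_glm(make_agent_data(2000, truth, seed = s))
    td <- tidy(fit)
    td$estimate[match(c("S", "P", "Or", "Oi", "bonus"), td$term)]
  })
  expect_true(all(abs(rowMeans(est) - truth) < 0.15))
})

test_that("degenerate outcomes are flagged, not fitted", {
  df <- make_agent_data(50, rep(0, 5), seed = 1)
  df$choice <- 1L
  fit <- agent_centric_glm(df)
  expect_true(all(fit$estimates$degenerate))
  expect_true(all(is.na(fit$estimates$estimate)))
})

test_that("ridge estimates converge to maximum likelihood as lambda -> 0", {
  df <- make_agent_data(400, c(1, 0.5, -1, 0, 0.5), seed = 7)
  X <- scale(as.matrix(df[, c("S", "P", "Or", "Oi", "bonus")]))
  ours <- tidy(agent_centric_glm(df, lambda = 1e-8))
  mle <- stats::glm(df$choice ~ X, family = stats::binomial())
  expect_lt(max(abs(ours$estimate - unname(stats::coef(mle))[-1])), 1e-3)
})

test_that("ridge shrinkage agrees with glmnet on a fixed penalty", {
  skip_if_not_installed("glmnet")
  df <- make_agent_data(400, c(1.5, 0, -1.5, 0, 1), seed = 11)
  X <- scale(as.matrix(df[, c("S", "P", "Or", "Oi", "bonus")]))
  lam <- 0.05
  ours <- tidy(agent_centric_glm(df, lambda = lam))
  gn <- glmnet::glmnet(X, df$choice, family = "binomial", alpha = 0,
                       lambda = lam, standardize = FALSE,
                       thresh = 1e-12)
  expect_lt(max(abs(ours$estimate - as.numeric(gn$beta))), 0.02)
})

test_that("separation at lambda = 0 is flagged and tamed by the ridge path", {
  withr::with_seed(3, {
    df <- tibble::tibble(
      participant = 1L, dtype = "self",
      S = c(rep(6, 10), rep(0, 10)), P = stats::rbinom(20, 6, 0.5),
      Or = stats::rbinom(20, 6, 0.5), Oi = stats::rbinom(20, 6, 0.5),
      bonus = rep(c(-0.5, 0.5), 10),
      choice = c(rep(1L, 10), rep(0L, 10))  # perfectly separated on S
    )
  })
  fit0 <- agent_centric_glm(df, lambda = 0)
  expect_true(all(fit0$estimates$separable))
  fit_r <- agent_centric_glm(df, lambda = 0.05)
  expect_false(any(fit_r$estimates$separable))
  expect_true(all(abs(tidy(fit_r)$estimate) < 12))
})

test_that("shared lambda selection behaves at both ends of the data regime", {
  # one large, well-conditioned dataset: the chosen lambda is small and the
  # penalised fit is close to maximum likelihood
  big <- make_agent_data(1500, c(1, 0, -1, 0, 0.5), seed = 21)
  grid <- 10^seq(-6, -1, length.out = 8)
  lam_big <- select_lambda(big, grid = grid, seed = 1)
  expect_lte(as.numeric(lam_big), 1e-3)
  fit_pen <- tidy(agent_centric_glm(big, lambda = as.numeric(lam_big)))
  fit_mle <- tidy(agent_centric_glm(big, lambda = 0))
  expect_lt(max(abs(fit_pen$estimate - fit_mle$estimate)), 0.05)

  # many small, near-separable datasets: regularisation wins
  small <- dplyr::bind_rows(lapply(1:8, function(pp) {
    make_agent_data(14, c(4, 0, -4, 0, 2), seed = 100 + pp, participant = pp)
  }))
  lam_small <- select_lambda(small, grid = 10^seq(-3, -1, length.out = 10),
                             seed = 2)
  expect_gt(as.numeric(lam_small), 1e-3)

  # deterministic given the fold seed
  expect_equal(as.numeric(select_lambda(small, seed = 5)),
               as.numeric(select_lambda(small, seed = 5)))
  expect_error(select_lambda(big, grid = numeric(0)), "Empty")
})

test_that("sequential position regressors invert opponent scores", {
  df <- tibble::tibble(
    participant = 1L, dtype = "self", choice = 0L,
    order = c("S-O1-P-O2", "O2-P-S-O1"),
    S = c(3, 1), P = c(5, 2), O1 = c(6, 0), O2 = c(0, 4),
    bonus = c(0.5, -0.5)
  )
  X <- socialbasis:::sequential_regressors(df)
  # own scores pass through; opponent scores are recoded x -> 6 - x
  expect_equal(unname(X[1, ]), c(3, 6 - 6, 5, 6 - 0, 0.5))
  expect_equal(unname(X[2, ]), c(6 - 4, 2, 1, 6 - 0, -0.5))
})

test_that("sequential position weights reflect a trained decider", {
  sched <- generate_schedule("study4", seed = 401, pre = 3, post = 3)
  aug <- add_decision_variables(sched)
  dy <- aug[aug$dtype != "group" & aug$phase == "training", ]
  # decider who compares positions 2 and 3 (the trained contingency)
  X <- socialbasis:::sequential_regressors(dy)
  withr::with_seed(5, {
    sims <- dplyr::bind_rows(lapply(1:6, function(pp) {
      eta <- 1.2 * scale(X[, "pos2"]) + 1.2 * scale(X[, "pos3"]) +
        1.0 * scale(X[, "bonus"])
      out <- dy
      out$participant <- pp
      out$choice <- stats::rbinom(nrow(dy), 1, stats::plogis(drop(eta)))
      out
    }))
  })
  fit <- sequential_position_glm(sims, lambda = 0.01)
  g <- glance(fit)
  m <- setNames(g$mean, g$term)
  expect_gt(m[["pos2"]], m[["pos1"]] + 0.3)
  expect_gt(m[["pos3"]], m[["pos4"]] + 0.3)
  expect_error(sequential_position_glm(aug |> dplyr::mutate(choice = 0L)),
               "dyadic")
})

test_that("accuracy summaries distinguish omniscient from random deciders", {
  sched <- generate_schedule("study2_group", seed = 77)
  aug <- add_decision_variables(sched)
  base <- aug[, c("trial", "decision", "dtype", "dv", "matched")]

  omni <- base |> dplyr::mutate(choice = as.integer(dv > 0))
  acc <- accuracy_rt_summary(omni)
  expect_true(all(acc$accuracy == 100))
  expect_true(all(is.na(acc$median_rt)))

  rand <- withr::with_seed(1, dplyr::bind_rows(replicate(20, base,
                                                         simplify = FALSE)) |>
                                dplyr::mutate(choice = stats::rbinom(dplyr::n(), 1, 0.5)))
  acc_r <- accuracy_rt_summary(rand)
  expect_true(all(abs(acc_r$accuracy - 50) < 5))

  # a decider with a noisy memory of the partner score is less accurate on
  # partner decisions than on self decisions
  noisy <- withr::with_seed(2, {
    reps <- dplyr::bind_rows(replicate(30, aug, simplify = FALSE))
    p_noisy <- reps$P + stats::rnorm(nrow(reps), sd = 2)
    opp_rel <- ifelse(reps$relevant_opponent == "O2", reps$O2, reps$O1)
    dv_seen <- ifelse(reps$dtype == "partner",
                      p_noisy - opp_rel + reps$bonus, reps$dv)
    reps$choice <- as.integer(dv_seen > 0)
    reps[reps$dtype != "group", ]
  })
  acc_n <- accuracy_rt_summary(noisy)
  self_acc <- mean(acc_n$accuracy[acc_n$dtype == "self"])
  partner_acc <- mean(acc_n$accuracy[acc_n$dtype == "partner"])
  expect_gt(self_acc, partner_acc + 5)

  acc_m <- accuracy_rt_summary(omni, matched_only = TRUE)
  expect_setequal(acc_m$dtype, c("self", "partner"))
  expect_error(accuracy_rt_summary(dplyr::select(omni, -matched),
                                   matched_only = TRUE), "matched")
})

test_that("standardisation is idempotent", {
  x <- stats::rnorm(50, 3, 2)
  expect_equal(socialbasis:::zscore(socialbasis:::zscore(x)),
               socialbasis:::zscore(x))
  expect_equal(socialbasis:::zscore(rep(2, 10)), rep(0, 10))
})

test_that("model comparison favours the generating model", {
  sched <- generate_schedule("study2_group", seed = 88)
  # (i) choices from the basis-function model
  ch_basis <- simulate_choices(sched, choice_regime("overweighting"),
                               n_participants = 6, n_sims = 6, seed = 3,
                               decisions = c("self", "partner"))
  cmp_b <- compare_model_accuracy(ch_basis, seed = 1)
  expect_gt(mean(cmp_b$logloss_diff), 0)

  # (ii) choices from an agent-centric pattern the basis model cannot express
  aug <- add_decision_variables(sched)
  dy <- aug[aug$dtype != "group", ]
  dy$Or <- ifelse(dy$relevant_opponent == "O2", dy$O2, dy$O1)
  dy$Oi <- ifelse(dy$relevant_opponent == "O2", dy$O1, dy$O2)
  Xa <- scale(as.matrix(dy[, c("S", "P", "Or", "Oi", "bonus")]))
  beta_a <- c(2, 1, -2, 0, 1)
  ch_agent <- withr::with_seed(4, dplyr::bind_rows(lapply(1:6, function(pp) {
    out <- dy
    out$participant <- pp
    out$choice <- stats::rbinom(nrow(dy), 1,
                                stats::plogis(drop(Xa %*% beta_a)))
    out
  })))
  cmp_a <- compare_model_accuracy(ch_agent, seed = 1)
  expect_lt(mean(cmp_a$logloss_diff), 0)
  expect_error(compare_model_accuracy(aug |> dplyr::mutate(choice = 0L)),
               "dyadic")
})
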