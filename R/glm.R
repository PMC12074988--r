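#' @importFrom stats plogis setNames
NULL

# L2-penalised logistic regression by Newton/IRLS. The intercept is never
# penalised; the penalty on the objective scale is n * lambda / 2 * sum(b^2)
# (matching the per-observation penalty convention of elastic-net software,
# so the same lambda grid is meaningful across datasets of different sizes).
ridge_logit <- function(X, y, lambda = 0, maxit = 200L, tol = 1e-10) {
  X <- as.matrix(X)
  n <- nrow(X)
  Xd <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xd)
  pen <- diag(c(0, rep(n * lambda, p - 1L)), p)
  beta <- numeric(p)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(Xd %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- crossprod(Xd, y - mu) - pen %*% beta
    H <- crossprod(Xd, Xd * w) + pen
    delta <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(delta)) break
    # dampen huge steps (separation at lambda = 0)
    if (max(abs(delta)) > 10) delta <- delta * 10 / max(abs(delta))
    beta <- beta + drop(delta)
    if (max(abs(delta)) < tol) {
      converged <- TRUE
      break
    }
  }
  eta <- drop(Xd %*% beta)
  mu <- pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12)
  deviance <- -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
  separable <- lambda == 0 && (!converged || max(abs(beta[-1])) > 12)
  list(beta = setNames(drop(beta), colnames(Xd)), deviance = deviance,
       converged = converged, separable = separable, n = n, lambda = lambda)
}

held_out_deviance <- function(beta, X, y) {
  eta <- drop(cbind(1, as.matrix(X)) %*% beta)
  mu <- pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12)
  -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
}

standardize_cols <- function(X) {
  apply(as.matrix(X), 2, zscore)
}

agent_regressors <- function(df) {
  X <- as.matrix(df[, c("S", "P", "Or", "Oi", "bonus")])
  colnames(X) <- c("S", "P", "Or", "Oi", "bonus")
  X
}

basis_regressors <- function(df) {
  X <- as.matrix(df[, c("inv_primary", "inv_secondary", "bonus")])
  colnames(X) <- c("inv_primary", "inv_secondary", "bonus")
  X
}

new_bf_glm <- function(estimates, model, lambda, decision_type = NULL) {
  structure(list(estimates = estimates, model = model, lambda = lambda,
                 decision_type = decision_type), class = "bf_glm")
}

#' @export
print.bf_glm <- function(x, ...) {
  cat("<bf_glm>", x$model, "model",
      if (!is.null(x$decision_type)) paste0("(", x$decision_type,
                                            " decisions)"),
      "- lambda =", x$lambda, "-", length(unique(x$estimates$participant)),
      "participants\n")
  print(glance(x))
  invisible(x)
}

fit_participants <- function(choices, make_X, lambda, model,
                             decision_type = NULL) {
  split_pp <- split(as.data.frame(choices), choices$participant)
  rows <- lapply(names(split_pp), function(pp) {
    df <- split_pp[[pp]]
    if (length(unique(df$choice)) < 2) {
      return(tibble(participant = as.integer(pp), term = NA_character_,
                    estimate = NA_real_, deviance = NA_real_, n = nrow(df),
                    separable = NA, converged = FALSE, degenerate = TRUE))
    }
    X <- standardize_cols(make_X(df))
    fit <- ridge_logit(X, df$choice, lambda = lambda)
    tibble(participant = as.integer(pp), term = names(fit$beta),
           estimate = unname(fit$beta), deviance = fit$deviance, n = fit$n,
           separable = fit$separable, converged = fit$converged,
           degenerate = FALSE)
  })
  new_bf_glm(bind_rows(rows), model, lambda, decision_type)
}

#' Agent-centric logistic decision-weight GLM
#'
#' Predicts engage (1) versus avoid (0) choices from five standardised
#' regressors: the performances of self (S), partner (P), relevant opponent
#' (Or) and irrelevant opponent (Oi), plus the bonus. Fitted separately per
#' participant and decision type; `lambda = 0` gives the maximum-likelihood
#' fit, `lambda > 0` the ridge-penalised fit. Participants with constant
#' outcomes or complete separation at `lambda = 0` are flagged in the result
#' rather than silently dropped.
#'
#' @param choices A tibble of decisions with columns `participant`, `choice`,
#'   `S`, `P`, `Or`, `Oi`, `bonus` (as produced by [simulate_choices()]).
#' @param decision_type `"self"` or `"partner"`; rows of other types are
#'   dropped.
#' @param lambda Ridge penalty (default 0).
#' @return A `bf_glm` object; use [tidy()] for per-participant betas and
#'   [glance()] for the group summary.
#' @export
agent_centric_glm <- function(choices, decision_type = c("self", "partner"),
                              lambda = 0) {
  decision_type <- match.arg(decision_type)
  df <- choices[choices$dtype == decision_type, , drop = FALSE]
  if (nrow(df) == 0) stop("No decisions of type ", decision_type, ".",
                          call. = FALSE)
  fit_participants(df, agent_regressors, lambda, "agent_centric",
                   decision_type)
}

#' Basis-function logistic GLM
#'
#' Like [agent_centric_glm()] but with the three basis-function regressors:
#' inverted primary projection, inverted secondary projection and bonus.
#' Dyadic decisions only.
#'
#' @inheritParams agent_centric_glm
#' @export
basis_function_glm <- function(choices, decision_type = c("self", "partner"),
                               lambda = 0) {
  decision_type <- match.arg(decision_type)
  df <- choices[choices$dtype == decision_type, , drop = FALSE]
  if (nrow(df) == 0) stop("No decisions of type ", decision_type, ".",
                          call. = FALSE)
  fit_participants(df, basis_regressors, lambda, "basis_function",
                   decision_type)
}

#' Cross-validated shared ridge penalty
#'
#' Selects a single regularisation coefficient for all participants: for each
#' candidate lambda the model is fitted under k-fold cross-validation within
#' each participant's dataset, the held-out deviances are summed over folds,
#' participants and repeats, and the lambda with the lowest total deviance
#' wins. The same lambda is then used for every participant so that decision
#' weights remain comparable across participants and conditions.
#'
#' @inheritParams agent_centric_glm
#' @param regressors `"agent"` (S, P, Or, Oi, bonus) or `"sequential"`
#'   (position scores + bonus, see [sequential_position_glm()]).
#' @param grid Lambda grid; default 25 log-spaced points in `[1e-3, 1e-1]`.
#'   For small test-phase datasets a wider grid up to 1 is appropriate.
#' @param k_folds Folds (default 3).
#' @param repeats Repetitions of the fold assignment (default 2).
#' @param seed Seed for the fold assignment.
#' @return The selected lambda, with the full deviance profile in
#'   `attr(, "profile")`.
#' @export
select_lambda <- function(choices, regressors = c("agent", "sequential"),
                          grid = 10^seq(-3, -1, length.out = 25),
                          k_folds = 3L, repeats = 2L, seed = 1L) {
  regressors <- match.arg(regressors)
  if (length(grid) == 0) stop("Empty lambda grid.", call. = FALSE)
  datasets <- lapply(split(as.data.frame(choices), choices$participant),
                     function(df) {
                       X <- standardize_cols(
                         if (regressors == "agent") agent_regressors(df)
                         else sequential_regressors(df))
                       list(X = X, y = df$choice)
                     })
  datasets <- Filter(function(d) length(unique(d$y)) > 1, datasets)
  if (length(datasets) == 0) stop("No usable datasets.", call. = FALSE)

  total <- setNames(numeric(length(grid)), signif(grid, 6))
  with_rng_seed(seed, {
    for (rep_i in seq_len(repeats)) {
      folds <- lapply(datasets, function(d) {
        sample(rep(seq_len(k_folds), length.out = length(d$y)))
      })
      for (gi in seq_along(grid)) {
        for (di in seq_along(datasets)) {
          d <- datasets[[di]]
          f <- folds[[di]]
          for (k in seq_len(k_folds)) {
            tr <- f != k
            if (length(unique(d$y[tr])) < 2) next
            fit <- ridge_logit(d$X[tr, , drop = FALSE], d$y[tr],
                               lambda = grid[gi])
            total[gi] <- total[gi] +
              held_out_deviance(fit$beta, d$X[!tr, , drop = FALSE], d$y[!tr])
          }
        }
      }
    }
  })
  best <- grid[which.min(total)]
  attr(best, "profile") <- tibble(lambda = grid, cv_deviance = unname(total))
  best
}

# inverted-opponent sequential position scores: pos1..pos4 with opponent
# scores recoded x -> 6 - x (the performance range is symmetric around 3)
sequential_regressors <- function(df) {
  n <- nrow(df)
  ord_mat <- do.call(rbind, strsplit(df$order, "-", fixed = TRUE))
  score_mat <- as.matrix(df[, player_labels()])
  idx <- matrix(match(ord_mat, player_labels()), n, 4)
  pos <- matrix(score_mat[cbind(rep(seq_len(n), 4), as.vector(idx))], n, 4)
  is_opp <- matrix(ord_mat %in% c("O1", "O2"), n, 4)
  pos[is_opp] <- 6 - pos[is_opp]
  colnames(pos) <- paste0("pos", 1:4)
  cbind(pos, bonus = df$bonus)
}

#' Sequential-position decision-weight GLM
#'
#' Regresses dyadic engage/avoid decisions onto the standardised performance
#' scores of the first to fourth sequence position plus the bonus, with
#' opponent scores inverted (6 recoded as 0, 5 as 1, ..., 0 as 6) so that all
#' five predictors point in the "engage" direction. Designed for the
#' sequence-contingent schedules, where position weights reveal which
#' sequence positions a decider has learned to prioritise.
#'
#' @param choices Dyadic decisions with `participant`, `choice`, `order`,
#'   per-identity scores and `bonus` columns.
#' @param lambda Ridge penalty; if `NULL`, selected by [select_lambda()] with
#'   the wide grid `[1e-3, 1e0]`.
#' @param ... Passed on to [select_lambda()].
#' @return A `bf_glm` object with terms `pos1`..`pos4` and `bonus`.
#' @export
sequential_position_glm <- function(choices, lambda = NULL, ...) {
  if (any(choices$dtype == "group")) {
    stop("Sequential position weights are defined for dyadic decisions ",
         "only; filter out group decisions first.", call. = FALSE)
  }
  if (is.null(lambda)) {
    lambda <- as.numeric(select_lambda(choices, regressors = "sequential",
                                       grid = 10^seq(-3, 0, length.out = 25),
                                       ...))
  }
  fit_participants(choices, sequential_regressors, lambda, "sequential")
}

#' Accuracy and reaction-time summary
#'
#' Percent-correct (the choice agrees with the sign of the bonus-inclusive
#' decision variable, which is never zero) and median reaction time, split by
#' decision type and decision index.
#'
#' @param choices Decisions with `choice`, `dv`, `dtype`, `decision` and
#'   optionally `rt` and `matched` columns.
#' @param matched_only Restrict to matched decisions (study-2 comparisons).
#' @return A tibble with `dtype`, `decision`, `n`, `accuracy` (percent) and
#'   `median_rt` (NA when no reaction times are present).
#' @export
accuracy_rt_summary <- function(choices, matched_only = FALSE) {
  df <- as_tibble(choices)
  if (matched_only) {
    if (!"matched" %in% names(df)) stop("No `matched` column.", call. = FALSE)
    df <- df[df$matched, , drop = FALSE]
  }
  if (!"rt" %in% names(df)) df$rt <- NA_real_
  df %>%
    mutate(correct = (.data$choice == 1) == (.data$dv > 0)) %>%
    group_by(.data$dtype, .data$decision) %>%
    summarise(n = dplyr::n(), accuracy = 100 * mean(.data$correct),
              median_rt = stats::median(.data$rt), .groups = "drop")
}

#' Predictive accuracy: basis-function versus agent-centric model
#'
#' Per participant, k-fold cross-validated predictive accuracy and log-loss
#' of (i) the basis-function model (inverted primary and secondary
#' projections + bonus) and (ii) the five-regressor agent-centric model, on
#' the same folds. Positive `accuracy_diff` means the basis-function model
#' predicts held-out choices better.
#'
#' @inheritParams agent_centric_glm
#' @param k_folds Cross-validation folds (default 5).
#' @param lambda Small stabilising ridge penalty used for both models
#'   (default 1e-4).
#' @param seed Fold-assignment seed.
#' @return A tibble with one row per participant: accuracies, log-losses and
#'   their paired differences (basis minus agent-centric).
#' @export
compare_model_accuracy <- function(choices, k_folds = 5L, lambda = 1e-4,
                                   seed = 1L) {
  if (any(choices$dtype == "group")) {
    stop("Model comparison is defined for dyadic decisions only.",
         call. = FALSE)
  }
  split_pp <- split(as.data.frame(choices), choices$participant)
  rows <- lapply(names(split_pp), function(pp) {
    df <- split_pp[[pp]]
    Xb <- standardize_cols(basis_regressors(df))
    Xa <- standardize_cols(agent_regressors(df))
    y <- df$choice
    f <- with_rng_seed(seed + as.integer(pp), {
      sample(rep(seq_len(k_folds), length.out = length(y)))
    })
    pred <- function(X) {
      p <- numeric(length(y))
      for (k in seq_len(k_folds)) {
        tr <- f != k
        if (length(unique(y[tr])) < 2) {
          p[!tr] <- mean(y[tr])
          next
        }
        fit <- ridge_logit(X[tr, , drop = FALSE], y[tr], lambda = lambda)
        p[!tr] <- plogis(drop(cbind(1, X[!tr, , drop = FALSE]) %*% fit$beta))
      }
      pmin(pmax(p, 1e-12), 1 - 1e-12)
    }
    pb <- pred(Xb); pa <- pred(Xa)
    tibble(
      participant = as.integer(pp),
      accuracy_basis = mean((pb > 0.5) == (y == 1)),
      accuracy_agent = mean((pa > 0.5) == (y == 1)),
      logloss_basis = -mean(y * log(pb) + (1 - y) * log(1 - pb)),
      logloss_agent = -mean(y * log(pa) + (1 - y) * log(1 - pa))
    )
  })
  bind_rows(rows) %>%
    mutate(accuracy_diff = .data$accuracy_basis - .data$accuracy_agent,
           logloss_diff = .data$logloss_agent - .data$logloss_basis)
}
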