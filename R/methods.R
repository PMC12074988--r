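#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_errorbar geom_hline
#'   geom_line geom_point geom_tile geom_ribbon labs facet_wrap
#'   scale_fill_gradient theme_minimal
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy per-participant decision weights
#'
#' @param x A `bf_glm` object.
#' @param ... Unused.
#' @return A tibble with one row per participant and term.
#' @export
tidy.bf_glm <- function(x, ...) {
  est <- x$estimates
  est[!is.na(est$term) & est$term != "(Intercept)",
      c("participant", "term", "estimate", "separable")]
}

#' Group-level summary of decision weights
#'
#' One-sample t-tests of the per-participant betas against zero, per term.
#'
#' @inheritParams tidy.bf_glm
#' @return A tibble with `term`, `mean`, `se`, `statistic`, `p.value`, `n`.
#' @export
glance.bf_glm <- function(x, ...) {
  td <- tidy(x)
  td %>%
    group_by(.data$term) %>%
    summarise(
      mean = mean(.data$estimate),
      se = stats::sd(.data$estimate) / sqrt(dplyr::n()),
      statistic = if (dplyr::n() > 1 && stats::sd(.data$estimate) > 0)
        stats::t.test(.data$estimate)$statistic else NA_real_,
      p.value = if (dplyr::n() > 1 && stats::sd(.data$estimate) > 0)
        stats::t.test(.data$estimate)$p.value else NA_real_,
      n = dplyr::n(), .groups = "drop"
    )
}

#' Plot group-mean decision weights
#'
#' Bar plot of the group-mean standardised decision weights with standard
#' errors, in the fixed term order of the fitted model.
#'
#' @param object A `bf_glm` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bf_glm <- function(object, ...) {
  g <- glance(object)
  lev <- switch(object$model,
    agent_centric = c("S", "P", "Or", "Oi", "bonus"),
    basis_function = c("inv_primary", "inv_secondary", "bonus"),
    sequential = c(paste0("pos", 1:4), "bonus"),
    unique(g$term)
  )
  g$term <- factor(g$term, levels = lev)
  ggplot(g, aes(x = .data$term, y = .data$mean)) +
    geom_col(fill = "grey35") +
    geom_errorbar(aes(ymin = .data$mean - .data$se,
                      ymax = .data$mean + .data$se), width = 0.25) +
    geom_hline(yintercept = 0, linewidth = 0.3) +
    labs(x = NULL, y = "decision weight (a.u.)",
         title = paste(object$model, "model",
                       if (!is.null(object$decision_type))
                         paste0("(", object$decision_type, " decisions)"))) +
    theme_minimal()
}

#' Plot the decorrelation matrix of a schedule
#'
#' Tile plot of the squared correlations between the basis projections and
#' the agent-centric / decision-related control variables.
#'
#' @param schedule A `bf_schedule` (or a precomputed `bf_balance_report`).
#' @param choices Optional choices to include choice-dependent variables.
#' @return A ggplot object.
#' @export
plot_schedule_balance <- function(schedule, choices = NULL) {
  m <- if (inherits(schedule, "bf_balance_report")) schedule$rsq_matrix
       else fig_rsq_matrix(schedule, choices)
  df <- as_tibble(as.table(m), .name_repair = ~ c("projection", "variable",
                                                  "rsq"))
  ggplot(df, aes(x = .data$variable, y = .data$projection,
                 fill = .data$rsq)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "firebrick",
                        limits = c(0, max(0.01, max(df$rsq)))) +
    labs(x = NULL, y = NULL, fill = expression(r^2)) +
    theme_minimal()
}
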