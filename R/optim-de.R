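# Differential evolution (best/1/bin) minimiser over box constraints.
# Deliberately minimal: the objective may be stochastic, so the caller is
# expected to freeze its random numbers across evaluations.
de_optimize <- function(fn, lower, upper, pop_size = 10 * length(lower),
                        n_iterations = 150L, F = 0.8, CR = 0.9, seed = 1L,
                        trace = TRUE) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(is.finite(lower)), all(is.finite(upper)),
            all(upper >= lower), pop_size >= 4)
  with_rng_seed(seed, {
    pop <- matrix(stats::runif(pop_size * d, rep(lower, each = pop_size),
                               rep(upper, each = pop_size)), pop_size, d)
    vals <- apply(pop, 1, fn)
    best_trace <- numeric(n_iterations)
    for (it in seq_len(n_iterations)) {
      best <- pop[which.min(vals), ]
      for (i in seq_len(pop_size)) {
        idx <- sample(setdiff(seq_len(pop_size), i), 2)
        trial <- best + F * (pop[idx[1], ] - pop[idx[2], ])
        cross <- stats::runif(d) < CR
        cross[sample.int(d, 1)] <- TRUE  # at least one mutated coordinate
        trial <- ifelse(cross, trial, pop[i, ])
        trial <- pmin(pmax(trial, lower), upper)
        v <- fn(trial)
        if (v <= vals[i]) {
          pop[i, ] <- trial
          vals[i] <- v
        }
      }
      best_trace[it] <- min(vals)
    }
    i_best <- which.min(vals)
    list(par = pop[i_best, ], value = vals[i_best],
         trace = if (trace) best_trace else NULL)
  })
}
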