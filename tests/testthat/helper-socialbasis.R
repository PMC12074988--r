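# shared fixtures: all 24 player orders and a small grid of score vectors
all_orders <- function() {
  perms <- list()
  labs <- c("S", "P", "O1", "O2")
  for (a in labs) for (b in setdiff(labs, a)) for (c in setdiff(labs, c(a, b)))
    perms[[length(perms) + 1L]] <- c(a, b, c, setdiff(labs, c(a, b, c)))
  perms
}

all_dyadic_decisions <- function() {
  expand.grid(dtype = c("self", "partner"), opp = c("O1", "O2"),
              stringsAsFactors = FALSE)
}

# deterministic small score sample on a fixed seed
sample_scores <- function(n, seed = 42) {
  withr::with_seed(seed, replicate(n, sample(0:6, 4, replace = TRUE),
                                   simplify = FALSE))
}

expect_balanced_counts <- function(x, levels, each) {
  tab <- table(factor(x, levels = levels))
  expect_true(all(tab == each),
              label = paste("counts", paste(tab, collapse = "/")))
}
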