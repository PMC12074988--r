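test_that("all 24 player orders are enumerated without duplicates", {
  orders <- enumerate_player_orders()
  expect_length(orders, 24)
  expect_equal(anyDuplicated(orders), 0)
  for (o in orders) expect_setequal(parse_order(o), c("S", "P", "O1", "O2"))
})

test_that("order sequences are counterbalanced in complete blocks", {
  s24 <- build_order_sequence(24, seed = 1)
  expect_true(all(table(s24) == 1))

  s144 <- build_order_sequence(144, seed = 2)
  expect_true(all(table(s144) == 6))
  # each 24-trial block is itself a complete permutation set
  for (blk in split(s144, rep(1:6, each = 24))) {
    expect_true(all(table(blk) == 1))
  }

  s108 <- build_order_sequence(108, seed = 3)
  expect_true(all(table(s108[1:96]) == 4))  # 4 complete blocks, 12 random

  expect_error(build_order_sequence(12), "at least 24")
  expect_identical(build_order_sequence(108, seed = 5),
                   build_order_sequence(108, seed = 5))
})

test_that("performance pools have matched means and the right support", {
  pool <- generate_performance_pool(144, seed = 10)
  mu <- vapply(pool, mean, numeric(1))
  expect_lte(diff(range(mu)), 0.25)
  expect_true(all(unlist(pool) %in% 0:6))
  expect_length(pool$S, 3 * 144)

  # degenerate distribution: all mass at 6 successes out of 6
  pool1 <- generate_performance_pool(30, prob = 1, seed = 1)
  expect_true(all(unlist(pool1) == 6))
})

test_that("study-1 schedules satisfy the printed cardinalities and balance", {
  s <- generate_schedule("study1_fmri", seed = 101)
  expect_equal(length(unique(s$trial)), 144)
  expect_equal(nrow(s), 288)
  expect_balanced_counts(s$dtype, c("self", "partner", "group"), 96)
  # both opponents relevant equally often within self and partner decisions
  for (tp in c("self", "partner")) {
    expect_balanced_counts(s$relevant_opponent[s$dtype == tp],
                           c("O1", "O2"), 48)
  }
  # bonus magnitudes balanced per decision type
  for (tp in c("self", "partner", "group")) {
    expect_balanced_counts(s$bonus[s$dtype == tp],
                           c(-1.5, -0.5, 0.5, 1.5), 24)
  }
  # two decisions of a trial never compare the same players; at most one
  # group decision per trial
  by_trial <- split(paste(s$dtype, s$relevant_opponent), s$trial)
  expect_true(all(vapply(by_trial, function(z) z[1] != z[2], logical(1))))
  expect_true(all(vapply(split(s$dtype, s$trial),
                         function(z) sum(z == "group") <= 1, logical(1))))
  # cue sequences aggregate to the scores
  n_success <- function(x) vapply(strsplit(x, ""), function(z)
    sum(z == "1"), numeric(1))
  expect_equal(n_success(s$cues_S), s$S)
  expect_equal(n_success(s$cues_O2), s$O2)

  rep <- validate_schedule(s)
  expect_true(all(rep$first_position_counts == 36))
  expect_true(all(rep$order_histogram == 6))
  expect_lte(rep$max_rsq, 0.01)
  # the null projection is not part of the decorrelation matrix
  expect_false("null" %in% colnames(rep$rsq_matrix))
})

test_that("same seed gives byte-identical schedule serialization", {
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_schedule(generate_schedule("study2_group", seed = 77), f1)
  write_schedule(generate_schedule("study2_group", seed = 77), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  back <- read_schedule(f1)
  expect_equal(nrow(back), 216)
  expect_identical(attr(back, "variant"), "study2_group")
  expect_identical(back$cues_S, generate_schedule("study2_group", 77)$cues_S)
})

test_that("study-2 group and derived no-group schedules mirror each other", {
  grp <- generate_schedule("study2_group", seed = 55)
  expect_equal(length(unique(grp$trial)), 108)
  expect_balanced_counts(grp$dtype, c("self", "partner", "group"), 72)
  expect_balanced_counts(grp$dtype[grp$matched], c("self", "partner"), 72)
  for (tp in c("self", "partner", "group")) {
    expect_balanced_counts(grp$bonus[grp$dtype == tp], c(-0.5, 0.5), 36)
  }

  ng <- derive_nogroup_from_group(grp, seed = 56)
  expect_balanced_counts(ng$dtype, c("self", "partner"), 108)
  for (tp in c("self", "partner")) {
    expect_balanced_counts(ng$relevant_opponent[ng$dtype == tp],
                           c("O1", "O2"), 54)
  }
  # matched decisions identical across the two schedules
  key <- function(x) x[x$matched, c("trial", "decision", "order", "S", "P",
                                    "O1", "O2", "dtype", "relevant_opponent",
                                    "bonus")]
  expect_identical(key(as.data.frame(grp)), key(as.data.frame(ng)))
  # replacements keep the group decision's bonus
  repl <- ng[!ng$matched, ]
  orig <- grp[grp$dtype == "group", ]
  expect_identical(repl$bonus, orig$bonus)
  expect_identical(repl$trial, orig$trial)
  # no trial compares the same player pair twice
  by_trial <- split(paste(ng$dtype, ng$relevant_opponent), ng$trial)
  expect_true(all(vapply(by_trial, function(z) z[1] != z[2], logical(1))))

  expect_error(derive_nogroup_from_group(ng), "study2_group")
})

test_that("study-4 schedules enforce the position contingencies", {
  s <- generate_schedule("study4", seed = 202, pre = 3, post = 4)
  expect_equal(length(unique(s$trial)), 96)
  expect_equal(nrow(s), 192)
  expect_equal(sum(s$phase == "training") / 2, 64)
  expect_equal(sum(s$phase == "test") / 2, 32)
  # one group and one dyadic decision per trial
  expect_true(all(vapply(split(s$dtype, s$trial),
                         function(z) sum(z == "group") == 1, logical(1))))
  expect_balanced_counts(s$dtype, c("group"), 96)

  dy <- s[s$dtype != "group", ]
  ords <- do.call(rbind, strsplit(dy$order, "-"))
  rel_own <- ifelse(dy$dtype == "self", "S", "P")
  p_own <- mapply(function(i, o) which(ords[i, ] == o),
                  seq_len(nrow(dy)), rel_own)
  p_opp <- mapply(function(i, o) which(ords[i, ] == o),
                  seq_len(nrow(dy)), dy$relevant_opponent)
  pair <- paste(pmin(p_own, p_opp), pmax(p_own, p_opp))
  expect_true(all(pair[dy$phase == "training"] == "2 3"))
  expect_true(all(pair[dy$phase == "test"] == "1 4"))

  # pre4/post3 variant
  s2 <- generate_schedule("study4", seed = 203, pre = 4, post = 3)
  dy2 <- s2[s2$dtype != "group", ]
  ords2 <- do.call(rbind, strsplit(dy2$order, "-"))
  own2 <- mapply(function(i, o) which(ords2[i, ] == o), seq_len(nrow(dy2)),
                 ifelse(dy2$dtype == "self", "S", "P"))
  opp2 <- mapply(function(i, o) which(ords2[i, ] == o), seq_len(nrow(dy2)),
                 dy2$relevant_opponent)
  pair2 <- paste(pmin(own2, opp2), pmax(own2, opp2))
  expect_true(all(pair2[dy2$phase == "training"] == "2 4"))
  expect_true(all(pair2[dy2$phase == "test"] == "1 3"))
})

test_that("decorrelation failure reports the best achieved r-squared", {
  err <- tryCatch(
    generate_schedule("study1_fmri", seed = 1,
                      decorrelation_threshold = 1e-6, max_resamples = 5),
    error = function(e) conditionMessage(e)
  )
  expect_match(err, "best max r\\^2")
})

test_that("decision relevance follows the 0 / 0.5 / 0.25 scoring rule", {
  s <- generate_schedule("study1_fmri", seed = 101)
  rel <- decision_relevance(s)
  expect_equal(rel$relevance, rep(0.25, 4))
  expect_equal(sum(rel$relevance), 1)
  # per-trial normalisation doubles the values for two-decision trials
  expect_equal(decision_relevance(s, per = "trial")$relevance, rep(0.5, 4))

  # degenerate schedules
  only_group <- s[s$dtype == "group", ]
  expect_equal(decision_relevance(only_group)$relevance, rep(0.25, 4))
  only_self_o1 <- s[s$dtype == "self" & s$relevant_opponent == "O1", ]
  rel2 <- decision_relevance(only_self_o1)
  expect_equal(rel2$relevance[rel2$player %in% c("S", "O1")], c(0.5, 0.5))
  expect_equal(rel2$relevance[rel2$player %in% c("P", "O2")], c(0, 0))
})

test_that("decision-variable augmentation matches the scalar core functions", {
  s <- generate_schedule("study2_group", seed = 55)
  aug <- add_decision_variables(s)
  rows <- c(1, 57, 100, 216)
  for (i in rows) {
    by_id <- unlist(aug[i, c("S", "P", "O1", "O2")])
    opp <- if (aug$dtype[i] == "group") NULL else aug$relevant_opponent[i]
    ip <- inverted_projections(aug$order[i], aug$dtype[i], opp, by_id)
    expect_equal(aug$inv_primary[i], unname(ip$inv_primary))
    expect_equal(aug$inv_secondary[i], unname(ip$inv_secondary))
    expect_equal(unname(unlist(aug[i, c("b1", "b2", "b3")])),
                 unname(project(scores_as_pos(by_id, aug$order[i]))))
    expect_equal(aug$dv[i],
                 agent_centric_dv(aug$dtype[i], by_id, opp, aug$bonus[i]))
  }
  expect_true(all(abs(aug$dv) >= 0.5))  # bonus-inclusive DV is never zero
})
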