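#' Sequential basis functions for the four-player decision space
#'
#' Three orthogonal length-4 weight vectors span every decision-relevant
#' comparison between two teams of two players observed in sequence.
#' `basis_matrix()` returns them as the rows of a 3 x 4 matrix:
#' `w1 = c(-1, 1, -1, 1)`, `w2 = c(1, 1, -1, -1)`, `w3 = c(1, -1, -1, 1)`.
#' The complementary `null_vector()` (`c(1, 1, 1, 1)`, the sum of all
#' performances) is orthogonal to all three and task-irrelevant because every
#' decision is a relative comparison.
#'
#' @return `basis_matrix()`: an integer matrix with rows `w1`, `w2`, `w3` and
#'   columns `pos1`..`pos4`; `null_vector()`: an integer vector of four ones.
#' @examples
#' basis_matrix() %*% null_vector()  # all zero: the null axis is orthogonal
#' @export
basis_matrix <- function() {
  m <- rbind(
    w1 = c(-1L, 1L, -1L, 1L),
    w2 = c(1L, 1L, -1L, -1L),
    w3 = c(1L, -1L, -1L, 1L)
  )
  colnames(m) <- paste0("pos", 1:4)
  m
}

#' @rdname basis_matrix
#' @export
null_vector <- function() c(1L, 1L, 1L, 1L)

# player labels in canonical order; S/P form the own team, O1/O2 the opponents
player_labels <- function() c("S", "P", "O1", "O2")

own_team <- function() c("S", "P")

#' Weight vector for a sequential comparison
#'
#' Weight vectors 1-3 are the basis functions themselves (group comparisons);
#' vectors 4-9 are the six dyadic comparisons of one sequence position against
#' another, each expressible as `(wi + wj)/2` or `(wi - wj)/2` for two basis
#' functions. `dyadic_weight_vector()` is the 4..9 subset.
#'
#' @param k Integer index in 1..9 (`weight_vector()`) or 4..9
#'   (`dyadic_weight_vector()`).
#' @return A length-4 numeric weight vector over sequence positions.
#' @examples
#' dyadic_weight_vector(6)                 # pos2 vs pos3
#' all(weight_vector(6) == (basis_matrix()[1, ] + basis_matrix()[2, ]) / 2)
#' @export
weight_vector <- function(k) {
  if (length(k) != 1L || !is.numeric(k) || is.na(k) || k != as.integer(k) ||
      k < 1 || k > 9) {
    stop("`k` must be a single integer in 1..9.", call. = FALSE)
  }
  k <- as.integer(k)
  W <- basis_matrix()
  v <- switch(k,
    W[1, ], W[2, ], W[3, ],
    (W[1, ] + W[3, ]) / 2,  # w4 = [ 0,  0, -1,  1]
    (W[2, ] - W[3, ]) / 2,  # w5 = [ 0,  1,  0, -1]
    (W[1, ] + W[2, ]) / 2,  # w6 = [ 0,  1, -1,  0]
    (W[1, ] - W[2, ]) / 2,  # w7 = [-1,  0,  0,  1]
    (W[2, ] + W[3, ]) / 2,  # w8 = [ 1,  0, -1,  0]
    (W[3, ] - W[1, ]) / 2   # w9 = [ 1, -1,  0,  0]
  )
  unname(v)
}

#' @rdname weight_vector
#' @export
dyadic_weight_vector <- function(k) {
  if (length(k) != 1L || !is.numeric(k) || is.na(k) || !(k %in% 4:9)) {
    stop("`k` must be a single integer in 4..9 (dyadic comparisons).",
         call. = FALSE)
  }
  weight_vector(k)
}

validate_pos <- function(pos) {
  if (!is.numeric(pos) || length(pos) != 4L || anyNA(pos)) {
    stop("`pos` must be a length-4 numeric vector of performance scores.",
         call. = FALSE)
  }
  if (any(pos != round(pos)) || any(pos < 0) || any(pos > 6)) {
    stop("Performance scores must be integers between 0 and 6.", call. = FALSE)
  }
  as.numeric(pos)
}

#' Project a performance sequence onto the basis functions
#'
#' Computes `b = W pos`, the dot products of the sequentially observed
#' performance scores with the three basis functions. Each projection is a
#' signed performance difference between pairs of sequence positions; with
#' integer scores in 0..6 every projection lies in -12..12.
#'
#' @param pos Length-4 vector of integer performance scores (0..6), indexed by
#'   sequence position.
#' @return Named numeric vector `c(b1, b2, b3)`.
#' @examples
#' project(c(4, 3, 2, 1))  # b = (-2, 4, 0)
#' project(c(3, 2, 2, 2))["b2"]  # first pair one point better: b2 = 1
#' @export
project <- function(pos) {
  pos <- validate_pos(pos)
  b <- as.numeric(basis_matrix() %*% pos)
  names(b) <- c("b1", "b2", "b3")
  b
}

#' Sequential decision variable for a weight vector
#'
#' `DV_k = w_k . pos` for `k` in 1..9: the performance difference implied by
#' the k-th sequential comparison. The non-social bonus is not included.
#'
#' @inheritParams project
#' @inheritParams weight_vector
#' @return A single numeric decision variable.
#' @export
sequential_dv <- function(k, pos) {
  pos <- validate_pos(pos)
  sum(weight_vector(k) * pos)
}

validate_order <- function(order) {
  order <- parse_order(order)
  if (length(order) != 4L || !setequal(order, player_labels()) ||
      anyDuplicated(order) > 0) {
    stop("`order` must contain each of S, P, O1, O2 exactly once.",
         call. = FALSE)
  }
  order
}

#' Parse and format player orders
#'
#' A player order records which identity occupied each of the four sequence
#' positions during the observation phase. Orders are written as strings such
#' as `"P-S-O1-O2"` (position 1 to 4) or given as character vectors of the
#' labels `S`, `P`, `O1`, `O2`.
#'
#' @param order An order string or length-4 character vector of labels.
#' @return `parse_order()`: a length-4 character vector of labels;
#'   `format_order()`: a single string.
#' @export
parse_order <- function(order) {
  if (is.character(order) && length(order) == 1L) {
    order <- strsplit(order, "-", fixed = TRUE)[[1]]
  }
  as.character(order)
}

#' @rdname parse_order
#' @export
format_order <- function(order) paste(parse_order(order), collapse = "-")

validate_decision <- function(dtype, relevant_opponent) {
  dtype <- match.arg(dtype, c("self", "partner", "group"))
  if (dtype == "group") {
    if (!is.null(relevant_opponent) && !identical(relevant_opponent, "both")) {
      stop("Group decisions have both opponents relevant.", call. = FALSE)
    }
    relevant_opponent <- "both"
  } else {
    if (is.null(relevant_opponent) || !(relevant_opponent %in% c("O1", "O2"))) {
      stop("Dyadic decisions need `relevant_opponent` of \"O1\" or \"O2\".",
           call. = FALSE)
    }
  }
  list(dtype = dtype, relevant_opponent = relevant_opponent)
}

#' Sort basis functions by decision relevance
#'
#' The primary basis function is the one whose +/- pattern partitions the four
#' sequence positions into the two teams under the given presentation order,
#' with the sign chosen so that the participant's own team is weighted
#' positively. For dyadic decisions the secondary basis function is the unique
#' other basis function such that the signed average of primary and secondary
#' equals the cued one-against-one comparison (relevant own player positive,
#' relevant opponent negative); the tertiary is the remaining one. For group
#' decisions only the primary is defined.
#'
#' @inheritParams parse_order
#' @param dtype Decision type: `"self"`, `"partner"` or `"group"`.
#' @param relevant_opponent `"O1"` or `"O2"` for dyadic decisions; ignored
#'   (both opponents relevant) for group decisions.
#' @return A list with `primary_idx`, `primary_sign`, `secondary_idx`,
#'   `secondary_sign`, `tertiary_idx` (secondary/tertiary are `NA` for group
#'   decisions).
#' @examples
#' sort_relevance("P-S-O1-O2", "group")  # primary is w2, positive sign
#' @export
sort_relevance <- function(order, dtype, relevant_opponent = NULL) {
  order <- validate_order(order)
  dec <- validate_decision(dtype, relevant_opponent)
  W <- basis_matrix()

  # team vector: +1 where own team sits, -1 at opponent positions
  team <- ifelse(order %in% own_team(), 1, -1)
  primary_idx <- NA_integer_
  primary_sign <- NA_real_
  for (i in 1:3) {
    for (s in c(1, -1)) {
      if (all(s * W[i, ] == team)) {
        primary_idx <- i
        primary_sign <- s
      }
    }
  }
  stopifnot(!is.na(primary_idx))  # the own-team pair always matches a pairing

  if (dec$dtype == "group") {
    return(list(primary_idx = primary_idx, primary_sign = primary_sign,
                secondary_idx = NA_integer_, secondary_sign = NA_real_,
                tertiary_idx = NA_integer_))
  }

  rel_own <- if (dec$dtype == "self") "S" else "P"
  # cued comparison: +1 at the relevant own player's position, -1 at the
  # relevant opponent's position, 0 elsewhere
  cued <- rep(0, 4)
  cued[order == rel_own] <- 1
  cued[order == dec$relevant_opponent] <- -1

  residual <- 2 * cued - primary_sign * W[primary_idx, ]
  secondary_idx <- NA_integer_
  secondary_sign <- NA_real_
  for (j in setdiff(1:3, primary_idx)) {
    for (s in c(1, -1)) {
      if (all(s * W[j, ] == residual)) {
        secondary_idx <- j
        secondary_sign <- s
      }
    }
  }
  stopifnot(!is.na(secondary_idx))
  tertiary_idx <- setdiff(1:3, c(primary_idx, secondary_idx))

  list(primary_idx = primary_idx, primary_sign = primary_sign,
       secondary_idx = secondary_idx, secondary_sign = secondary_sign,
       tertiary_idx = as.integer(tertiary_idx))
}

#' Invert relevance-sorted basis functions to the agent-centric frame
#'
#' Re-expressed in the fixed identity ordering `[S, P, Or, Oi]`, the signed
#' primary basis function is always `c(1, 1, -1, -1)` (own team minus opponent
#' team) and the signed secondary is always `c(1, -1, -1, 1)` (relevant
#' players positive for own/negative for opponent, irrelevant players with the
#' opposite pattern). Their mean `c(1, 0, -1, 0)` is the cued dyadic
#' comparison: irrelevant players cancel.
#'
#' @param sorted Output of [sort_relevance()] for a dyadic decision.
#' @return A list with elements `primary` and `secondary`, each a named
#'   numeric vector over `c("S"/"P", ..., "Or", "Oi")` identity slots.
#' @export
invert_to_agent_centric <- function(sorted) {
  if (is.na(sorted$secondary_idx)) {
    stop("The inverted secondary basis function is undefined for group ",
         "decisions.", call. = FALSE)
  }
  nm <- c("S", "P", "Or", "Oi")
  list(
    primary = stats::setNames(c(1, 1, -1, -1), nm),
    secondary = stats::setNames(c(1, -1, -1, 1), nm)
  )
}

scores_as_pos <- function(scores_by_identity, order) {
  order <- validate_order(order)
  miss <- setdiff(player_labels(), names(scores_by_identity))
  if (length(miss)) {
    stop("Missing scores for: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  as.numeric(scores_by_identity[order])
}

#' Agent-centric decision variable
#'
#' `DV_self = S - Or + B`, `DV_partner = P - Or + B`,
#' `DV_group = S + P - O1 - O2 + B`. With `include_bonus = FALSE` the bonus
#' term is dropped. Because bonuses have fractional part 0.5 and scores are
#' integers, the bonus-inclusive DV is never zero: each decision has a correct
#' response.
#'
#' @inheritParams sort_relevance
#' @param scores_by_identity Named numeric vector with entries `S`, `P`, `O1`,
#'   `O2`.
#' @param bonus Non-social bonus (e.g. -1.5, -0.5, 0.5, 1.5).
#' @param include_bonus Include the bonus term? Default `TRUE`.
#' @return A single numeric decision variable.
#' @examples
#' agent_centric_dv("self", c(S = 4, P = 1, O1 = 2, O2 = 5), "O1", bonus = 0.5)
#' @export
agent_centric_dv <- function(dtype, scores_by_identity, relevant_opponent = NULL,
                             bonus = 0, include_bonus = TRUE) {
  dec <- validate_decision(dtype, relevant_opponent)
  miss <- setdiff(player_labels(), names(scores_by_identity))
  if (length(miss)) {
    stop("Missing scores for: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  s <- scores_by_identity
  dv <- switch(dec$dtype,
    self = s[["S"]] - s[[dec$relevant_opponent]],
    partner = s[["P"]] - s[[dec$relevant_opponent]],
    group = s[["S"]] + s[["P"]] - s[["O1"]] - s[["O2"]]
  )
  if (include_bonus) dv <- dv + bonus
  unname(dv)
}

#' Pay-off of an engage/avoid choice
#'
#' Engaging yields the veridical (bonus-inclusive) decision variable, positive
#' or negative; avoiding always yields zero.
#'
#' @param choice `"engage"` or `"avoid"` (or 1/0).
#' @param dv Bonus-inclusive decision variable.
#' @return Numeric pay-off, vectorised over inputs.
#' @export
payoff <- function(choice, dv) {
  if (is.numeric(choice)) {
    engage <- choice == 1
  } else {
    choice <- match.arg(as.character(choice), c("engage", "avoid"),
                        several.ok = TRUE)
    engage <- choice == "engage"
  }
  ifelse(engage, dv, 0)
}

#' Inverted basis-function projections for a decision
#'
#' Convenience wrapper combining [project()], [sort_relevance()] and the sign
#' bookkeeping: returns the agent-centric (inverted) primary and secondary
#' projections for one decision, i.e. `primary_sign * b[primary]` (own team
#' minus opponent team) and, for dyadic decisions,
#' `secondary_sign * b[secondary]`.
#'
#' @inheritParams sort_relevance
#' @param scores_by_identity Named numeric vector with entries `S`, `P`, `O1`,
#'   `O2`.
#' @return A list with `inv_primary`, `inv_secondary` (NA for group
#'   decisions), and the `sorted` relevance structure.
#' @export
inverted_projections <- function(order, dtype, relevant_opponent = NULL,
                                 scores_by_identity) {
  order <- validate_order(order)
  pos <- scores_as_pos(scores_by_identity, order)
  b <- project(pos)
  sorted <- sort_relevance(order, dtype, relevant_opponent)
  inv_primary <- sorted$primary_sign * b[[sorted$primary_idx]]
  inv_secondary <- if (is.na(sorted$secondary_idx)) NA_real_ else
    sorted$secondary_sign * b[[sorted$secondary_idx]]
  list(inv_primary = inv_primary, inv_secondary = inv_secondary,
       sorted = sorted)
}
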