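# Personal utility function (PUF) construction.
#
# The utility of a state starts at 1 for full health ("11111") and loses,
# for each dimension, a decrement that depends on the level:
#   level 1: nothing
#   level 3: the dimension's relative swing weight w_d (section C ratings,
#            normalised to sum to 1 over the five dimensions)
#   level 2: w_d scaled by the dimension's level-2 fraction (section D)
# Because the level-3 decrements sum to 1, u("33333") = 0 exactly, so every
# PUF lives on the 0-1 scale before anchoring at dead.

#' Relative dimension weights from swing ratings
#'
#' Proportional normalisation of the section C swing ratings:
#' `w_d = r_d / sum(r)`. A zero rating yields a zero weight (the dimension
#' contributes nothing to the utility function). The weights always sum to 1.
#' Normalisation does not require that exactly one dimension was rated 100 —
#' records where none or several were are handled identically.
#'
#' @param swing Five ratings in 0--100, at least one positive (named by
#'   dimension or given in the fixed order MO, SC, UA, PD, AD).
#' @return Named numeric vector of weights summing to 1.
#' @export
#' @examples
#' dimension_weights(c(100, 80, 80, 90, 82))
dimension_weights <- function(swing) {
  r <- as_dimension_vector(swing, "swing ratings")
  tot <- sum(r)
  if (tot <= 0) {
    stop("all swing ratings are zero; dimension weights are undefined", call. = FALSE)
  }
  r / tot
}

#' Per-level utility decrements from weights and point allocations
#'
#' The level-3 decrement of a dimension equals its relative weight. The
#' level-2 decrement scales that weight by a fraction derived from the
#' section D points `p_d` given to the intermediate (extreme to moderate)
#' improvement:
#'
#' * `"share_of_swing"` (default): `delta_{d,2} = w_d * p_d / 100`. The
#'   points given to the intermediate improvement are read as the share of
#'   the full swing recovered by moving from extreme to moderate problems,
#'   i.e. as the badness of remaining at level 2 relative to level 3.
#' * `"remaining_badness"`: `delta_{d,2} = w_d * (1 - p_d / 100)`, the
#'   semantically opposite reading, retained as an option.
#'
#' At `p_d = 50` the two conventions coincide. See the package vignette for
#' why `"share_of_swing"` is the default.
#'
#' @param weights Named weights summing to 1 (from [dimension_weights()]).
#' @param allocation Five section D point allocations in 0--100.
#' @param level2_mapping `"share_of_swing"` or `"remaining_badness"`.
#' @return A 5 x 3 matrix of decrements (rows = dimensions, columns =
#'   levels 1--3; column 1 is all zeros).
#' @export
level_decrements <- function(weights, allocation,
                             level2_mapping = c("share_of_swing", "remaining_badness")) {
  level2_mapping <- match.arg(level2_mapping)
  w <- as_dimension_vector(weights, "weights", lo = 0, hi = 1)
  if (abs(sum(w) - 1) > 1e-9) stop("weights must sum to 1", call. = FALSE)
  p <- as_dimension_vector(allocation, "level allocations")
  frac <- switch(level2_mapping,
                 share_of_swing = p / 100,
                 remaining_badness = 1 - p / 100)
  dec <- cbind(`1` = rep(0, 5), `2` = w * frac, `3` = w)
  rownames(dec) <- PUF_DIMENSIONS
  dec
}

#' Fit a personal utility function
#'
#' Constructs a respondent's utility function over the 243-state space from
#' their section C swing ratings and section D point allocations. The fitted
#' object carries the relative dimension weights, the level-2 fractions and
#' the per-level decrements; utilities of states are obtained with
#' [predict()] and the full ordering with [rank_states()].
#'
#' @inheritParams level_decrements
#' @param swing Five swing ratings in 0--100, at least one positive.
#' @param allocation Five intermediate-improvement point allocations in
#'   0--100.
#' @return An object of class `"puf"` with components `weights`,
#'   `allocation`, `level2_fraction`, `decrements` (5 x 3 matrix) and
#'   `level2_mapping`.
#' @seealso [default_puf()], [anchor_puf()], [rank_states()]
#' @export
#' @examples
#' fit <- puf(swing = c(100, 80, 80, 90, 82), allocation = rep(50, 5))
#' predict(fit, c("11111", "21111", "33333"))
puf <- function(swing, allocation,
                level2_mapping = c("share_of_swing", "remaining_badness")) {
  level2_mapping <- match.arg(level2_mapping)
  w <- dimension_weights(swing)
  p <- as_dimension_vector(allocation, "level allocations")
  dec <- level_decrements(w, p, level2_mapping)
  frac <- switch(level2_mapping,
                 share_of_swing = p / 100,
                 remaining_badness = 1 - p / 100)
  structure(list(weights = w,
                 allocation = p,
                 level2_fraction = frac,
                 decrements = dec,
                 level2_mapping = level2_mapping,
                 call = match.call()),
            class = "puf")
}

#' The interview tool's default utility function
#'
#' The fallback used when sections E/F tasks were generated without tailored
#' inputs: a rating of 100 on every dimension and an allocation of 50 to
#' every intermediate improvement (equal weights of 0.2; level-2 decrements
#' of 0.1).
#'
#' @inheritParams level_decrements
#' @return A `"puf"` object.
#' @export
default_puf <- function(level2_mapping = "share_of_swing") {
  puf(rep(100, 5), rep(50, 5), level2_mapping)
}

#' @export
print.puf <- function(x, digits = 4, ...) {
  cat(if (inherits(x, "anchored_puf")) "<anchored_puf>" else "<puf>",
      "level-2 mapping:", x$level2_mapping, "\n")
  if (inherits(x, "anchored_puf")) {
    cat("  status:", x$status, " dead utility:",
        format(x$dead_utility, digits = digits), "\n")
  }
  m <- cbind(weight = x$weights,
             level2_fraction = x$level2_fraction,
             decrement2 = x$decrements[, 2],
             decrement3 = x$decrements[, 3])
  print(round(m, digits))
  invisible(x)
}

#' @export
summary.puf <- function(object, ...) {
  u <- predict(object)
  structure(list(puf = object,
                 range = range(u),
                 mean_utility = mean(u),
                 n_negative = sum(u < 0)),
            class = "summary.puf")
}

#' @export
print.summary.puf <- function(x, digits = 4, ...) {
  print(x$puf, digits = digits)
  cat(sprintf("  243 states: utilities in [%.4f, %.4f], mean %.4f, %d below 0\n",
              x$range[1], x$range[2], x$mean_utility, x$n_negative))
  invisible(x)
}

#' Extract utility decrements from a fitted PUF
#'
#' @param object A `"puf"` (or `"anchored_puf"`).
#' @param ... Unused.
#' @return A 5 x 2 matrix of level-2 and level-3 decrements.
#' @export
coef.puf <- function(object, ...) {
  object$decrements[, c("2", "3"), drop = FALSE]
}

#' State utilities under a fitted PUF
#'
#' `u(s) = 1 - sum_d delta_{d, level_d(s)}` with a zero decrement at
#' level 1. For an unanchored PUF, `u("11111") = 1` and `u("33333") = 0`;
#' after anchoring, values below 0 mark states worse than dead.
#'
#' @param object A `"puf"` object.
#' @param states Character vector of state codes; defaults to all 243.
#' @param ... Unused.
#' @return Named numeric vector of utilities.
#' @export
predict.puf <- function(object, states = enumerate_states(), ...) {
  m <- state_levels(states)
  dec <- object$decrements
  u <- rep(1, nrow(m))
  for (d in 1:5) u <- u - dec[d, ][m[, d]]
  setNames(u, states)
}

#' @rdname predict.puf
#' @param x A `"puf"` object (alias of `predict` matching the protocol's
#'   terminology).
#' @export
state_utility <- function(x, states = enumerate_states()) {
  stopifnot(inherits(x, "puf"))
  predict(x, states)
}

#' @export
plot.puf <- function(x, ...) {
  m <- rbind(level2 = x$decrements[, 2], level3 = x$decrements[, 3])
  barplot(m, beside = TRUE, names.arg = PUF_DIMENSIONS,
          legend.text = c("level 2", "level 3"),
          ylab = "utility decrement", main = "PUF decrements by dimension", ...)
  invisible(x)
}

#' Rank all 243 states under a fitted PUF
#'
#' Sorts the full state space by utility (descending); ties are broken by
#' ascending lexicographic state code so the ranking is deterministic. Rank
#' 1 is `"11111"`; for an unanchored PUF rank 243 is `"33333"`.
#'
#' @param x A `"puf"` object.
#' @return A data frame of class `"state_ranking"` with columns `rank`
#'   (1--243), `state` and `utility`.
#' @export
#' @examples
#' head(rank_states(default_puf()))
rank_states <- function(x) {
  stopifnot(inherits(x, "puf"))
  u <- predict(x)
  ord <- order(-u, names(u), method = "radix")
  out <- data.frame(rank = seq_along(u),
                    state = names(u)[ord],
                    utility = unname(u[ord]),
                    stringsAsFactors = FALSE)
  class(out) <- c("state_ranking", "data.frame")
  out
}
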