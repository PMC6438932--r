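# Adaptive task generation: section E validation pairs, the section F
# bisection search for the personal location of dead, and the section G
# interaction tasks.

#' Generate the two tailored validation pairs (section E)
#'
#' Both pairs are chosen from the respondent's own 243-state ranking and must
#' not dominate one another. Pair 1 (the "easier" task) targets a large
#' utility disparity: starting from the quartile ranks `ceiling(0.25 * 243)`
#' and `ceiling(0.75 * 243)` the ranks are pushed outward, one step at a
#' time, until the first non-dominating pair is found. Pair 2 (the "harder"
#' task) is the adjacent-rank pair with the smallest utility gap among
#' non-dominating adjacent pairs, taking the candidate nearest the median
#' rank (ties towards the lower rank). Option A is always the state with the
#' higher estimated utility.
#'
#' @param ranking A full [rank_states()] ranking.
#' @return A list of two tasks, each a list with `task_index`, `option_a`,
#'   `option_b`, `rank_a`, `rank_b` and `utility_gap`.
#' @export
generate_validation_pairs <- function(ranking) {
  stopifnot(inherits(ranking, "state_ranking"))
  n <- nrow(ranking)
  non_dominating <- function(a, b) !dominates(a, b) && !dominates(b, a)
  as_pair <- function(task_index, lo, hi) {
    list(task_index = as.integer(task_index),
         option_a = ranking$state[lo], option_b = ranking$state[hi],
         rank_a = lo, rank_b = hi,
         utility_gap = ranking$utility[lo] - ranking$utility[hi])
  }

  lo0 <- ceiling(0.25 * n)
  hi0 <- ceiling(0.75 * n)
  pair1 <- NULL
  for (k in 0:(n - 1)) {
    for (i in 0:k) {
      lo <- lo0 - i
      hi <- hi0 + (k - i)
      if (lo < 1L || hi > n) next
      if (non_dominating(ranking$state[lo], ranking$state[hi])) {
        pair1 <- as_pair(1L, lo, hi)
        break
      }
    }
    if (!is.null(pair1)) break
  }

  med <- ceiling(n / 2)
  cand <- seq_len(n - 1L)
  ok <- vapply(cand, function(r) non_dominating(ranking$state[r], ranking$state[r + 1L]),
               logical(1))
  cand <- cand[ok]
  gaps <- ranking$utility[cand] - ranking$utility[cand + 1L]
  min_gap <- min(gaps)
  best <- cand[gaps <= min_gap + 1e-12]
  best <- best[order(abs(best - med), best)][1L]
  pair2 <- as_pair(2L, best, best + 1L)

  list(pair1, pair2)
}

#' Next rank to present in the bisection search for dead
#'
#' The search keeps a lower bound (a state the respondent prefers to dying
#' now — dead is worse than it) and an upper bound (a state worse than dead).
#' The next presented state is the round-half-up midpoint of the two bounds'
#' ranks; while only an upper bound is known, the implicit lower bound is
#' rank 1 (full health). After an initial choice of dying now over `"33333"`
#' the first midpoint is therefore rank 122.
#'
#' @param lower_rank Rank of the current better bound, or `NULL` when only
#'   an upper bound is known.
#' @param upper_rank Rank of the current worse bound.
#' @param total Number of ranked states (243).
#' @return The integer rank to present next.
#' @export
#' @examples
#' bisection_next(NULL, 243)  # 122
#' bisection_next(122, 243)   # 183
#' bisection_next(NULL, 122)  # 62
bisection_next <- function(lower_rank = NULL, upper_rank, total = 243L) {
  lo <- if (is.null(lower_rank) || is.na(lower_rank)) 1L else as.integer(lower_rank)
  up <- as.integer(upper_rank)
  if (is.na(up) || up > total || lo < 1L || up <= lo) {
    stop("bisection bounds must satisfy 1 <= lower < upper <= total", call. = FALSE)
  }
  if (up - lo < 2L) {
    stop("bisection interval exhausted: no rank strictly between the bounds",
         call. = FALSE)
  }
  as.integer(ceiling((lo + up) / 2))
}

new_bracket <- function(classification, lower_rank = NA_integer_,
                        upper_rank = NA_integer_) {
  structure(list(classification = classification,
                 lower_rank = as.integer(lower_rank),
                 upper_rank = as.integer(upper_rank)),
            class = "dead_bracket")
}

#' @export
print.dead_bracket <- function(x, ...) {
  cat("<dead_bracket>", x$classification,
      if (!is.na(x$lower_rank)) sprintf(" lower rank %d", x$lower_rank) else "",
      if (!is.na(x$upper_rank)) sprintf(" upper rank %d", x$upper_rank) else "",
      "\n", sep = "")
  invisible(x)
}

#' Run the five-task bisection search for the location of dead (section F)
#'
#' The first task always presents `"33333"` (rank 243). Choosing 10 years in
#' the state (choice `"A"`) at the first task classifies dead as lying below
#' `"33333"` and stops the search; otherwise exactly five tasks are
#' presented, each at the [bisection_next()] midpoint of the current bounds.
#' Choice `"A"` makes the presented state the new lower (better) bound;
#' choice `"B"` (dying now) makes it the new upper bound. A respondent who
#' always chooses `"B"` is classified `above_mildest`: dead lies between
#' full health and the mildest state presented (recorded as `upper_rank`).
#' After a completed search the bracket spans 15 or 16 ranks.
#'
#' @param ranking A full [rank_states()] ranking.
#' @param answer_fn A function taking a state code and returning `"A"`
#'   (prefer 10 years in the state) or `"B"` (prefer dying now).
#' @return A list with `record` (a [dead_search_record()]) and `bracket`
#'   (classification `below_33333`, `bracketed` or `above_mildest` with the
#'   bounding ranks).
#' @export
#' @examples
#' # the worked example: dying now over 33333, then 10 years in every
#' # subsequent state, locates dead between the 228th and 243rd ranked states
#' ans <- local({ i <- 0; function(state) { i <<- i + 1; if (i == 1) "B" else "A" } })
#' run_dead_search(rank_states(default_puf()), ans)$bracket
run_dead_search <- function(ranking, answer_fn) {
  stopifnot(inherits(ranking, "state_ranking"), is.function(answer_fn))
  n <- nrow(ranking)
  lower <- NULL
  upper <- NULL
  ranks <- integer(0)
  states <- character(0)
  choices <- character(0)
  rank <- n
  for (task in 1:5) {
    state <- ranking$state[rank]
    ch <- answer_fn(state)
    if (!identical(ch, "A") && !identical(ch, "B")) {
      stop("answer_fn must return 'A' or 'B'", call. = FALSE)
    }
    ranks <- c(ranks, rank)
    states <- c(states, state)
    choices <- c(choices, ch)
    if (ch == "A") {
      if (task == 1L) break
      lower <- rank
    } else {
      upper <- rank
    }
    if (task < 5L) rank <- bisection_next(lower, upper, total = n)
  }
  record <- dead_search_record(ranks, states, choices)
  bracket <- bracket_from_record(record)
  list(record = record, bracket = bracket)
}

#' Reconstruct the dead bracket from a recorded choice sequence
#'
#' Replays a section F record's choices through the bisection bookkeeping to
#' recover the final bounds; used when estimating PUFs from stored study
#' files.
#'
#' @param record A [dead_search_record()].
#' @return A `"dead_bracket"` object.
#' @export
bracket_from_record <- function(record) {
  stopifnot(inherits(record, "dead_search"))
  if (record$choices[1L] == "A") {
    return(new_bracket("below_33333", lower_rank = record$presented_ranks[1L]))
  }
  lower <- NA_integer_
  upper <- NA_integer_
  for (i in seq_along(record$choices)) {
    if (record$choices[i] == "A") {
      lower <- record$presented_ranks[i]
    } else {
      upper <- record$presented_ranks[i]
    }
  }
  if (is.na(lower)) {
    new_bracket("above_mildest", upper_rank = min(record$presented_ranks))
  } else {
    new_bracket("bracketed", lower_rank = lower, upper_rank = upper)
  }
}

#' Generate the two interaction tasks (section G)
#'
#' Each task compares two one-level improvements in the same dimension that
#' differ only in the level of a second dimension. Task 1 improves the most
#' important dimension from extreme to moderate problems, either with no
#' problems elsewhere (option A) or with moderate problems in the least
#' important dimension (option B). Task 2 improves the least important
#' dimension from moderate to no problems, either with no problems elsewhere
#' (A) or with moderate problems in the most important dimension (B). Under
#' a purely additive utility function the options of each task are equally
#' valuable, so systematic preference for one signals an interaction.
#'
#' @param most,least Dimension codes of the respondent's most and least
#'   important dimensions (must differ); see [most_least_dimensions()].
#' @return A list of two tasks, each with `task_index`, `option_a` and
#'   `option_b`, where an option is a list with `from` and `to` state codes.
#' @export
#' @examples
#' generate_interaction_tasks("MO", "AD")
generate_interaction_tasks <- function(most, least) {
  stopifnot(most %in% PUF_DIMENSIONS, least %in% PUF_DIMENSIONS)
  if (identical(most, least)) {
    stop("the most and least important dimensions must differ", call. = FALSE)
  }
  st <- function(...) {
    mods <- c(...)
    v <- setNames(rep(1L, 5), PUF_DIMENSIONS)
    v[names(mods)] <- mods
    format_state(v)
  }
  task1 <- list(
    task_index = 1L,
    option_a = list(from = st(setNames(3L, most)), to = st(setNames(2L, most))),
    option_b = list(from = st(setNames(c(3L, 2L), c(most, least))),
                    to = st(setNames(c(2L, 2L), c(most, least))))
  )
  task2 <- list(
    task_index = 2L,
    option_a = list(from = st(setNames(3L, least)), to = st(setNames(2L, least))),
    option_b = list(from = st(setNames(c(3L, 2L), c(least, most))),
                    to = st(setNames(c(2L, 2L), c(least, most))))
  )
  list(task1, task2)
}

#' Most and least important dimensions from a section B ranking
#'
#' Uses the averaging rank statistic ([ranks_avg()]); ties for most
#' important are broken by the higher section C rating, ties for least
#' important by the lower rating, and any remaining ties by the fixed
#' dimension order (first position for "most", last for "least", so the two
#' always differ).
#'
#' @param ranking Section B ranking groups.
#' @param swing Section C swing ratings (used only for tie-breaking; may be
#'   omitted).
#' @return A list with elements `most` and `least`.
#' @export
most_least_dimensions <- function(ranking, swing = NULL) {
  r <- ranks_avg(check_ranking_groups(ranking))[PUF_DIMENSIONS]
  s <- if (is.null(swing)) setNames(rep(0, 5), PUF_DIMENSIONS)
       else as_dimension_vector(swing, "swing ratings")
  idx <- seq_along(PUF_DIMENSIONS)
  most <- PUF_DIMENSIONS[order(r, -s, idx)][1L]
  least <- PUF_DIMENSIONS[order(-r, s, -idx)][1L]
  list(most = most, least = least)
}

#' Tally section G interaction responses across respondents
#'
#' Counts choices of A, B, indifference and missing responses per task over
#' a set of respondents; percentages use the number of respondents as the
#' denominator (so missing responses are counted, not dropped).
#'
#' @param respondents A list of [respondent_record()]s or a study object
#'   from [read_study()] / [simulate_cohort()].
#' @return A data frame with columns `task_index`, `response`, `count` and
#'   `percent`.
#' @export
tally_interactions <- function(respondents) {
  if (inherits(respondents, "puf_study")) respondents <- respondents$respondents
  n <- length(respondents)
  responses <- c("A", "B", "indifferent", "missing")
  out <- do.call(rbind, lapply(1:2, function(t) {
    ch <- vapply(respondents, function(r) {
      hit <- Filter(function(ic) ic$task_index == t, r$interactions)
      if (length(hit)) hit[[1L]]$choice else "missing"
    }, character(1))
    counts <- vapply(responses, function(x) sum(ch == x), integer(1))
    data.frame(task_index = t, response = responses, count = counts,
               percent = if (n > 0) 100 * counts / n else rep(0, 4),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  out
}
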