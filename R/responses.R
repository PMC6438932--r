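# Data model for a respondent's elicitation record.
#
# Sections of the interview:
#   A  self-reported profile + VAS (twice: current and worst-experienced)
#   B  ranking of the five dimensions, ties allowed (ordered groups)
#   C  swing ratings 0-100 per dimension (most valued swing rated 100)
#   D  allocation of 100 points between the extreme->moderate and the
#      moderate->none improvement per dimension (we store the points given
#      to the intermediate, i.e. extreme->moderate, improvement)
#   E  two forced-choice validation pairs
#   F  up to five 10-years-in-state vs dying-now choices (bisection search)
#   G  two interaction tasks, indifference allowed

# --- small input helpers -----------------------------------------------------

as_dimension_vector <- function(x, what, lo = 0, hi = 100) {
  if (is.list(x)) x <- unlist(x)
  if (length(x) != 5L || !is.numeric(x)) {
    stop(sprintf("%s must be five numeric values (one per dimension)", what),
         call. = FALSE)
  }
  if (!is.null(names(x)) && any(nzchar(names(x)))) {
    if (!setequal(names(x), PUF_DIMENSIONS)) {
      stop(sprintf("%s names must be %s", what,
                   paste(PUF_DIMENSIONS, collapse = ", ")), call. = FALSE)
    }
    x <- x[PUF_DIMENSIONS]
  } else {
    names(x) <- PUF_DIMENSIONS
  }
  if (any(is.na(x)) || any(x < lo) || any(x > hi)) {
    stop(sprintf("%s must lie in [%s, %s] with no missing values", what, lo, hi),
         call. = FALSE)
  }
  x
}

check_ranking_groups <- function(groups) {
  if (!is.list(groups) || !length(groups)) {
    stop("ranking must be a non-empty list of dimension groups", call. = FALSE)
  }
  groups <- lapply(groups, function(g) as.character(unlist(g)))
  flat <- unlist(groups)
  if (any(!lengths(groups))) stop("ranking groups must be non-empty", call. = FALSE)
  if (anyDuplicated(flat)) {
    stop("ranking groups must be disjoint (dimension listed twice: ",
         flat[duplicated(flat)][1L], ")", call. = FALSE)
  }
  if (!setequal(flat, PUF_DIMENSIONS)) {
    stop("ranking must cover exactly the five dimensions ",
         paste(PUF_DIMENSIONS, collapse = ", "), call. = FALSE)
  }
  groups
}

# --- record constructors -----------------------------------------------------

#' Section A self-report
#'
#' @param current_profile,worst_profile State codes self-reported for today's
#'   health and for the worst health problems ever experienced.
#' @param current_vas,worst_vas Integer VAS ratings in 0--100.
#' @return An object of class `"self_report"`.
#' @export
self_report <- function(current_profile, current_vas, worst_profile, worst_vas) {
  parse_state(current_profile)
  parse_state(worst_profile)
  for (v in list(current_vas, worst_vas)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 100) {
      stop("VAS ratings must be single values in [0, 100]", call. = FALSE)
    }
  }
  structure(list(current_profile = current_profile,
                 current_vas = as.numeric(current_vas),
                 worst_profile = worst_profile,
                 worst_vas = as.numeric(worst_vas)),
            class = "self_report")
}

#' Section E pair-choice record
#'
#' A forced choice between two non-dominating health states; no indifference
#' option is permitted.
#'
#' @param task_index 1 (the easier pair) or 2 (the harder pair).
#' @param option_a,option_b State codes; neither may dominate the other.
#' @param choice `"A"` or `"B"`.
#' @return An object of class `"pair_choice"`.
#' @export
pair_choice <- function(task_index, option_a, option_b, choice) {
  stopifnot(task_index %in% 1:2)
  if (dominates(option_a, option_b) || dominates(option_b, option_a)) {
    stop(sprintf("pair (%s, %s) violates the non-dominance restriction",
                 option_a, option_b), call. = FALSE)
  }
  if (!choice %in% c("A", "B")) {
    stop("pair choice must be 'A' or 'B' (no indifference permitted)", call. = FALSE)
  }
  structure(list(task_index = as.integer(task_index), option_a = option_a,
                 option_b = option_b, choice = choice),
            class = "pair_choice")
}

#' Section F dead-search record
#'
#' The sequence of up to five 10-years-in-state vs dying-now choices. The
#' first presented state is always `"33333"` (rank 243). A respondent who
#' prefers 10 years in `"33333"` (choice `"A"`) at the first task is not
#' given further tasks; otherwise exactly five tasks are presented.
#'
#' @param presented_ranks Integer ranks (1--243) of the presented states, in
#'   presentation order.
#' @param presented_states State codes matching `presented_ranks`.
#' @param choices Character vector of `"A"` (prefer 10 years in the state)
#'   or `"B"` (prefer dying now), same length as `presented_ranks`.
#' @return An object of class `"dead_search"`.
#' @export
dead_search_record <- function(presented_ranks, presented_states, choices) {
  n <- length(presented_ranks)
  if (n < 1L || n > 5L) stop("between 1 and 5 tasks must be recorded", call. = FALSE)
  if (length(presented_states) != n || length(choices) != n) {
    stop("presented_ranks, presented_states and choices must have equal length",
         call. = FALSE)
  }
  if (!all(choices %in% c("A", "B"))) {
    stop("dead-search choices must be 'A' or 'B'", call. = FALSE)
  }
  if (presented_ranks[1L] != 243L || presented_states[1L] != "33333") {
    stop("the first dead-search task must present '33333' at rank 243", call. = FALSE)
  }
  if (n < 5L && !(n == 1L && choices[1L] == "A")) {
    stop("a dead search stops early only when the first choice is 'A'", call. = FALSE)
  }
  invisible(lapply(presented_states, parse_state))
  if (any(presented_ranks < 1L | presented_ranks > 243L)) {
    stop("presented ranks must lie in 1..243", call. = FALSE)
  }
  structure(list(presented_ranks = as.integer(presented_ranks),
                 presented_states = as.character(presented_states),
                 choices = as.character(choices)),
            class = "dead_search")
}

#' Section G interaction-task record
#'
#' @param task_index 1 or 2.
#' @param choice `"A"`, `"B"` or `"indifferent"` (ties are permitted here).
#' @return An object of class `"interaction_choice"`.
#' @export
interaction_choice <- function(task_index, choice) {
  stopifnot(task_index %in% 1:2)
  if (!choice %in% c("A", "B", "indifferent")) {
    stop("interaction choice must be 'A', 'B' or 'indifferent'", call. = FALSE)
  }
  structure(list(task_index = as.integer(task_index), choice = choice),
            class = "interaction_choice")
}

#' Assemble a respondent record
#'
#' Bundles one respondent's section A--G responses. Structural errors
#' (malformed codes, out-of-range ratings) are raised immediately; softer
#' protocol findings are reported by [validate_record()].
#'
#' @param respondent_id Unique identifier string.
#' @param ranking Section B: list of ordered, disjoint groups of dimension
#'   codes, most important first, e.g. `list("PD", c("MO","AD"), "SC", "UA")`.
#' @param swing Section C: five ratings in 0--100 (named by dimension or in
#'   fixed order); at least one must be positive.
#' @param allocation Section D: five point allocations in 0--100 for the
#'   intermediate (extreme to moderate) improvement of each dimension.
#' @param self_report Optional [self_report()] object.
#' @param pair_choices List of [pair_choice()] records (section E).
#' @param dead_search Optional [dead_search_record()] (section F).
#' @param interactions List of [interaction_choice()] records (section G).
#' @param used_default_tasks `TRUE` when the sections E/F tasks were
#'   generated from the interview tool's defaults (ratings of 100 and
#'   allocations of 50 on all dimensions) rather than from this respondent's
#'   section C/D answers.
#' @return An object of class `"respondent_record"`.
#' @export
respondent_record <- function(respondent_id, ranking, swing, allocation,
                              self_report = NULL, pair_choices = list(),
                              dead_search = NULL, interactions = list(),
                              used_default_tasks = FALSE) {
  if (!is.character(respondent_id) || length(respondent_id) != 1L ||
      is.na(respondent_id) || !nzchar(respondent_id)) {
    stop("respondent_id must be a non-empty string", call. = FALSE)
  }
  ranking <- check_ranking_groups(ranking)
  swing <- as_dimension_vector(swing, "swing ratings")
  if (all(swing == 0)) {
    stop("all swing ratings are zero; dimension weights are undefined", call. = FALSE)
  }
  allocation <- as_dimension_vector(allocation, "level allocations")
  if (!is.null(self_report)) stopifnot(inherits(self_report, "self_report"))
  stopifnot(all(vapply(pair_choices, inherits, logical(1), "pair_choice")))
  if (!is.null(dead_search)) stopifnot(inherits(dead_search, "dead_search"))
  stopifnot(all(vapply(interactions, inherits, logical(1), "interaction_choice")))
  structure(list(respondent_id = respondent_id,
                 self_report = self_report,
                 ranking = ranking,
                 swing = swing,
                 allocation = allocation,
                 pair_choices = pair_choices,
                 dead_search = dead_search,
                 interactions = interactions,
                 used_default_tasks = isTRUE(used_default_tasks)),
            class = "respondent_record")
}

#' @export
print.respondent_record <- function(x, ...) {
  cat("<respondent_record>", x$respondent_id, "\n")
  cat("  ranking:   ", format_ranking_string(x$ranking), "\n")
  cat("  swing:     ", paste(sprintf("%s=%g", PUF_DIMENSIONS, x$swing), collapse = " "), "\n")
  cat("  allocation:", paste(sprintf("%s=%g", PUF_DIMENSIONS, x$allocation), collapse = " "), "\n")
  cat("  sections:  ",
      if (is.null(x$self_report)) "" else "A",
      "BCD",
      if (length(x$pair_choices)) "E" else "",
      if (is.null(x$dead_search)) "" else "F",
      if (length(x$interactions)) "G" else "", "\n", sep = "")
  invisible(x)
}

# --- tie-aware rank statistics ----------------------------------------------

#' Numeric ranks from a tied ranking: averaging method
#'
#' Tied dimensions receive the arithmetic mean of the rank positions their
#' group occupies (so two dimensions tied at the top both get 1.5). Over the
#' five dimensions the ranks always sum to 15.
#'
#' @param ranking A list of ordered, disjoint groups of dimension codes,
#'   most important first (a subset of the dimensions is allowed, in which
#'   case ranks cover `1..n` for the `n` dimensions present).
#' @return A named numeric vector of ranks.
#' @seealso [ranks_eq()] for the shared-position variant.
#' @export
#' @examples
#' ranks_avg(list(c("MO", "SC"), "UA", "PD", "AD"))
ranks_avg <- function(ranking) {
  groups <- lapply(ranking, function(g) as.character(unlist(g)))
  sizes <- lengths(groups)
  starts <- cumsum(c(1L, sizes[-length(sizes)]))
  out <- numeric(0)
  for (i in seq_along(groups)) {
    r <- mean(seq(starts[i], length.out = sizes[i]))
    out[groups[[i]]] <- r
  }
  present <- PUF_DIMENSIONS[PUF_DIMENSIONS %in% names(out)]
  out[c(present, setdiff(names(out), present))]
}

#' Numeric ranks from a tied ranking: shared-position method
#'
#' Every member of a tied group receives the rank position at which the
#' group starts, and the following positions are skipped once per tie (so
#' two dimensions tied at the top both get 1 and the next dimension gets 3).
#'
#' @inheritParams ranks_avg
#' @return A named numeric vector of ranks.
#' @export
#' @examples
#' ranks_eq(list(c("MO", "SC"), "UA", "PD", "AD"))
ranks_eq <- function(ranking) {
  groups <- lapply(ranking, function(g) as.character(unlist(g)))
  sizes <- lengths(groups)
  starts <- cumsum(c(1L, sizes[-length(sizes)]))
  out <- numeric(0)
  for (i in seq_along(groups)) out[groups[[i]]] <- starts[i]
  present <- PUF_DIMENSIONS[PUF_DIMENSIONS %in% names(out)]
  out[c(present, setdiff(names(out), present))]
}

# --- record validation -------------------------------------------------------

finding <- function(severity, field, message) {
  data.frame(severity = severity, field = field, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a respondent record against the elicitation protocol
#'
#' Structural validity is enforced by the constructors; this function
#' reports softer findings as a data frame instead of raising errors. An
#' `"error"` finding marks a record that cannot enter PUF estimation (e.g.
#' all swing ratings zero in a hand-built list); `"warning"` findings flag
#' protocol deviations seen in practice, such as no dimension rated 100,
#' several dimensions rated 100, or a full five-way tie in the ranking.
#'
#' @param record A [respondent_record()] (or a bare list with the same
#'   fields).
#' @return A data frame with columns `severity`, `field`, `message`;
#'   zero rows for a fully conformant record.
#' @export
validate_record <- function(record) {
  out <- finding(character(0), character(0), character(0))
  swing <- record$swing
  if (all(swing == 0)) {
    out <- rbind(out, finding("error", "swing",
                              "all swing ratings are zero; weights undefined"))
  } else {
    if (max(swing) < 100) {
      out <- rbind(out, finding("warning", "swing", "no dimension rated 100"))
    }
    if (sum(swing == 100) > 1) {
      out <- rbind(out, finding("warning", "swing", "multiple dimensions rated 100"))
    }
  }
  if (length(record$ranking) == 1L) {
    out <- rbind(out, finding("warning", "ranking",
                              "all five dimensions tied in a single rank group"))
  }
  if (!is.null(record$dead_search)) {
    ds <- record$dead_search
    if (ds$presented_ranks[1L] != 243L) {
      out <- rbind(out, finding("error", "dead_search",
                                "first presented state must be rank 243 ('33333')"))
    }
  }
  if (length(record$pair_choices)) {
    idx <- vapply(record$pair_choices, function(p) p$task_index, integer(1))
    if (anyDuplicated(idx)) {
      out <- rbind(out, finding("warning", "pair_choices",
                                "duplicate section E task indices"))
    }
  }
  out
}
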