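# Aggregating individual PUFs into a social utility function (value set).

#' Summary statistics of utility decrements across respondents
#'
#' For each dimension and level (2 and 3), computes the minimum, first
#' quartile, median, mean, third quartile, maximum, standard deviation (n-1
#' denominator) and standard error of the respondents' decrements. Quartiles
#' use linear interpolation between order statistics (the spreadsheet
#' convention, `quantile(type = 7)`).
#'
#' @param pufs A non-empty list of `"puf"` or `"anchored_puf"` objects (a
#'   single fit is accepted). Anchored fits contribute their anchored
#'   decrements.
#' @return A data frame of class `"decrement_summary"` with columns
#'   `dimension`, `level`, `min`, `q1`, `median`, `mean`, `q3`, `max`, `sd`,
#'   `se`, and the number of contributing respondents in `attr(, "n")`.
#' @export
summarize_decrements <- function(pufs) {
  if (inherits(pufs, "puf")) pufs <- list(pufs)
  if (!length(pufs)) stop("no personal utility functions supplied", call. = FALSE)
  stopifnot(all(vapply(pufs, inherits, logical(1), "puf")))
  n <- length(pufs)
  rows <- expand.grid(level = c(2L, 3L), dimension = PUF_DIMENSIONS,
                      stringsAsFactors = FALSE)[, c("dimension", "level")]
  stats <- t(mapply(function(d, lev) {
    x <- vapply(pufs, function(p) p$decrements[d, as.character(lev)], numeric(1))
    q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
    s <- if (n > 1) sd(x) else 0
    c(min = min(x), q1 = q[1], median = q[2], mean = mean(x), q3 = q[3],
      max = max(x), sd = s, se = s / sqrt(n))
  }, rows$dimension, rows$level))
  out <- cbind(rows, as.data.frame(stats))
  rownames(out) <- NULL
  new_decrement_summary(out, n)
}

new_decrement_summary <- function(df, n) {
  stopifnot(all(c("dimension", "level", "min", "q1", "median", "mean",
                  "q3", "max", "sd", "se") %in% names(df)))
  attr(df, "n") <- as.integer(n)
  class(df) <- c("decrement_summary", "data.frame")
  df
}

# central decrements as a 5 x 3 matrix (level-1 column of zeros)
central_decrements <- function(summary, central) {
  dec <- cbind(`1` = rep(0, 5), `2` = rep(NA_real_, 5), `3` = rep(NA_real_, 5))
  rownames(dec) <- PUF_DIMENSIONS
  for (i in seq_len(nrow(summary))) {
    dec[summary$dimension[i], as.character(summary$level[i])] <-
      summary[[central]][i]
  }
  if (anyNA(dec)) stop("summary must cover levels 2 and 3 of all five dimensions",
                       call. = FALSE)
  dec
}

#' Build a social value set from aggregated decrements
#'
#' The social utility function (SUF) averages the individual PUFs; the
#' average may be the mean or the median of the respondents' decrements.
#' Every state is valued as 1 minus the sum of the chosen central decrements
#' for its levels, so the value set inherits monotonicity in dominance from
#' the decrements' non-negativity.
#'
#' @param x A `"decrement_summary"` (e.g. from [summarize_decrements()] or
#'   [pilot_table()]) or a list of (anchored) `"puf"` objects, which is
#'   summarised first.
#' @param central `"mean"` or `"median"`.
#' @return An object of class `"value_set"`: a list with the `summary`, the
#'   chosen `central` measure, the central `decrements` matrix and `values`,
#'   a named vector over all 243 state codes.
#' @export
#' @examples
#' vs <- value_set(pilot_table("table9"), central = "mean")
#' round(vs$values[c("11112", "33333")], 3)
value_set <- function(x, central = c("mean", "median")) {
  central <- match.arg(central)
  summary <- if (inherits(x, "decrement_summary")) x else summarize_decrements(x)
  dec <- central_decrements(summary, central)
  carrier <- structure(list(decrements = dec), class = "puf")
  values <- predict.puf(carrier)
  structure(list(summary = summary, central = central,
                 decrements = dec, values = values),
            class = "value_set")
}

#' @export
print.value_set <- function(x, digits = 4, ...) {
  n <- attr(x$summary, "n")
  cat("<value_set> central measure:", x$central,
      if (!is.null(n)) sprintf(" (n = %d respondents)", n) else "", "\n")
  cat("  value range:",
      sprintf("%.4f ('%s') to %.4f ('11111')",
              min(x$values), names(x$values)[which.min(x$values)],
              max(x$values)), "\n")
  nf <- x$values[names(x$values) != "11111"]
  cat("  highest non-full-health value:",
      sprintf("%.4f ('%s')", max(nf), names(nf)[which.max(nf)]), "\n")
  cat("  central decrements:\n")
  print(round(x$decrements[, c("2", "3")], digits))
  invisible(x)
}

#' @export
predict.value_set <- function(object, states = enumerate_states(), ...) {
  m <- state_levels(states)  # validates
  object$values[rownames(m)]
}

#' @export
as.data.frame.value_set <- function(x, ...) {
  data.frame(state = names(x$values), value = unname(x$values),
             stringsAsFactors = FALSE)
}

#' Run the full estimation pipeline over a study
#'
#' For each respondent: fit the PUF from sections C/D, rank the 243 states,
#' reconstruct the section F bracket, locate dead, anchor, then aggregate
#' the anchored decrements into a value set. Respondents whose tasks were
#' generated from the tool's defaults (`used_default_tasks`) are dropped by
#' default, since their section F answers do not refer to their own state
#' ranking; respondents without a section F record cannot be anchored and
#' are skipped with a warning.
#'
#' @param study A `"puf_study"` (from [read_study()] or
#'   [simulate_cohort()]), or a bare list of [respondent_record()]s.
#' @param central `"mean"` or `"median"`.
#' @param level2_mapping Level-2 decrement convention, see
#'   [level_decrements()]; defaults to the study metadata, else
#'   `"share_of_swing"`.
#' @param outlier_threshold Passed to [filter_outliers()].
#' @param include_unrescaled Keep respondents for whom no state is worse
#'   than dead, with their unrescaled 0-1 values (default); `FALSE` drops
#'   them from the aggregation.
#' @param include_default_tasks Keep `used_default_tasks` respondents.
#' @return A list with `value_set`, `anchored` (named list of kept
#'   anchored PUFs), `excluded` (outliers), `dropped` (respondent ids not
#'   used) and `n_used`.
#' @export
estimate_value_set <- function(study, central = c("mean", "median"),
                               level2_mapping = NULL,
                               outlier_threshold = -10,
                               include_unrescaled = TRUE,
                               include_default_tasks = FALSE) {
  central <- match.arg(central)
  respondents <- if (inherits(study, "puf_study")) study$respondents else study
  if (is.null(level2_mapping)) {
    level2_mapping <- if (inherits(study, "puf_study") &&
                          !is.null(study$metadata$level2_mapping)) {
      study$metadata$level2_mapping
    } else "share_of_swing"
  }
  anchored <- list()
  dropped <- character(0)
  for (r in respondents) {
    if (r$used_default_tasks && !include_default_tasks) {
      dropped <- c(dropped, r$respondent_id)
      next
    }
    if (is.null(r$dead_search)) {
      warning("respondent ", r$respondent_id,
              " has no section F record and cannot be anchored; skipped",
              call. = FALSE)
      dropped <- c(dropped, r$respondent_id)
      next
    }
    fit <- puf(r$swing, r$allocation, level2_mapping)
    ranking <- rank_states(fit)
    bracket <- bracket_from_record(r$dead_search)
    u_dead <- dead_utility(fit, bracket, ranking)
    anchored[[r$respondent_id]] <- anchor_puf(fit, u_dead)
  }
  flt <- filter_outliers(anchored, outlier_threshold)
  kept <- flt$kept
  if (!include_unrescaled) {
    kept <- Filter(function(a) a$status == "rescaled", kept)
  }
  if (!length(kept)) stop("no respondents left to aggregate", call. = FALSE)
  list(value_set = value_set(kept, central),
       anchored = kept,
       excluded = flt$excluded,
       dropped = dropped,
       n_used = length(kept))
}
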