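# Anchoring a 0-1 PUF at dead = 0 using the section F bracket.

#' Utility of dead on a respondent's 0-1 scale
#'
#' The location of dead is taken as the midpoint between the utilities of
#' the two states bracketing it. For a respondent who always preferred dying
#' now (`above_mildest`), dead is assumed to lie between full health and the
#' mildest state presented, so the midpoint uses utility 1 as the better
#' bound. For a respondent for whom no state is worse than dead
#' (`below_33333`), no dead utility exists on the 0-1 scale and `NA` is
#' returned.
#'
#' @param x The respondent's `"puf"`.
#' @param bracket A `"dead_bracket"` from [run_dead_search()] or
#'   [bracket_from_record()].
#' @param ranking The respondent's [rank_states()] ranking; recomputed from
#'   `x` by default.
#' @return A single utility value, or `NA` for `below_33333`.
#' @export
dead_utility <- function(x, bracket, ranking = rank_states(x)) {
  stopifnot(inherits(x, "puf"), inherits(bracket, "dead_bracket"),
            inherits(ranking, "state_ranking"))
  n <- nrow(ranking)
  u_at <- function(rank) {
    if (is.na(rank) || rank < 1L || rank > n) {
      stop("bracket rank inconsistent with the supplied ranking", call. = FALSE)
    }
    ranking$utility[rank]
  }
  switch(bracket$classification,
         below_33333 = NA_real_,
         bracketed = {
           if (!(bracket$lower_rank < bracket$upper_rank)) {
             stop("bracketed bounds must satisfy lower_rank < upper_rank", call. = FALSE)
           }
           (u_at(bracket$lower_rank) + u_at(bracket$upper_rank)) / 2
         },
         above_mildest = (1 + u_at(bracket$upper_rank)) / 2,
         stop("unknown bracket classification: ", bracket$classification,
              call. = FALSE))
}

#' Anchor a PUF at dead = 0
#'
#' Rescales a 0-1 personal utility function so that the located dead
#' midpoint maps to 0 while full health stays at 1:
#' `value(s) = (u(s) - u_dead) / (1 - u_dead)`, equivalently each decrement
#' is divided by `1 - u_dead`. States below the dead midpoint then take
#' negative values. When `dead_utility` is `NA` (dead below `"33333"`), the
#' values pass through unchanged and the result is flagged
#' `unrescaled_dead_below_33333` — equivalent to conservatively anchoring
#' dead at `"33333"`.
#'
#' @param x A `"puf"` object.
#' @param dead_utility The dead midpoint on the 0-1 scale (strictly below
#'   1), or `NA`.
#' @return An object of class `c("anchored_puf", "puf")` with the rescaled
#'   `decrements`, the original fit in `$source`, plus `$dead_utility` and
#'   `$status` (`"rescaled"` or `"unrescaled_dead_below_33333"`).
#' @export
#' @examples
#' a <- anchor_puf(default_puf(), dead_utility = 0.5)
#' predict(a, c("11111", "33333"))
anchor_puf <- function(x, dead_utility) {
  stopifnot(inherits(x, "puf"))
  if (inherits(x, "anchored_puf")) stop("PUF is already anchored", call. = FALSE)
  out <- x
  if (is.null(dead_utility) || is.na(dead_utility)) {
    out$dead_utility <- NA_real_
    out$status <- "unrescaled_dead_below_33333"
  } else {
    if (!is.numeric(dead_utility) || length(dead_utility) != 1L) {
      stop("dead_utility must be a single number or NA", call. = FALSE)
    }
    if (dead_utility >= 1) {
      stop("dead_utility must be strictly below 1 (full health)", call. = FALSE)
    }
    out$decrements <- x$decrements / (1 - dead_utility)
    out$dead_utility <- dead_utility
    out$status <- "rescaled"
  }
  out$source <- x
  class(out) <- c("anchored_puf", "puf")
  out
}

#' Exclude extreme anchored PUFs
#'
#' The anchoring arithmetic can produce implausibly extreme value functions
#' when a respondent locates dead very close to full health (the rescaling
#' divides by `1 - u_dead`). This rule makes the exclusion explicit and
#' reproducible: any anchored PUF whose value of `"33333"` falls below
#' `threshold` is moved to the excluded set with status
#' `"excluded_outlier"`.
#'
#' @param anchored A list of `"anchored_puf"` objects.
#' @param threshold Negative cutoff on the anchored value of `"33333"`
#'   (default -10).
#' @return A list with components `kept` and `excluded`.
#' @export
filter_outliers <- function(anchored, threshold = -10) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  if (threshold >= 0) stop("threshold must be negative", call. = FALSE)
  stopifnot(all(vapply(anchored, inherits, logical(1), "anchored_puf")))
  worst <- vapply(anchored, function(a) unname(predict(a, "33333")), numeric(1))
  out <- anchored[worst >= threshold]
  excluded <- lapply(anchored[worst < threshold], function(a) {
    a$status <- "excluded_outlier"
    a
  })
  list(kept = out, excluded = excluded)
}
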