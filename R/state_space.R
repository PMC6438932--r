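# The descriptive system: five EQ-5D dimensions, three severity levels each
# (1 = no problems, 2 = moderate problems, 3 = extreme problems), giving a
# 3^5 = 243 state space. States are coded as 5-character digit strings in the
# fixed dimension order MO, SC, UA, PD, AD (e.g. "21312").

PUF_DIMENSIONS <- c("MO", "SC", "UA", "PD", "AD")

PUF_DIMENSION_LABELS <- c(
  MO = "Mobility",
  SC = "Self-care",
  UA = "Usual activities",
  PD = "Pain/discomfort",
  AD = "Anxiety/depression"
)

#' The five health dimensions in their fixed order
#'
#' Returns the dimension codes of the descriptive system in the order used
#' throughout the package (and in all state code strings): MO (mobility),
#' SC (self-care), UA (usual activities), PD (pain/discomfort),
#' AD (anxiety/depression).
#'
#' @param labels If `TRUE`, return the long labels named by code instead of
#'   the bare codes.
#' @return A character vector of length five.
#' @export
#' @examples
#' puf_dimensions()
puf_dimensions <- function(labels = FALSE) {
  if (labels) PUF_DIMENSION_LABELS else PUF_DIMENSIONS
}

#' Parse a 5-character health-state code
#'
#' A state code is a string of five digits, each in 1--3, giving the severity
#' level on each dimension in the fixed order MO, SC, UA, PD, AD. `"11111"`
#' is full health and `"33333"` the worst describable state.
#'
#' @param code A single 5-character string, e.g. `"31112"`.
#' @return A named integer vector of levels (names `MO`, `SC`, `UA`, `PD`,
#'   `AD`).
#' @seealso [format_state()] for the inverse.
#' @export
#' @examples
#' parse_state("31112")
parse_state <- function(code) {
  if (!is.character(code) || length(code) != 1L || is.na(code)) {
    stop("state code must be a single character string", call. = FALSE)
  }
  if (nchar(code) != 5L) {
    stop(sprintf("state code '%s' must have 5 characters, got %d",
                 code, nchar(code)), call. = FALSE)
  }
  digits <- strsplit(code, "", fixed = TRUE)[[1L]]
  bad <- which(!digits %in% c("1", "2", "3"))
  if (length(bad)) {
    stop(sprintf("state code '%s': invalid level '%s' at position %d (dimension %s)",
                 code, digits[bad[1L]], bad[1L], PUF_DIMENSIONS[bad[1L]]),
         call. = FALSE)
  }
  setNames(as.integer(digits), PUF_DIMENSIONS)
}

#' Format levels as a health-state code
#'
#' @param levels An integer vector of five levels in 1--3 (named or in the
#'   fixed dimension order).
#' @return A 5-character state code.
#' @export
#' @examples
#' format_state(c(MO = 3, SC = 1, UA = 1, PD = 1, AD = 2))
format_state <- function(levels) {
  if (length(levels) != 5L || any(is.na(levels)) || !all(levels %in% 1:3)) {
    stop("levels must be five integers in 1..3", call. = FALSE)
  }
  if (!is.null(names(levels))) {
    if (!setequal(names(levels), PUF_DIMENSIONS)) {
      stop("named levels must use dimension names ",
           paste(PUF_DIMENSIONS, collapse = ", "), call. = FALSE)
    }
    levels <- levels[PUF_DIMENSIONS]
  }
  paste(as.integer(levels), collapse = "")
}

#' Level matrix for a vector of state codes
#'
#' Vectorised companion to [parse_state()]: one row per code, one column per
#' dimension.
#'
#' @param codes Character vector of 5-character state codes.
#' @return An integer matrix with `length(codes)` rows and columns
#'   `MO, SC, UA, PD, AD`; row names are the codes.
#' @export
state_levels <- function(codes) {
  if (!is.character(codes)) stop("codes must be a character vector", call. = FALSE)
  ok <- !is.na(codes) & grepl("^[123]{5}$", codes)
  if (!all(ok)) {
    stop(sprintf("malformed state code '%s' at position %d",
                 codes[which(!ok)[1L]], which(!ok)[1L]), call. = FALSE)
  }
  m <- matrix(as.integer(unlist(strsplit(codes, "", fixed = TRUE), use.names = FALSE)),
              ncol = 5L, byrow = TRUE)
  colnames(m) <- PUF_DIMENSIONS
  rownames(m) <- codes
  m
}

#' Enumerate all 243 health states
#'
#' All 3^5 = 243 states of the descriptive system, in lexicographic code
#' order (so `"11111"` is first and `"33333"` last).
#'
#' @return A character vector of 243 state codes.
#' @export
#' @examples
#' length(enumerate_states())
enumerate_states <- function() {
  g <- expand.grid(AD = 1:3, PD = 1:3, UA = 1:3, SC = 1:3, MO = 1:3)
  paste0(g$MO, g$SC, g$UA, g$PD, g$AD)
}

#' Level sum score of health states
#'
#' Sum of the five dimension levels, a crude proxy for severity; ranges from
#' 5 (`"11111"`) to 15 (`"33333"`).
#'
#' @param codes Character vector of state codes.
#' @return Integer vector of level sums.
#' @export
#' @examples
#' level_sum_score(c("11111", "31112", "33333"))
level_sum_score <- function(codes) {
  as.integer(rowSums(state_levels(codes)))
}

#' Dominance between two health states
#'
#' State `a` dominates state `b` when `a` is at least as good (level less
#' than or equal) on every dimension and strictly better on at least one.
#' Dominance is a strict partial order; non-dominating pairs are
#' "incomparable" and are the only pairs eligible for the validation choice
#' tasks.
#'
#' @param a,b State codes (or named level vectors as from [parse_state()]).
#' @return `TRUE` iff `a` dominates `b`.
#' @export
#' @examples
#' dominates("11111", "21111")  # TRUE
#' dominates("21111", "11121")  # FALSE: incomparable
dominates <- function(a, b) {
  la <- if (is.character(a)) parse_state(a) else a
  lb <- if (is.character(b)) parse_state(b) else b
  all(la <= lb) && any(la < lb)
}
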