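# Study files: JSON is the canonical format (nested records); a flat CSV
# export/import is provided for spreadsheet work. Conventions in force
# (level-2 mapping, duration framing, seed) are carried in the metadata so
# every value set is reproducible from its inputs.

#' Bundle respondent records into a study
#'
#' @param respondents A list of [respondent_record()]s with unique ids.
#' @param metadata A named list; typically `study_id`, `duration_years`
#'   (the life-duration framing of the section F tasks, metadata only — it
#'   does not enter the arithmetic) and `level2_mapping`.
#' @return An object of class `"puf_study"`.
#' @export
new_study <- function(respondents = list(), metadata = list()) {
  stopifnot(all(vapply(respondents, inherits, logical(1), "respondent_record")))
  ids <- vapply(respondents, function(r) r$respondent_id, character(1))
  if (anyDuplicated(ids)) {
    stop("respondent ids must be unique within a study (duplicate: ",
         ids[duplicated(ids)][1L], ")", call. = FALSE)
  }
  if (!length(respondents)) {
    warning("study contains no respondents", call. = FALSE)
  }
  structure(list(metadata = metadata, respondents = respondents),
            class = "puf_study")
}

#' @export
print.puf_study <- function(x, ...) {
  cat("<puf_study>", if (!is.null(x$metadata$study_id)) x$metadata$study_id else "",
      "-", length(x$respondents), "respondents\n")
  invisible(x)
}

# --- ranking group serialization ----------------------------------------------

#' Serialize / parse ranking groups
#'
#' The flat string form joins tied dimensions with `","` and separates rank
#' groups (most important first) with `">"`, e.g. `"PD>MO,AD>SC>UA"`.
#'
#' @param ranking A list of ranking groups.
#' @return `format_ranking_string()`: a single string;
#'   `parse_ranking_string()`: a list of character vectors.
#' @export
format_ranking_string <- function(ranking) {
  paste(vapply(ranking, function(g) paste(unlist(g), collapse = ","), character(1)),
        collapse = ">")
}

#' @rdname format_ranking_string
#' @param x A ranking string such as `"PD>MO,AD>SC>UA"`.
#' @export
parse_ranking_string <- function(x) {
  groups <- lapply(strsplit(x, ">", fixed = TRUE)[[1L]],
                   function(g) strsplit(g, ",", fixed = TRUE)[[1L]])
  check_ranking_groups(groups)
}

# --- JSON ---------------------------------------------------------------------

record_to_list <- function(r) {
  out <- list(respondent_id = r$respondent_id)
  if (!is.null(r$self_report)) {
    out$self_report <- unclass(r$self_report)
  }
  out$ranking <- lapply(r$ranking, I)
  out$swing <- as.list(r$swing)
  out$allocation <- as.list(r$allocation)
  if (length(r$pair_choices)) {
    out$pair_choices <- lapply(r$pair_choices, unclass)
  }
  if (!is.null(r$dead_search)) {
    out$dead_search <- list(presented_ranks = I(r$dead_search$presented_ranks),
                            presented_states = I(r$dead_search$presented_states),
                            choices = I(r$dead_search$choices))
  }
  if (length(r$interactions)) {
    out$interactions <- lapply(r$interactions, unclass)
  }
  out$used_default_tasks <- r$used_default_tasks
  out
}

record_from_list <- function(x) {
  sr <- if (!is.null(x$self_report)) {
    do.call(self_report, x$self_report)
  }
  pcs <- lapply(x$pair_choices, function(p) {
    pair_choice(p$task_index, p$option_a, p$option_b, p$choice)
  })
  ds <- if (!is.null(x$dead_search)) {
    dead_search_record(unlist(x$dead_search$presented_ranks),
                       unlist(x$dead_search$presented_states),
                       unlist(x$dead_search$choices))
  }
  ics <- lapply(x$interactions, function(ic) {
    interaction_choice(ic$task_index, ic$choice)
  })
  respondent_record(respondent_id = x$respondent_id,
                    ranking = lapply(x$ranking, unlist),
                    swing = unlist(x$swing),
                    allocation = unlist(x$allocation),
                    self_report = sr,
                    pair_choices = pcs,
                    dead_search = ds,
                    interactions = ics,
                    used_default_tasks = isTRUE(x$used_default_tasks))
}

#' Write / read a study file (JSON)
#'
#' The JSON layout mirrors the record structure: a `metadata` object and a
#' `respondents` array, with ranking groups as arrays of arrays, state codes
#' as 5-character strings and the dead search as parallel arrays of
#' presented ranks, states and choices. Reading validates every record and
#' reports schema violations with the offending respondent's id.
#'
#' @param study A `"puf_study"`.
#' @param path File path.
#' @return `read_study()` returns a `"puf_study"`; `write_study()` returns
#'   `path` invisibly.
#' @export
write_study <- function(study, path) {
  stopifnot(inherits(study, "puf_study"))
  obj <- list(metadata = study$metadata,
              respondents = lapply(study$respondents, record_to_list))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_study
#' @export
read_study <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop("cannot parse study file '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  respondents <- lapply(obj$respondents, function(x) {
    tryCatch(record_from_list(x),
             error = function(e) {
               stop("invalid record for respondent '",
                    if (is.null(x$respondent_id)) "<missing id>" else x$respondent_id,
                    "': ", conditionMessage(e), call. = FALSE)
             })
  })
  new_study(respondents, metadata = lapply(obj$metadata, function(m) m))
}

# --- flat CSV -----------------------------------------------------------------

#' Write / read a study as a flat CSV
#'
#' One row per respondent. Ranking groups are serialised with
#' [format_ranking_string()]; the dead search becomes three `";"`-joined
#' columns; the two section E pairs and two section G choices get fixed
#' columns. Missing sections are empty cells. Study metadata is not carried
#' by the CSV form — pass it back through `metadata` when reading.
#'
#' @inheritParams write_study
#' @param metadata Metadata list attached to the study on reading.
#' @return `read_study_csv()` returns a `"puf_study"`; `write_study_csv()`
#'   returns `path` invisibly.
#' @export
write_study_csv <- function(study, path) {
  stopifnot(inherits(study, "puf_study"))
  rows <- lapply(study$respondents, function(r) {
    row <- list(respondent_id = r$respondent_id,
                ranking = format_ranking_string(r$ranking))
    sr <- r$self_report
    row$current_profile <- if (is.null(sr)) NA else sr$current_profile
    row$current_vas <- if (is.null(sr)) NA else sr$current_vas
    row$worst_profile <- if (is.null(sr)) NA else sr$worst_profile
    row$worst_vas <- if (is.null(sr)) NA else sr$worst_vas
    for (d in PUF_DIMENSIONS) row[[paste0("swing_", d)]] <- unname(r$swing[d])
    for (d in PUF_DIMENSIONS) row[[paste0("alloc_", d)]] <- unname(r$allocation[d])
    for (t in 1:2) {
      hit <- Filter(function(p) p$task_index == t, r$pair_choices)
      row[[paste0("pair", t, "_a")]] <- if (length(hit)) hit[[1]]$option_a else NA
      row[[paste0("pair", t, "_b")]] <- if (length(hit)) hit[[1]]$option_b else NA
      row[[paste0("pair", t, "_choice")]] <- if (length(hit)) hit[[1]]$choice else NA
    }
    ds <- r$dead_search
    row$dead_ranks <- if (is.null(ds)) NA else paste(ds$presented_ranks, collapse = ";")
    row$dead_states <- if (is.null(ds)) NA else paste(ds$presented_states, collapse = ";")
    row$dead_choices <- if (is.null(ds)) NA else paste(ds$choices, collapse = "")
    for (t in 1:2) {
      hit <- Filter(function(ic) ic$task_index == t, r$interactions)
      row[[paste0("g", t, "_choice")]] <- if (length(hit)) hit[[1]]$choice else NA
    }
    row$used_default_tasks <- r$used_default_tasks
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_study_csv
#' @export
read_study_csv <- function(path, metadata = list()) {
  df <- read.csv(path, colClasses = "character", na.strings = "")
  num <- function(x) if (is.na(x)) NA_real_ else as.numeric(x)
  respondents <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    sr <- if (!is.na(row$current_profile)) {
      self_report(row$current_profile, num(row$current_vas),
                  row$worst_profile, num(row$worst_vas))
    }
    pcs <- list()
    for (t in 1:2) {
      a <- row[[paste0("pair", t, "_a")]]
      if (!is.na(a)) {
        pcs <- c(pcs, list(pair_choice(t, a, row[[paste0("pair", t, "_b")]],
                                       row[[paste0("pair", t, "_choice")]])))
      }
    }
    ds <- if (!is.na(row$dead_ranks)) {
      dead_search_record(
        as.integer(strsplit(row$dead_ranks, ";", fixed = TRUE)[[1L]]),
        strsplit(row$dead_states, ";", fixed = TRUE)[[1L]],
        strsplit(row$dead_choices, "", fixed = TRUE)[[1L]])
    }
    ics <- list()
    for (t in 1:2) {
      ch <- row[[paste0("g", t, "_choice")]]
      if (!is.na(ch)) ics <- c(ics, list(interaction_choice(t, ch)))
    }
    tryCatch(
      respondent_record(
        respondent_id = row$respondent_id,
        ranking = parse_ranking_string(row$ranking),
        swing = vapply(paste0("swing_", PUF_DIMENSIONS), function(cn) num(row[[cn]]),
                       numeric(1), USE.NAMES = FALSE),
        allocation = vapply(paste0("alloc_", PUF_DIMENSIONS), function(cn) num(row[[cn]]),
                            numeric(1), USE.NAMES = FALSE),
        self_report = sr, pair_choices = pcs, dead_search = ds,
        interactions = ics,
        used_default_tasks = tolower(row$used_default_tasks) %in% c("true", "1")),
      error = function(e) {
        stop("invalid record for respondent '", row$respondent_id, "': ",
             conditionMessage(e), call. = FALSE)
      })
  })
  new_study(respondents, metadata = metadata)
}

#' Export a value set as CSV
#'
#' Writes the 243 `(state, value)` rows; with `summary_path`, also writes
#' the decrement summary table (min, quartiles, mean, max, sd, se per
#' dimension and level).
#'
#' @param vs A `"value_set"`.
#' @param path Destination for the state values.
#' @param summary_path Optional destination for the summary table.
#' @return `path`, invisibly.
#' @export
write_value_set_csv <- function(vs, path, summary_path = NULL) {
  stopifnot(inherits(vs, "value_set"))
  write.csv(as.data.frame(vs), path, row.names = FALSE)
  if (!is.null(summary_path)) {
    write.csv(as.data.frame(unclass(vs$summary)), summary_path, row.names = FALSE)
  }
  invisible(path)
}

#' Export anchored PUF state values as a long CSV
#'
#' One row per respondent and state: `respondent_id`, `status`, `state`,
#' `value`.
#'
#' @param anchored A named list of `"anchored_puf"` objects (names are
#'   respondent ids).
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_anchored_csv <- function(anchored, path) {
  states <- enumerate_states()
  rows <- lapply(names(anchored), function(id) {
    a <- anchored[[id]]
    data.frame(respondent_id = id, status = a$status, state = states,
               value = unname(predict(a, states)), stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
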