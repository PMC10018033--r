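#' Forced-choice trial tables
#'
#' A trial table is a tibble of two-interval forced-choice observations in
#' binomial form: one row per (subject, stimulus, condition, group) cell with
#' the number of "faster" (comparison-chosen) responses and the number of
#' trials. Per-trial binary data are represented with `trials = 1` rows and
#' collapsed with [aggregate_binomial()].
#'
#' @param data A data frame with columns `subject`, `stimulus`, `condition`,
#'   `successes`, `trials` and optionally `group`.
#' @param study Optional study label stored as metadata.
#' @param reference Optional reference stimulus value (same units as
#'   `stimulus`), e.g. the standard speed of the discrimination task.
#' @param units Stimulus units label (default `"cm/s"`).
#'
#' @return A tibble of class `psy_trials` with metadata attributes
#'   `study`, `reference` and `units`.
#' @export
#' @examples
#' psy_trials(data.frame(
#'   subject = "S1", stimulus = c(1, 2), condition = "vib0",
#'   successes = c(2, 9), trials = 10
#' ), reference = 1.5)
psy_trials <- function(data, study = NA_character_, reference = NA_real_,
                       units = "cm/s") {
  stopifnot(is.data.frame(data))
  required <- c("subject", "stimulus", "condition", "successes", "trials")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop(sprintf("%s column not found", missing_cols[1]), call. = FALSE)
  }
  out <- tibble::as_tibble(data)
  if (!"group" %in% names(out)) out$group <- "all"
  out$group <- as.character(out$group)
  out$group[is.na(out$group)] <- "all"
  out$subject <- as.character(out$subject)
  out$condition <- as.character(out$condition)
  if (!is.numeric(out$stimulus)) {
    stop("stimulus values could not be parsed as numbers", call. = FALSE)
  }
  out$stimulus <- as.numeric(out$stimulus)
  out$successes <- as.integer(out$successes)
  out$trials <- as.integer(out$trials)
  out <- out[, c("subject", "stimulus", "condition", "group",
                 "successes", "trials")]

  bad <- which(out$successes > out$trials)
  if (length(bad) > 0) {
    stop(sprintf("successes exceed trials in row %d", bad[1]), call. = FALSE)
  }
  if (any(!is.finite(out$stimulus))) {
    stop("stimulus values must be finite", call. = FALSE)
  }
  if (any(out$trials < 1L)) stop("trials must be >= 1", call. = FALSE)
  if (any(out$successes < 0L)) stop("successes must be >= 0", call. = FALSE)
  grp_per_subj <- tapply(out$group, out$subject, function(g) length(unique(g)))
  if (any(grp_per_subj > 1)) {
    stop(sprintf("subject %s appears in more than one group",
                 names(grp_per_subj)[which(grp_per_subj > 1)[1]]),
         call. = FALSE)
  }

  attr(out, "study") <- study
  attr(out, "reference") <- reference
  attr(out, "units") <- units
  class(out) <- c("psy_trials", class(out))
  out
}

trials_meta <- function(table) {
  list(study = attr(table, "study") %||% NA_character_,
       reference = attr(table, "reference") %||% NA_real_,
       units = attr(table, "units") %||% "cm/s")
}

restore_trials <- function(df, meta) {
  psy_trials(df, study = meta$study, reference = meta$reference,
             units = meta$units)
}

#' Read a forced-choice trial table from CSV
#'
#' Reads long-format forced-choice data. Two dialects are accepted and
#' distinguished by the schema: per-trial files carry a binary `response`
#' column (one row per trial), aggregated files carry `successes`/`trials`
#' counts. Per-trial rows are kept as `trials = 1` cells; collapse them with
#' [aggregate_binomial()].
#'
#' @param path Path to a CSV file with a header row.
#' @param schema Named list or character vector mapping canonical column names
#'   (`subject`, `stimulus`, `condition`, `group`, `response` or
#'   `successes`/`trials`) to the column names used in the file. Canonical
#'   names are assumed for entries not listed.
#' @inheritParams psy_trials
#'
#' @return A [psy_trials] tibble.
#' @export
read_trials <- function(path, schema = list(), study = NA_character_,
                        reference = NA_real_, units = "cm/s") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  schema <- as.list(schema)

  col_for <- function(canonical) {
    nm <- schema[[canonical]] %||% canonical
    if (nm %in% names(raw)) nm else NA_character_
  }

  need <- function(canonical) {
    nm <- col_for(canonical)
    if (is.na(nm)) {
      stop(sprintf("%s column not found", canonical), call. = FALSE)
    }
    raw[[nm]]
  }

  df <- tibble::tibble(
    subject = as.character(need("subject")),
    stimulus = need("stimulus"),
    condition = as.character(need("condition"))
  )
  if (!is.numeric(df$stimulus)) {
    suppressWarnings(conv <- as.numeric(df$stimulus))
    if (any(is.na(conv) & !is.na(df$stimulus))) {
      stop("stimulus values could not be parsed as numbers", call. = FALSE)
    }
    df$stimulus <- conv
  }
  grp_col <- col_for("group")
  if (!is.na(grp_col)) df$group <- as.character(raw[[grp_col]])

  resp_col <- col_for("response")
  succ_col <- col_for("successes")
  if (!is.na(succ_col)) {
    df$successes <- need("successes")
    df$trials <- need("trials")
  } else if (!is.na(resp_col)) {
    resp <- raw[[resp_col]]
    if (!all(resp %in% c(0, 1))) {
      stop("response column must be binary (0/1)", call. = FALSE)
    }
    df$successes <- as.integer(resp)
    df$trials <- 1L
  } else {
    stop("successes column not found (nor a per-trial response column)",
         call. = FALSE)
  }

  psy_trials(df, study = study, reference = reference, units = units)
}

#' Collapse a trial table to one binomial cell per design point
#'
#' Sums successes and trials over duplicate (subject, stimulus, condition,
#' group) rows, turning per-trial Bernoulli rows into binomial counts.
#' Idempotent; total successes and trials are conserved exactly.
#'
#' @param table A [psy_trials] tibble.
#' @return A [psy_trials] tibble with unique cells.
#' @export
aggregate_binomial <- function(table) {
  meta <- trials_meta(table)
  out <- table |>
    dplyr::group_by(.data$subject, .data$stimulus, .data$condition,
                    .data$group) |>
    dplyr::summarise(successes = sum(.data$successes),
                     trials = sum(.data$trials), .groups = "drop") |>
    dplyr::arrange(.data$group, .data$subject, .data$condition, .data$stimulus)
  restore_trials(out, meta)
}

#' Validate a trial table and report problems
#'
#' Report-only checks: impossible counts, duplicate (aggregatable) cells, and
#' subjects observed at a single stimulus level, for whom a slope cannot be
#' identified.
#'
#' @param table A data frame shaped like a [psy_trials] table.
#' @return A tibble with columns `type`, `row` (first offending row or `NA`)
#'   and `message`; zero rows when the table is clean.
#' @export
validate_trials <- function(table) {
  viol <- list()
  add <- function(type, row, message) {
    viol[[length(viol) + 1]] <<- tibble::tibble(
      type = type, row = as.integer(row), message = message)
  }
  if (!"group" %in% names(table)) table$group <- "all"

  bad <- which(table$successes > table$trials)
  for (r in bad) {
    add("successes_exceed_trials", r,
        sprintf("row %d: successes (%d) > trials (%d)",
                r, table$successes[r], table$trials[r]))
  }
  empty <- which(table$trials < 1)
  for (r in empty) add("empty_cell", r, sprintf("row %d: trials < 1", r))

  key <- paste(table$subject, table$stimulus, table$condition, table$group,
               sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    add("duplicate_cells", dup[1],
        sprintf("%d duplicate cells; aggregatable with aggregate_binomial()",
                length(dup)))
  }
  n_levels <- tapply(table$stimulus, table$subject,
                     function(x) length(unique(x)))
  for (s in names(n_levels)[n_levels < 2]) {
    add("slope_unidentifiable", NA,
        sprintf("slope unidentifiable for subject %s (single stimulus level)",
                s))
  }
  if (length(viol) == 0) {
    return(tibble::tibble(type = character(), row = integer(),
                          message = character()))
  }
  dplyr::bind_rows(viol)
}

#' Write a trial table to CSV
#'
#' Writes the canonical long-format CSV (subject, stimulus, condition, group,
#' successes, trials). Stimulus values are written at full precision so that
#' [read_trials()] round-trips the table.
#'
#' @param table A [psy_trials] tibble.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trials <- function(table, path) {
  df <- as.data.frame(table)[, c("subject", "stimulus", "condition", "group",
                                 "successes", "trials")]
  readr::write_csv(df, path)
  invisible(path)
}
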