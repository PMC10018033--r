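# Synthetic forced-choice data from the generative hierarchy.

#' Experimental design specification
#'
#' @param n_subjects Subjects per group.
#' @param stimulus_levels Numeric vector of comparison stimulus values (at
#'   least two, otherwise slopes are unidentifiable).
#' @param repetitions Trials per (stimulus, condition) cell.
#' @param conditions Condition labels (e.g. masking vibration off/on).
#' @param groups Group labels.
#' @param reference Reference stimulus value, if the task has one.
#' @param units Stimulus units.
#' @return A list of class `psy_design`.
#' @export
design_spec <- function(n_subjects, stimulus_levels, repetitions,
                        conditions = c("vib0", "vib1"), groups = "all",
                        reference = NA_real_, units = "cm/s") {
  stopifnot(n_subjects >= 1, repetitions >= 1,
            length(conditions) >= 1, length(groups) >= 1)
  if (length(unique(stimulus_levels)) < 2) {
    stop("at least two stimulus levels are required (slope unidentifiable)",
         call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 stimulus_levels = as.numeric(stimulus_levels),
                 repetitions = as.integer(repetitions),
                 conditions = as.character(conditions),
                 groups = as.character(groups),
                 reference = reference, units = units),
            class = "psy_design")
}

#' Trials per participant implied by a design
#' @param design A [design_spec()].
#' @return Integer: stimulus levels x conditions x repetitions.
#' @export
trials_per_subject <- function(design) {
  length(design$stimulus_levels) * length(design$conditions) *
    design$repetitions
}

#' Design presets emulating the two example studies
#'
#' `touch_vibrations`: 9 participants, two masking-vibration conditions,
#' seven comparison speeds evenly spaced over 1.0-16.0 cm/s, 40 repetitions
#' per speed x condition = 560 trials per participant.
#'
#' `touch_diabetes`: three groups (controls, mild, moderate) of 20
#' participants, two masking conditions, five speeds evenly spaced over
#' 0.6-6.4 cm/s, reference 3.4 cm/s, 12 repetitions per speed x condition =
#' 120 trials per participant.
#'
#' The published studies state ranges, counts and totals but not the exact
#' stimulus grids; the presets use evenly spaced grids between the stated
#' endpoints and are an emulation of those designs, not a reproduction.
#'
#' @param name `"touch_vibrations"` or `"touch_diabetes"`.
#' @return A [design_spec()].
#' @export
preset_design <- function(name = c("touch_vibrations", "touch_diabetes")) {
  name <- match.arg(name)
  switch(name,
    touch_vibrations = design_spec(
      n_subjects = 9,
      stimulus_levels = seq(1.0, 16.0, length.out = 7),
      repetitions = 40,
      conditions = c("vib0", "vib1"),
      groups = "all",
      reference = NA_real_),
    touch_diabetes = design_spec(
      n_subjects = 20,
      stimulus_levels = seq(0.6, 6.4, length.out = 5),
      repetitions = 12,
      conditions = c("vib0", "vib1"),
      groups = c("controls", "mild", "moderate"),
      reference = 3.4)
  )
}

#' True population parameters for recovery studies
#'
#' Named truth fixtures paired with [preset_design()]. Values are chosen so
#' that the population psychometric curves span roughly (0.1, 0.9) over the
#' design's stimulus grid: unbiased observers (PSE at the grid midpoint /
#' reference), masking vibration reducing the slope, and clinical groups
#' ordered controls > mild > moderate in slope.
#'
#' @param name `"touch_vibrations"` or `"touch_diabetes"`.
#' @return A tibble of class `psy_truth` with one row per (group, condition):
#'   population `pse` and slope `beta`, and between-subject precisions
#'   `tau_pse`, `tau_beta`.
#' @export
preset_truth <- function(name = c("touch_vibrations", "touch_diabetes")) {
  name <- match.arg(name)
  tab <- switch(name,
    touch_vibrations = tibble::tibble(
      group = "all",
      condition = rep(c("vib0", "vib1"), each = 1),
      pse = 8.5,
      beta = c(0.25, 0.17),
      tau_pse = 1,
      tau_beta = 900),
    touch_diabetes = tibble::tibble(
      group = rep(c("controls", "mild", "moderate"), each = 2),
      condition = rep(c("vib0", "vib1"), times = 3),
      pse = 3.4,
      beta = c(0.45, 0.30, 0.28, 0.20, 0.18, 0.12),
      tau_pse = 16,
      tau_beta = 400)
  )
  structure(tab, class = c("psy_truth", class(tab)))
}

#' Draw subject-level parameters from a true population
#'
#' Subject PSEs and slopes are drawn from normal distributions around the
#' population values with the stated precisions (precisions above `1e12` are
#' capped there, making the draws effectively degenerate at the population
#' values). Reproducible for a given seed.
#'
#' @param pop A [preset_truth()]-shaped tibble (columns `group`, `condition`,
#'   `pse`, `beta`, `tau_pse`, `tau_beta`).
#' @param design A [design_spec()].
#' @param seed Integer seed.
#' @return Tibble with one row per (subject, condition): `subject`, `group`,
#'   `condition`, `pse`, `beta`.
#' @export
draw_subject_params <- function(pop, design, seed) {
  stopifnot(all(c("group", "condition", "pse", "beta", "tau_pse",
                  "tau_beta") %in% names(pop)))
  set.seed(seed)
  grid <- tidyr::expand_grid(group = design$groups,
                             subject_no = seq_len(design$n_subjects),
                             condition = design$conditions)
  grid$subject <- sprintf("%s_%02d", grid$group, grid$subject_no)
  grid <- dplyr::inner_join(grid, pop, by = c("group", "condition"))
  if (nrow(grid) != design$n_subjects * length(design$groups) *
        length(design$conditions)) {
    stop("truth table does not cover every (group, condition) of the design",
         call. = FALSE)
  }
  sd_pse <- 1 / sqrt(pmin(grid$tau_pse, 1e12))
  sd_beta <- 1 / sqrt(pmin(grid$tau_beta, 1e12))
  tibble::tibble(
    subject = grid$subject, group = grid$group, condition = grid$condition,
    pse = stats::rnorm(nrow(grid), grid$pse, sd_pse),
    beta = stats::rnorm(nrow(grid), grid$beta, sd_beta))
}

#' Simulate a forced-choice dataset from subject parameters
#'
#' For every (subject, condition, stimulus) cell, successes are drawn as
#' `Binomial(repetitions, pnorm(beta * (x - pse)))`. Returns an aggregated
#' trial table carrying the design metadata and seed.
#'
#' @param design A [design_spec()].
#' @param params Subject parameters from [draw_subject_params()].
#' @param seed Integer seed.
#' @param study Study label recorded in the table metadata.
#' @return A [psy_trials] tibble.
#' @export
simulate_dataset <- function(design, params, seed, study = "simulated") {
  stopifnot(all(c("subject", "group", "condition", "pse", "beta")
                %in% names(params)))
  set.seed(seed)
  cells <- tidyr::expand_grid(
    params[, c("subject", "group", "condition", "pse", "beta")],
    stimulus = design$stimulus_levels)
  prob <- stats::pnorm(cells$beta * (cells$stimulus - cells$pse))
  cells$successes <- stats::rbinom(nrow(cells), design$repetitions, prob)
  cells$trials <- design$repetitions
  out <- psy_trials(
    cells[, c("subject", "stimulus", "condition", "group", "successes",
              "trials")],
    study = study, reference = design$reference, units = design$units)
  attr(out, "seed") <- seed
  out
}

#' Simulate a complete study from a named truth
#'
#' Convenience wrapper: draws subject parameters (seed) and trial outcomes
#' (seed + 1) in one call.
#'
#' @param design A [design_spec()].
#' @param truth A truth table as from [preset_truth()].
#' @param seed Integer seed.
#' @param study Study label.
#' @return List with `data` (a [psy_trials] table), `params` (subject-level
#'   truth) and `truth` (population-level truth).
#' @export
simulate_study <- function(design, truth, seed, study = "simulated") {
  params <- draw_subject_params(truth, design, seed)
  data <- simulate_dataset(design, params, seed + 1L, study = study)
  list(data = data, params = params, truth = truth)
}

#' Restrict a design and truth to selected groups
#'
#' @param design A [design_spec()].
#' @param truth A truth tibble.
#' @param groups Character vector of group labels to keep.
#' @return List with the filtered `design` and `truth`.
#' @export
filter_groups <- function(design, truth, groups) {
  stopifnot(all(groups %in% design$groups))
  design$groups <- groups
  truth <- truth[truth$group %in% groups, ]
  list(design = design, truth = truth)
}
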