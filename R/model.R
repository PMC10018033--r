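#' Declare a hierarchical psychometric model
#'
#' Describes one variant of the two-stage hierarchical probit model. At the
#' first stage every (subject, condition) pair has its own psychometric curve,
#' written either as intercept/slope (`alpha + beta * x`) or as PSE/slope
#' (`beta * (x - pse)`). At the second stage subject-level parameters are
#' normal around population locations with estimated precisions; population
#' locations are normal around zero with their own Gamma-distributed
#' precisions. All normal distributions are parameterized by mean and
#' PRECISION (inverse variance); Gamma priors are shape/rate.
#'
#' @param parameterization `"pse_slope"` (focus on the point of subjective
#'   equality) or `"intercept_slope"`.
#' @param grouping `"none"` or `"by_group"`: whether population locations are
#'   indexed by a group label (e.g. clinical groups) in addition to condition.
#' @param precision Structure of the between-subject precisions:
#'   `"by_condition"` (one per condition, the default), `"by_subject"` (each
#'   subject has its own reliability), or `"by_group_and_condition"`.
#' @param hyperpriors Optional overrides, a list with any of `tau = c(shape=,
#'   rate=)` (first-stage precisions, default Gamma(1, 0.001)), `sigma =
#'   c(shape=, rate=)` (population-location precisions, default Gamma(1,
#'   0.01)), `pop_mean` (population prior mean, default 0).
#'
#' @return An object of class `psy_model`.
#' @seealso [build_model()] for named variants, [bind_model()] to attach data.
#' @export
psy_model <- function(parameterization = c("pse_slope", "intercept_slope"),
                      grouping = c("none", "by_group"),
                      precision = c("by_condition", "by_subject",
                                    "by_group_and_condition"),
                      hyperpriors = list()) {
  parameterization <- match.arg(parameterization)
  grouping <- match.arg(grouping)
  precision <- match.arg(precision)
  if (precision == "by_group_and_condition" && grouping != "by_group") {
    stop("precision 'by_group_and_condition' requires grouping 'by_group'",
         call. = FALSE)
  }
  hp <- list(tau = c(shape = 1, rate = 0.001),
             sigma = c(shape = 1, rate = 0.01),
             pop_mean = 0)
  for (nm in names(hyperpriors)) {
    if (!nm %in% names(hp)) stop(sprintf("unknown hyperprior '%s'", nm),
                                 call. = FALSE)
    value <- hyperpriors[[nm]]
    if (nm %in% c("tau", "sigma")) {
      stopifnot(all(c("shape", "rate") %in% names(value)))
      if (any(value <= 0)) stop("hyperprior parameters must be positive",
                                call. = FALSE)
    }
    hp[[nm]] <- value
  }
  structure(list(parameterization = parameterization, grouping = grouping,
                 precision = precision, hyperpriors = hp, link = "probit",
                 joint = FALSE, conversion = NULL),
            class = "psy_model")
}

#' Build a named model variant
#'
#' Convenience constructor for the model variants used throughout the package:
#' \describe{
#'   \item{`intercept_slope`}{hierarchy on (alpha, beta) per condition.}
#'   \item{`pse_slope`}{hierarchy on (pse, beta) per condition.}
#'   \item{`per_subject_precision`}{pse/slope with one precision pair per
#'     subject, letting individual reliability differ.}
#'   \item{`grouped`}{pse/slope with population locations and precisions per
#'     (group, condition).}
#'   \item{`joint`}{two-study intercept/slope model in which current
#'     population locations are centered on the historical ones, the slope
#'     scaled by a Weber-law conversion factor (see [build_joint_model()]).}
#' }
#'
#' @param variant One of `"intercept_slope"`, `"pse_slope"`,
#'   `"per_subject_precision"`, `"grouped"`, `"joint"`.
#' @param conversion Slope conversion factor for the `joint` variant; `NULL`
#'   computes it from the data at [bind_model()] time.
#' @param hyperpriors Passed to [psy_model()].
#' @return A `psy_model`.
#' @export
build_model <- function(variant = c("pse_slope", "intercept_slope",
                                    "per_subject_precision", "grouped",
                                    "joint"),
                        conversion = NULL, hyperpriors = list()) {
  variant <- match.arg(variant)
  switch(variant,
    intercept_slope = psy_model("intercept_slope", hyperpriors = hyperpriors),
    pse_slope = psy_model("pse_slope", hyperpriors = hyperpriors),
    per_subject_precision = psy_model("pse_slope", precision = "by_subject",
                                      hyperpriors = hyperpriors),
    grouped = psy_model("pse_slope", grouping = "by_group",
                        precision = "by_group_and_condition",
                        hyperpriors = hyperpriors),
    joint = build_joint_model(psy_model("intercept_slope",
                                        hyperpriors = hyperpriors),
                              psy_model("intercept_slope",
                                        hyperpriors = hyperpriors),
                              conversion = conversion)
  )
}

#' Build a joint two-study hierarchical model
#'
#' Combines a current and a historical study in one hierarchy: each study has
#' its own subject level and population locations, and the current population
#' locations are centered on the historical ones, with the current slope
#' location scaled by a conversion factor (Weber's law: sensitivity to speed
#' scales inversely with stimulus magnitude, so slopes transfer across
#' stimulus ranges only after rescaling). Posterior precisions of the
#' centering distributions quantify agreement between the studies. First-stage
#' precision hyperpriors default to Gamma(1, 0.01) in this variant.
#'
#' @param current_spec,historical_spec `psy_model` objects with the same
#'   parameterization and no grouping.
#' @param conversion Positive factor by which the historical slope location is
#'   multiplied to center the current one; `NULL` (default) uses the ratio of
#'   mean current stimulus to mean historical stimulus at binding time.
#' @return A `psy_model` with `joint = TRUE`.
#' @export
build_joint_model <- function(current_spec, historical_spec,
                              conversion = NULL) {
  stopifnot(inherits(current_spec, "psy_model"),
            inherits(historical_spec, "psy_model"))
  if (current_spec$parameterization != historical_spec$parameterization) {
    stop("joint model requires the same parameterization in both studies",
         call. = FALSE)
  }
  if (current_spec$grouping != "none" || historical_spec$grouping != "none") {
    stop("joint model supports ungrouped studies only", call. = FALSE)
  }
  if (!is.null(conversion) && (!is.finite(conversion) || conversion <= 0)) {
    stop("conversion factor must be positive", call. = FALSE)
  }
  spec <- current_spec
  spec$joint <- TRUE
  spec$conversion <- conversion
  spec$hyperpriors$tau <- c(shape = 1, rate = 0.01)
  spec
}

#' Power prior specification
#'
#' Describes borrowing from a historical study: the historical likelihood
#' enters the posterior raised to the power `a0` in `[0, 1]` (`a0 = 0` ignores
#' the historical data, `a0 = 1` pools it fully). Population locations and
#' precisions are shared between the studies; historical subject slopes are
#' centered at the shared slope location divided by the conversion factor.
#'
#' @param historical A [psy_trials] table of historical data.
#' @param a0 Borrowing weight in `[0, 1]`.
#' @param conversion Positive slope conversion factor (current-scale slope =
#'   historical-scale slope times `conversion`); `NULL` computes the ratio of
#'   mean current to mean historical stimulus at [bind_model()] time.
#' @return An object of class `psy_power`.
#' @export
power_prior <- function(historical, a0, conversion = NULL) {
  if (!is.numeric(a0) || length(a0) != 1 || is.na(a0) || a0 < 0 || a0 > 1) {
    stop("a0 must be a single value in [0, 1]", call. = FALSE)
  }
  if (!is.null(conversion) && (!is.finite(conversion) || conversion <= 0)) {
    stop("conversion factor must be positive", call. = FALSE)
  }
  structure(list(historical = as_psy_trials(historical), a0 = a0,
                 conversion = conversion),
            class = "psy_power")
}

as_psy_trials <- function(data) {
  if (inherits(data, "psy_trials")) return(data)
  psy_trials(data)
}

name1 <- function(parameterization, subject_level = TRUE) {
  if (parameterization == "pse_slope") {
    if (subject_level) "pse" else "PSE"
  } else {
    if (subject_level) "alpha" else "a"
  }
}

pname <- function(base, ...) {
  kv <- c(...)
  kv <- kv[!is.na(kv)]
  if (length(kv) == 0) return(base)
  sprintf("%s[%s]", base, paste(names(kv), kv, sep = "=", collapse = ","))
}

#' Bind a model specification to data
#'
#' Resolves a declarative [psy_model] against one (or, for power-prior and
#' joint models, two) trial tables: enumerates every subject-level,
#' population-level and precision parameter, assigns canonical names such as
#' `beta[subject=S1,cond=vib0]` or `PSE[group=controls,cond=vib1]`, and
#' precomputes the index structure used by the sampler and the density
#' functions.
#'
#' @param spec A `psy_model`.
#' @param data Current-study trial table (aggregated or per-trial; aggregated
#'   internally).
#' @param power Optional [power_prior()] specification.
#' @param historical Historical trial table, required when `spec` is a joint
#'   model (ignored otherwise; use `power` for power-prior borrowing).
#' @return A `psy_model_bound` object. Its `param_names` field lists every
#'   parameter in canonical order.
#' @export
bind_model <- function(spec, data, power = NULL, historical = NULL) {
  stopifnot(inherits(spec, "psy_model"))
  data <- aggregate_binomial(as_psy_trials(data))
  if (!is.null(power)) {
    stopifnot(inherits(power, "psy_power"))
    if (spec$joint) stop("use either a joint spec or a power prior, not both",
                         call. = FALSE)
    if (spec$grouping != "none") {
      stop("power-prior borrowing supports ungrouped models only",
           call. = FALSE)
    }
    historical <- aggregate_binomial(power$historical)
  } else if (spec$joint) {
    if (is.null(historical)) stop("joint model requires historical data",
                                  call. = FALSE)
    historical <- aggregate_binomial(as_psy_trials(historical))
  } else {
    historical <- NULL
  }

  if (!is.null(historical)) {
    overlap <- intersect(unique(data$subject), unique(historical$subject))
    if (length(overlap) > 0) {
      stop(sprintf(
        "subject labels shared across studies (%s); prefix one study's labels",
        paste(utils::head(overlap, 3), collapse = ", ")), call. = FALSE)
    }
  }

  conversion <- spec$conversion %||% (if (!is.null(power)) power$conversion)
  if (!is.null(historical) && is.null(conversion)) {
    conversion <- mean(data$stimulus) / mean(historical$stimulus)
  }

  if (spec$grouping == "by_group" && all(data$group == "all")) {
    stop("grouped model requires data with a group column", call. = FALSE)
  }

  roster <- function(tab, study) {
    r <- dplyr::distinct(tibble::as_tibble(tab)[, c("subject", "condition",
                                                    "group")])
    r$study <- study
    # stable order: subjects and conditions by first appearance
    r[order(match(r$subject, unique(tab$subject)),
            match(r$condition, unique(tab$condition))), ]
  }
  blocks <- roster(data, "current")
  if (!is.null(historical)) {
    blocks <- rbind(blocks, roster(historical, "historical"))
  }
  B <- nrow(blocks)
  param <- spec$parameterization
  hp <- spec$hyperpriors

  sub1 <- name1(param, TRUE)   # pse | alpha
  pop1 <- name1(param, FALSE)  # PSE | a
  hist_suffix <- function(study) ifelse(study == "historical" & spec$joint,
                                        "0", "")

  blocks$p1_name <- pname_vec(paste0(sub1, hist_suffix(blocks$study)),
                              subject = blocks$subject,
                              cond = blocks$condition)
  blocks$p2_name <- pname_vec(paste0("beta", hist_suffix(blocks$study)),
                              subject = blocks$subject,
                              cond = blocks$condition)

  # --- population nodes -----------------------------------------------------
  conds_cur <- unique(data$condition)
  conds_hist <- if (is.null(historical)) character() else
    unique(historical$condition)
  pop_rows <- list()
  add_pop <- function(name, parent = NA_character_, coef = 1, sigma) {
    pop_rows[[length(pop_rows) + 1]] <<- tibble::tibble(
      name = name, parent = parent, coef = coef, sigma = sigma)
  }
  sig1 <- paste0("sigma_", pop1)  # sigma_PSE | sigma_a
  sig2 <- "sigma_b"

  if (spec$joint) {
    conds <- unique(c(conds_cur, conds_hist))
    for (h in conds) {
      add_pop(pname(paste0(pop1, "0"), cond = h), sigma = paste0(sig1, "0"))
      add_pop(pname("b0", cond = h), sigma = paste0(sig2, "0"))
    }
    for (h in conds_cur) {
      add_pop(pname(pop1, cond = h), parent = pname(paste0(pop1, "0"),
                                                    cond = h),
              coef = 1, sigma = pname(sig1, cond = h))
      add_pop(pname("b", cond = h), parent = pname("b0", cond = h),
              coef = conversion, sigma = pname(sig2, cond = h))
    }
  } else if (spec$grouping == "by_group") {
    combos <- dplyr::distinct(blocks[, c("group", "condition")])
    for (r in seq_len(nrow(combos))) {
      add_pop(pname(pop1, group = combos$group[r], cond = combos$condition[r]),
              sigma = sig1)
      add_pop(pname("b", group = combos$group[r], cond = combos$condition[r]),
              sigma = sig2)
    }
  } else {
    conds <- unique(c(conds_cur, conds_hist))
    for (h in conds) {
      add_pop(pname(pop1, cond = h), sigma = sig1)
      add_pop(pname("b", cond = h), sigma = sig2)
    }
  }
  pop <- dplyr::bind_rows(pop_rows)

  # --- map each block to its population nodes -------------------------------
  if (spec$joint) {
    first <- ifelse(blocks$study == "historical", paste0(pop1, "0"), pop1)
    second <- ifelse(blocks$study == "historical", "b0", "b")
    blocks$pop1_name <- pname_vec(first, cond = blocks$condition)
    blocks$pop2_name <- pname_vec(second, cond = blocks$condition)
    blocks$coef1 <- 1
    blocks$coef2 <- 1
  } else if (spec$grouping == "by_group") {
    blocks$pop1_name <- pname_vec(pop1, group = blocks$group,
                                  cond = blocks$condition)
    blocks$pop2_name <- pname_vec("b", group = blocks$group,
                                  cond = blocks$condition)
    blocks$coef1 <- 1
    blocks$coef2 <- 1
  } else {
    blocks$pop1_name <- pname_vec(pop1, cond = blocks$condition)
    blocks$pop2_name <- pname_vec("b", cond = blocks$condition)
    blocks$coef1 <- 1
    # power prior: historical slopes live on the historical stimulus scale
    blocks$coef2 <- ifelse(blocks$study == "historical" & !spec$joint,
                           1 / (conversion %||% 1), 1)
  }

  # --- precision (tau) nodes ------------------------------------------------
  tau1_base <- paste0("tau_", sub1)  # tau_pse | tau_alpha
  tau2_base <- "tau_beta"
  suffix <- hist_suffix(blocks$study)
  tau_key <- switch(spec$precision,
    by_condition = pname_vec(NA, cond = blocks$condition),
    by_subject = pname_vec(NA, subject = blocks$subject),
    by_group_and_condition = pname_vec(NA, group = blocks$group,
                                       cond = blocks$condition))
  blocks$tau1_name <- paste0(tau1_base, suffix, tau_key)
  blocks$tau2_name <- paste0(tau2_base, suffix, tau_key)

  tau <- tibble::tibble(name = unique(c(blocks$tau1_name, blocks$tau2_name)),
                        shape = hp$tau[["shape"]], rate = hp$tau[["rate"]])
  sigma <- tibble::tibble(name = unique(pop$sigma),
                          shape = hp$sigma[["shape"]],
                          rate = hp$sigma[["rate"]])

  # --- parameter vector layout ---------------------------------------------
  param_names <- c(blocks$p1_name, blocks$p2_name, pop$name, tau$name,
                   sigma$name)
  stopifnot(!anyDuplicated(param_names))
  idx <- stats::setNames(seq_along(param_names), param_names)

  blocks$i1 <- idx[blocks$p1_name]
  blocks$i2 <- idx[blocks$p2_name]
  blocks$pop1 <- idx[blocks$pop1_name]
  blocks$pop2 <- idx[blocks$pop2_name]
  blocks$tau1 <- idx[blocks$tau1_name]
  blocks$tau2 <- idx[blocks$tau2_name]
  blocks$weight <- ifelse(blocks$study == "historical" & !spec$joint,
                          if (!is.null(power)) power$a0 else 1, 1)
  pop$idx <- idx[pop$name]
  pop$parent_idx <- ifelse(is.na(pop$parent), NA_integer_, idx[pop$parent])
  pop$sigma_idx <- idx[pop$sigma]
  tau$idx <- idx[tau$name]
  sigma$idx <- idx[sigma$name]

  bound <- structure(list(
    spec = spec, parameterization = param, blocks = tibble::as_tibble(blocks),
    pop = pop, tau = tau, sigma = sigma, param_names = param_names,
    n_blocks = B, data = data, historical = historical,
    a0 = if (!is.null(power)) power$a0 else NULL,
    conversion = conversion
  ), class = "psy_model_bound")
  bound$cells <- model_cells(bound, data, weight = 1)
  if (!is.null(historical)) {
    w <- if (!is.null(power)) power$a0 else 1
    bound$cells <- rbind(bound$cells,
                         model_cells(bound, historical, weight = w))
  }
  bound
}

# vectorized canonical parameter names; base may be NA to emit only "[...]"
pname_vec <- function(base, ...) {
  kv <- list(...)
  kv <- kv[!vapply(kv, function(x) all(is.na(x)), logical(1))]
  inner <- do.call(paste, c(purrr::imap(kv, ~ paste0(.y, "=", .x)),
                            sep = ","))
  if (length(base) == 1 && is.na(base)) sprintf("[%s]", inner)
  else sprintf("%s[%s]", base, inner)
}

# Map a trial table onto a bound model's blocks; returns per-cell indices.
model_cells <- function(bound, table, weight = 1) {
  table <- aggregate_binomial(as_psy_trials(table))
  key <- paste(bound$blocks$subject, bound$blocks$condition, sep = "\r")
  m <- match(paste(table$subject, table$condition, sep = "\r"), key)
  if (anyNA(m)) {
    bad <- which(is.na(m))[1]
    stop(sprintf("no parameter for subject %s, condition %s",
                 table$subject[bad], table$condition[bad]), call. = FALSE)
  }
  data.frame(x = table$stimulus, y = table$successes, n = table$trials,
             w = rep_len(weight, length(m)), block = m,
             i1 = bound$blocks$i1[m], i2 = bound$blocks$i2[m],
             lch = lchoose(table$trials, table$successes))
}

PROB_EPS <- 1e-12

cell_loglik <- function(parameterization, p1, p2, x, y, n, lch) {
  eta <- if (parameterization == "pse_slope") p2 * (x - p1) else p1 + p2 * x
  p <- pmin(pmax(stats::pnorm(eta), PROB_EPS), 1 - PROB_EPS)
  lch + y * log(p) + (n - y) * log1p(-p)
}

get_par <- function(params, nm) {
  v <- params[nm]
  if (anyNA(v)) {
    stop(sprintf("missing parameter: %s", nm[which(is.na(v))[1]]),
         call. = FALSE)
  }
  unname(v)
}

#' Hierarchical model log-likelihood
#'
#' Sum over binomial cells of the log probability mass (including the binomial
#' coefficient) with success probability `pnorm(linear predictor)`, clamped to
#' `[1e-12, 1 - 1e-12]` so extreme linear predictors stay finite.
#'
#' @param spec A bound model from [bind_model()].
#' @param params Named numeric vector covering the subject-level parameters of
#'   every (subject, condition) present in `data` (canonical names, see
#'   [bind_model()]).
#' @param data Trial table to evaluate; defaults to the table the model was
#'   bound to.
#' @return The log-likelihood (a single number).
#' @export
log_likelihood <- function(spec, params, data = spec$data) {
  stopifnot(inherits(spec, "psy_model_bound"))
  cells <- model_cells(spec, data)
  p1 <- get_par(params, spec$blocks$p1_name[cells$block])
  p2 <- get_par(params, spec$blocks$p2_name[cells$block])
  sum(cell_loglik(spec$parameterization, p1, p2, cells$x, cells$y, cells$n,
                  cells$lch))
}

#' Hierarchical model log-prior
#'
#' Sum of the log-densities of every stochastic node given its parents:
#' normal (mean, precision) terms for subject-level and population-level
#' locations and Gamma (shape, rate) terms for all precision parameters.
#' Returns `-Inf` (rather than raising) when any precision is non-positive,
#' so samplers reject such states.
#'
#' @inheritParams log_likelihood
#' @return The log-prior density (a single number, possibly `-Inf`).
#' @export
log_prior <- function(spec, params) {
  stopifnot(inherits(spec, "psy_model_bound"))
  tau_v <- get_par(params, spec$tau$name)
  sigma_v <- get_par(params, spec$sigma$name)
  if (any(tau_v <= 0) || any(sigma_v <= 0)) return(-Inf)

  blocks <- spec$blocks
  p1 <- get_par(params, blocks$p1_name)
  p2 <- get_par(params, blocks$p2_name)
  pop_v <- get_par(params, spec$pop$name)
  pop_of <- stats::setNames(pop_v, spec$pop$name)
  tau_of <- stats::setNames(tau_v, spec$tau$name)
  sigma_of <- stats::setNames(sigma_v, spec$sigma$name)

  lp <- sum(stats::dnorm(p1, blocks$coef1 * pop_of[blocks$pop1_name],
                         1 / sqrt(tau_of[blocks$tau1_name]), log = TRUE)) +
    sum(stats::dnorm(p2, blocks$coef2 * pop_of[blocks$pop2_name],
                     1 / sqrt(tau_of[blocks$tau2_name]), log = TRUE))

  parent_mean <- ifelse(is.na(spec$pop$parent),
                        spec$spec$hyperpriors$pop_mean,
                        spec$pop$coef * pop_of[spec$pop$parent])
  lp <- lp + sum(stats::dnorm(pop_v, parent_mean,
                              1 / sqrt(sigma_of[spec$pop$sigma]), log = TRUE))
  lp + sum(stats::dgamma(tau_v, shape = spec$tau$shape, rate = spec$tau$rate,
                         log = TRUE)) +
    sum(stats::dgamma(sigma_v, shape = spec$sigma$shape,
                      rate = spec$sigma$rate, log = TRUE))
}

#' Power-prior log-posterior
#'
#' Unnormalized log-posterior under a fixed-weight power prior: the current
#' log-likelihood plus `a0` times the historical log-likelihood plus the
#' log-prior of the shared parameter structure. `a0 = 0` reduces exactly to
#' the current-only posterior; `a0 = 1` to the posterior of the pooled data.
#'
#' @inheritParams log_likelihood
#' @param current Current-study trial table.
#' @param pp A [power_prior()] specification (its historical table and `a0`
#'   are used; the spec should have been bound with the same `power`).
#' @return The unnormalized log-posterior density.
#' @export
log_posterior_power <- function(spec, params, current, pp) {
  stopifnot(inherits(spec, "psy_model_bound"), inherits(pp, "psy_power"))
  if (pp$a0 < 0 || pp$a0 > 1) stop("a0 must be in [0, 1]", call. = FALSE)
  ll_hist <- if (pp$a0 > 0) {
    pp$a0 * log_likelihood(spec, params, pp$historical)
  } else 0
  log_likelihood(spec, params, current) + ll_hist + log_prior(spec, params)
}
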