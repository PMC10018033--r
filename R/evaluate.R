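# Model comparison and posterior-similarity metrics.

# Cell-wise log-likelihood matrix [cells x draws] for a draw matrix [S x P].
cell_ll_matrix <- function(fit, cells, draw_mat) {
  blocks <- fit$spec$blocks
  p1 <- t(draw_mat[, blocks$p1_name[cells$block], drop = FALSE])
  p2 <- t(draw_mat[, blocks$p2_name[cells$block], drop = FALSE])
  eta <- if (fit$spec$parameterization == "pse_slope") {
    p2 * (cells$x - p1)
  } else {
    p1 + p2 * cells$x
  }
  p <- pmin(pmax(stats::pnorm(eta), PROB_EPS), 1 - PROB_EPS)
  cells$lch + cells$y * log(p) + (cells$n - cells$y) * log1p(-p)
}

#' Log pointwise predictive density
#'
#' For each binomial cell, the log of the posterior-averaged likelihood
#' `log( mean_s p(y_i | theta_s) )`, summed over cells; the Monte Carlo
#' uncertainty is reported as the standard deviation of the per-chain lppd
#' values. Cells whose averaged likelihood underflows to zero contribute
#' `-Inf` and are flagged.
#'
#' @param fit A `psy_fit`.
#' @param data Trial table to evaluate on; defaults to the fitted (current)
#'   data.
#' @return A list with `value`, `mc_error`, and `flagged` (indices of cells
#'   with zero averaged likelihood, normally empty).
#' @export
lppd <- function(fit, data = fit$data) {
  stopifnot(inherits(fit, "psy_fit"))
  cells <- model_cells(fit$spec, data)
  n_iter <- dim(fit$draws)[1]
  n_chains <- dim(fit$draws)[2]
  ll <- cell_ll_matrix(fit, cells, draw_matrix(fit))
  m <- apply(ll, 1, max)
  avg <- rowMeans(exp(ll - m))
  per_cell <- m + log(avg)
  per_chain <- vapply(seq_len(n_chains), function(ch) {
    cols <- (ch - 1) * n_iter + seq_len(n_iter)
    mm <- apply(ll[, cols, drop = FALSE], 1, max)
    sum(mm + log(rowMeans(exp(ll[, cols, drop = FALSE] - mm))))
  }, numeric(1))
  list(value = sum(per_cell),
       mc_error = stats::sd(per_chain),
       flagged = which(!is.finite(per_cell)))
}

# Subject-level parameter vector at posterior means. level = "individual"
# uses each subject's own posterior means; "overall" replaces them with the
# population posterior means (through each block's coefficient, so
# historical-scale slopes stay on their own scale).
posterior_mean_params <- function(fit, level = c("individual", "overall")) {
  level <- match.arg(level)
  blocks <- fit$spec$blocks
  dm <- draw_matrix(fit)
  means <- colMeans(dm)
  params <- means
  if (level == "overall") {
    params[blocks$p1_name] <- blocks$coef1 * means[blocks$pop1_name]
    params[blocks$p2_name] <- blocks$coef2 * means[blocks$pop2_name]
  }
  params
}

#' Sum of squared errors of fitted response probabilities
#'
#' Sum over cells of the squared difference between the observed proportion
#' (`successes / trials`) and the fitted probit probability. At the
#' `individual` level the fitted values use each subject's posterior-mean
#' parameters; at the `overall` level every subject is replaced by the
#' population posterior means.
#'
#' @inheritParams lppd
#' @param level `"individual"` or `"overall"`.
#' @return A single number.
#' @export
sum_squared_errors <- function(fit, level = c("individual", "overall"),
                               data = fit$data) {
  stopifnot(inherits(fit, "psy_fit"))
  level <- match.arg(level)
  cells <- model_cells(fit$spec, data)
  if (any(cells$n == 0)) {
    warning("cells with zero trials excluded from SSE")
    cells <- cells[cells$n > 0, ]
  }
  params <- posterior_mean_params(fit, level)
  blocks <- fit$spec$blocks
  p1 <- unname(params[blocks$p1_name[cells$block]])
  p2 <- unname(params[blocks$p2_name[cells$block]])
  eta <- if (fit$spec$parameterization == "pse_slope") {
    p2 * (cells$x - p1)
  } else {
    p1 + p2 * cells$x
  }
  sum((cells$y / cells$n - stats::pnorm(eta))^2)
}

# log-likelihood of `data` at posterior-mean parameters of the given level
loglik_at_means <- function(fit, level, data = fit$data) {
  log_likelihood(fit$spec, posterior_mean_params(fit, level), data)
}

#' Overlap of two posterior distributions
#'
#' Histogram intersection: both draw vectors are binned on their shared range
#' with `n_bins` equal-width bins, each histogram normalized to unit area, and
#' the overlap is the area under the bin-wise minimum of the two densities.
#' 1 means identical histograms, 0 disjoint supports. Symmetric in its
#' arguments.
#'
#' @param samples_a,samples_b Numeric draw vectors (non-empty).
#' @param n_bins Number of bins (default 50).
#' @return A proportion in `[0, 1]`.
#' @export
posterior_overlap <- function(samples_a, samples_b, n_bins = 50) {
  stopifnot(length(samples_a) > 0, length(samples_b) > 0)
  if (n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
  lo <- min(samples_a, samples_b)
  hi <- max(samples_a, samples_b)
  if (lo == hi) return(1)  # all draws of both vectors at one identical point
  breaks <- seq(lo, hi, length.out = n_bins + 1)
  bw <- breaks[2] - breaks[1]
  count <- function(x) {
    idx <- pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1),
                n_bins)
    tabulate(idx, nbins = n_bins)
  }
  da <- count(samples_a) / (length(samples_a) * bw)
  db <- count(samples_b) / (length(samples_b) * bw)
  sum(pmin(da, db)) * bw
}

population_pse_draws <- function(fit) {
  d <- augment_derived(fit)
  nm <- dimnames(d)[[3]]
  sel <- grepl("^PSE\\[", nm) | nm == "PSE"
  if (!any(sel)) {
    stop("fit has no population PSE parameter", call. = FALSE)
  }
  as.vector(d[, , sel, drop = FALSE])
}

#' Model comparison table
#'
#' One row pair (individual, overall effects) per fitted model: log-likelihood
#' at the posterior means of that level's parameters, lppd with its Monte
#' Carlo error (draw-based, reported on the individual row), sum of squared
#' errors at both levels, and the 95% credible interval of the population PSE
#' (pooled over all population-level PSE parameters) with its width on the
#' overall row.
#'
#' @param fits A `psy_fit` or (preferably named) list of them.
#' @param labels Model labels; defaults to the list names.
#' @return A tibble with columns `model`, `effects`, `loglik`, `lppd`,
#'   `lppd_mc_error`, `sse`, `pse_ci_low`, `pse_ci_high`, `ci_width`.
#' @export
compare_models <- function(fits, labels = NULL) {
  if (inherits(fits, "psy_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1)
  labels <- labels %||% names(fits) %||% paste0("model", seq_along(fits))
  if (is.null(names(fits))) names(fits) <- labels
  rows <- purrr::map2(fits, labels, function(fit, lab) {
    lp <- lppd(fit)
    pse <- population_pse_draws(fit)
    ci <- stats::quantile(pse, c(0.025, 0.975), names = FALSE)
    tibble::tibble(
      model = lab,
      effects = c("individual", "overall"),
      loglik = c(loglik_at_means(fit, "individual"),
                 loglik_at_means(fit, "overall")),
      lppd = c(lp$value, NA_real_),
      lppd_mc_error = c(lp$mc_error, NA_real_),
      sse = c(sum_squared_errors(fit, "individual"),
              sum_squared_errors(fit, "overall")),
      pse_ci_low = c(NA_real_, ci[1]),
      pse_ci_high = c(NA_real_, ci[2]),
      ci_width = c(NA_real_, ci[2] - ci[1]))
  })
  dplyr::bind_rows(rows)
}

#' Fit a grid of power-prior weights
#'
#' Fits the model once per borrowing weight in `a0_grid` and assembles a
#' comparison table (one individual/overall row pair per weight, as in
#' [compare_models()]), plus the weight selected by the minimum
#' population-PSE credible-interval width.
#'
#' @param data Current-study trial table.
#' @param spec A `psy_model` (ungrouped).
#' @param historical Historical trial table.
#' @param a0_grid Numeric vector of weights in `[0, 1]`.
#' @param config A [chain_config()]; the same seed is reused for every grid
#'   point.
#' @param conversion Optional slope conversion factor (see [power_prior()]).
#' @param keep_fits Keep the individual `psy_fit` objects in the result
#'   attribute `fits` (default `FALSE`).
#' @return A tibble of class `psy_power_grid` with the [compare_models()]
#'   columns plus `a0`; the selected weight is in attribute `selected_a0`.
#' @export
power_grid <- function(data, spec, historical, a0_grid,
                       config = chain_config(), conversion = NULL,
                       keep_fits = FALSE) {
  stopifnot(length(a0_grid) >= 1)
  if (any(a0_grid < 0 | a0_grid > 1)) {
    stop("all a0 grid values must be in [0, 1]", call. = FALSE)
  }
  fits <- purrr::map(a0_grid, function(a0) {
    run_chains(data, spec, config,
               power = power_prior(historical, a0, conversion))
  })
  tab <- compare_models(fits, labels = format(a0_grid))
  tab <- dplyr::mutate(tab, a0 = rep(a0_grid, each = 2), .before = 1)
  tab$model <- NULL
  widths <- tab$ci_width[tab$effects == "overall"]
  sel <- select_a0(stats::setNames(widths, a0_grid))
  attr(tab, "selected_a0") <- sel
  if (keep_fits) attr(tab, "fits") <- fits
  class(tab) <- c("psy_power_grid", class(tab))
  tab
}

#' Select the power-prior weight
#'
#' Chooses the borrowing weight minimizing the population-PSE credible
#' interval width; ties are broken toward the larger `a0` (more borrowing at
#' equal uncertainty).
#'
#' @param widths Either a named numeric vector (names are `a0` values, values
#'   are CI widths) or a [power_grid()] table.
#' @param criterion Only `"min_ci_width"` is implemented.
#' @return The selected `a0` (a single number).
#' @export
select_a0 <- function(widths, criterion = "min_ci_width") {
  criterion <- match.arg(criterion, "min_ci_width")
  if (inherits(widths, "psy_power_grid") || is.data.frame(widths)) {
    tab <- widths[widths$effects == "overall", ]
    widths <- stats::setNames(tab$ci_width, tab$a0)
  }
  if (length(widths) == 0) stop("empty a0 grid", call. = FALSE)
  a0 <- as.numeric(names(widths))
  stopifnot(!anyNA(a0))
  best <- widths == min(widths)
  max(a0[best])
}
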