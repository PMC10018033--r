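# broom-style methods for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted hierarchical psychometric model
#'
#' One row per parameter (including derived PSEs for intercept/slope models):
#' posterior mean, sd, percentiles, credible interval and R-hat. Equivalent to
#' [summarize_posterior()].
#'
#' @param x A `psy_fit`.
#' @param level Credible-interval level.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy psy_fit
#' @export
tidy.psy_fit <- function(x, level = 0.95, ...) {
  summarize_posterior(x, level = level)
}

#' One-row summary of a fitted model
#'
#' @param x A `psy_fit`.
#' @param ... Unused.
#' @return A tibble with sampler dimensions, the worst R-hat, log-likelihood
#'   at individual posterior means, lppd (with Monte Carlo error) and the
#'   individual-level sum of squared errors.
#' @method glance psy_fit
#' @export
glance.psy_fit <- function(x, ...) {
  lp <- lppd(x)
  tibble::tibble(
    n_chains = dim(x$draws)[2],
    n_iter = dim(x$draws)[1],
    n_parameters = dim(x$draws)[3],
    max_rhat = max(gelman_rubin(x)),
    loglik = loglik_at_means(x, "individual"),
    lppd = lp$value,
    lppd_mc_error = lp$mc_error,
    sse = sum_squared_errors(x, "individual"))
}

#' Tidy draws in long format
#'
#' @param fit A `psy_fit`.
#' @param parameters Optional regular expression restricting parameters.
#' @return Tibble with columns `chain`, `iteration`, `parameter`, `value`.
#' @export
tidy_draws <- function(fit, parameters = NULL) {
  stopifnot(inherits(fit, "psy_fit"))
  nm <- dimnames(fit$draws)[[3]]
  if (!is.null(parameters)) nm <- nm[grepl(parameters, nm)]
  d <- fit$draws[, , nm, drop = FALSE]
  tibble::tibble(
    chain = rep(rep(seq_len(dim(d)[2]), each = dim(d)[1]), times = dim(d)[3]),
    iteration = rep(seq_len(dim(d)[1]), times = dim(d)[2] * dim(d)[3]),
    parameter = rep(nm, each = dim(d)[1] * dim(d)[2]),
    value = as.vector(d))
}
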