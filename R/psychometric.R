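#' Probit psychometric curve parameters
#'
#' Bundles the intercept `alpha` and slope `beta` of a probit psychometric
#' function, whose response probability at stimulus `x` is
#' `pnorm(alpha + beta * x)`.
#'
#' @param alpha Intercept on the probit scale.
#' @param beta Slope, probit units per stimulus unit.
#' @return A list of class `curve_params`.
#' @export
curve_params <- function(alpha, beta) {
  stopifnot(is.finite(alpha), is.finite(beta))
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta)),
            class = "curve_params")
}

#' Probit response probability
#'
#' Probability of the "comparison larger" response at stimulus value `x` under
#' a probit psychometric function: the standard normal CDF of the linear
#' predictor `alpha + beta * x`.
#'
#' @param params A [curve_params] object (or list with `alpha`, `beta`).
#' @param x Stimulus value(s).
#' @return Probabilities in (0, 1), one per element of `x`.
#' @export
#' @examples
#' probit_response_prob(curve_params(0, 1), 0) # 0.5
probit_response_prob <- function(params, x) {
  stopifnot(all(is.finite(x)))
  stats::pnorm(params$alpha + params$beta * x)
}

#' Point of subjective equality
#'
#' The stimulus value at which the response probability is exactly 0.5:
#' `-alpha / beta`.
#'
#' @inheritParams probit_response_prob
#' @return The PSE in stimulus units.
#' @export
pse_from_params <- function(params) {
  if (params$beta == 0) {
    stop("degenerate slope: PSE undefined for beta = 0", call. = FALSE)
  }
  -params$alpha / params$beta
}

#' Just noticeable difference from the slope
#'
#' JND convention used throughout this package: half the 25%-75% interquartile
#' span of the fitted probit curve, `qnorm(0.75) / beta`. The JND is inversely
#' proportional to the slope; steeper curves mean more precise responses.
#'
#' @param beta Probit slope, must be positive.
#' @return The JND in stimulus units.
#' @export
jnd_from_slope <- function(beta) {
  if (!is.finite(beta) || beta <= 0) {
    stop("JND undefined for beta <= 0", call. = FALSE)
  }
  stats::qnorm(0.75) / beta
}

#' Predicted psychometric curve on a stimulus grid
#'
#' @inheritParams probit_response_prob
#' @param grid Numeric vector of stimulus values.
#' @return Numeric vector of response probabilities, same length as `grid`.
#' @export
predict_curve <- function(params, grid) {
  stopifnot(all(is.finite(grid)))
  probit_response_prob(params, grid)
}
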