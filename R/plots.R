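# ggplot2 graphics for results.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Posterior densities of the population parameters
#'
#' @param object A `psy_fit`.
#' @param parameters Regular expression selecting parameters (default: the
#'   population locations).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot psy_fit
#' @export
autoplot.psy_fit <- function(object, parameters = "^(PSE|b|a)0?\\[", ...) {
  df <- tidy_draws(object, parameters)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value,
                                   colour = factor(.data$chain))) +
    ggplot2::geom_density() +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "value", colour = "chain") +
    ggplot2::theme_minimal()
}

#' Observed and fitted psychometric curves
#'
#' Observed proportions per cell (points) with the posterior-mean individual
#' psychometric curves (lines), one facet per subject.
#'
#' @param fit A `psy_fit`.
#' @param n_grid Grid resolution for the fitted curves.
#' @return A ggplot.
#' @export
plot_psychometric <- function(fit, n_grid = 101) {
  stopifnot(inherits(fit, "psy_fit"))
  data <- fit$data
  obs <- dplyr::mutate(tibble::as_tibble(data),
                       prop = .data$successes / .data$trials)
  params <- posterior_mean_params(fit, "individual")
  blocks <- fit$spec$blocks[fit$spec$blocks$study == "current", ]
  grid <- seq(min(data$stimulus), max(data$stimulus), length.out = n_grid)
  curves <- purrr::map(seq_len(nrow(blocks)), function(r) {
    p1 <- params[[blocks$p1_name[r]]]
    p2 <- params[[blocks$p2_name[r]]]
    eta <- if (fit$spec$parameterization == "pse_slope") {
      p2 * (grid - p1)
    } else {
      p1 + p2 * grid
    }
    tibble::tibble(subject = blocks$subject[r],
                   condition = blocks$condition[r],
                   stimulus = grid, prob = stats::pnorm(eta))
  })
  curves <- dplyr::bind_rows(curves)
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$stimulus,
                                    colour = .data$condition)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$prop), size = 1) +
    ggplot2::geom_line(data = curves, ggplot2::aes(y = .data$prob)) +
    ggplot2::facet_wrap(~subject) +
    ggplot2::labs(y = "P(comparison judged faster)",
                  x = "stimulus") +
    ggplot2::theme_minimal()
}

#' Credible-interval width across the borrowing-weight grid
#'
#' @param object A [power_grid()] table.
#' @param ... Unused.
#' @return A ggplot of overall-PSE CI width against `a0`, with the selected
#'   weight highlighted.
#' @method autoplot psy_power_grid
#' @export
autoplot.psy_power_grid <- function(object, ...) {
  df <- object[object$effects == "overall", ]
  sel <- attr(object, "selected_a0")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a0, y = .data$ci_width)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = sel, linetype = "dashed") +
    ggplot2::labs(x = "a0 (historical-data weight)",
                  y = "95% CI width of population PSE") +
    ggplot2::theme_minimal()
}
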