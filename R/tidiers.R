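#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an expression fit
#'
#' One row per fitted (reaction, condition) pair with the predicted flux,
#' the expression-derived target, the residual weight and the absolute
#' residual.
#'
#' @param x An `lpm_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy lpm_fit
#' @export
tidy.lpm_fit <- function(x, ...) x$residuals

#' One-row fit summary
#'
#' @param x An `lpm_fit`.
#' @param ... Unused.
#' @return Tibble with `alpha`, `n_conditions`, `discrepancy` (total
#'   unweighted mapping discrepancy), `fit_term` (weighted) and
#'   `penalty_sum` (summed `|v|` over penalized reactions).
#' @method glance lpm_fit
#' @export
glance.lpm_fit <- function(x, ...) {
  tibble::tibble(
    alpha = x$config$alpha,
    n_conditions = nrow(x$by_condition),
    discrepancy = x$discrepancy,
    fit_term = x$fit_term,
    penalty_sum = x$penalty_sum
  )
}

#' @method tidy lpm_iffpr
#' @export
tidy.lpm_iffpr <- function(x, ...) x$history

#' @method glance lpm_iffpr
#' @export
glance.lpm_iffpr <- function(x, ...) {
  tibble::tibble(
    processed = x$processed,
    steps = nrow(x$history),
    accepted = sum(x$history$accepted),
    initial_d = x$initial_d,
    final_d = x$final_d,
    reduction_pct = if (x$initial_d > 0) {
      100 * (1 - x$final_d / x$initial_d)
    } else 0,
    stopped_early = x$stopped_early
  )
}

#' @method tidy lpm_redtil
#' @export
tidy.lpm_redtil <- function(x, ...) x$cut_log

#' @method glance lpm_redtil
#' @export
glance.lpm_redtil <- function(x, ...) {
  tibble::tibble(
    n_cuts = nrow(x$cut_log),
    n_iter = x$n_iter,
    threshold = x$threshold,
    discrepancy = x$solution$discrepancy
  )
}

#' Discrepancy trajectory of a bound-reduction run
#'
#' Plots the total model mapping discrepancy against the halving step,
#' marking accepted and rejected steps.
#'
#' @param object An `lpm_iffpr`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot lpm_iffpr
#' @export
autoplot.lpm_iffpr <- function(object, ...) {
  hist <- object$history
  ggplot2::ggplot(hist, ggplot2::aes(x = .data$step, y = .data$d)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$accepted)) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2166ac",
                                            `FALSE` = "#b2182b")) +
    ggplot2::labs(x = "halving step", y = "total mapping discrepancy d",
                  colour = "accepted") +
    ggplot2::theme_minimal()
}

#' Residuals of an expression fit, by condition
#'
#' @param object An `lpm_fit`.
#' @param ... Unused.
#' @return A ggplot of predicted flux against the expression-derived target.
#' @method autoplot lpm_fit
#' @export
autoplot.lpm_fit <- function(object, ...) {
  ggplot2::ggplot(object$residuals,
                  ggplot2::aes(x = .data$vfit, y = .data$flux)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "expression-derived target flux",
                  y = "fitted flux") +
    ggplot2::theme_minimal()
}

#' Carbon-call z-score profile
#'
#' Bar panels of transporter z-scores per condition, the package's analogue
#' of the classic carbon-source figure.
#'
#' @param object A `carbon_call`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot carbon_call
#' @export
autoplot.carbon_call <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$transporter, y = .data$z,
                               fill = .data$call)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = NULL, y = "uptake z-score", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
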