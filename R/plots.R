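#' Plot a stratified prevalence table
#'
#' Grouped bar chart of per-level emotion prevalence with binomial
#' standard-error bars.
#'
#' @param object An `emospect_prevalence`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.emospect_prevalence <- function(object, ...) {
  rows <- object$rows
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$emotion, y = .data$pct,
                                     fill = .data$level)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$pct - 100 * .data$se,
                   ymax = .data$pct + 100 * .data$se),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25
    ) +
    ggplot2::labs(x = NULL, y = "Reviews expressing emotion (%)",
                  fill = object$stratifier,
                  title = paste("Emotion prevalence by", object$stratifier)) +
    ggplot2::theme_minimal()
}

#' Forest plot of logistic-regression odds ratios
#'
#' @param object An `emospect_fit` of subclass `emospect_logit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.emospect_logit <- function(object, ...) {
  tb <- object$terms[object$terms$term != "(Intercept)", ]
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$or, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_lo, xmax = .data$ci_hi), height = 0.2
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (log scale), Wald 95% CI", y = NULL,
                  title = object$model_id) +
    ggplot2::theme_minimal()
}

#' Coefficient plot for an OLS fit
#'
#' @param object An `emospect_fit` of subclass `emospect_ols`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.emospect_ols <- function(object, ...) {
  tb <- object$terms[object$terms$term != "(Intercept)", ]
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$estimate - 1.959964 * .data$se,
                   xmax = .data$estimate + 1.959964 * .data$se),
      height = 0.2
    ) +
    ggplot2::labs(x = "Coefficient (95% CI)", y = NULL, title = object$model_id) +
    ggplot2::theme_minimal()
}

#' Planted-versus-recovered scatter for a roundtrip check
#'
#' @param object An `emospect_roundtrip`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.emospect_roundtrip <- function(object, ...) {
  prev <- dplyr::mutate(object$prevalence, panel = "prevalence")
  bet <- tibble::tibble(
    emotion = object$sentiment_betas$term,
    planted = object$sentiment_betas$planted,
    recovered = object$sentiment_betas$estimate,
    panel = "sentiment slope"
  )
  d <- dplyr::bind_rows(prev, bet)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$planted, y = .data$recovered)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = "Planted value", y = "Recovered estimate",
                  title = "Generator roundtrip: planted vs recovered") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
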