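#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

effect_labels <- c(
  beta_lag_fwd = "X1 on Y2 | Y1",
  beta_lag_rev = "X1 on Y1 | Y2",
  beta_change = "X1 on Y2 - Y1",
  beta_change_on_change = "X2 - X1 on Y2 - Y1"
)

#' Plot the fitted SPAM parameters and fit
#'
#' Dot plot of the five reported parameter estimates of a [fit_spam()]
#' result, annotated with the global fit statistics.
#'
#' @param object A `spam_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.spam_fit <- function(object, ...) {
  df <- tidy(object)
  df$term <- factor(df$term, levels = rev(df$term))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(
      x = "standardized estimate", y = NULL,
      title = "SPAM parameter estimates",
      subtitle = sprintf("chi2 = %.2f (df = %d), CFI = %.3f, RMSEA = %.3f, n = %d",
                         object$chi2, object$df, object$cfi, object$rmsea, object$n_obs)
    )
}

#' Plot the effect structure of a SPAM evaluation
#'
#' Dot plot of the four standardized effects per direction, comparing the
#' effects implied by the input correlations with those reproduced by the
#' fitted SPAM. The characteristic spurious signature is both lagged effects
#' sharing a sign, the change effect taking the opposite sign, and the
#' change-on-change effect flipping back.
#'
#' @param object A `spam_evaluation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.spam_evaluation <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(cols = c("input", "predicted"),
                        names_to = "source", values_to = "estimate")
  df$effect <- factor(effect_labels[df$effect], levels = rev(unname(effect_labels)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$effect,
                                   colour = .data$source, shape = .data$source)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(size = 2.5, position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::facet_wrap(~direction, labeller = ggplot2::as_labeller(
      c(xy = "X predicting Y", yx = "Y predicting X"))) +
    ggplot2::labs(x = "standardized effect", y = NULL, colour = NULL, shape = NULL,
                  title = "Input-implied vs SPAM-reproduced effects")
}

#' Plot pooled meta-analytic estimates
#'
#' Point estimates with 95% confidence intervals for the 14 pooled
#' correlations and effects of a [meta_table()] result (summary estimates
#' only; per-study forest displays are out of scope).
#'
#' @param object A `spam_meta` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.spam_meta <- function(object, ...) {
  df <- object
  df$association <- factor(df$association, levels = rev(df$association))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pooled, y = .data$association)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
                            height = 0.2, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$kind), size = 2.5) +
    ggplot2::labs(x = "pooled estimate (r scale, 95% CI)", y = NULL, colour = NULL,
                  title = "Random-effects pooled correlations and effects")
}
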