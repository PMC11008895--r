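#' Plot efficiency scores over time
#'
#' Boxplots of DEA scores by year with the per-year mean overlaid; the
#' horizontal line at 1 separates efficient (super-efficiency > 1) from
#' inefficient units.
#'
#' @param scores tibble from [sbm_efficiency()] or
#'   [super_sbm_efficiency()] containing `year` and `score` columns.
#' @return A ggplot object.
#' @export
plot_efficiency <- function(scores) {
  stopifnot(all(c("year", "score") %in% names(scores)))
  ggplot2::ggplot(scores, ggplot2::aes(factor(.data$year), .data$score)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, fill = "grey90") +
    ggplot2::stat_summary(fun = mean, geom = "point", colour = "firebrick") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = "year", y = "SBM score") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.eco_transition <- function(object, ...) {
  df <- as.data.frame.table(object$probs, responseName = "prob")
  ggplot2::ggplot(df, ggplot2::aes(.data$to, .data$from, fill = .data$prob)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(is.na(.data$prob), "-",
                                                   sprintf("%.2f", .data$prob))),
                       size = 3) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 na.value = "grey95") +
    ggplot2::labs(x = "state at t+1", y = "state at t", fill = "prob") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gm11 <- function(object, h = 0, ...) {
  n <- length(object$data)
  df <- tibble(period = object$t0 + seq_len(n) - 1,
               actual = object$data, fitted = object$fitted)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$period)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$actual, colour = "actual")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted, colour = "GM(1,1)")) +
    ggplot2::labs(x = "period", y = "value", colour = NULL) +
    ggplot2::theme_minimal()
  if (h > 0) {
    fc <- forecast(object, h)
    p <- p + ggplot2::geom_line(data = fc,
      ggplot2::aes(.data$period, .data$combined, colour = "forecast"),
      linetype = 2)
  }
  p
}

#' @export
autoplot.grey_hybrid <- function(object, ...) {
  df <- tidyr::pivot_longer(object$fitted, c("actual", "gm", "combined"),
                            names_to = "series", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$period, .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(actual = "black", gm = "steelblue",
                                            combined = "firebrick"),
                                 labels = c(actual = "actual", gm = "GM(1,1)",
                                            combined = "grey-neural")) +
    ggplot2::labs(x = "period", y = "value", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sfa_fit <- function(object, ...) {
  ggplot2::ggplot(object$te, ggplot2::aes(factor(.data$year), .data$te)) +
    ggplot2::geom_boxplot(fill = "grey90", outlier.size = 0.6) +
    ggplot2::labs(x = "year", y = "technical efficiency") +
    ggplot2::theme_minimal()
}

#' Plot a direct/indirect effects decomposition
#'
#' Dot-and-whisker display of the direct, indirect and total effects per
#' regressor with +/- 1.96 simulation standard errors.
#'
#' @param effects tibble from [effects_decomposition()].
#' @return A ggplot object.
#' @export
plot_effects <- function(effects) {
  long <- purrr::map_dfr(c("direct", "indirect", "total"), function(kind) {
    tibble(term = effects$term, kind = kind,
           estimate = effects[[kind]], se = effects[[paste0(kind, "_se")]])
  })
  ggplot2::ggplot(long, ggplot2::aes(.data$estimate, .data$term,
                                     colour = .data$kind)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$estimate - 1.96 * .data$se,
                   xmax = .data$estimate + 1.96 * .data$se),
      height = 0.2, position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::labs(x = "effect on outcome", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
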