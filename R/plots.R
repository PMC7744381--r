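#' Plot standardized loadings of a fitted model
#'
#' Loading profile over the item positions; items from columns with missing
#' data (if any) are highlighted.
#'
#' @param object A [fit_cfa()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mdcfa_fit <- function(object, ...) {
  df <- tidy(object)
  df$position <- seq_len(nrow(df))
  miss_cols <- if (!is.null(object$spec$design)) object$spec$design$columns else integer()
  df$group <- ifelse(df$position %in% miss_cols, "with missing data", "complete")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$standardized)) +
    ggplot2::geom_line(color = "grey50") +
    ggplot2::geom_point(ggplot2::aes(color = .data$group), size = 2) +
    ggplot2::geom_hline(yintercept = object$spec$lambda_genuine[1],
                        linetype = "dashed") +
    ggplot2::labs(x = "item position", y = "standardized loading",
                  color = NULL,
                  title = sprintf("%s model", object$spec$kind)) +
    ggplot2::theme_minimal()
}

#' Plot Monte Carlo study results
#'
#' `type = "fit"` shows the mean fit statistics against the missing
#' percentage per model and column set; `type = "loadings"` the mean
#' standardized loadings with the expected value as reference; `type =
#' "curves"` the per-item mean loading curves.
#'
#' @param object A [run_study()] result.
#' @param type `"fit"`, `"loadings"` or `"curves"`.
#' @param statistic Fit statistic for `type = "fit"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mdcfa_study <- function(object, type = c("fit", "loadings", "curves"),
                                 statistic = "chi2", ...) {
  type <- match.arg(type)
  if (type == "fit") {
    df <- dplyr::filter(object$fit, .data$item_range != "none")
    ggplot2::ggplot(df, ggplot2::aes(x = 100 * .data$percent,
                                     y = .data[[statistic]],
                                     color = .data$model)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::facet_wrap(~ .data$item_range) +
      ggplot2::labs(x = "% missing in selected columns", y = statistic,
                    color = NULL) +
      ggplot2::theme_minimal()
  } else if (type == "loadings") {
    ggplot2::ggplot(object$loadings,
                    ggplot2::aes(x = 100 * .data$percent, y = .data$mean_std,
                                 color = .data$model)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::geom_hline(yintercept = object$config$loading,
                          linetype = "dashed") +
      ggplot2::facet_wrap(~ .data$item_range) +
      ggplot2::labs(x = "% missing in selected columns",
                    y = "mean standardized loading", color = NULL) +
      ggplot2::theme_minimal()
  } else {
    plot_loading_curves(object)
  }
}

#' Per-item mean loading curves of a study
#'
#' One panel per model and column set, one curve per missing percentage —
#' the per-item view in which size equivalence (all items loading equally)
#' or its failure is visible.
#'
#' @param study A [run_study()] result.
#' @param item_range Optional column-set label to restrict to.
#' @return A ggplot object.
#' @export
plot_loading_curves <- function(study, item_range = NULL) {
  df <- study$curves
  if (!is.null(item_range)) {
    df <- dplyr::filter(df, .data$item_range %in% !!item_range)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$mean_std,
                                   color = factor(100 * .data$percent),
                                   group = .data$percent)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = study$config$loading,
                        linetype = "dashed") +
    ggplot2::facet_grid(.data$item_range ~ .data$model) +
    ggplot2::labs(x = "item position", y = "mean standardized loading",
                  color = "% missing") +
    ggplot2::theme_minimal()
}
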