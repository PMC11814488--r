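#' Plot methods
#'
#' `autoplot()` methods for the package's result types: training curves for
#' fits, F1-vs-fraction curves for rankings, subsite ratio profiles, and
#' top-feature importance charts.
#'
#' @param object Result object.
#' @param ... Unused.
#' @return A ggplot.
#' @name oglcnac-plots
NULL

#' @rdname oglcnac-plots
#' @export
autoplot.srnn_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$training_log, -"epoch",
                            names_to = "series", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed") +
    ggplot2::labs(x = "epoch", y = "loss",
                  title = "Training and validation loss",
                  subtitle = sprintf("best validation epoch: %d",
                                     object$best_epoch)) +
    ggplot2::theme_minimal()
}

#' @rdname oglcnac-plots
#' @export
autoplot.ranking_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fraction,
                                       y = 100 * .data$f1)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 100 * attr(object, "baseline_f1"),
                        linetype = "dotted") +
    ggplot2::labs(x = "fraction of top-ranked features", y = "F1 (%)",
                  title = "F1 across top-ranked feature fractions",
                  subtitle = "dotted line: all features, no regularization") +
    ggplot2::theme_minimal()
}

#' @rdname oglcnac-plots
#' @export
autoplot.ratio_profile <- function(object, ...) {
  df <- object[object$flag == "ok", , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$ratio)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(-1, 1), linetype = "dotted") +
    ggplot2::labs(x = "subsite position", y = "mean-value ratio (signed)",
                  title = attr(object, "feature")) +
    ggplot2::theme_minimal()
}

#' @rdname oglcnac-plots
#' @param n_top Number of top features to show.
#' @export
autoplot.feature_ranking <- function(object, n_top = 20, ...) {
  df <- head(object, n_top)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "input-group weight norm", y = NULL,
                  title = sprintf("Top %d features", nrow(df))) +
    ggplot2::theme_minimal()
}
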