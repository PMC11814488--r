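#' Tidy and glance methods
#'
#' broom-style accessors: `tidy()` on a fit returns the weight-based
#' feature importance ranking; `glance()` a one-row training summary.
#' On a Monte-Carlo cross-validation result, `tidy()` returns the
#' per-repeat metrics and `glance()` the mean/sd summary in wide form.
#'
#' @param x An `srnn_fit` or `og_mccv` object.
#' @param ... Unused.
#' @return A tibble.
#' @name oglcnac-tidiers
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname oglcnac-tidiers
#' @export
tidy.srnn_fit <- function(x, ...) {
  feature_importance(x)
}

#' @rdname oglcnac-tidiers
#' @export
glance.srnn_fit <- function(x, ...) {
  tibble::tibble(
    n_parameters = length(flatten_params(x$params)),
    stopped_epoch = x$stopped_epoch,
    best_epoch = x$best_epoch,
    train_loss = x$training_log$train_loss[x$best_epoch],
    val_loss = min(x$training_log$val_loss),
    lambda = x$spec$lambda,
    reg_input = x$spec$reg_input,
    reg_hidden = x$spec$reg_hidden)
}

#' @rdname oglcnac-tidiers
#' @export
tidy.og_mccv <- function(x, ...) {
  x$per_repeat
}

#' @rdname oglcnac-tidiers
#' @export
glance.og_mccv <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$summary, names_from = "metric",
                             values_from = c("mean", "sd"))
  dplyr::bind_cols(tibble::tibble(repeats = nrow(x$per_repeat)), wide)
}
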