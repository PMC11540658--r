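#' Compare predicted trait values with ground truth
#'
#' The evaluation harness used throughout: R-squared computed as
#' `1 - SS_res / SS_tot` about the truth mean (the predicted-vs-truth
#' convention; the squared Pearson correlation is also reported for
#' users who expect that definition) and MAPE, the mean of
#' `|pred - truth| / |truth|`. Pairs with zero truth are excluded from
#' MAPE with a warning.
#'
#' @param predicted,truth numeric vectors of equal length >= 2.
#' @return An `eval_summary`: `r_squared`, `pearson_r2`, `mape`, `n`,
#'   and the pair table in `$data`.
#' @examples
#' evaluate(c(1.1, 2.2, 3.3), c(1, 2, 3))
#' @export
evaluate <- function(predicted, truth) {
  predicted <- as.numeric(predicted)
  truth <- as.numeric(truth)
  if (length(predicted) != length(truth)) {
    stop("predicted and truth must have equal length (",
         length(predicted), " vs ", length(truth), ")")
  }
  if (length(truth) < 2) stop("need at least 2 pairs")
  if (any(!is.finite(predicted)) || any(!is.finite(truth))) {
    stop("non-finite values in predicted/truth")
  }
  nz <- truth != 0
  if (!all(nz)) {
    warning(sum(!nz), " pair(s) with zero truth excluded from MAPE")
  }
  mape <- mean(abs(predicted[nz] - truth[nz]) / abs(truth[nz]))
  r2 <- r_squared(predicted, truth)
  pr2 <- if (stats::sd(predicted) == 0 || stats::sd(truth) == 0) {
    NA_real_
  } else {
    stats::cor(predicted, truth)^2
  }
  structure(
    list(r_squared = r2, pearson_r2 = pr2, mape = mape,
         n = length(truth),
         data = tibble::tibble(predicted = predicted, truth = truth)),
    class = "eval_summary"
  )
}

#' @export
print.eval_summary <- function(x, ...) {
  cat(sprintf("# eval_summary: n = %d, R^2 = %.4f, MAPE = %.4f\n",
              x$n, x$r_squared, x$mape))
  invisible(x)
}

#' Glance at an evaluation summary
#' @param x an `eval_summary`.
#' @param ... unused.
#' @return One-row tibble: `r_squared`, `pearson_r2`, `mape`, `n`.
#' @method glance eval_summary
#' @export
glance.eval_summary <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, pearson_r2 = x$pearson_r2,
                 mape = x$mape, n = x$n)
}

#' Tidy an evaluation summary
#' @param x an `eval_summary`.
#' @param ... unused.
#' @return The pair table with per-pair absolute percentage error.
#' @method tidy eval_summary
#' @export
tidy.eval_summary <- function(x, ...) {
  dplyr::mutate(
    x$data,
    ape = ifelse(.data$truth == 0, NA_real_,
                 abs(.data$predicted - .data$truth) / abs(.data$truth))
  )
}

#' Predicted-versus-truth scatter plot of an evaluation summary
#'
#' @param object an `eval_summary`.
#' @param ... unused.
#' @return A ggplot: pairs against the identity line, annotated with
#'   R-squared and MAPE.
#' @method autoplot eval_summary
#' @export
autoplot.eval_summary <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$truth, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = "ground truth", y = "predicted",
      subtitle = sprintf("n = %d, R² = %.3f, MAPE = %.3f",
                         object$n, object$r_squared, object$mape)) +
    ggplot2::theme_minimal()
}

#' Write an evaluation summary as JSON
#'
#' @param x an `eval_summary`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_eval_summary <- function(x, path) {
  stopifnot(inherits(x, "eval_summary"))
  jsonlite::write_json(
    list(r_squared = x$r_squared, pearson_r2 = x$pearson_r2,
         mape = x$mape, n = x$n),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
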