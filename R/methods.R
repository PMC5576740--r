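#' @export
print.nmf_lp_fit <- function(x, ...) {
  cat("<nmf_lp_fit> ", length(x$node_ids), " nodes, k = ", x$k,
      " (", x$mode, " mode)\n", sep = "")
  last <- x$history[nrow(x$history), ]
  cat("  ", nrow(x$history), " iterations, stopped by ", x$stopped_by,
      if (!x$converged) " (not converged)", "\n", sep = "")
  cat("  objective ", format(last$objective, digits = 6),
      ", reconstruction error ", format(last$recon_error, digits = 6),
      "\n", sep = "")
  invisible(x)
}

#' Per-iteration optimization trace of a fitted model
#'
#' @param x An `nmf_lp_fit`.
#' @param ... Unused.
#' @return A tibble with one row per iteration: `iteration`, `objective`
#'   (the joint objective J) and `recon_error` (`||A - UV||_F^2`).
#' @method tidy nmf_lp_fit
#' @export
tidy.nmf_lp_fit <- function(x, ...) {
  x$history
}

#' One-row summary of a fitted model
#'
#' @param x An `nmf_lp_fit`.
#' @param ... Unused.
#' @return A one-row tibble: problem sizes, penalty weights, iteration count,
#'   final objective and reconstruction error, convergence flag and the
#'   stopping rule that fired.
#' @method glance nmf_lp_fit
#' @export
glance.nmf_lp_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble::tibble(
    n = length(x$node_ids),
    k = x$k,
    mode = x$mode,
    lambda = x$config$lambda,
    mu = x$config$mu,
    iterations = nrow(x$history),
    objective = last$objective,
    recon_error = last$recon_error,
    converged = x$converged,
    stopped_by = x$stopped_by
  )
}

#' Plot the optimization trace of a fitted model
#'
#' Draws the joint objective and the adjacency reconstruction error against
#' the iteration number, on a log10 y scale.
#'
#' @param object An `nmf_lp_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nmf_lp_fit
#' @export
autoplot.nmf_lp_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, -"iteration",
                              names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$iteration, .data$value,
                                     colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-fold benchmark results
#'
#' @param object An `lp_benchmark` tibble from [run_benchmark()].
#' @param ... Unused.
#' @return A ggplot object showing per-fold AUC by method.
#' @method autoplot lp_benchmark
#' @export
autoplot.lp_benchmark <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    stats::reorder(.data$method, .data$auc, FUN = mean), .data$auc)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "fold AUC") +
    ggplot2::theme_minimal()
}
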