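#' Plot a fitted coefficient tensor (2-D grids)
#'
#' Heatmap of the posterior-mean image coefficient; screened voxels show as
#' exact zeros.
#'
#' @param object A `"btr_fit"` with a 2-D image grid.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.btr_fit <- function(object, ...) {
  if (object$dims$D != 2 || is.null(object$B))
    stop("autoplot.btr_fit currently draws 2-D coefficient maps", call. = FALSE)
  df <- tibble::tibble(
    row = rep(seq_len(object$dims$p[1]), times = object$dims$p[2]),
    col = rep(seq_len(object$dims$p[2]), each = object$dims$p[1]),
    value = as.vector(object$B))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "B",
                  title = "Posterior-mean image coefficient") +
    ggplot2::theme_minimal()
}

#' DIC trace across candidate ranks
#'
#' @param rank_result The list returned by [select_rank()].
#' @return A ggplot object.
#' @export
plot_dic_trace <- function(rank_result) {
  ggplot2::ggplot(rank_result$dic_table, ggplot2::aes(x = .data$rank, y = .data$dic)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_point(data = dplyr::filter(rank_result$dic_table,
                                             .data$rank == rank_result$best_rank),
                        colour = "red", size = 3) +
    ggplot2::labs(x = "tensor rank", y = "DIC") +
    ggplot2::theme_minimal()
}

#' Trace plots of monitored chains
#'
#' @param object A `"btr_fit"` or `"btr_draws"`.
#' @param params Parameter blocks passed to [tidy_draws()].
#' @return A ggplot object.
#' @export
plot_trace <- function(object, params = c("sigma2", "tau")) {
  ggplot2::ggplot(tidy_draws(object, params),
                  ggplot2::aes(x = .data$draw, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "stored draw", y = NULL) +
    ggplot2::theme_minimal()
}

#' RRMSE comparison plot
#'
#' @param eval_table Output of [evaluate_methods()].
#' @return A ggplot object.
#' @export
plot_rrmse <- function(eval_table) {
  ggplot2::ggplot(eval_table, ggplot2::aes(x = .data$method, y = .data$rrmse)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = NULL, y = "relative RMSE") +
    ggplot2::theme_minimal()
}
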