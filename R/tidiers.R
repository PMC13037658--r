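#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an inversion result
#'
#' One row per free-energy term plus the hyperparameters, in long form.
#'
#' @param x an `inversion_result`.
#' @param ... unused.
#' @return a tibble with `term`, `value`.
#' @method tidy inversion_result
#' @export
tidy.inversion_result <- function(x, ...) {
  tibble::tibble(
    term = c(names(x$F_terms), paste0("lambda_", seq_along(x$lambda))),
    value = c(unname(x$F_terms), unname(x$lambda))
  )
}

#' One-line summary of an inversion result
#'
#' @param x an `inversion_result`.
#' @param ... unused.
#' @return a one-row tibble: `method`, `free_energy`, `n_components`,
#'   `converged`, `n_iter`, `n_active_patches`.
#' @method glance inversion_result
#' @export
glance.inversion_result <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    free_energy = x$F,
    n_components = length(x$lambda),
    converged = x$converged,
    n_iter = x$n_iter,
    n_active_patches = if (is.null(x$active_patches)) NA_integer_ else
      length(x$active_patches)
  )
}

#' Tidy a benchmark result
#'
#' @param x a `benchmark_result`.
#' @param ... unused.
#' @return the per-step metric curve tibble.
#' @method tidy benchmark_result
#' @export
tidy.benchmark_result <- function(x, ...) x$curves

#' Summarise a benchmark result
#'
#' @param x a `benchmark_result`.
#' @param ... unused.
#' @return the method-by-metric summary tibble (mean distortion score and
#'   chance level when nulls were run).
#' @method glance benchmark_result
#' @export
glance.benchmark_result <- function(x, ...) x$summary

#' Plot metric-versus-distortion curves
#'
#' Draws the fit metric against millimetres of distortion for each
#' trajectory seed, one panel per metric, with the per-curve peak marked.
#'
#' @param object a tibble of [sweep_trajectory()] rows (possibly several
#'   seeds/metrics) or a `benchmark_result`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot benchmark_result
#' @export
autoplot.benchmark_result <- function(object, ...) {
  plot_metric_curves(object$curves)
}

#' @rdname autoplot.benchmark_result
#' @export
plot_metric_curves <- function(object, ...) {
  curves <- if (inherits(object, "benchmark_result")) object$curves else object
  peaks <- curves |>
    dplyr::group_by(.data$method, .data$metric, .data$trajectory_seed) |>
    dplyr::group_modify(function(df, key) {
      pk <- find_peak(df)
      df[which(df$distortion_mm == pk)[1], c("distortion_mm", "value")]
    }) |>
    dplyr::ungroup()
  ggplot2::ggplot(curves, ggplot2::aes(
    x = .data$distortion_mm, y = .data$value,
    group = interaction(.data$trajectory_seed, .data$method),
    colour = .data$method)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(data = peaks, shape = 18, size = 3) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "distortion (mm, mean vertex-vertex distance)",
                  y = "fit metric") +
    ggplot2::theme_minimal()
}

#' Plot distortion scores against chance
#'
#' Mean distortion score per method/metric with the permuted-lead-field
#' chance level (when available) as a dashed line.
#'
#' @param result a `benchmark_result`.
#' @return a ggplot.
#' @export
plot_distortion_scores <- function(result) {
  stopifnot(inherits(result, "benchmark_result"))
  p <- ggplot2::ggplot(result$summary, ggplot2::aes(
    x = .data$method, y = .data$mean_score_mm, fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "mean peak distortion (mm)") +
    ggplot2::theme_minimal()
  if (!is.null(result$summary$chance_mm)) {
    p <- p + ggplot2::geom_hline(
      yintercept = result$summary$chance_mm[1], linetype = "dashed")
  }
  p
}
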