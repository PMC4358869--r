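#' Plot LD decay
#' @param object a `gs_ld_decay` from [ld_decay()].
#' @param ... unused.
#' @export
autoplot.gs_ld_decay <- function(object, ...) {
  ggplot2::ggplot(object[!is.na(object$mean_r2), ],
                  ggplot2::aes(x = .data$bin_cm + 0.5, y = .data$mean_r2)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "distance (cM)", y = expression(mean ~ r^2),
                  title = "LD decay") +
    ggplot2::theme_minimal()
}

#' Plot between-breed persistence of LD phase
#' @param object a `gs_phase` from [phase_persistence()].
#' @param ... unused.
#' @export
autoplot.gs_phase <- function(object, ...) {
  ggplot2::ggplot(object[!is.na(object$R_AB), ],
                  ggplot2::aes(x = .data$bin_cm + 0.5, y = .data$R_AB)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "distance (cM)", y = expression(R[AB]),
                  title = "Persistence of LD phase") +
    ggplot2::theme_minimal()
}

#' Plot study response and accuracy trajectories
#'
#' @param object a `gs_study` from [run_study()].
#' @param metric which aggregated mean to draw, e.g. `"crossbred_mean"`,
#'   `"heterosis"`, `"breed_average"`, `"acc_A"`.
#' @param ... unused.
#' @export
autoplot.gs_study <- function(object, metric = "crossbred_mean", ...) {
  if (is.null(object$summary)) abort("study has no aggregated summary")
  mcol <- paste0(metric, "_mean")
  scol <- paste0(metric, "_se")
  if (!mcol %in% names(object$summary))
    abort(sprintf("unknown metric `%s`", metric))
  df <- object$summary
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generation, y = .data[[mcol]],
                                   colour = .data$scenario)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data[[mcol]] - .data[[scol]],
      ymax = .data[[mcol]] + .data[[scol]])) +
    ggplot2::labs(x = "generation", y = metric, colour = "scenario") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
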