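# ggplot2 views of the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Observed-vs-fitted plot of a fitted QSAR model
#'
#' @param object a `qsar_model` produced by [fit_mlr()] (published models
#'   carry no training data to plot).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.qsar_model <- function(object, ...) {
  if (is.null(object$fit)) {
    stop("no training data stored with this model (published models are ",
         "fixed predictors); plot predictions instead", call. = FALSE)
  }
  df <- tibble::tibble(
    observed = object$fit$model[[1]],
    fitted = stats::fitted(object$fit)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fitted, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = paste("fitted", object$response),
      y = paste("observed", object$response),
      title = sprintf("R2 = %.2f, Q2 = %.2f (n = %d)",
                      object$metrics$r_squared,
                      object$metrics$q_squared %||% NA,
                      object$metrics$n)
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of a correlation scan
#'
#' R-squared per score column (and condition, if present), mirroring the
#' layout of a flexibility-by-condition correlation table; the best cell is
#' outlined.
#'
#' @param scan result of [correlation_scan()].
#' @return a ggplot.
#' @export
plot_correlation_scan <- function(scan) {
  cond_cols <- setdiff(names(scan),
                       c("score", "r", "r_squared", "p_value", "n",
                         "slope_sign", "best"))
  scan$condition <- if (length(cond_cols)) {
    do.call(paste, c(scan[cond_cols], sep = " / "))
  } else "all"
  ggplot2::ggplot(scan, ggplot2::aes(x = .data$score, y = .data$condition,
                                     fill = .data$r_squared)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = scan[scan$best, ], fill = NA,
                       colour = "black", linewidth = 1) +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f\n(%.2g)", .data$r_squared, .data$p_value)),
      size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7fb8",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "score column", y = NULL, fill = "R²") +
    ggplot2::theme_minimal()
}

#' Plot one or two hydropathy profiles with difference regions
#'
#' @param p1 profile from [hydropathy_profile()].
#' @param p2 optional second profile on the same coordinates.
#' @param regions optional regions tibble from [hydropathy_diff_regions()],
#'   shaded.
#' @return a ggplot.
#' @export
plot_hydropathy <- function(p1, p2 = NULL, regions = NULL) {
  df <- dplyr::bind_rows(
    dplyr::mutate(p1, sequence = "seq1"),
    if (!is.null(p2)) dplyr::mutate(p2, sequence = "seq2")
  )
  g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                        y = .data$hydropathy,
                                        colour = .data$sequence))
  if (!is.null(regions) && nrow(regions) > 0) {
    g <- g + ggplot2::geom_rect(
      data = regions, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf),
      fill = "grey85")
  }
  g + ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "window start position",
                  y = "Kyte-Doolittle hydropathy") +
    ggplot2::theme_minimal()
}

#' Donor-distance distribution with the active-pose threshold
#'
#' @param fingerprints tibble with columns `donor_distance` and `is_active`
#'   (e.g. the pipeline's `fingerprints.csv`).
#' @param threshold active-pose cutoff to draw (default 5).
#' @return a ggplot.
#' @export
plot_active_poses <- function(fingerprints, threshold = 5.0) {
  ggplot2::ggplot(fingerprints,
                  ggplot2::aes(x = .data$donor_distance,
                               fill = .data$is_active)) +
    ggplot2::geom_histogram(binwidth = 0.25, boundary = 0) +
    ggplot2::geom_vline(xintercept = threshold, linetype = 2) +
    ggplot2::labs(x = "donor to His Nε-H distance (Å)",
                  y = "poses", fill = "active") +
    ggplot2::theme_minimal()
}
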