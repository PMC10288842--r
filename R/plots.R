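#' Plot a Kaplan-Meier curve
#'
#' Step curve with a pointwise 95% confidence ribbon and censoring ticks;
#' grouped fits are coloured by stratum.
#'
#' @param object An `mtv_km` from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mtv_km
#' @export
autoplot.mtv_km <- function(object, ...) {
  tb <- tidy(object)
  grouped <- "strata" %in% names(tb)
  add_origin <- function(d) {
    dplyr::bind_rows(
      dplyr::slice(d, 1) |>
        dplyr::mutate(time = 0, estimate = 1, conf.low = 1, conf.high = 1,
          n.censor = 0),
      d)
  }
  tb <- if (grouped) {
    tb |> dplyr::group_by(.data$strata) |>
      dplyr::group_modify(~ add_origin(.x)) |> dplyr::ungroup()
  } else {
    add_origin(tb)
  }
  p <- if (grouped) {
    ggplot2::ggplot(tb, ggplot2::aes(.data$time, .data$estimate,
      colour = .data$strata, fill = .data$strata))
  } else {
    ggplot2::ggplot(tb, ggplot2::aes(.data$time, .data$estimate))
  }
  p +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low,
      ymax = .data$conf.high), alpha = 0.15, colour = NA) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::geom_point(data = dplyr::filter(tb, .data$n.censor > 0),
      shape = 3, size = 1.5) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Overall survival") +
    ggplot2::theme_minimal()
}

#' Plot a fixed-horizon ROC curve
#'
#' Empirical ROC with the chance diagonal and the Youden-optimal operating
#' point marked.
#'
#' @param object An `mtv_roc` from [roc_fixed_horizon()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mtv_roc
#' @export
autoplot.mtv_roc <- function(object, ...) {
  tb <- tidy(object) |> dplyr::arrange(1 - .data$specificity, .data$sensitivity)
  opt <- tibble(fpr = 1 - object$specificity, tpr = object$sensitivity)
  ggplot2::ggplot(tb, ggplot2::aes(1 - .data$specificity, .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
      colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::geom_point(data = opt, ggplot2::aes(.data$fpr, .data$tpr),
      colour = "red", size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("%s, %g-month horizon", object$marker, object$horizon),
      subtitle = sprintf("AUC %.3f (95%% CI %.3f-%.3f); cutoff > %.4g",
        object$auc, object$auc_ci95[1], object$auc_ci95[2], object$cutoff)) +
    ggplot2::theme_minimal()
}

#' Plot an axial slice of a PET volume with lesion outlines
#'
#' @param volume A [pet_volume()].
#' @param k Axial slice index (third array dimension); defaults to the
#'   middle slice.
#' @param seg Optional `mtv_segmentation` whose labelled voxels are
#'   outlined on the slice.
#' @return A ggplot object.
#' @export
plot_pet_slice <- function(volume, k = NULL, seg = NULL) {
  stopifnot(inherits(volume, "pet_volume"))
  d <- dim(volume)
  if (is.null(k)) k <- ceiling(d[3] / 2)
  sp <- attr(volume, "spacing")
  slc <- volume[, , k]
  df <- expand.grid(x = (seq_len(d[1]) - 0.5) * sp[1],
    y = (seq_len(d[2]) - 0.5) * sp[2])
  df$suv <- as.vector(slc)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$suv)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "magma", name = "SUV") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
      title = sprintf("Axial slice k = %d", k)) +
    ggplot2::theme_minimal()
  if (!is.null(seg)) {
    lab <- seg$labels[, , k]
    if (any(lab > 0)) {
      df$lesion <- as.vector(lab) > 0
      p <- p + ggplot2::geom_tile(
        data = dplyr::filter(df, .data$lesion),
        fill = NA, colour = "cyan", linewidth = 0.2)
    }
  }
  p
}
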