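# ggplot2 display helpers.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

.raster_df <- function(m, spacing = c(1, 1)) {
  tibble::tibble(
    axial_mm = rep((seq_len(nrow(m)) - 0.5) * spacing[1], ncol(m)),
    lateral_mm = rep((seq_len(ncol(m)) - 0.5) * spacing[2],
                     each = nrow(m)),
    value = as.vector(m)
  )
}

#' Plot a reconstructed image
#'
#' @param object A `recon_image`.
#' @param ... Unused.
#' @return A ggplot raster in mm coordinates (depth increasing downward).
#' @export
autoplot.recon_image <- function(object, ...) {
  sp <- object$spacing
  if (anyNA(sp)) sp <- c(1, 1)
  df <- .raster_df(object$pixels, sp)
  ggplot2::ggplot(df, ggplot2::aes(.data$lateral_mm, .data$axial_mm,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = if (object$kind == "bmode")
      "cividis" else "inferno") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "lateral (mm)", y = "depth (mm)",
                  fill = object$kind,
                  title = toupper(gsub("_star", "*", object$kind))) +
    ggplot2::theme_minimal()
}

#' Plot a thresholded BURST*-over-B-mode overlay
#'
#' Gray anatomical B-mode with the suprathreshold BURST* pixels in a hot
#' scale, both in dB.
#'
#' @param object An [overlay()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.overlay_image <- function(object, ...) {
  bm <- .raster_df(object$bmode_db)
  bs <- .raster_df(object$burst_db)
  bs <- bs[!is.na(bs$value), , drop = FALSE]
  p <- ggplot2::ggplot(bm, ggplot2::aes(.data$lateral_mm, .data$axial_mm)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 na.value = "black", name = "B-mode (dB)")
  if (nrow(bs) > 0) {
    p <- p +
      ggplot2::geom_point(data = bs, ggplot2::aes(colour = .data$value),
                          shape = 15, size = 1.5) +
      ggplot2::scale_colour_gradient(low = "red", high = "yellow",
                                     name = "BURST* (dB)")
  }
  p + ggplot2::coord_equal() +
    ggplot2::labs(x = "position (px)", y = "position (px)") +
    ggplot2::theme_minimal()
}

#' Plot a Hill fit with its data
#'
#' Replicate points, condition means, and the fitted curve on a log
#' concentration axis (zero doses shown at the lowest positive tick).
#'
#' @param object A [fit_hill()] result.
#' @param n_curve Points along the fitted curve.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hill_fit <- function(object, n_curve = 200, ...) {
  dat <- object$data
  pos <- dat$concentration[dat$concentration > 0]
  floor_c <- if (length(pos)) min(pos) / 3 else 1
  dat$conc_plot <- pmax(dat$concentration, floor_c)
  p <- ggplot2::ggplot(dat, ggplot2::aes(.data$conc_plot, .data$response)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration (uM)", y = "response") +
    ggplot2::theme_minimal()
  if (object$identifiable) {
    grid <- tibble::tibble(
      concentration = exp(seq(log(floor_c), log(max(pos)),
                              length.out = n_curve)))
    grid$response <- predict(object, grid)
    grid$conc_plot <- grid$concentration
    p <- p + ggplot2::geom_line(data = grid, colour = "firebrick")
  }
  p
}

#' Plot an ex vivo length profile
#'
#' @param profile An [ex_vivo_profile()] tibble.
#' @return A ggplot of integrated BURST* signal against signed length from
#'   the landmark.
#' @export
plot_length_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(.data$length_mm,
                                        .data$burst_star)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "length relative to landmark (mm)",
                  y = "integrated BURST* signal") +
    ggplot2::theme_minimal()
}
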