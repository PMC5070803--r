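#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Plot a FRAP recovery curve with its fit
#' @param object A `frap_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.frap_fit <- function(object, ...) {
  stopifnot(object$converged)
  grid <- tibble::tibble(
    time_s = seq(0, max(object$curve$time_s), length.out = 200)
  )
  grid$fit <- predict(object, grid)
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$time_s, .data$intensity)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fit),
                       colour = "firebrick", linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = object$f0 + object$plateau_gain,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "time post-bleach (s)", y = "normalized intensity",
                  title = sprintf("mobile fraction %.2f, t1/2 %.3g s",
                                  object$mobile_fraction, object$t_half)) +
    ggplot2::theme_minimal()
}

#' Plot a recovery curve
#' @param object A `recovery_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.recovery_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_s, .data$intensity)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::labs(x = "time from bleach (s)", y = "normalized intensity") +
    ggplot2::theme_minimal()
}

#' Plot a ring intensity profile
#' @param object A `ring_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ring_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$r_um, .data$mean_intensity)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "distance from ROI edge (um)",
                  y = "mean normalized intensity") +
    ggplot2::theme_minimal()
}

#' Plot spreading width against time post-activation
#' @param object A `spreading_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spreading_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_s, .data$width_um)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$out_of_support)) +
    ggplot2::labs(x = "time post-activation (s)", y = "spreading width (um)") +
    ggplot2::theme_minimal()
}

#' Plot a kymograph
#' @param object A `kymograph`.
#' @param ... Unused.
#' @return A ggplot (time on y, arclength on x).
#' @export
autoplot.kymograph <- function(object, ...) {
  df <- tidyr::expand_grid(
    time_s = (seq_len(nrow(object$data)) - 1) * object$frame_interval,
    arclength_um = object$arclength_um
  )
  df$intensity <- as.vector(t(object$data))
  ggplot2::ggplot(df, ggplot2::aes(.data$arclength_um, .data$time_s,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "arclength (um)", y = "time (s)") +
    ggplot2::theme_minimal()
}

#' Rose plot of origin-translated tracks
#'
#' All tracks translated to a common origin, coloured by net displacement —
#' the standard presentation of spot mobility cohorts.
#'
#' @param tracks A linked spot tibble (see [link_tracks()]).
#' @return A ggplot.
#' @export
plot_tracks <- function(tracks) {
  tr <- translate_to_origin(tracks)
  disp <- tr |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(displacement_um = sqrt(dplyr::last(.data$x_rel_um)^2 +
                                              dplyr::last(.data$y_rel_um)^2),
                     .groups = "drop")
  tr <- dplyr::left_join(tr, disp, by = "track_id")
  ggplot2::ggplot(tr, ggplot2::aes(.data$x_rel_um, .data$y_rel_um,
                                   group = .data$track_id,
                                   colour = .data$displacement_um)) +
    ggplot2::geom_path(alpha = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::scale_colour_viridis_c(name = "displacement (um)") +
    ggplot2::labs(x = "x (um)", y = "y (um)") +
    ggplot2::theme_minimal()
}
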