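#' Simulate filaments elongating from fixed nodes
#'
#' Each filament is a straight segment anchored at its origin whose tip
#' advances at a constant rate (nm/s), rendered frame by frame as a
#' PSF-blurred line plus camera noise. Filaments start with a resolvable
#' `initial_length` so that the half-maximum tip front used by
#' [estimate_tip_velocity()] tracks the true tip rather than the blurred
#' centroid of a sub-resolution object; the growth increment is exactly
#' `rate * elapsed_time`.
#'
#' @inheritParams simulate_photoactivation
#' @param n_filaments Number of filaments.
#' @param rate Elongation rate in nm/s (>= 0).
#' @param origins Optional two-column matrix of origins (um). Defaults to a
#'   grid with enough clearance for the full grown length.
#' @param directions Optional vector of direction angles (radians). Defaults
#'   to random directions.
#' @param durations Growth duration per filament, s. Defaults to the full
#'   acquisition.
#' @param initial_length Filament length at frame 1, um.
#' @param amplitude Peak intensity of the rendered line.
#'
#' @return A list with `stack` and `truth` (tibble: `filament`, `frame`,
#'   `time_s`, `tip_um` arclength, plus per-filament `origin_x`, `origin_y`,
#'   `dir_x`, `dir_y`, `rate_nm_s`).
#' @export
simulate_growing_filaments <- function(params, n_filaments, rate,
                                       origins = NULL, directions = NULL,
                                       durations = NULL, initial_length = 2,
                                       amplitude = 1) {
  stopifnot(inherits(params, "sim_params"))
  if (rate < 0) stop("`rate` must be non-negative", call. = FALSE)
  rate_um <- rate / 1000
  n_t <- params$n_frames
  t_total <- (n_t - 1) * params$frame_interval
  if (is.null(durations)) durations <- rep(t_total, n_filaments)
  durations <- rep_len(durations, n_filaments)
  max_len <- initial_length + rate_um * max(durations)

  w_um <- (params$image_shape[2L] - 1) * params$pixel_size
  h_um <- (params$image_shape[1L] - 1) * params$pixel_size
  margin <- 4 * params$psf_sigma

  .with_seed(.substream_seed(params$seed, 211L), {
    if (is.null(directions)) directions <- stats::runif(n_filaments, 0, 2 * pi)
    directions <- rep_len(directions, n_filaments)
    if (is.null(origins)) {
      # grid with one full grown length + margin of clearance per cell
      pitch <- 2 * (max_len + margin)
      ncol_g <- max(1L, floor(w_um / pitch))
      nrow_g <- ceiling(n_filaments / ncol_g)
      if (nrow_g * pitch > h_um) {
        stop("image too small to place the requested filaments", call. = FALSE)
      }
      k <- seq_len(n_filaments) - 1L
      origins <- cbind(
        (k %% ncol_g) * pitch + pitch / 2,
        (k %/% ncol_g) * pitch + pitch / 2
      )
    }
    stopifnot(nrow(origins) == n_filaments)

    dx <- cos(directions); dy <- sin(directions)
    # truncate filaments that would leave the field of view
    for (i in seq_len(n_filaments)) {
      tip_x <- origins[i, 1L] + dx[i] * max_len
      tip_y <- origins[i, 2L] + dy[i] * max_len
      if (tip_x < margin || tip_x > w_um - margin ||
          tip_y < margin || tip_y > h_um - margin) {
        room <- max_len
        for (lim in c((margin - origins[i, 1L]) / dx[i],
                      (w_um - margin - origins[i, 1L]) / dx[i],
                      (margin - origins[i, 2L]) / dy[i],
                      (h_um - margin - origins[i, 2L]) / dy[i])) {
          if (is.finite(lim) && lim > 0) room <- min(room, lim)
        }
        durations[i] <- max(0, (room - initial_length) / max(rate_um, 1e-12))
        warning(sprintf("filament %d would leave the field of view; growth truncated at %.2f s",
                        i, durations[i]), call. = FALSE)
      }
    }

    times <- (seq_len(n_t) - 1) * params$frame_interval
    tips <- outer(times, durations, pmin) * rate_um + initial_length  # T x F

    # line density so that the blurred peak of a long filament is `amplitude`
    sig_px <- params$psf_sigma / params$pixel_size
    spacing <- params$pixel_size / 4
    w_sample <- amplitude * sig_px * sqrt(2 * pi) * (spacing / params$pixel_size)

    frames <- array(0, c(n_t, params$image_shape))
    for (t in seq_len(n_t)) {
      px <- numeric(0); py <- numeric(0)
      for (i in seq_len(n_filaments)) {
        s <- seq(0, tips[t, i], by = spacing)
        px <- c(px, origins[i, 1L] + dx[i] * s)
        py <- c(py, origins[i, 2L] + dy[i] * s)
      }
      img <- .render_points(px, py, rep(w_sample, length(px)), params)
      frames[t, , ] <- .add_noise(img, params)
    }

    truth <- tibble::tibble(
      filament = rep(seq_len(n_filaments), each = n_t),
      frame = rep(seq_len(n_t), n_filaments),
      time_s = rep(times, n_filaments),
      tip_um = as.vector(tips),
      origin_x = rep(origins[, 1L], each = n_t),
      origin_y = rep(origins[, 2L], each = n_t),
      dir_x = rep(dx, each = n_t),
      dir_y = rep(dy, each = n_t),
      rate_nm_s = rate
    )
    list(stack = image_stack(frames, params$pixel_size, params$frame_interval),
         truth = truth)
  })
}

#' Simulate a static cell scene with a bright membrane shell
#'
#' Renders a cell of a requested shape whose outer shell (within
#' `shell_thickness` of the boundary) and interior have designed intensities,
#' blurred by the PSF plus camera noise. The membrane intensity may be a
#' per-frame vector to emulate translocation time courses.
#'
#' @inheritParams simulate_photoactivation
#' @param mask_spec A list of arguments for [make_cell_mask()] (e.g.
#'   `list(shape = "disk", radius = 8)`).
#' @param membrane_intensity Scalar or per-frame vector of shell intensity.
#' @param cytosol_intensity Scalar or per-frame vector of interior intensity.
#' @param shell_thickness Shell thickness, um.
#'
#' @return A list with `stack`, `cell_mask`, `membrane_mask`, `cytosol_mask`
#'   and `shell_is_whole_cell` (flag set when the thickness swallows the
#'   whole shape).
#' @export
simulate_cell_scene <- function(params, mask_spec, membrane_intensity,
                                cytosol_intensity, shell_thickness = 1) {
  stopifnot(inherits(params, "sim_params"))
  if (any(membrane_intensity < 0) || any(cytosol_intensity < 0)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  mask <- do.call(make_cell_mask,
                  c(mask_spec, list(dim = params$image_shape,
                                    pixel_size = params$pixel_size)))
  dist_in <- boundary_distance(mask, params$pixel_size)
  membrane <- mask & dist_in <= shell_thickness
  cytosol <- mask & !membrane
  whole <- !any(cytosol)
  if (whole) {
    warning("shell thickness covers the whole cell; cytosol is empty",
            call. = FALSE)
  }
  n_t <- params$n_frames
  mem <- rep_len(membrane_intensity, n_t)
  cyt <- rep_len(cytosol_intensity, n_t)
  sig_px <- params$psf_sigma / params$pixel_size
  kern <- .gauss_kernel(sig_px)
  .with_seed(.substream_seed(params$seed, 97L), {
    frames <- array(0, c(n_t, params$image_shape))
    for (t in seq_len(n_t)) {
      img <- matrix(0, params$image_shape[1L], params$image_shape[2L])
      img[membrane] <- mem[t]
      img[cytosol] <- cyt[t]
      img <- as.matrix(EBImage::filter2(img, kern, boundary = "circular"))
      frames[t, , ] <- .add_noise(img, params)
    }
    list(stack = image_stack(frames, params$pixel_size, params$frame_interval),
         cell_mask = mask, membrane_mask = membrane, cytosol_mask = cytosol,
         shell_is_whole_cell = whole)
  })
}
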