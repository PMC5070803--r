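#' Simulate a photoactivation pulse-chase experiment
#'
#' Molecules are photoconverted inside a circular ROI at frame 1 and then
#' followed: a mobile subpopulation performs 2D Brownian motion with per-axis
#' step SD `sqrt(2 * D * frame_interval)`, an immobile subpopulation stays
#' put, and every molecule photobleaches exponentially with cumulative
#' illumination. Frames are rendered as sums of Gaussian PSFs plus camera
#' noise; the exact molecule trajectories and brightnesses are returned as
#' ground truth.
#'
#' @param params A [sim_params()].
#' @param D Diffusion coefficient, um^2/s (>= 0).
#' @param immobile_fraction Fraction of molecules that never move, in `[0, 1]`.
#' @param roi Activation region, a [circular_roi()]; must lie inside `cell_mask`.
#' @param n_molecules Number of photoactivated molecules.
#' @param decay_constant Photobleaching rate per second of cumulative exposure.
#' @param cell_mask Logical matrix confining the molecules. Defaults to the
#'   whole frame.
#' @param exposure_per_frame Illumination time per frame, s. Defaults to the
#'   frame interval (stream acquisition).
#' @param brightness Initial per-molecule brightness (intensity units).
#'
#' @return A list with `stack` (an [image_stack()]) and `truth` (a tibble with
#'   one row per molecule per frame: `molecule`, `frame`, `x_um`, `y_um`,
#'   `brightness`, `mobility`).
#' @export
simulate_photoactivation <- function(params, D, immobile_fraction, roi,
                                     n_molecules = 1000L, decay_constant = 0,
                                     cell_mask = NULL,
                                     exposure_per_frame = params$frame_interval,
                                     brightness = 1) {
  stopifnot(inherits(params, "sim_params"), inherits(roi, "circular_roi"))
  if (D < 0) stop("`D` must be non-negative", call. = FALSE)
  if (immobile_fraction < 0 || immobile_fraction > 1) {
    stop("`immobile_fraction` must be in [0, 1]", call. = FALSE)
  }
  if (is.null(cell_mask)) {
    cell_mask <- matrix(TRUE, params$image_shape[1L], params$image_shape[2L])
  }
  .check_roi_in_mask(roi, cell_mask, params$pixel_size)

  .with_seed(params$seed, {
    n_t <- params$n_frames
    p0 <- .runif_in_circle(n_molecules, roi)
    n_imm <- round(immobile_fraction * n_molecules)
    mobility <- rep(c("immobile", "mobile"), c(n_imm, n_molecules - n_imm))
    mobile <- mobility == "mobile"
    step_sd <- sqrt(2 * D * params$frame_interval)

    xs <- matrix(0, n_t, n_molecules); ys <- matrix(0, n_t, n_molecules)
    xs[1L, ] <- p0$x; ys[1L, ] <- p0$y
    if (n_t > 1L) for (t in 2L:n_t) {
      xs[t, ] <- xs[t - 1L, ]; ys[t, ] <- ys[t - 1L, ]
      if (any(mobile)) {
        st <- .brownian_step(xs[t, mobile], ys[t, mobile], step_sd,
                             cell_mask, params$pixel_size)
        xs[t, mobile] <- st$x; ys[t, mobile] <- st$y
      }
    }
    # brightness after the exposure accumulated before each frame
    cum_exp <- (seq_len(n_t) - 1) * exposure_per_frame
    bright <- matrix(brightness * exp(-decay_constant * cum_exp),
                     n_t, n_molecules)

    frames <- array(0, c(n_t, params$image_shape))
    for (t in seq_len(n_t)) {
      img <- .render_points(xs[t, ], ys[t, ], bright[t, ], params)
      frames[t, , ] <- .add_noise(img, params)
    }
    list(
      stack = image_stack(frames, params$pixel_size, params$frame_interval),
      truth = .truth_tibble(xs, ys, bright, mobility)
    )
  })
}

#' Simulate a FRAP experiment
#'
#' Molecules are spread uniformly over the cell mask; a `bound_fraction` never
#' moves, the rest diffuse with coefficient `D`. At `bleach_frame` every
#' molecule inside the ROI is darkened by `bleach_depth`. Diffusing unbleached
#' molecules subsequently exchange with the ROI, producing the recovery.
#'
#' @inheritParams simulate_photoactivation
#' @param bound_fraction Fraction of molecules immobilized by binding, `[0, 1]`.
#' @param bleach_depth Fraction of brightness removed inside the ROI at the
#'   bleach frame, `(0, 1]`.
#' @param bleach_frame Frame index at which the bleach occurs (molecules are
#'   darkened from this frame on).
#' @param keep_truth Set `FALSE` to omit the per-molecule truth tibble
#'   (which grows as molecules x frames) when only the stack is needed.
#'
#' @return A list with `stack`, `truth` (as in [simulate_photoactivation()];
#'   `NULL` when `keep_truth = FALSE`), `bleach_frame`, and
#'   `expected_plateau`: the asymptotic ROI intensity relative to pre-bleach
#'   predicted by particle-count bookkeeping on this realization
#'   (bleached-survivor bound molecules plus the equilibrated mobile pool).
#' @export
simulate_frap <- function(params, D, bound_fraction, roi, bleach_depth = 1,
                          cell_mask = NULL, n_molecules = 4000L,
                          bleach_frame = 6L, brightness = 1,
                          keep_truth = TRUE) {
  stopifnot(inherits(params, "sim_params"), inherits(roi, "circular_roi"))
  if (bound_fraction < 0 || bound_fraction > 1) {
    stop("`bound_fraction` must be in [0, 1]", call. = FALSE)
  }
  if (bleach_depth <= 0 || bleach_depth > 1) {
    stop("`bleach_depth` must be in (0, 1]", call. = FALSE)
  }
  if (bleach_frame < 1L || bleach_frame > params$n_frames) {
    stop("`bleach_frame` is beyond the acquisition", call. = FALSE)
  }
  if (is.null(cell_mask)) {
    cell_mask <- matrix(TRUE, params$image_shape[1L], params$image_shape[2L])
  }
  .check_roi_in_mask(roi, cell_mask, params$pixel_size)

  .with_seed(params$seed, {
    n_t <- params$n_frames
    p0 <- .runif_in_mask(n_molecules, cell_mask, params$pixel_size)
    n_bound <- round(bound_fraction * n_molecules)
    mobility <- rep(c("immobile", "mobile"), c(n_bound, n_molecules - n_bound))
    mobile <- mobility == "mobile"
    step_sd <- sqrt(2 * D * params$frame_interval)

    xs <- matrix(0, n_t, n_molecules); ys <- matrix(0, n_t, n_molecules)
    xs[1L, ] <- p0$x; ys[1L, ] <- p0$y
    if (n_t > 1L) for (t in 2L:n_t) {
      xs[t, ] <- xs[t - 1L, ]; ys[t, ] <- ys[t - 1L, ]
      if (any(mobile)) {
        st <- .brownian_step(xs[t, mobile], ys[t, mobile], step_sd,
                             cell_mask, params$pixel_size)
        xs[t, mobile] <- st$x; ys[t, mobile] <- st$y
      }
    }
    in_roi_at_bleach <-
      (xs[bleach_frame, ] - roi$x)^2 + (ys[bleach_frame, ] - roi$y)^2 <= roi$radius^2
    b_mol <- rep(brightness, n_molecules)
    b_post <- b_mol * ifelse(in_roi_at_bleach, 1 - bleach_depth, 1)
    bright <- matrix(b_mol, n_t, n_molecules, byrow = TRUE)
    bright[seq_len(n_t) >= bleach_frame, ] <-
      matrix(b_post, sum(seq_len(n_t) >= bleach_frame), n_molecules, byrow = TRUE)

    # bookkeeping oracle for the recovery plateau (relative to pre-bleach ROI)
    area_frac <- sum(roi_mask(roi, dim(cell_mask), params$pixel_size) & cell_mask) /
      sum(cell_mask)
    pre_roi <- sum(b_mol[in_roi_at_bleach])
    plateau <- (sum(b_post[in_roi_at_bleach & !mobile]) +
                  sum(b_post[mobile]) * area_frac) / pre_roi

    frames <- array(0, c(n_t, params$image_shape))
    for (t in seq_len(n_t)) {
      img <- .render_points(xs[t, ], ys[t, ], bright[t, ], params)
      frames[t, , ] <- .add_noise(img, params)
    }
    list(
      stack = image_stack(frames, params$pixel_size, params$frame_interval),
      truth = if (keep_truth) .truth_tibble(xs, ys, bright, mobility),
      bleach_frame = as.integer(bleach_frame),
      expected_plateau = plateau
    )
  })
}
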