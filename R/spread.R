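#' Fit an exponential photobleaching decay against cumulative exposure
#'
#' Fits `I = I0 * exp(-k * E)` where `E` is the cumulative illumination time
#' (frame index times exposure per frame). Plotted against cumulative
#' exposure, series acquired with different inter-frame intervals but the
#' same exposure collapse onto one curve, which is the diagnostic this
#' parameterization supports.
#'
#' @param intensity Numeric vector of per-frame intensities.
#' @param exposure_per_frame Illumination time per frame, s (> 0).
#' @param interval_per_frame Wall-clock time per frame, s (recorded for
#'   reference; the fit depends only on exposure).
#' @return An `exposure_decay` object with elements `k` (per second of
#'   exposure), `i0`, `rss`, `converged`, and the data.
#' @export
fit_exposure_decay <- function(intensity, exposure_per_frame,
                               interval_per_frame = exposure_per_frame) {
  stopifnot(exposure_per_frame > 0)
  if (length(intensity) < 5L) stop("need at least 5 samples", call. = FALSE)
  if (mean(intensity > 0) < 0.5) {
    return(structure(list(converged = FALSE,
                          reason = "non-positive intensities dominate"),
                     class = "exposure_decay"))
  }
  e <- (seq_along(intensity) - 1) * exposure_per_frame
  if (stats::sd(intensity) == 0) {  # constant series: exact zero-rate fit
    return(structure(list(converged = TRUE, k = 0, i0 = mean(intensity),
                          rss = 0, exposure_s = e, intensity = intensity,
                          interval_per_frame = interval_per_frame),
                     class = "exposure_decay"))
  }
  pos <- intensity > 0
  # log-linear start, refined by nonlinear least squares
  lf <- stats::lm(log(intensity[pos]) ~ e[pos])
  st <- list(i0 = exp(stats::coef(lf)[[1L]]), k = max(-stats::coef(lf)[[2L]], 0))
  fit <- tryCatch(
    minpack.lm::nlsLM(intensity ~ i0 * exp(-k * e), start = st,
                      lower = c(i0 = 0, k = 0)),
    error = function(err) NULL
  )
  if (is.null(fit)) {
    return(structure(list(converged = FALSE, reason = "no convergence"),
                     class = "exposure_decay"))
  }
  p <- as.list(stats::coef(fit))
  structure(list(converged = TRUE, k = p$k, i0 = p$i0,
                 rss = sum(stats::residuals(fit)^2),
                 exposure_s = e, intensity = intensity,
                 interval_per_frame = interval_per_frame),
            class = "exposure_decay")
}

#' @export
print.exposure_decay <- function(x, ...) {
  if (!x$converged) {
    cat("<exposure_decay> fit failed:", x$reason, "\n")
  } else {
    cat(sprintf("<exposure_decay> I = %.3g * exp(-%.3g * exposure_s)\n", x$i0, x$k))
  }
  invisible(x)
}

#' @export
tidy.exposure_decay <- function(x, ...) {
  if (!x$converged) return(tibble::tibble(term = character(), estimate = double()))
  tibble::tibble(term = c("i0", "k"), estimate = c(x$i0, x$k))
}

#' @export
glance.exposure_decay <- function(x, ...) {
  tibble::tibble(converged = x$converged,
                 k = if (x$converged) x$k else NA_real_,
                 rss = if (x$converged) x$rss else NA_real_)
}

#' Ring intensity profile around an activation ROI
#'
#' Bins every cell pixel by its Euclidean distance from the edge of the
#' circular ROI (pixels inside the ROI count as distance 0) into half-open
#' annuli `[R, R + delta_r)`, after normalizing the frame so the total
#' intensity over the cell mask equals 1. The mean normalized intensity per
#' annulus is returned; annuli with no cell pixels are reported as missing.
#'
#' @param frame 2D matrix, one time point.
#' @param roi A [circular_roi()] inside the cell mask.
#' @param pixel_size um/px.
#' @param delta_r Ring width, um (> 0). Default two pixels.
#' @param cell_mask Logical matrix delimiting the cell; defaults to the whole
#'   frame.
#' @param time_post_activation Seconds since activation, stored on the result.
#' @return A `ring_profile`: tibble with `r_um` (bin left edge),
#'   `mean_intensity`, `n_pixels`.
#' @export
ring_profile <- function(frame, roi, pixel_size, delta_r = 2 * pixel_size,
                         cell_mask = NULL, time_post_activation = NA_real_) {
  stopifnot(is.matrix(frame), inherits(roi, "circular_roi"), delta_r > 0)
  if (is.null(cell_mask)) cell_mask <- matrix(TRUE, nrow(frame), ncol(frame))
  .check_roi_in_mask(roi, cell_mask, pixel_size)
  total <- sum(frame[cell_mask])
  if (total <= 0) {
    norm <- frame * 0
  } else {
    norm <- frame / total
  }
  g <- .coord_grids(nrow(frame), ncol(frame), pixel_size)
  dist_edge <- pmax(sqrt((g$x - roi$x)^2 + (g$y - roi$y)^2) - roi$radius, 0)
  r_max <- max(dist_edge[cell_mask])
  breaks <- seq(0, r_max + delta_r, by = delta_r)
  bin <- findInterval(dist_edge[cell_mask], breaks, rightmost.closed = FALSE)
  vals <- norm[cell_mask]
  n_bins <- length(breaks) - 1L
  mean_i <- rep(NA_real_, n_bins); n_px <- integer(n_bins)
  agg_n <- tapply(vals, bin, length)
  agg_m <- tapply(vals, bin, mean)
  ids <- as.integer(names(agg_m))
  keep <- ids >= 1L & ids <= n_bins
  mean_i[ids[keep]] <- agg_m[keep]
  n_px[ids[keep]] <- agg_n[keep]
  out <- tibble::tibble(r_um = breaks[-length(breaks)],
                        mean_intensity = mean_i, n_pixels = n_px)
  class(out) <- c("ring_profile", class(out))
  attr(out, "delta_r") <- delta_r
  attr(out, "time_post_activation") <- time_post_activation
  attr(out, "total_intensity") <- total
  out
}

#' Spreading width of a ring profile
#'
#' The distance from the ROI edge at which the ring-averaged intensity first
#' falls to half of the profile's maximum at that time point, linearly
#' interpolated between the bracketing annuli. A purely numerical statistic:
#' no functional form is assumed for the profile. If the profile never drops
#' below half maximum within its support, the largest measured distance is
#' returned with attribute `out_of_support = TRUE`. Secondary peaks beyond
#' the first crossing are ignored (attribute `multimodal` flags them).
#'
#' @param profile A `ring_profile` from [ring_profile()].
#' @return Width in um (`NA` for an all-zero profile), with attributes
#'   `out_of_support` and `multimodal`.
#' @export
spreading_width <- function(profile) {
  ok <- !is.na(profile$mean_intensity)
  if (sum(ok) < 3L) stop("profile needs at least 3 non-missing bins", call. = FALSE)
  r <- profile$r_um[ok]; v <- profile$mean_intensity[ok]
  if (all(v <= 0)) {
    out <- NA_real_
    attr(out, "out_of_support") <- FALSE
    attr(out, "multimodal") <- FALSE
    return(out)
  }
  i_max <- which.max(v)
  half <- v[i_max] / 2
  width <- NA_real_; oos <- FALSE
  if (i_max == length(v)) {
    width <- r[length(r)]; oos <- TRUE
  } else {
    below <- which(v[(i_max + 1L):length(v)] < half)
    if (!length(below)) {
      width <- r[length(r)]; oos <- TRUE
    } else {
      j <- i_max + below[1L]          # first bin below half, outward
      # linear interpolation between bin centres of (j-1, j)
      cr <- r + (r[2L] - r[1L]) / 2   # bin centres
      width <- cr[j - 1L] + (v[j - 1L] - half) / (v[j - 1L] - v[j]) *
        (cr[j] - cr[j - 1L])
    }
  }
  multimodal <- FALSE
  if (!oos && !is.na(width)) {
    beyond <- v[r > width]
    if (length(beyond) && any(beyond > half)) multimodal <- TRUE
  }
  attr(width, "out_of_support") <- oos
  attr(width, "multimodal") <- multimodal
  width
}

#' Spreading width versus time post-activation
#'
#' Applies [ring_profile()] + [spreading_width()] to every frame at or after
#' the activation frame.
#'
#' @param stack An [image_stack()].
#' @inheritParams ring_profile
#' @param activation_frame Index of the first post-activation frame.
#' @return A `spreading_curve`: tibble with `time_s` (0 at activation),
#'   `width_um`, `out_of_support`.
#' @export
spreading_vs_time <- function(stack, roi, delta_r = 2 * stack$pixel_size,
                              cell_mask = NULL, activation_frame = 1L) {
  stopifnot(inherits(stack, "image_stack"))
  if (activation_frame < 1L || activation_frame > n_frames(stack)) {
    stop("`activation_frame` outside the stack", call. = FALSE)
  }
  frames <- activation_frame:n_frames(stack)
  rows <- purrr::map_dfr(frames, function(t) {
    pr <- ring_profile(stack_frame(stack, t), roi, stack$pixel_size,
                       delta_r, cell_mask,
                       time_post_activation = (t - activation_frame) * stack$frame_interval)
    w <- spreading_width(pr)
    tibble::tibble(
      frame = t,
      time_s = (t - activation_frame) * stack$frame_interval,
      width_um = as.numeric(w),
      out_of_support = isTRUE(attr(w, "out_of_support"))
    )
  })
  class(rows) <- c("spreading_curve", class(rows))
  rows
}

#' Spreading width directly from molecule positions (oracle route)
#'
#' Computes the same ring/half-maximum statistic from a set of point
#' positions instead of a rendered image: positions are histogrammed into
#' annuli around the ROI edge and converted to a mean per-pixel-area density
#' profile. Used to validate the image route against simulation ground truth.
#'
#' @param x_um,y_um Molecule positions at one time point.
#' @param roi A [circular_roi()].
#' @param delta_r Ring width, um.
#' @param r_max Largest distance to consider, um.
#' @return A `ring_profile` tibble (density units).
#' @export
position_ring_profile <- function(x_um, y_um, roi, delta_r, r_max) {
  d <- pmax(sqrt((x_um - roi$x)^2 + (y_um - roi$y)^2) - roi$radius, 0)
  breaks <- seq(0, r_max + delta_r, by = delta_r)
  bin <- findInterval(d, breaks, rightmost.closed = FALSE)
  n_bins <- length(breaks) - 1L
  counts <- tabulate(bin[bin >= 1L & bin <= n_bins], n_bins)
  # annulus areas around the ROI edge; the innermost bin includes the ROI disk
  outer_r <- roi$radius + breaks[-1L]
  inner_r <- roi$radius + breaks[-length(breaks)]
  area <- pi * (outer_r^2 - inner_r^2)
  area[1L] <- area[1L] + pi * roi$radius^2
  out <- tibble::tibble(r_um = breaks[-length(breaks)],
                        mean_intensity = counts / area / max(length(x_um), 1L),
                        n_pixels = counts)
  class(out) <- c("ring_profile", class(out))
  attr(out, "delta_r") <- delta_r
  out
}

#' Diffusion travel bound 4 D t
#'
#' The conventional upper scale for how far a molecule with effective
#' diffusion coefficient `D` travels in time `t` in two dimensions, taken as
#' `4 * D * t` (units as printed: um when D is in um^2/s and t in s). A
#' documented helper for sanity-checking spreading measurements; not used in
#' any computation.
#'
#' @param D Effective diffusion coefficient, um^2/s.
#' @param t Time, s.
#' @return `4 * D * t`.
#' @export
diffusion_travel_bound <- function(D, t) {
  stopifnot(D >= 0, t >= 0)
  4 * D * t
}

#' Convert a filament elongation rate to subunits per second
#'
#' Divides a barbed-end elongation rate in nm/s by the helical rise per
#' actin subunit (2.7 nm).
#'
#' @param rate_nm_s Elongation rate, nm/s.
#' @param rise_nm Axial rise per subunit, nm.
#' @return Subunits per second (not rounded).
#' @export
rate_to_subunits <- function(rate_nm_s, rise_nm = 2.7) {
  stopifnot(rise_nm > 0)
  rate_nm_s / rise_nm
}
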