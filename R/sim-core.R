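#' Simulation parameters
#'
#' Shared acquisition settings for every synthetic scene: calibration, frame
#' count, point-spread-function width, camera noise and the random seed. With
#' the same seed every simulator is bit-reproducible.
#'
#' The defaults describe a streaming TIRF-class acquisition: 0.1 um pixels,
#' 25 Hz (0.04 s frame interval), an isotropic Gaussian PSF of sigma 0.12 um,
#' Poisson shot noise at `poisson_gain` photons per intensity unit and
#' additive Gaussian read noise.
#'
#' @param pixel_size um/px (> 0).
#' @param frame_interval s between frames (> 0).
#' @param n_frames Number of frames.
#' @param image_shape `c(rows, cols)` in pixels.
#' @param psf_sigma PSF standard deviation in um (> 0).
#' @param poisson_gain Photons per intensity unit for shot noise;
#'   `NULL` or `0` disables shot noise.
#' @param read_noise_sigma Gaussian read-noise SD in intensity units;
#'   `0` disables.
#' @param seed Integer seed driving all randomness of a scene.
#' @return A `sim_params` object.
#' @export
sim_params <- function(pixel_size = 0.1, frame_interval = 0.04, n_frames = 25L,
                       image_shape = c(128L, 128L), psf_sigma = 0.12,
                       poisson_gain = NULL, read_noise_sigma = 0, seed = 1L) {
  stopifnot(pixel_size > 0, frame_interval > 0, psf_sigma > 0,
            n_frames >= 1, length(image_shape) == 2L, all(image_shape >= 4))
  structure(
    list(pixel_size = pixel_size, frame_interval = frame_interval,
         n_frames = as.integer(n_frames), image_shape = as.integer(image_shape),
         psf_sigma = psf_sigma, poisson_gain = poisson_gain,
         read_noise_sigma = read_noise_sigma, seed = as.integer(seed)),
    class = "sim_params"
  )
}

# One seed governs all stochastic components; per-module substreams are
# derived arithmetically so modules remain independent under a shared seed.
.substream_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset) %% 2147483647)
}

# run code under a local RNG state derived from seed
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# odd-sized normalized Gaussian kernel, sigma in px
.gauss_kernel <- function(sigma_px) {
  h <- max(1L, ceiling(3 * sigma_px))
  x <- seq(-h, h)
  k <- exp(-x^2 / (2 * sigma_px^2))
  k2 <- outer(k, k)
  k2 / sum(k2)
}

# Render point emitters into one frame: bilinear binning of (x, y) um
# positions with weights, then PSF blur. Circular convolution conserves
# total intensity exactly; scenes keep emitters away from frame borders.
.render_points <- function(x_um, y_um, weights, params) {
  nr <- params$image_shape[1L]; nc <- params$image_shape[2L]
  img <- matrix(0, nr, nc)
  if (length(x_um)) {
    cx <- x_um / params$pixel_size   # 0-based fractional pixel coords
    cy <- y_um / params$pixel_size
    c0 <- floor(cx); r0 <- floor(cy)
    fx <- cx - c0;   fy <- cy - r0
    idx_all <- integer(0); w_all <- numeric(0)
    for (k in 1:4) {
      dc <- k %in% c(2, 4); dr <- k %in% c(3, 4)
      w <- weights * (if (dc) fx else 1 - fx) * (if (dr) fy else 1 - fy)
      rr <- r0 + dr + 1L; cc <- c0 + dc + 1L
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc & w > 0
      if (any(ok)) {
        idx_all <- c(idx_all, rr[ok] + (cc[ok] - 1L) * nr)
        w_all <- c(w_all, w[ok])
      }
    }
    if (length(idx_all)) {
      # sparse accumulation sums duplicate pixel hits in C
      img[] <- as.vector(Matrix::sparseMatrix(
        i = idx_all, j = rep(1L, length(idx_all)), x = w_all,
        dims = c(nr * nc, 1L)
      ))
    }
  }
  sig_px <- params$psf_sigma / params$pixel_size
  as.matrix(EBImage::filter2(img, .gauss_kernel(sig_px), boundary = "circular"))
}

# Poisson shot noise then Gaussian read noise (camera model). Consumes RNG.
.add_noise <- function(img, params) {
  g <- params$poisson_gain
  if (!is.null(g) && g > 0) {
    img <- matrix(stats::rpois(length(img), pmax(img, 0) * g) / g,
                  nrow(img), ncol(img))
  }
  if (params$read_noise_sigma > 0) {
    img <- img + matrix(stats::rnorm(length(img), 0, params$read_noise_sigma),
                        nrow(img), ncol(img))
  }
  img
}

# Brownian step for positions constrained to a mask. A proposed step landing
# outside the mask is rejected (the molecule keeps its position that frame):
# this preserves the uniform stationary distribution and molecule number.
.brownian_step <- function(x, y, step_sd, mask, pixel_size) {
  n <- length(x)
  if (step_sd == 0 || n == 0L) return(list(x = x, y = y))
  nx <- x + stats::rnorm(n, 0, step_sd)
  ny <- y + stats::rnorm(n, 0, step_sd)
  ok <- .inside_mask(nx, ny, mask, pixel_size)
  list(x = ifelse(ok, nx, x), y = ifelse(ok, ny, y))
}

.inside_mask <- function(x_um, y_um, mask, pixel_size) {
  cc <- round(x_um / pixel_size) + 1L
  rr <- round(y_um / pixel_size) + 1L
  ok <- cc >= 1L & cc <= ncol(mask) & rr >= 1L & rr <= nrow(mask)
  ok[ok] <- mask[cbind(rr[ok], cc[ok])]
  ok
}

# uniform points inside an arbitrary mask, by area-weighted pixel choice
# plus sub-pixel jitter
.runif_in_mask <- function(n, mask, pixel_size) {
  idx <- which(mask)
  pick <- sample(idx, n, replace = TRUE)
  rr <- ((pick - 1L) %% nrow(mask)) + 1L
  cc <- ((pick - 1L) %/% nrow(mask)) + 1L
  list(
    x = (cc - 1L + stats::runif(n, -0.5, 0.5)) * pixel_size,
    y = (rr - 1L + stats::runif(n, -0.5, 0.5)) * pixel_size
  )
}

# uniform points inside a circle
.runif_in_circle <- function(n, roi) {
  r <- roi$radius * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  list(x = roi$x + r * cos(th), y = roi$y + r * sin(th))
}

.check_roi_in_mask <- function(roi, mask, pixel_size, n_probe = 64L) {
  th <- seq(0, 2 * pi, length.out = n_probe + 1L)[-1L]
  px <- roi$x + roi$radius * cos(th)
  py <- roi$y + roi$radius * sin(th)
  if (!all(.inside_mask(c(px, roi$x), c(py, roi$y), mask, pixel_size))) {
    stop("ROI is not fully inside the cell mask", call. = FALSE)
  }
  invisible(TRUE)
}

# long tibble of molecule truth from per-frame position matrices
.truth_tibble <- function(xs, ys, brightness, mobility) {
  n_mol <- ncol(xs); n_t <- nrow(xs)
  tibble::tibble(
    molecule = rep(seq_len(n_mol), each = n_t),
    frame = rep(seq_len(n_t), n_mol),
    x_um = as.vector(xs),
    y_um = as.vector(ys),
    brightness = as.vector(brightness),
    mobility = rep(mobility, each = n_t)
  )
}
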