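# --- Euclidean distance transform ------------------------------------------
# Felzenszwalb-Huttenlocher lower-envelope transform, one axis at a time.
# Anisotropy-aware: each axis carries its own sampling step, which is what a
# confocal z-stack with z spacing != xy spacing needs.

.dt1d <- function(f, h) {
  n <- length(f)
  if (n == 1L) return(f)
  d <- numeric(n)
  v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1L] <- 1L; z[1L] <- -Inf; z[2L] <- Inf
  h2 <- h * h
  for (q in 2:n) {
    repeat {
      p <- v[k]
      s <- ((f[q] + h2 * q * q) - (f[p] + h2 * p * p)) / (2 * h2 * (q - p))
      if (s <= z[k]) {
        k <- k - 1L
      } else {
        k <- k + 1L; v[k] <- q; z[k] <- s; z[k + 1L] <- Inf
        break
      }
    }
  }
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < q) k <- k + 1L
    p <- v[k]
    d[q] <- h2 * (q - p)^2 + f[p]
  }
  d
}

# squared EDT of sites (TRUE = site at distance 0), spacing per axis.
# Non-sites start at a large finite sentinel so the envelope stays numeric.
.edt_squared <- function(sites, spacing) {
  d <- dim(sites)
  big <- 4 * sum((d * spacing)^2)
  f <- array(ifelse(sites, 0, big), d)
  nd <- length(d)
  for (ax in seq_len(nd)) {
    f <- apply(f, setdiff(seq_len(nd), ax), .dt1d, h = spacing[ax])
    # apply returns the processed axis first; rotate back into place
    perm <- order(c(ax, setdiff(seq_len(nd), ax)))
    f <- aperm(f, perm)
  }
  f
}

#' Inward distance to the mask boundary
#'
#' Euclidean distance of every inside pixel/voxel to the nearest outside
#' pixel, in micrometres. Supports anisotropic 3D masks.
#'
#' @param mask Logical 2D matrix or 3D array (`z x y x x`).
#' @param pixel_size Lateral pixel size, um.
#' @param z_spacing z spacing, um; required for 3D masks.
#' @return Numeric array of distances (0 outside the mask).
#' @export
boundary_distance <- function(mask, pixel_size, z_spacing = NULL) {
  nd <- length(dim(mask))
  if (nd == 2L) {
    spacing <- c(pixel_size, pixel_size)
  } else if (nd == 3L) {
    if (is.null(z_spacing)) {
      stop("3D masks require `z_spacing` (anisotropic voxels)", call. = FALSE)
    }
    spacing <- c(z_spacing, pixel_size, pixel_size)
  } else stop("mask must be 2D or 3D", call. = FALSE)
  d2 <- .edt_squared(!mask, spacing)
  out <- sqrt(d2)
  out[!mask] <- 0
  out
}

# --- segmentation -----------------------------------------------------------

#' Intensity-based cell segmentation
#'
#' Gaussian smoothing, Otsu's between-class-variance threshold, retention of
#' the largest connected component and hole filling. For 3D input the
#' threshold is computed on the whole volume, the component is grown from the
#' best slice by geodesic reconstruction (6-connectivity) and holes are
#' filled slice-wise.
#'
#' @param image 2D matrix or 3D array (`z x y x x`), non-constant.
#' @param pixel_size um/px.
#' @param smoothing_sigma Smoothing SD, um.
#' @param z_spacing z spacing, um (3D only; recorded on the result).
#' @param invert Set `TRUE` for inverted-contrast input (dark cell on bright
#'   background).
#' @return A `cell_mask`: logical array with attributes `pixel_size` and
#'   `z_spacing`.
#' @export
segment_cell <- function(image, pixel_size, smoothing_sigma = 0.5,
                         z_spacing = NULL, invert = FALSE) {
  stopifnot(pixel_size > 0)
  if (diff(range(image)) == 0) stop("constant image cannot be segmented", call. = FALSE)
  if (invert) image <- max(image) - image
  nd <- length(dim(image))
  sig_px <- smoothing_sigma / pixel_size
  smooth2d <- function(m) {
    if (sig_px <= 0) m else
      as.matrix(EBImage::filter2(m, .gauss_kernel(sig_px), boundary = "replicate"))
  }
  if (nd == 2L) {
    sm <- smooth2d(image)
    rng <- range(sm)
    sm01 <- (sm - rng[1L]) / diff(rng)
    th <- EBImage::otsu(EBImage::Image(sm01), range = c(0, 1))
    bw <- sm01 > th
    lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bw)))
    tab <- tabulate(lab[lab > 0])
    if (!length(tab)) stop("no foreground found", call. = FALSE)
    keep <- which.max(tab)
    mask <- matrix(lab == keep, nrow(image), ncol(image))
    mask <- matrix(EBImage::imageData(EBImage::fillHull(EBImage::Image(mask))) > 0,
                   nrow(image), ncol(image))
  } else if (nd == 3L) {
    sm <- array(0, dim(image))
    for (z in seq_len(dim(image)[1L])) sm[z, , ] <- smooth2d(image[z, , ])
    rng <- range(sm)
    sm01 <- (sm - rng[1L]) / diff(rng)
    th <- EBImage::otsu(EBImage::Image(as.vector(sm01), dim = c(length(sm01), 1L)),
                        range = c(0, 1))
    bw <- sm01 > th
    # seed: largest 2D component on the slice with most foreground
    z_best <- which.max(apply(bw, 1L, sum))
    lab <- EBImage::imageData(EBImage::bwlabel(
      EBImage::Image(matrix(bw[z_best, , ], dim(bw)[2L], dim(bw)[3L]))))
    tab <- tabulate(lab[lab > 0])
    if (!length(tab)) stop("no foreground found", call. = FALSE)
    seed <- array(FALSE, dim(bw))
    seed[z_best, , ] <- lab == which.max(tab)
    mask <- .geodesic_reconstruct(seed, bw)
    for (z in seq_len(dim(mask)[1L])) {
      mask[z, , ] <- EBImage::imageData(EBImage::fillHull(
        EBImage::Image(matrix(mask[z, , ], dim(mask)[2L], dim(mask)[3L])))) > 0
    }
  } else stop("image must be 2D or 3D", call. = FALSE)
  structure(mask, pixel_size = pixel_size, z_spacing = z_spacing,
            class = c("cell_mask", class(mask)))
}

# iterative 6-connected dilation of seed constrained to mask
.geodesic_reconstruct <- function(seed, mask) {
  cur <- seed & mask
  repeat {
    d <- dim(cur)
    grown <- cur
    shift_or <- function(a, ax, by) {
      out <- array(FALSE, d)
      idx_src <- lapply(d, seq_len); idx_dst <- idx_src
      if (by > 0) { idx_src[[ax]] <- 1:(d[ax] - 1); idx_dst[[ax]] <- 2:d[ax] }
      else { idx_src[[ax]] <- 2:d[ax]; idx_dst[[ax]] <- 1:(d[ax] - 1) }
      out[idx_dst[[1L]], idx_dst[[2L]], idx_dst[[3L]]] <-
        a[idx_src[[1L]], idx_src[[2L]], idx_src[[3L]]]
      out
    }
    for (ax in 1:3) for (by in c(-1L, 1L)) grown <- grown | shift_or(cur, ax, by)
    grown <- grown & mask
    if (identical(grown, cur)) return(cur)
    cur <- grown
  }
}

#' Partition a cell mask into membrane shell and cytosol
#'
#' The membrane compartment is every pixel/voxel within `thickness` of the
#' cell boundary (inward Euclidean distance transform); the cytosol is the
#' remainder. The two compartments are an exact partition of the mask.
#'
#' @param mask A `cell_mask` from [segment_cell()], or a logical array with a
#'   `pixel_size` supplied explicitly.
#' @param thickness Shell thickness, um (>= 0). Default 1 um.
#' @param pixel_size,z_spacing Calibration overrides when `mask` is a bare
#'   array.
#' @return A `shell_partition`: list with `membrane`, `cytosol`, `thickness`
#'   and `shell_is_whole_cell` flag (set when the shell swallows the mask).
#' @export
membrane_shell <- function(mask, thickness = 1, pixel_size = NULL,
                           z_spacing = NULL) {
  if (is.null(pixel_size)) pixel_size <- attr(mask, "pixel_size")
  if (is.null(z_spacing)) z_spacing <- attr(mask, "z_spacing")
  if (is.null(pixel_size)) stop("`pixel_size` required", call. = FALSE)
  if (thickness < 0) stop("`thickness` must be >= 0", call. = FALSE)
  m <- array(as.logical(mask), dim(mask))
  dist_in <- boundary_distance(m, pixel_size, z_spacing)
  membrane <- m & dist_in <= thickness
  cytosol <- m & !membrane
  whole <- any(m) && !any(cytosol)
  if (whole) warning("shell thickness covers the whole mask; cytosol is empty",
                     call. = FALSE)
  structure(list(membrane = membrane, cytosol = cytosol, cell = m,
                 thickness = thickness, pixel_size = pixel_size,
                 z_spacing = z_spacing, shell_is_whole_cell = whole),
            class = "shell_partition")
}

#' Membrane / cytosol intensity ratio over time
#'
#' Per frame: `(mean membrane - background) / (mean cytosol - background)`,
#' with the background taken as the mean intensity outside the cell mask in
#' that frame. With `reference_frame` set, a `fold_change` column divides the
#' ratio series by its value at that frame.
#'
#' @param stack An [image_stack()] sharing the partition's geometry.
#' @param partition A [membrane_shell()] partition.
#' @param reference_frame Optional frame index for fold-change normalization.
#' @return A tibble with `frame`, `time_s`, `ratio` (and `fold_change`).
#' @export
membrane_cytosol_ratio <- function(stack, partition, reference_frame = NULL) {
  stopifnot(inherits(stack, "image_stack"), inherits(partition, "shell_partition"))
  d_im <- dim(stack$data)[-1L]
  if (!identical(as.integer(d_im), as.integer(dim(partition$cell)))) {
    stop("partition geometry does not match the stack", call. = FALSE)
  }
  outside <- !partition$cell
  ratio <- vapply(seq_len(n_frames(stack)), function(t) {
    fr <- stack_frame(stack, t)
    bg <- if (any(outside)) mean(fr[outside]) else 0
    mem <- mean(fr[partition$membrane]) - bg
    cyt <- mean(fr[partition$cytosol]) - bg
    if (!is.finite(cyt) || cyt <= 0) NA_real_ else mem / cyt
  }, numeric(1L))
  out <- tibble::tibble(frame = seq_len(n_frames(stack)),
                        time_s = frame_times(stack), ratio = ratio)
  if (!is.null(reference_frame)) {
    ref <- ratio[reference_frame]
    out$fold_change <- ratio / ref
  }
  out
}

# --- kymographs -------------------------------------------------------------

# bilinear sample of a matrix at 0-based pixel coordinates
.interp2 <- function(img, x_px, y_px) {
  nr <- nrow(img); nc <- ncol(img)
  c0 <- floor(x_px); r0 <- floor(y_px)
  fx <- x_px - c0; fy <- y_px - r0
  c0 <- pmin(pmax(c0, 0), nc - 2L); r0 <- pmin(pmax(r0, 0), nr - 2L)
  i00 <- img[cbind(r0 + 1L, c0 + 1L)]; i01 <- img[cbind(r0 + 1L, c0 + 2L)]
  i10 <- img[cbind(r0 + 2L, c0 + 1L)]; i11 <- img[cbind(r0 + 2L, c0 + 2L)]
  i00 * (1 - fx) * (1 - fy) + i01 * fx * (1 - fy) +
    i10 * (1 - fx) * fy + i11 * fx * fy
}

#' Space-time kymograph along a polyline
#'
#' Samples each frame along a polyline at one-pixel arclength steps,
#' averaging over `line_width_px` parallel offsets perpendicular to the local
#' segment direction, producing a `time x arclength` matrix.
#'
#' @param stack An [image_stack()] (2D + t).
#' @param polyline Two-column matrix of vertices in um (at least 2 rows).
#' @param line_width_px Width of the averaging band, px (odd; default 1).
#' @return A `kymograph` object: list with `data` (time x arclength),
#'   `arclength_um`, `pixel_size`, `frame_interval`.
#' @export
kymograph <- function(stack, polyline, line_width_px = 1L) {
  stopifnot(inherits(stack, "image_stack"), is.matrix(polyline),
            ncol(polyline) == 2L, nrow(polyline) >= 2L)
  px <- stack$pixel_size
  seg_len <- sqrt(diff(polyline[, 1L])^2 + diff(polyline[, 2L])^2)
  total <- sum(seg_len)
  n_s <- max(2L, round(total / px) + 1L)
  s_query <- seq(0, total, length.out = n_s)
  cum <- c(0, cumsum(seg_len))
  seg_of <- pmin(findInterval(s_query, cum, rightmost.closed = TRUE), length(seg_len))
  frac <- (s_query - cum[seg_of]) / seg_len[seg_of]
  xq <- polyline[seg_of, 1L] + frac * (polyline[seg_of + 1L, 1L] - polyline[seg_of, 1L])
  yq <- polyline[seg_of, 2L] + frac * (polyline[seg_of + 1L, 2L] - polyline[seg_of, 2L])
  # unit normals of the local segment, for the width averaging
  tx <- (polyline[seg_of + 1L, 1L] - polyline[seg_of, 1L]) / seg_len[seg_of]
  ty <- (polyline[seg_of + 1L, 2L] - polyline[seg_of, 2L]) / seg_len[seg_of]
  nx <- -ty; ny <- tx
  offsets <- (seq_len(line_width_px) - (line_width_px + 1) / 2) * px

  d_im <- dim(stack$data)[2:3]
  all_x <- as.vector(outer(xq, offsets * 0, "+") + outer(nx, offsets))
  all_y <- as.vector(outer(yq, offsets * 0, "+") + outer(ny, offsets))
  if (any(all_x < 0 | all_x > (d_im[2L] - 1) * px |
          all_y < 0 | all_y > (d_im[1L] - 1) * px)) {
    stop("polyline (with width band) exits the image", call. = FALSE)
  }
  kym <- matrix(0, n_frames(stack), n_s)
  for (t in seq_len(n_frames(stack))) {
    fr <- stack_frame(stack, t)
    vals <- .interp2(fr, all_x / px, all_y / px)
    kym[t, ] <- rowMeans(matrix(vals, n_s, line_width_px))
  }
  structure(list(data = kym, arclength_um = s_query,
                 pixel_size = px, frame_interval = stack$frame_interval),
            class = "kymograph")
}

#' Filament tip velocity from a kymograph
#'
#' Per frame, the tip is the farthest arclength position whose intensity
#' still reaches `threshold_fraction` of that row's maximum (the half-max
#' front), refined by linear interpolation to the crossing; the velocity is
#' the least-squares slope of tip position against time, in nm/s. The
#' per-row relative threshold makes the front robust to photobleaching.
#'
#' @param kym A [kymograph()].
#' @param threshold_fraction Fraction of the row maximum defining the front.
#' @return A `tip_velocity` object: list with `velocity_nm_s`, `intercept_um`,
#'   `tips` (tibble `time_s`, `tip_um`), `converged`.
#' @export
estimate_tip_velocity <- function(kym, threshold_fraction = 0.5) {
  stopifnot(inherits(kym, "kymograph"))
  if (nrow(kym$data) < 5L) stop("kymograph needs at least 5 rows", call. = FALSE)
  s <- kym$arclength_um
  tips <- rep(NA_real_, nrow(kym$data))
  for (t in seq_len(nrow(kym$data))) {
    row <- kym$data[t, ]
    m <- max(row)
    if (!is.finite(m) || m <= 0) next
    thr <- threshold_fraction * m
    above <- which(row >= thr)
    if (!length(above)) next
    j <- max(above)
    if (j < length(row)) {
      frac <- (row[j] - thr) / (row[j] - row[j + 1L])
      tips[t] <- s[j] + frac * (s[j + 1L] - s[j])
    } else tips[t] <- s[j]
  }
  ok <- !is.na(tips)
  if (sum(ok) < 3L) {
    return(structure(list(converged = FALSE, velocity_nm_s = NA_real_,
                          tips = tibble::tibble()), class = "tip_velocity"))
  }
  time_s <- (seq_len(nrow(kym$data)) - 1) * kym$frame_interval
  fit <- stats::lm(tips[ok] ~ time_s[ok])
  structure(list(
    converged = TRUE,
    velocity_nm_s = unname(stats::coef(fit)[2L]) * 1000,
    intercept_um = unname(stats::coef(fit)[1L]),
    tips = tibble::tibble(time_s = time_s[ok], tip_um = tips[ok])
  ), class = "tip_velocity")
}

#' @export
print.tip_velocity <- function(x, ...) {
  if (!x$converged) cat("<tip_velocity> no front crossed the threshold\n")
  else cat(sprintf("<tip_velocity> %.2f nm/s over %d frames\n",
                   x$velocity_nm_s, nrow(x$tips)))
  invisible(x)
}

# --- projections and background --------------------------------------------

#' Temporal colour-coded maximum intensity projection
#'
#' Each frame is tinted with a hue drawn along a colormap (default
#' blue-to-red across the acquisition) and the projection takes the
#' per-pixel, per-channel maximum of the tinted frames. A static object
#' bright in every frame accumulates the full spectrum and appears white; a
#' moving object leaves a coloured trail whose hue encodes time.
#'
#' @param stack An [image_stack()] with >= 2 frames.
#' @param colormap A function `n -> colours`; default blue-cyan-green-
#'   yellow-red ramp.
#' @return A `height x width x 3` RGB array in `[0, 1]`, class `temporal_mip`.
#' @export
temporal_mip <- function(stack, colormap = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  n_t <- n_frames(stack)
  if (n_t < 2L) stop("need at least 2 frames", call. = FALSE)
  if (is.null(colormap)) {
    colormap <- grDevices::colorRampPalette(
      c("blue", "cyan", "green", "yellow", "red"))
  }
  cols <- grDevices::col2rgb(colormap(n_t)) / 255
  top <- max(stack$data)
  if (top <= 0) top <- 1
  d_im <- dim(stack$data)[2:3]
  out <- array(0, c(d_im, 3L))
  for (t in seq_len(n_t)) {
    fr <- pmax(stack_frame(stack, t), 0) / top
    for (ch in 1:3) out[, , ch] <- pmax(out[, , ch], fr * cols[ch, t])
  }
  structure(pmin(out, 1), class = "temporal_mip")
}

#' @export
plot.temporal_mip <- function(x, ...) {
  op <- graphics::par(mar = c(0, 0, 0, 0)); on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::rasterImage(grDevices::as.raster(unclass(x)), 0, 0, 1, 1, ...)
  invisible(x)
}

#' Rolling-ball background subtraction
#'
#' Grayscale morphological opening with a ball-shaped (spherical-cap)
#' structuring element: the background is what remains after eroding and
#' re-dilating with the ball, and is subtracted from the image. Structures
#' narrower than the ball (spots, filaments) are removed from the background
#' and therefore preserved in the output; smooth ramps are kept in the
#' background and removed. Output is clamped at zero.
#'
#' @param image 2D matrix.
#' @param radius_px Ball radius in pixels (>= 1).
#' @param height Ball height in intensity units; defaults to `radius_px`.
#' @return Background-subtracted matrix (>= 0), with the estimated
#'   background in attribute `background`.
#' @export
rolling_ball_background <- function(image, radius_px, height = radius_px) {
  stopifnot(is.matrix(image), radius_px >= 1)
  r <- radius_px
  off <- expand.grid(dr = -floor(r):floor(r), dc = -floor(r):floor(r))
  off <- off[off$dr^2 + off$dc^2 <= r^2, ]
  ball <- height * (sqrt(pmax(1 - (off$dr^2 + off$dc^2) / r^2, 0)) - 1)  # <= 0
  nr <- nrow(image); nc <- ncol(image)
  shift_rep <- function(m, dr, dc) {
    ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
    ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
    m[ri, ci, drop = FALSE]
  }
  ero <- matrix(Inf, nr, nc)
  for (k in seq_len(nrow(off))) {
    ero <- pmin(ero, shift_rep(image, off$dr[k], off$dc[k]) - ball[k])
  }
  dil <- matrix(-Inf, nr, nc)
  for (k in seq_len(nrow(off))) {
    dil <- pmax(dil, shift_rep(ero, -off$dr[k], -off$dc[k]) + ball[k])
  }
  out <- pmax(image - dil, 0)
  attr(out, "background") <- dil
  out
}

#' Pairwise Pearson correlation matrix
#'
#' Pairwise-complete Pearson correlations between all numeric columns of a
#' result table. Pairs with fewer than 3 complete rows, and zero-variance
#' columns, are reported as missing.
#'
#' @param result_table Data frame of per-sample measurements.
#' @return Correlation matrix (numeric columns of the input).
#' @export
pairwise_correlation <- function(result_table) {
  num <- result_table[vapply(result_table, is.numeric, logical(1L))]
  if (ncol(num) < 2L) stop("need at least 2 numeric columns", call. = FALSE)
  m <- suppressWarnings(stats::cor(as.matrix(num), use = "pairwise.complete.obs"))
  cc <- !is.na(as.matrix(num))
  n_pair <- t(cc) %*% cc
  m[n_pair < 3L] <- NA_real_
  sds <- apply(num, 2L, stats::sd, na.rm = TRUE)
  m[sds == 0, ] <- NA_real_
  m[, sds == 0] <- NA_real_
  diag(m)[sds > 0] <- 1
  m
}
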