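#' Calibrated image stack
#'
#' The universal input container: a time series of 2D frames (optionally with
#' a z dimension) together with its spatial and temporal calibration. All
#' physical coordinates in the package are micrometres, with the origin at the
#' centre of the top-left pixel and 0-based pixel indexing, so
#' `x_um = (col - 1) * pixel_size` and `y_um = (row - 1) * pixel_size`.
#'
#' @param data Numeric array, `time x y x x` (3D) or `time x z x y x x` (4D).
#'   A single 2D matrix is promoted to a one-frame stack.
#' @param pixel_size Pixel size in micrometres per pixel (> 0).
#' @param frame_interval Time between frames in seconds (> 0).
#' @param z_spacing Optional z spacing in micrometres; required for 4D data.
#'
#' @return An `image_stack` object.
#' @export
image_stack <- function(data, pixel_size, frame_interval, z_spacing = NULL) {
  if (is.matrix(data)) {
    data <- array(data, dim = c(1L, nrow(data), ncol(data)))
  }
  stopifnot(is.array(data), length(dim(data)) %in% c(3L, 4L))
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    stop("`pixel_size` must be a single positive number (um/px)", call. = FALSE)
  }
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L || frame_interval <= 0) {
    stop("`frame_interval` must be a single positive number (s)", call. = FALSE)
  }
  if (length(dim(data)) == 4L && is.null(z_spacing)) {
    stop("4D stacks require `z_spacing` (um)", call. = FALSE)
  }
  structure(
    list(data = data, pixel_size = pixel_size,
         frame_interval = frame_interval, z_spacing = z_spacing),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  ax <- if (length(d) == 4L) "T x Z x Y x X" else "T x Y x X"
  cat("<image_stack> ", paste(d, collapse = " x "), " (", ax, ")\n", sep = "")
  cat("  pixel size: ", x$pixel_size, " um/px; frame interval: ",
      x$frame_interval, " s", sep = "")
  if (!is.null(x$z_spacing)) cat("; z spacing: ", x$z_spacing, " um", sep = "")
  cat("\n")
  invisible(x)
}

#' Number of frames in a stack
#' @param stack An [image_stack()].
#' @return Integer frame count.
#' @export
n_frames <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  dim(stack$data)[1L]
}

#' Extract one frame of a stack
#'
#' @param stack An [image_stack()].
#' @param t Frame index (1-based).
#' @return A `y x x` matrix (3D stacks) or `z x y x x` array (4D stacks).
#' @export
stack_frame <- function(stack, t) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  if (t < 1L || t > d[1L]) stop("frame index out of range", call. = FALSE)
  if (length(d) == 3L) {
    matrix(stack$data[t, , ], d[2L], d[3L])
  } else {
    array(stack$data[t, , , ], d[2L:4L])
  }
}

#' Times of each frame relative to the first
#' @param stack An [image_stack()].
#' @return Numeric vector of times in seconds, starting at 0.
#' @export
frame_times <- function(stack) {
  (seq_len(n_frames(stack)) - 1) * stack$frame_interval
}

#' Circular region of interest
#'
#' Activation / bleach region used throughout: a circle given by its centre
#' and radius, both in micrometres in image coordinates.
#'
#' @param x,y Centre, um.
#' @param radius Radius, um (> 0).
#' @return A `circular_roi` object.
#' @export
circular_roi <- function(x, y, radius) {
  stopifnot(is.numeric(x), is.numeric(y), is.numeric(radius), length(radius) == 1L)
  if (radius <= 0) stop("`radius` must be positive", call. = FALSE)
  structure(list(x = x, y = y, radius = radius), class = "circular_roi")
}

#' @export
print.circular_roi <- function(x, ...) {
  cat(sprintf("<circular_roi> centre (%.3g, %.3g) um, radius %.3g um\n",
              x$x, x$y, x$radius))
  invisible(x)
}

# pixel-centre coordinate grids in um for an H x W frame
.coord_grids <- function(nr, nc, pixel_size) {
  list(
    x = matrix(rep((seq_len(nc) - 1) * pixel_size, each = nr), nr, nc),
    y = matrix(rep((seq_len(nr) - 1) * pixel_size, nc), nr, nc)
  )
}

#' Rasterize a circular ROI to a pixel mask
#'
#' @param roi A [circular_roi()].
#' @param dim Frame dimensions `c(rows, cols)`.
#' @param pixel_size um/px.
#' @return Logical matrix, `TRUE` inside the circle.
#' @export
roi_mask <- function(roi, dim, pixel_size) {
  g <- .coord_grids(dim[1L], dim[2L], pixel_size)
  (g$x - roi$x)^2 + (g$y - roi$y)^2 <= roi$radius^2
}

#' Binary masks for simple cell shapes
#'
#' Generates the cell outlines used by the simulators: a disk, an ellipse, or
#' a filled polygon, rasterized on a pixel grid.
#'
#' @param shape `"disk"`, `"ellipse"` or `"polygon"`.
#' @param dim Frame dimensions `c(rows, cols)` in pixels.
#' @param pixel_size um/px.
#' @param center Centre `c(x, y)` in um (disk/ellipse). Defaults to the image centre.
#' @param radius Disk radius in um, or `c(rx, ry)` semi-axes for an ellipse.
#' @param vertices Two-column matrix of polygon vertices in um (polygon only).
#' @return Logical matrix mask.
#' @export
make_cell_mask <- function(shape = c("disk", "ellipse", "polygon"), dim, pixel_size,
                           center = NULL, radius = NULL, vertices = NULL) {
  shape <- match.arg(shape)
  g <- .coord_grids(dim[1L], dim[2L], pixel_size)
  if (is.null(center)) {
    center <- c((dim[2L] - 1) * pixel_size / 2, (dim[1L] - 1) * pixel_size / 2)
  }
  if (shape == "disk") {
    stopifnot(length(radius) == 1L, radius > 0)
    return((g$x - center[1L])^2 + (g$y - center[2L])^2 <= radius^2)
  }
  if (shape == "ellipse") {
    stopifnot(length(radius) == 2L, all(radius > 0))
    return(((g$x - center[1L]) / radius[1L])^2 +
             ((g$y - center[2L]) / radius[2L])^2 <= 1)
  }
  stopifnot(is.matrix(vertices), ncol(vertices) == 2L, nrow(vertices) >= 3L)
  .point_in_polygon(g$x, g$y, vertices)
}

# even-odd ray casting, vectorized over query points
.point_in_polygon <- function(px, py, vertices) {
  n <- nrow(vertices)
  inside <- matrix(FALSE, nrow(px), ncol(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vertices[i, 1L]; yi <- vertices[i, 2L]
    xj <- vertices[j, 1L]; yj <- vertices[j, 2L]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
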