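#' Simulate a two-channel node scene with designed colocalization
#'
#' Places `n_b` channel-B nodes (e.g. actin nodes) and `n_a` channel-A nodes
#' (e.g. formin puncta) so that a designed fraction of A nodes lies within
#' `coloc_offset` of a distinct B node, while every other inter-node distance
#' exceeds `3 * max(coloc_offset, guard)` — so a downstream distance-threshold
#' colocalization measurement recovers the designed fraction. Nodes may
#' random-walk between frames.
#'
#' @inheritParams simulate_photoactivation
#' @param n_a,n_b Node counts per channel.
#' @param overlap_fraction Designed fraction of A nodes colocalized with a B
#'   node, `[0, 1]`; requires `round(overlap_fraction * n_a) <= n_b`.
#' @param coloc_offset Maximum centre distance of a designed pair, um.
#' @param step_scale Per-frame random-walk step SD, um (0 = static nodes).
#' @param guard Minimum geometry scale used for the separation rule when
#'   `coloc_offset` is very small; defaults to `2 * psf_sigma`.
#' @param amplitude Peak node brightness, intensity units.
#' @param max_tries Placement retries before giving up.
#'
#' @return A list with `channel_a` and `channel_b` (two [image_stack()]s),
#'   `truth` (tibble: `channel`, `node`, `frame`, `x_um`, `y_um`,
#'   `matched_b` — for A nodes, the paired B node id or `NA`), and
#'   `overlap_fraction` actually realized.
#' @export
simulate_node_scene <- function(params, n_a, n_b, overlap_fraction,
                                coloc_offset = 0.2, step_scale = 0,
                                guard = 2 * params$psf_sigma,
                                amplitude = 1, max_tries = 2000L) {
  stopifnot(inherits(params, "sim_params"))
  if (overlap_fraction < 0 || overlap_fraction > 1) {
    stop("`overlap_fraction` must be in [0, 1]", call. = FALSE)
  }
  n_match <- round(overlap_fraction * n_a)
  if (n_match > n_b) {
    stop("`overlap_fraction * n_a` exceeds `n_b`: not enough B nodes to pair",
         call. = FALSE)
  }
  min_sep <- 3 * max(coloc_offset, guard)
  margin <- 4 * params$psf_sigma + min_sep
  w_um <- (params$image_shape[2L] - 1) * params$pixel_size
  h_um <- (params$image_shape[1L] - 1) * params$pixel_size
  if (w_um - 2 * margin <= 0 || h_um - 2 * margin <= 0) {
    stop("image too small for the requested geometry", call. = FALSE)
  }

  .with_seed(params$seed, {
    place <- function(n, existing_x, existing_y, sep) {
      px <- numeric(0); py <- numeric(0)
      tries <- 0L
      while (length(px) < n) {
        if (tries >= max_tries) {
          stop("node placement impossible at the requested density", call. = FALSE)
        }
        cx <- stats::runif(1, margin, w_um - margin)
        cy <- stats::runif(1, margin, h_um - margin)
        d2 <- (c(existing_x, px) - cx)^2 + (c(existing_y, py) - cy)^2
        if (!length(d2) || min(d2) > sep^2) {
          px <- c(px, cx); py <- c(py, cy); tries <- 0L
        } else tries <- tries + 1L
      }
      list(x = px, y = py)
    }

    b <- place(n_b, numeric(0), numeric(0), min_sep)
    matched_b_id <- if (n_match > 0) sample(n_b, n_match) else integer(0)
    th <- stats::runif(n_match, 0, 2 * pi)
    rr <- coloc_offset * sqrt(stats::runif(n_match))
    ax <- b$x[matched_b_id] + rr * cos(th)
    ay <- b$y[matched_b_id] + rr * sin(th)
    a_free <- place(n_a - n_match, c(b$x, ax), c(b$y, ay), min_sep)
    ax <- c(ax, a_free$x); ay <- c(ay, a_free$y)
    matched <- c(matched_b_id, rep(NA_integer_, n_a - n_match))

    n_t <- params$n_frames
    walk <- function(x0, y0) {
      xs <- matrix(0, n_t, length(x0)); ys <- xs
      xs[1L, ] <- x0; ys[1L, ] <- y0
      if (n_t > 1L && step_scale > 0) {
        for (t in 2L:n_t) {
          xs[t, ] <- xs[t - 1L, ] + stats::rnorm(length(x0), 0, step_scale)
          ys[t, ] <- ys[t - 1L, ] + stats::rnorm(length(x0), 0, step_scale)
        }
      } else if (n_t > 1L) {
        xs[] <- rep(x0, each = n_t); ys[] <- rep(y0, each = n_t)
      }
      list(x = xs, y = ys)
    }
    wa <- walk(ax, ay); wb <- walk(b$x, b$y)

    render <- function(w, n) {
      frames <- array(0, c(n_t, params$image_shape))
      for (t in seq_len(n_t)) {
        img <- .render_points(w$x[t, ], w$y[t, ],
                              rep(amplitude * 2 * pi *
                                    (params$psf_sigma / params$pixel_size)^2, n),
                              params)
        frames[t, , ] <- .add_noise(img, params)
      }
      image_stack(frames, params$pixel_size, params$frame_interval)
    }

    truth <- dplyr::bind_rows(
      tibble::tibble(channel = "a",
                     node = rep(seq_len(n_a), each = n_t),
                     frame = rep(seq_len(n_t), n_a),
                     x_um = as.vector(wa$x), y_um = as.vector(wa$y),
                     matched_b = rep(matched, each = n_t)),
      tibble::tibble(channel = "b",
                     node = rep(seq_len(n_b), each = n_t),
                     frame = rep(seq_len(n_t), n_b),
                     x_um = as.vector(wb$x), y_um = as.vector(wb$y),
                     matched_b = NA_integer_)
    )
    list(channel_a = render(wa, n_a), channel_b = render(wb, n_b),
         truth = truth, overlap_fraction = n_match / n_a)
  })
}
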