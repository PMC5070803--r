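#' Detect punctate spots in a single frame
#'
#' Difference-of-Gaussians band-pass detection: the frame is smoothed at
#' `psf_sigma` and `1.6 * psf_sigma`, the difference taken, local maxima
#' found within a radius of one sigma, and maxima kept when their band-pass
#' amplitude exceeds `snr_threshold` times a robust noise estimate (the MAD
#' of the filtered image). Positions are refined to sub-pixel accuracy by an
#' intensity-weighted centroid over the 3x3 neighbourhood.
#'
#' @param frame 2D numeric matrix.
#' @param pixel_size um/px.
#' @param psf_sigma Expected spot sigma, um (> 0).
#' @param snr_threshold Detection threshold in units of the robust noise SD.
#' @return A tibble with one row per spot: `id`, `x_um`, `y_um`, `intensity`
#'   (band-pass amplitude at the maximum). Empty for blank frames.
#' @export
detect_spots <- function(frame, pixel_size, psf_sigma, snr_threshold = 5) {
  stopifnot(is.matrix(frame), psf_sigma > 0, pixel_size > 0)
  empty <- tibble::tibble(id = integer(), x_um = double(), y_um = double(),
                          intensity = double())
  if (diff(range(frame)) == 0) return(empty)

  sig_px <- psf_sigma / pixel_size
  bp <- as.matrix(EBImage::filter2(frame, .gauss_kernel(sig_px),
                                   boundary = "replicate")) -
    as.matrix(EBImage::filter2(frame, .gauss_kernel(1.6 * sig_px),
                               boundary = "replicate"))
  # robust noise scale, floored well above numerical round-off so noise-free
  # frames do not promote FFT residue to detections
  noise <- max(stats::mad(bp), 1e-9 * max(abs(bp)))
  if (noise == 0) return(empty)

  r <- max(1L, round(sig_px))
  nr <- nrow(bp); nc <- ncol(bp)
  # local maximum within a (2r+1) square window (superset of the sigma disk)
  dil <- bp
  for (dc in -r:r) for (dr in -r:r) {
    if (dr == 0 && dc == 0) next
    sh <- matrix(-Inf, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    sh[rs - dr, cs - dc] <- bp[rs, cs]
    dil <- pmax(dil, sh)
  }
  is_max <- bp >= dil & bp > snr_threshold * noise
  # exclude the one-pixel border so the 3x3 centroid is always defined
  is_max[c(1L, nr), ] <- FALSE
  is_max[, c(1L, nc)] <- FALSE
  idx <- which(is_max)
  if (!length(idx)) return(empty)

  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  x <- numeric(length(idx)); y <- numeric(length(idx))
  for (k in seq_along(idx)) {
    w <- bp[(rr[k] - 1L):(rr[k] + 1L), (cc[k] - 1L):(cc[k] + 1L)]
    w <- pmax(w, 0)
    if (sum(w) == 0) w[2L, 2L] <- 1
    x[k] <- (cc[k] - 1L) + sum(sweep(w, 2L, -1:1, "*")) / sum(w)
    y[k] <- (rr[k] - 1L) + sum(sweep(w, 1L, -1:1, "*")) / sum(w)
  }
  ord <- order(y, x)
  tibble::tibble(id = seq_along(idx),
                 x_um = x[ord] * pixel_size, y_um = y[ord] * pixel_size,
                 intensity = bp[idx][ord])
}

#' Detect spots in every frame of a stack
#'
#' @param stack An [image_stack()].
#' @inheritParams detect_spots
#' @return A tibble of spots with a `frame` column.
#' @export
detect_spots_stack <- function(stack, psf_sigma, snr_threshold = 5) {
  stopifnot(inherits(stack, "image_stack"))
  purrr::map_dfr(seq_len(n_frames(stack)), function(t) {
    sp <- detect_spots(stack_frame(stack, t), stack$pixel_size,
                       psf_sigma, snr_threshold)
    if (nrow(sp)) dplyr::mutate(sp, frame = t, .before = 1L) else NULL
  })
}

#' Link per-frame spots into tracks
#'
#' Greedy global nearest-neighbour linking: for each consecutive frame pair,
#' all candidate links with distance at most `search_radius` are sorted by
#' distance (ties broken by earlier frame, then lower spot id) and accepted
#' when both endpoints are still unmatched. Unmatched spots start new tracks;
#' there is no gap closing, so a disappearance or a jump beyond the radius
#' ends the track.
#'
#' @param spots A tibble with columns `frame`, `id`, `x_um`, `y_um` (and
#'   optionally `intensity`), as from [detect_spots_stack()].
#' @param search_radius Maximum per-step displacement, um.
#' @return The spots tibble with a `track_id` column, ordered by track and
#'   frame.
#' @export
link_tracks <- function(spots, search_radius = 1) {
  stopifnot(search_radius > 0)
  need <- c("frame", "id", "x_um", "y_um")
  stopifnot(all(need %in% names(spots)))
  spots <- dplyr::arrange(spots, .data$frame, .data$id)
  if (!nrow(spots)) return(dplyr::mutate(spots, track_id = integer()))

  spots$.row <- seq_len(nrow(spots))
  track_of <- rep(NA_integer_, nrow(spots))
  next_track <- 1L
  frames <- sort(unique(spots$frame))
  by_frame <- split(spots, spots$frame)

  for (fi in seq_along(frames)) {
    cur <- by_frame[[as.character(frames[fi])]]
    new_idx <- cur$.row[is.na(track_of[cur$.row])]
    if (length(new_idx)) {
      track_of[new_idx] <- seq(next_track, length.out = length(new_idx))
      next_track <- next_track + length(new_idx)
    }
    if (fi == length(frames)) break
    if (frames[fi + 1L] != frames[fi] + 1L) next  # missing frame: tracks end
    nxt <- by_frame[[as.character(frames[fi + 1L])]]
    if (!nrow(cur) || !nrow(nxt)) next
    d <- sqrt(outer(cur$x_um, nxt$x_um, "-")^2 + outer(cur$y_um, nxt$y_um, "-")^2)
    cand <- which(d <= search_radius, arr.ind = TRUE)
    if (!nrow(cand)) next
    ord <- order(d[cand], cur$id[cand[, 1L]], nxt$id[cand[, 2L]])
    used_a <- logical(nrow(cur)); used_b <- logical(nrow(nxt))
    for (k in ord) {
      i <- cand[k, 1L]; j <- cand[k, 2L]
      if (!used_a[i] && !used_b[j]) {
        used_a[i] <- TRUE; used_b[j] <- TRUE
        track_of[nxt$.row[j]] <- track_of[cur$.row[i]]
      }
    }
  }
  out <- dplyr::mutate(spots, track_id = track_of[.data$.row])
  out$.row <- NULL
  dplyr::arrange(out, .data$track_id, .data$frame)
}

#' Per-track displacement, speed and excursion statistics
#'
#' For each track: `displacement_um` is the net start-to-end distance,
#' `mean_speed_um_s` the mean consecutive-step distance over the frame
#' interval, `max_excursion_um` the largest distance from the starting
#' position. Single-spot tracks have no defined speed and are reported with
#' `NA`. The returned tibble carries the cohort fraction of tracks whose
#' maximum excursion stays within `excursion_threshold` as attribute
#' `fraction_within`; see [excursion_fraction()].
#'
#' @param tracks A linked spot tibble from [link_tracks()].
#' @param frame_interval s per frame.
#' @param excursion_threshold Cohort excursion threshold, um (default 2).
#' @return A tibble with one row per track.
#' @export
track_statistics <- function(tracks, frame_interval, excursion_threshold = 2) {
  stopifnot(frame_interval > 0, nrow(tracks) >= 1)
  stats_tbl <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::summarise(
      n_spots = dplyr::n(),
      start_frame = .data$frame[1L],
      displacement_um = sqrt((dplyr::last(.data$x_um) - .data$x_um[1L])^2 +
                               (dplyr::last(.data$y_um) - .data$y_um[1L])^2),
      mean_speed_um_s = if (dplyr::n() < 2L) NA_real_ else
        mean(sqrt(diff(.data$x_um)^2 + diff(.data$y_um)^2)) / frame_interval,
      max_excursion_um = max(sqrt((.data$x_um - .data$x_um[1L])^2 +
                                    (.data$y_um - .data$y_um[1L])^2)),
      .groups = "drop"
    )
  attr(stats_tbl, "fraction_within") <-
    mean(stats_tbl$max_excursion_um <= excursion_threshold)
  attr(stats_tbl, "excursion_threshold") <- excursion_threshold
  stats_tbl
}

#' Fraction of tracks staying within an excursion threshold
#'
#' @param track_stats Output of [track_statistics()].
#' @param threshold Excursion threshold, um.
#' @return Proportion of tracks with `max_excursion_um <= threshold`.
#' @export
excursion_fraction <- function(track_stats, threshold = 2) {
  mean(track_stats$max_excursion_um <= threshold)
}

#' Translate tracks to a common origin
#'
#' Subtracts each track's first position so every track starts at (0, 0),
#' the standard rose-plot presentation of spot mobility.
#'
#' @param tracks A linked spot tibble from [link_tracks()].
#' @return The tibble with added `x_rel_um`, `y_rel_um` columns.
#' @export
translate_to_origin <- function(tracks) {
  tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::mutate(x_rel_um = .data$x_um - .data$x_um[1L],
                  y_rel_um = .data$y_um - .data$y_um[1L]) |>
    dplyr::ungroup()
}

#' Bidirectional colocalization of two point sets
#'
#' The fraction of A points lying within `distance_threshold` of any B point,
#' and vice versa. The two fractions are independent (a B point may serve
#' several A points); empty inputs give `NA` for the corresponding fraction.
#'
#' @param a,b Tibbles or data frames with `x_um`, `y_um` columns.
#' @param distance_threshold Colocalization distance, um (> 0).
#' @return A one-row tibble: `fraction_a_near_b`, `fraction_b_near_a`,
#'   `n_a`, `n_b`.
#' @export
colocalize_spots <- function(a, b, distance_threshold) {
  stopifnot(distance_threshold > 0)
  frac <- function(p, q) {
    if (!nrow(p)) return(NA_real_)
    if (!nrow(q)) return(NA_real_)
    d2 <- outer(p$x_um, q$x_um, "-")^2 + outer(p$y_um, q$y_um, "-")^2
    mean(apply(d2, 1L, min) <= distance_threshold^2)
  }
  tibble::tibble(
    fraction_a_near_b = frac(a, b),
    fraction_b_near_a = frac(b, a),
    n_a = nrow(a), n_b = nrow(b)
  )
}
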