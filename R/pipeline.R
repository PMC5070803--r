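#' Write an image stack as multi-page TIFF with a calibration sidecar
#'
#' Pixel data are stored as 16-bit TIFF pages (axis order `T[,Z],Y,X`).
#' Stacks whose values lie in `[0, 1]` are written on the 16-bit grid
#' directly, so grid-valued data round-trip bit-identically; other stacks
#' are affinely rescaled, with the offset and scale recorded in the YAML
#' sidecar (`<path>.yaml`) together with pixel size, frame interval and
#' axis layout (quantization error is at most `(max - min) / 65535`).
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  rng <- range(stack$data)
  if (rng[1L] >= 0 && rng[2L] <= 1) {
    offset <- 0; scale <- 1
  } else {
    offset <- rng[1L]
    scale <- if (diff(rng) > 0) diff(rng) else 1
  }
  norm <- round((stack$data - offset) / scale * 65535) / 65535
  pages <- list()
  if (length(d) == 3L) {
    for (t in seq_len(d[1L])) pages[[t]] <- matrix(norm[t, , ], d[2L], d[3L])
    axes <- "TYX"; n_z <- NULL
  } else {
    k <- 0L
    for (t in seq_len(d[1L])) for (z in seq_len(d[2L])) {
      k <- k + 1L
      pages[[k]] <- matrix(norm[t, z, , ], d[3L], d[4L])
    }
    axes <- "TZYX"; n_z <- d[2L]
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  meta <- list(axes = axes, pixel_size_um = stack$pixel_size,
               frame_interval_s = stack$frame_interval,
               intensity_offset = offset, intensity_scale = scale)
  if (!is.null(n_z)) meta$n_z <- n_z
  if (!is.null(stack$z_spacing)) meta$z_spacing_um <- stack$z_spacing
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' Read a calibrated image stack from multi-page TIFF
#'
#' Reads the sidecar written by [write_stack()] when present; otherwise
#' calibration must be supplied explicitly. A single-page TIFF becomes a
#' one-frame stack.
#'
#' @param path TIFF path.
#' @param pixel_size,frame_interval,z_spacing Calibration overrides (um/px,
#'   s, um); required if no sidecar exists.
#' @param n_z Number of z slices per time point for 4D data without sidecar.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, pixel_size = NULL, frame_interval = NULL,
                       z_spacing = NULL, n_z = NULL) {
  sidecar <- paste0(path, ".yaml")
  offset <- 0; scale <- 1
  if (file.exists(sidecar)) {
    meta <- yaml::read_yaml(sidecar)
    if (is.null(pixel_size)) pixel_size <- meta$pixel_size_um
    if (is.null(frame_interval)) frame_interval <- meta$frame_interval_s
    if (is.null(z_spacing)) z_spacing <- meta$z_spacing_um
    if (is.null(n_z)) n_z <- meta$n_z
    if (!is.null(meta$intensity_offset)) offset <- meta$intensity_offset
    if (!is.null(meta$intensity_scale)) scale <- meta$intensity_scale
  }
  if (is.null(pixel_size) || is.null(frame_interval)) {
    stop("no calibration sidecar found: supply `pixel_size` (um/px) and `frame_interval` (s)",
         call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  if (offset != 0 || scale != 1) {
    pages <- lapply(pages, function(m) m * scale + offset)
  }
  nr <- nrow(pages[[1L]]); nc <- ncol(pages[[1L]])
  if (is.null(n_z)) {
    data <- array(0, c(length(pages), nr, nc))
    for (t in seq_along(pages)) data[t, , ] <- pages[[t]]
  } else {
    n_t <- length(pages) / n_z
    stopifnot(n_t == round(n_t))
    data <- array(0, c(n_t, n_z, nr, nc))
    k <- 0L
    for (t in seq_len(n_t)) for (z in seq_len(n_z)) {
      k <- k + 1L
      data[t, z, , ] <- pages[[k]]
    }
  }
  image_stack(data, pixel_size, frame_interval, z_spacing)
}

#' Pipeline run configuration
#'
#' Assembles, validates and (de)serializes the parameters of a pipeline run.
#' All physical parameters are in the package's user-facing units (lengths
#' um, times s, rates nm/s); configurations round-trip losslessly through
#' YAML.
#'
#' @param preset One of `"photoactivation"`, `"frap"`, `"nodes"`,
#'   `"filaments"`, `"cell"`.
#' @param seed Integer master seed for the run.
#' @param output_dir Output directory.
#' @param ... Stage parameter overrides (e.g. `search_radius`, `delta_r`,
#'   `shell_thickness`, `snr_threshold`, `coloc_threshold`, plus any
#'   [sim_params()] field).
#' @return A `run_config` list.
#' @export
run_config <- function(preset = c("photoactivation", "frap", "nodes",
                                  "filaments", "cell"),
                       seed = 1L, output_dir = tempfile("nodetrace_run_"), ...) {
  preset <- match.arg(preset)
  cfg <- list(preset = preset, seed = as.integer(seed),
              output_dir = output_dir,
              pixel_size = 0.1, frame_interval = 0.04,
              search_radius = 1.0, snr_threshold = 5,
              coloc_threshold = 0.24, delta_r = 0.2,
              shell_thickness = 1.0)
  dots <- list(...)
  cfg[names(dots)] <- dots
  for (p in c("pixel_size", "frame_interval", "search_radius", "snr_threshold",
              "coloc_threshold", "delta_r", "shell_thickness")) {
    if (cfg[[p]] <= 0) stop(sprintf("`%s` must be positive", p), call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname run_config
#' @param cfg A `run_config` (for [write_run_config()]).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' Run a simulation-plus-analysis pipeline stage chain
#'
#' Simulates the configured preset scene, runs the matching analysis stages,
#' and writes every declared output (TIFF stacks, CSV tables) together with
#' a structured plain-text log recording parameters, seed, package version
#' and per-stage timing. Two runs with equal configuration are identical.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a named list of result objects (also written to
#'   `cfg$output_dir`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$output_dir, "run_log.txt")
  log_lines <- c(
    sprintf("nodetrace %s", as.character(utils::packageVersion("nodetrace"))),
    sprintf("preset: %s", cfg$preset),
    sprintf("seed: %d", cfg$seed),
    paste0("param ", names(unclass(cfg)), ": ",
           vapply(unclass(cfg), function(v) paste(format(v), collapse = ","),
                  character(1L)))
  )
  results <- list()
  stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(code), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    log_lines <<- c(log_lines, sprintf("stage %s: %.2f s", name,
                                       proc.time()[["elapsed"]] - t0))
    out
  }
  write_csv0 <- function(df, name) {
    utils::write.csv(df, file.path(cfg$output_dir, name), row.names = FALSE)
  }

  if (cfg$preset == "photoactivation") {
    p <- sim_params(pixel_size = cfg$pixel_size, frame_interval = cfg$frame_interval,
                    n_frames = 26L, image_shape = c(160L, 160L),
                    read_noise_sigma = 0.01, seed = .substream_seed(cfg$seed, 1L))
    roi <- circular_roi(8, 8, 0.8)
    sim <- stage("simulate", simulate_photoactivation(
      p, D = 5, immobile_fraction = 0.2, roi = roi, n_molecules = 800L,
      decay_constant = 0.5))
    stage("write", {
      write_stack(sim$stack, file.path(cfg$output_dir, "stack.tif"))
      write_csv0(sim$truth, "truth.csv")
    })
    sc <- stage("spread", spreading_vs_time(sim$stack, roi, delta_r = cfg$delta_r))
    write_csv0(sc, "spreading_curve.csv")
    results <- list(sim = sim, spreading = sc)
  } else if (cfg$preset == "frap") {
    # 12-um cell, 4.8 s acquisition: ~5 whole-cell mixing times at D = 10,
    # so the recovery plateau is identifiable (see the methods vignette)
    p <- sim_params(pixel_size = 0.2, frame_interval = 0.02, n_frames = 240L,
                    image_shape = c(96L, 96L), read_noise_sigma = 0.02,
                    seed = .substream_seed(cfg$seed, 2L))
    ctr <- (p$image_shape - 1) * p$pixel_size / 2
    geom <- list(
      cell_mask = make_cell_mask("disk", p$image_shape, p$pixel_size,
                                 center = c(ctr[2L], ctr[1L]), radius = 6),
      roi = circular_roi(ctr[2L], ctr[1L], 1.5)
    )
    geom$background <- !geom$cell_mask
    geom$reference <- geom$cell_mask &
      !roi_mask(circular_roi(ctr[2L], ctr[1L], 3), p$image_shape, p$pixel_size)
    sim <- stage("simulate", simulate_frap(
      p, D = 10, bound_fraction = 0.2, roi = geom$roi, bleach_depth = 1,
      cell_mask = geom$cell_mask, n_molecules = 8000L, bleach_frame = 6L))
    stage("write", write_stack(sim$stack, file.path(cfg$output_dir, "stack.tif")))
    curve <- stage("extract", extract_recovery(
      sim$stack, geom$roi, geom$background, geom$reference, sim$bleach_frame))
    fit <- stage("fit", fit_two_exp(curve))
    write_csv0(curve, "recovery_curve.csv")
    write_csv0(glance(fit), "frap_fit.csv")
    results <- list(sim = sim, curve = curve, fit = fit)
  } else if (cfg$preset == "nodes") {
    p <- sim_params(pixel_size = cfg$pixel_size, frame_interval = 1,
                    n_frames = 3L, image_shape = c(192L, 192L),
                    read_noise_sigma = 0.02, seed = .substream_seed(cfg$seed, 3L))
    sim <- stage("simulate", simulate_node_scene(
      p, n_a = 40L, n_b = 40L, overlap_fraction = 0.55, coloc_offset = 0.1))
    sa <- stage("detect", detect_spots_stack(sim$channel_a, p$psf_sigma,
                                             cfg$snr_threshold))
    sb <- detect_spots_stack(sim$channel_b, p$psf_sigma, cfg$snr_threshold)
    co <- stage("colocalize", colocalize_spots(sa[sa$frame == 1L, ],
                                               sb[sb$frame == 1L, ],
                                               cfg$coloc_threshold))
    write_csv0(sim$truth, "truth.csv")
    write_csv0(co, "colocalization.csv")
    results <- list(sim = sim, spots_a = sa, spots_b = sb, coloc = co)
  } else if (cfg$preset == "filaments") {
    p <- sim_params(pixel_size = cfg$pixel_size, frame_interval = cfg$frame_interval,
                    n_frames = 126L, image_shape = c(168L, 168L),
                    read_noise_sigma = 0.1, seed = .substream_seed(cfg$seed, 4L))
    sim <- stage("simulate", simulate_growing_filaments(
      p, n_filaments = 4L, rate = 25.2))
    vel <- stage("velocity", filament_velocities(sim))
    write_csv0(sim$truth, "truth.csv")
    write_csv0(vel, "tip_velocities.csv")
    results <- list(sim = sim, velocities = vel)
  } else {
    p <- sim_params(pixel_size = 0.2, frame_interval = 1, n_frames = 5L,
                    image_shape = c(96L, 96L), read_noise_sigma = 0.02,
                    seed = .substream_seed(cfg$seed, 5L))
    sim <- stage("simulate", simulate_cell_scene(
      p, list(shape = "disk", radius = 7), membrane_intensity = 2,
      cytosol_intensity = 1, shell_thickness = cfg$shell_thickness))
    seg <- stage("segment", segment_cell(stack_frame(sim$stack, 1L), p$pixel_size))
    part <- stage("shell", membrane_shell(seg, cfg$shell_thickness))
    ratio <- stage("ratio", membrane_cytosol_ratio(sim$stack, part,
                                                   reference_frame = 1L))
    write_csv0(ratio, "membrane_cytosol_ratio.csv")
    results <- list(sim = sim, mask = seg, partition = part, ratio = ratio)
  }
  writeLines(log_lines, log_path)
  invisible(results)
}

# shared FRAP benchmark geometry: 20-um cell, 2-um central ROI, reference =
# whole cell minus a 4-um guard zone around the ROI (low-variance bleaching
# correction), background outside the cell
.frap_geometry <- function(params) {
  ctr <- (params$image_shape - 1) * params$pixel_size / 2
  cell <- make_cell_mask("disk", params$image_shape, params$pixel_size,
                         center = c(ctr[2L], ctr[1L]), radius = 10)
  guard <- roi_mask(circular_roi(ctr[2L], ctr[1L], 4),
                    params$image_shape, params$pixel_size)
  list(
    cell_mask = cell,
    roi = circular_roi(ctr[2L], ctr[1L], 2),
    reference = cell & !guard,
    background = !cell
  )
}

#' Tip velocities for every filament of a simulated scene
#'
#' Extracts a kymograph along each filament's true axis and estimates the
#' tip velocity from its half-maximum front.
#'
#' @param sim Output of [simulate_growing_filaments()].
#' @param line_margin Extra line length beyond the final tip, um.
#' @return Tibble with `filament`, `velocity_nm_s`, `true_rate_nm_s`.
#' @export
filament_velocities <- function(sim, line_margin = 0.4) {
  truth1 <- sim$truth[!duplicated(sim$truth$filament), ]
  tips_final <- tapply(sim$truth$tip_um, sim$truth$filament, max)
  purrr::map_dfr(seq_len(nrow(truth1)), function(i) {
    len <- tips_final[[i]] + line_margin
    line <- rbind(
      c(truth1$origin_x[i], truth1$origin_y[i]),
      c(truth1$origin_x[i] + truth1$dir_x[i] * len,
        truth1$origin_y[i] + truth1$dir_y[i] * len)
    )
    kym <- kymograph(sim$stack, line)
    tv <- estimate_tip_velocity(kym)
    tibble::tibble(filament = truth1$filament[i],
                   velocity_nm_s = tv$velocity_nm_s,
                   true_rate_nm_s = truth1$rate_nm_s[i])
  })
}
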