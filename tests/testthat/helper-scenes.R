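# Small fixture builders shared across tests. Everything is generated in
# code at test time; no stored image data.

# quiet acquisition: no camera noise, deterministic
quiet_params <- function(n_frames = 5L, image_shape = c(64L, 64L),
                         pixel_size = 0.1, frame_interval = 0.04, seed = 1L,
                         poisson_gain = NULL, read_noise_sigma = 0, ...) {
  sim_params(pixel_size = pixel_size, frame_interval = frame_interval,
             n_frames = n_frames, image_shape = image_shape,
             poisson_gain = poisson_gain, read_noise_sigma = read_noise_sigma,
             seed = seed, ...)
}

# a rendered single-frame image containing PSF spots at given um positions
render_spot_frame <- function(xy, pixel_size = 0.1, psf_sigma = 0.12,
                              image_shape = c(64L, 64L), amplitude = 1,
                              noise_sd = 0) {
  p <- sim_params(pixel_size = pixel_size, frame_interval = 1, n_frames = 1L,
                  image_shape = image_shape, psf_sigma = psf_sigma,
                  read_noise_sigma = noise_sd, seed = 7L)
  w <- amplitude * 2 * pi * (psf_sigma / pixel_size)^2
  img <- nodetrace:::.render_points(xy[, 1L], xy[, 2L], rep(w, nrow(xy)), p)
  if (noise_sd > 0) {
    set.seed(7L)
    img <- img + matrix(rnorm(length(img), 0, noise_sd), nrow(img), ncol(img))
  }
  img
}

# spots tibble straight from simulation truth (bypasses detection)
truth_as_spots <- function(truth) {
  dplyr::transmute(truth, frame, id = molecule, x_um, y_um,
                   intensity = brightness)
}

# compact FRAP scene for fit tests: 10-um cell, 1-um ROI
small_frap <- function(seed = 1L, D = 5, bound_fraction = 0.2,
                       n_molecules = 3000L, n_frames = 160L) {
  p <- sim_params(pixel_size = 0.2, frame_interval = 0.02, n_frames = n_frames,
                  image_shape = c(64L, 64L), read_noise_sigma = 0.02,
                  seed = seed)
  ctr <- (p$image_shape - 1) * p$pixel_size / 2
  cell <- make_cell_mask("disk", p$image_shape, p$pixel_size,
                         center = c(ctr[2L], ctr[1L]), radius = 5)
  roi <- circular_roi(ctr[2L], ctr[1L], 1)
  guard <- roi_mask(circular_roi(ctr[2L], ctr[1L], 2), p$image_shape, p$pixel_size)
  sim <- simulate_frap(p, D = D, bound_fraction = bound_fraction, roi = roi,
                       bleach_depth = 1, cell_mask = cell,
                       n_molecules = n_molecules, bleach_frame = 6L)
  list(params = p, sim = sim, roi = roi, cell = cell,
       reference = cell & !guard, background = !cell)
}
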