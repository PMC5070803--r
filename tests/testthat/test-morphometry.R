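test_that("the distance transform matches EBImage on 2D masks", {
  set.seed(5)
  m <- matrix(FALSE, 48L, 56L)
  m[8:40, 10:48] <- TRUE
  m[cbind(sample(8:40, 12), sample(10:48, 12))] <- FALSE  # punch holes
  d_pkg <- boundary_distance(m, 1)
  d_ebi <- EBImage::imageData(EBImage::distmap(EBImage::Image(m)))
  expect_equal(d_pkg, d_ebi, tolerance = 1e-12)
})

test_that("membrane shell of a disk matches the analytic annulus area", {
  # disk radius 10 um, shell 1 um: area pi (10^2 - 9^2) = 59.69 um^2
  px <- 0.1
  mask <- make_cell_mask("disk", c(256L, 256L), px, radius = 10)
  part <- membrane_shell(mask, thickness = 1, pixel_size = px)
  shell_area <- sum(part$membrane) * px^2
  expect_equal(shell_area, pi * (10^2 - 9^2), tolerance = 0.05)
  # exact partition of the mask
  expect_true(all((part$membrane | part$cytosol) == mask))
  expect_false(any(part$membrane & part$cytosol))
})

test_that("degenerate shell thicknesses behave as contracted", {
  mask <- make_cell_mask("disk", c(64L, 64L), 0.2, radius = 4)
  p0 <- membrane_shell(mask, thickness = 0, pixel_size = 0.2)
  expect_false(any(p0$membrane))
  expect_warning(pw <- membrane_shell(mask, thickness = 10, pixel_size = 0.2),
                 "whole mask")
  expect_true(pw$shell_is_whole_cell)
  expect_true(all(pw$membrane == mask))
})

test_that("3D shells respect anisotropic voxel sizes", {
  # 3D ball, radius 4 um, voxels 0.5 um (z) x 0.25 um (xy)
  nz <- 21L; nxy <- 41L
  zc <- (nz - 1) / 2 * 0.5; xyc <- (nxy - 1) / 2 * 0.25
  ball <- array(FALSE, c(nz, nxy, nxy))
  for (z in seq_len(nz)) {
    g <- expand.grid(y = seq_len(nxy), x = seq_len(nxy))
    r2 <- ((z - 1) * 0.5 - zc)^2 + ((g$y - 1) * 0.25 - xyc)^2 +
      ((g$x - 1) * 0.25 - xyc)^2
    ball[z, , ] <- matrix(r2 <= 4^2, nxy, nxy)
  }
  expect_error(membrane_shell(ball, 1, pixel_size = 0.25), "z_spacing")
  part <- membrane_shell(ball, 1, pixel_size = 0.25, z_spacing = 0.5)
  vol <- function(m) sum(m) * 0.5 * 0.25^2
  expect_equal(vol(part$membrane), 4 / 3 * pi * (4^3 - 3^3), tolerance = 0.12)
  expect_equal(vol(part$cytosol), 4 / 3 * pi * 3^3, tolerance = 0.12)
})

test_that("segmentation recovers synthetic cells and honors contracts", {
  p <- quiet_params(n_frames = 1L, image_shape = c(128L, 128L),
                    pixel_size = 0.2, seed = 91L, read_noise_sigma = 0.1)
  sc <- simulate_cell_scene(p, list(shape = "disk", radius = 8),
                            membrane_intensity = 1, cytosol_intensity = 1,
                            shell_thickness = 1)
  seg <- segment_cell(stack_frame(sc$stack, 1L), 0.2)
  jacc <- sum(seg & sc$cell_mask) / sum(seg | sc$cell_mask)
  expect_gte(jacc, 0.95)
  # inverted contrast with the flag gives the same mask
  seg_inv <- segment_cell(max(stack_frame(sc$stack, 1L)) -
                            stack_frame(sc$stack, 1L), 0.2, invert = TRUE)
  expect_equal(sum(xor(seg, seg_inv)), 0L)
  expect_error(segment_cell(matrix(3, 32L, 32L), 0.2), "constant")
})

test_that("with two blobs the larger one is retained", {
  img <- matrix(0, 100L, 100L)
  img[10:40, 10:40] <- 1    # 31 x 31
  img[60:75, 60:75] <- 1    # 16 x 16
  seg <- segment_cell(img, pixel_size = 1, smoothing_sigma = 1)
  expect_true(seg[25, 25]); expect_false(seg[67, 67])
})

test_that("membrane/cytosol ratios report designed contrast and ramps", {
  p <- quiet_params(n_frames = 5L, image_shape = c(96L, 96L),
                    pixel_size = 0.2, seed = 92L)
  ramp <- seq(1, 2, length.out = 5L)
  sc <- simulate_cell_scene(p, list(shape = "disk", radius = 7),
                            membrane_intensity = ramp, cytosol_intensity = 1,
                            shell_thickness = 1)
  part <- membrane_shell(sc$cell_mask, 1, pixel_size = 0.2)
  rt <- membrane_cytosol_ratio(sc$stack, part, reference_frame = 1L)
  # PSF blur mixes the thin shell with its surroundings; the ratio tracks the
  # designed ramp shape (fold change), not the exact plateau values
  expect_equal(rt$fold_change[1L], 1)
  fit <- lm(rt$ratio ~ ramp)
  expect_gt(summary(fit)$r.squared, 0.99)
  # uniform scene: ratio 1 within noise
  sc1 <- simulate_cell_scene(p, list(shape = "disk", radius = 7),
                             membrane_intensity = 1, cytosol_intensity = 1,
                             shell_thickness = 1)
  rt1 <- membrane_cytosol_ratio(sc1$stack, part)
  expect_equal(rt1$ratio, rep(1, 5L), tolerance = 0.05)
})

test_that("ratio is invariant to global intensity scaling", {
  p <- quiet_params(n_frames = 2L, image_shape = c(96L, 96L),
                    pixel_size = 0.2, seed = 93L)
  sc <- simulate_cell_scene(p, list(shape = "disk", radius = 7),
                            membrane_intensity = 2, cytosol_intensity = 1,
                            shell_thickness = 1)
  part <- membrane_shell(sc$cell_mask, 1, pixel_size = 0.2)
  r1 <- membrane_cytosol_ratio(sc$stack, part)$ratio
  scaled <- sc$stack; scaled$data <- scaled$data * 11
  r2 <- membrane_cytosol_ratio(scaled, part)$ratio
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("kymographs reproduce static and advancing sources", {
  p <- quiet_params(n_frames = 10L, image_shape = c(64L, 64L), seed = 94L,
                    frame_interval = 1)
  s <- simulate_growing_filaments(p, n_filaments = 1L, rate = 0,
                                  origins = matrix(c(1.5, 3.2), 1L),
                                  directions = 0, initial_length = 2)
  kym <- kymograph(s$stack, rbind(c(1.5, 3.2), c(4.5, 3.2)))
  for (t in 2:10) expect_equal(kym$data[t, ], kym$data[1L, ], tolerance = 1e-12)
  expect_error(kymograph(s$stack, rbind(c(-1, 3.2), c(4.5, 3.2))), "exits")
})

test_that("kymograph round trip recovers the true tip trajectory", {
  p <- quiet_params(n_frames = 101L, image_shape = c(96L, 96L), seed = 95L,
                    frame_interval = 0.04)
  s <- simulate_growing_filaments(p, n_filaments = 1L, rate = 200,
                                  origins = matrix(c(2, 4.8), 1L),
                                  directions = 0, initial_length = 2)
  kym <- kymograph(s$stack, rbind(c(2, 4.8), c(6, 4.8)))
  tv <- estimate_tip_velocity(kym)
  truth_tips <- s$truth$tip_um
  # tip front tracks truth within a pixel at every sampled frame
  resid <- tv$tips$tip_um - truth_tips[match(round(tv$tips$time_s, 9),
                                             round(s$truth$time_s, 9))]
  expect_lt(max(abs(resid)), 0.1 + 1e-9)
  expect_equal(tv$velocity_nm_s, 200, tolerance = 0.05)
})

test_that("tip velocimetry is unbiased on noise-free synthetic kymographs", {
  # hand-built kymograph: front advancing 0.02 um per 0.04 s = 500 nm/s
  s_axis <- seq(0, 10, by = 0.1)
  rows <- t(vapply(0:99, function(i) {
    tip <- 2 + 0.02 * i
    ifelse(s_axis <= tip, 1, pmax(0, 1 - (s_axis - tip) / 0.05))
  }, numeric(length(s_axis))))
  kym <- structure(list(data = rows, arclength_um = s_axis,
                        pixel_size = 0.1, frame_interval = 0.04),
                   class = "kymograph")
  tv <- estimate_tip_velocity(kym)
  expect_equal(tv$velocity_nm_s, 500, tolerance = 0.01)
  # static filament: zero velocity
  kst <- structure(list(data = rows[rep(1L, 10L), ], arclength_um = s_axis,
                        pixel_size = 0.1, frame_interval = 0.04),
                   class = "kymograph")
  expect_equal(estimate_tip_velocity(kst)$velocity_nm_s, 0, tolerance = 1e-9)
  # sub-pixel advance per frame is recovered by regression over many rows
  rows_sub <- t(vapply(0:199, function(i) {
    tip <- 2 + 0.002 * i  # 0.02 px per frame
    ifelse(s_axis <= tip, 1, pmax(0, 1 - (s_axis - tip) / 0.05))
  }, numeric(length(s_axis))))
  ks <- structure(list(data = rows_sub, arclength_um = s_axis,
                       pixel_size = 0.1, frame_interval = 0.04),
                  class = "kymograph")
  expect_equal(estimate_tip_velocity(ks)$velocity_nm_s, 50, tolerance = 0.02)
  # all-dark kymograph: failure flag
  dark <- structure(list(data = matrix(0, 6L, 20L), arclength_um = 1:20,
                         pixel_size = 0.1, frame_interval = 0.04),
                    class = "kymograph")
  expect_false(estimate_tip_velocity(dark)$converged)
})

test_that("temporal MIP encodes frame order as hue", {
  p <- quiet_params(n_frames = 5L, image_shape = c(32L, 32L), seed = 96L)
  data <- array(0, c(5L, 32L, 32L))
  data[3L, 16L, 16L] <- 1           # bright only in frame 3
  data[, 8L, 8L] <- 1               # bright in every frame
  st <- image_stack(data, 0.1, 0.04)
  mip <- temporal_mip(st)
  cols <- grDevices::col2rgb(grDevices::colorRampPalette(
    c("blue", "cyan", "green", "yellow", "red"))(5L)) / 255
  expect_equal(as.numeric(unclass(mip)[16L, 16L, ]), as.numeric(cols[, 3L]))
  # a pixel bright in all frames covers the spectrum: all channels saturated
  expect_equal(as.numeric(unclass(mip)[8L, 8L, ]), c(1, 1, 1))
})

test_that("rolling-ball subtraction removes ramps and keeps spots", {
  flat <- matrix(4, 40L, 40L)
  out <- rolling_ball_background(flat, 5)
  expect_true(all(out == 0))
  # spot on a ramp: ramp removed, spot amplitude preserved within 5%
  ramp <- outer(seq(0, 2, length.out = 60L), rep(1, 60L))
  img <- ramp
  img[29:31, 29:31] <- img[29:31, 29:31] + 10
  out2 <- rolling_ball_background(img, 12)
  expect_lt(max(out2[-(27:33), -(27:33)]), 0.5)
  expect_equal(max(out2), 10, tolerance = 0.05)
  # huge radius limit: image minus its minimum
  sm <- outer(seq(1, 2, length.out = 15L), seq(1, 1.5, length.out = 15L))
  out3 <- rolling_ball_background(sm, 40, height = 0.01)
  expect_equal(out3, sm - min(sm), tolerance = 0.05, ignore_attr = TRUE)
})

test_that("pairwise correlations match hand computation and flag degeneracy", {
  tbl <- tibble::tibble(a = c(1, 2, 3, 4), b = c(2, 1, 4, 3),
                        c = -c(1, 2, 3, 4), k = rep(5, 4))
  m <- pairwise_correlation(tbl)
  expect_equal(m["a", "a"], 1)
  expect_equal(m["a", "c"], -1)
  expect_equal(m["a", "b"], cor(tbl$a, tbl$b))  # 0.6 by hand
  expect_equal(cor(tbl$a, tbl$b), 0.6)
  expect_true(all(is.na(m["k", ])))
  few <- tibble::tibble(x = c(1, 2, NA, NA), y = c(1, NA, 2, 3))
  expect_true(all(is.na(suppressWarnings(pairwise_correlation(few))["x", "y"])))
})
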