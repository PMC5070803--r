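test_that("identical seeds give bit-identical stacks and truth", {
  p <- quiet_params(n_frames = 4L, seed = 11L, read_noise_sigma = 0.05,
                    poisson_gain = 100)
  roi <- circular_roi(3.2, 3.2, 0.8)
  a <- simulate_photoactivation(p, D = 2, immobile_fraction = 0.3, roi = roi,
                                n_molecules = 50L, decay_constant = 0.2)
  b <- simulate_photoactivation(p, D = 2, immobile_fraction = 0.3, roi = roi,
                                n_molecules = 50L, decay_constant = 0.2)
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$truth, b$truth)
})

test_that("nothing moves or fades with D = 0, no decay, no noise", {
  p <- quiet_params(n_frames = 5L, seed = 2L)
  s <- simulate_photoactivation(p, D = 0, immobile_fraction = 0,
                                roi = circular_roi(3.2, 3.2, 0.8),
                                n_molecules = 40L, decay_constant = 0)
  for (t in 2:5) {
    expect_identical(stack_frame(s$stack, t), stack_frame(s$stack, 1L))
  }
})

test_that("Brownian step SD matches sqrt(2 D dt)", {
  # closed-form increment oracle: sqrt(2 * 5 * 0.04) = 0.6325 um per axis
  p <- quiet_params(n_frames = 21L, image_shape = c(400L, 400L), seed = 5L)
  s <- simulate_photoactivation(p, D = 5, immobile_fraction = 0,
                                roi = circular_roi(20, 20, 2),
                                n_molecules = 600L, decay_constant = 0)
  tr <- s$truth
  dx <- unlist(tapply(tr$x_um, tr$molecule, diff))
  expect_gt(length(dx), 1e4)
  expect_equal(sd(dx), sqrt(2 * 5 * 0.04), tolerance = 0.02)
})

test_that("mobile-molecule MSD follows 4 D t; immobile molecules are frozen", {
  p <- quiet_params(n_frames = 11L, image_shape = c(400L, 400L), seed = 9L)
  s <- simulate_photoactivation(p, D = 3, immobile_fraction = 0.25,
                                roi = circular_roi(20, 20, 2),
                                n_molecules = 2000L, decay_constant = 0)
  tr <- s$truth
  xs <- matrix(tr$x_um, nrow = 11L)   # frames x molecules
  ys <- matrix(tr$y_um, nrow = 11L)
  mob <- matrix(tr$mobility, nrow = 11L)[1L, ] == "mobile"
  # immobile: identical positions in every frame
  expect_true(all(apply(xs[, !mob, drop = FALSE], 2L, function(v) all(v == v[1L]))))
  # mobile MSD at a few lags
  for (lag in c(2L, 5L, 10L)) {
    msd <- mean((xs[1L + lag, mob] - xs[1L, mob])^2 +
                  (ys[1L + lag, mob] - ys[1L, mob])^2)
    expect_equal(msd, 4 * 3 * lag * p$frame_interval, tolerance = 0.05)
  }
  # mixture MSD slope scales with the mobile fraction
  msd_all <- mean((xs[11L, ] - xs[1L, ])^2 + (ys[11L, ] - ys[1L, ])^2)
  expect_equal(msd_all, 0.75 * 4 * 3 * 10 * p$frame_interval, tolerance = 0.07)
})

test_that("rendered intensity conserves photons before noise", {
  p <- quiet_params(n_frames = 3L, seed = 4L)
  s <- simulate_photoactivation(p, D = 1, immobile_fraction = 0,
                                roi = circular_roi(3.2, 3.2, 0.6),
                                n_molecules = 80L, decay_constant = 0.5)
  tr <- s$truth
  for (t in 1:3) {
    total_truth <- sum(tr$brightness[tr$frame == t])
    expect_equal(sum(stack_frame(s$stack, t)), total_truth, tolerance = 0.01)
  }
})

test_that("brightness decays with cumulative exposure and never increases", {
  p <- quiet_params(n_frames = 6L, seed = 3L)
  s <- simulate_photoactivation(p, D = 0, immobile_fraction = 1,
                                roi = circular_roi(3.2, 3.2, 0.6),
                                n_molecules = 10L, decay_constant = 2)
  b <- matrix(s$truth$brightness, nrow = 6L)
  expect_true(all(diff(b[, 1L]) < 0))
  expect_equal(b[6L, 1L] / b[1L, 1L], exp(-2 * 5 * p$frame_interval),
               tolerance = 1e-10)
})

test_that("invalid photoactivation inputs are rejected", {
  p <- quiet_params()
  mask <- matrix(FALSE, 64L, 64L); mask[20:40, 20:40] <- TRUE
  expect_error(simulate_photoactivation(p, D = -1, immobile_fraction = 0,
                                        roi = circular_roi(3, 3, 0.5),
                                        n_molecules = 5L),
               "non-negative")
  expect_error(simulate_photoactivation(p, D = 1, immobile_fraction = 0,
                                        roi = circular_roi(0.5, 0.5, 0.4),
                                        n_molecules = 5L, cell_mask = mask),
               "inside the cell mask")
})

test_that("FRAP truth bookkeeping predicts the observed plateau", {
  sc <- small_frap(seed = 21L, D = 8, bound_fraction = 0.2)
  sim <- sc$sim
  # independent oracle: recompute the plateau from the truth record
  tr <- sim$truth
  atb <- tr[tr$frame == sim$bleach_frame, ]
  roi <- sc$roi
  inr <- (atb$x_um - roi$x)^2 + (atb$y_um - roi$y)^2 <= roi$radius^2
  post <- atb$brightness * 0 + ifelse(inr, 0, 1)  # bleach depth 1
  afrac <- sum(roi_mask(roi, dim(sc$cell), sc$params$pixel_size) & sc$cell) /
    sum(sc$cell)
  oracle <- (sum(post[inr & atb$mobility == "immobile"]) +
               sum(post[atb$mobility == "mobile"]) * afrac) / sum(inr)
  expect_equal(sim$expected_plateau, oracle, tolerance = 1e-10)
  # rendered ROI means track the truth-position ROI brightness exactly
  # (same realization, so occupancy fluctuations cancel)
  rm_ <- roi_mask(roi, dim(sc$cell), sc$params$pixel_size)
  img_roi <- vapply(seq_len(160), function(t) {
    mean(stack_frame(sim$stack, t)[rm_])
  }, numeric(1L))
  truth_roi <- vapply(seq_len(160), function(t) {
    d <- tr[tr$frame == t, ]
    sum(d$brightness[(d$x_um - roi$x)^2 + (d$y_um - roi$y)^2 <= roi$radius^2])
  }, numeric(1L))
  r_img <- mean(img_roi[141:160]) / mean(img_roi[1:5])
  r_truth <- mean(truth_roi[141:160]) / mean(truth_roi[1:5])
  expect_equal(r_img, r_truth, tolerance = 0.03)
  # and both sit near the bookkeeping plateau, up to occupancy fluctuation
  expect_equal(r_truth, sim$expected_plateau, tolerance = 0.15)
})

test_that("free diffusion recovers at least 95% of pre-bleach", {
  sc <- small_frap(seed = 8L, D = 15, bound_fraction = 0)
  curve <- extract_recovery(sc$sim$stack, sc$roi, sc$background,
                            sc$reference, sc$sim$bleach_frame)
  late <- mean(curve$intensity[curve$time_s > 2])
  expect_gte(late, 0.95)
})

test_that("node scenes realize the designed overlap exactly in truth", {
  p <- quiet_params(n_frames = 1L, image_shape = c(256L, 256L), seed = 31L)
  sc <- simulate_node_scene(p, n_a = 24L, n_b = 24L, overlap_fraction = 0.5,
                            coloc_offset = 0.1)
  expect_equal(sc$overlap_fraction, 0.5)
  a1 <- sc$truth[sc$truth$channel == "a" & sc$truth$frame == 1L, ]
  b1 <- sc$truth[sc$truth$channel == "b" & sc$truth$frame == 1L, ]
  matched <- !is.na(a1$matched_b)
  expect_equal(sum(matched), 12L)
  d_match <- sqrt((a1$x_um[matched] - b1$x_um[a1$matched_b[matched]])^2 +
                    (a1$y_um[matched] - b1$y_um[a1$matched_b[matched]])^2)
  expect_true(all(d_match <= 0.1 + 1e-12))
  # unmatched A nodes are kept clear of every B node
  d_un <- outer(a1$x_um[!matched], b1$x_um, "-")^2 +
    outer(a1$y_um[!matched], b1$y_um, "-")^2
  expect_true(all(sqrt(d_un) > 3 * 2 * p$psf_sigma - 1e-12))
  expect_error(simulate_node_scene(p, n_a = 10L, n_b = 2L,
                                   overlap_fraction = 1),
               "not enough B nodes")
})

test_that("filament truth advances exactly rate x time", {
  p <- quiet_params(n_frames = 6L, image_shape = c(128L, 128L),
                    frame_interval = 1, seed = 12L)
  s <- simulate_growing_filaments(p, n_filaments = 2L, rate = 25.2)
  tr <- s$truth[s$truth$filament == 1L, ]
  # 25.2 nm/s for 5 s -> 126 nm = 0.126 um of growth
  expect_equal(tr$tip_um[6L] - tr$tip_um[1L], 0.126, tolerance = 1e-12)
  s0 <- simulate_growing_filaments(p, n_filaments = 1L, rate = 0)
  for (t in 2:6) {
    expect_identical(stack_frame(s0$stack, t), stack_frame(s0$stack, 1L))
  }
})

test_that("filaments leaving the field of view are truncated with a warning", {
  p <- quiet_params(n_frames = 6L, image_shape = c(48L, 48L),
                    frame_interval = 1, seed = 13L)
  expect_warning(
    s <- simulate_growing_filaments(p, n_filaments = 1L, rate = 100,
                                    origins = matrix(c(4, 2.4), 1L),
                                    directions = 0, initial_length = 0.5),
    "field of view")
  expect_lt(max(s$truth$tip_um), 2.4)
})

test_that("cell scenes have the designed membrane/cytosol contrast", {
  p <- quiet_params(n_frames = 2L, image_shape = c(96L, 96L),
                    pixel_size = 0.2, seed = 14L)
  sc <- simulate_cell_scene(p, list(shape = "disk", radius = 7),
                            membrane_intensity = 2, cytosol_intensity = 1,
                            shell_thickness = 1)
  fr <- stack_frame(sc$stack, 1L)
  # interior of each compartment (PSF-affected border pixels excluded)
  core_cyt <- sc$cytosol_mask & !(boundary_distance(sc$cytosol_mask, 0.2) <= 0.4)
  core_mem <- sc$membrane_mask &
    (boundary_distance(sc$cell_mask, 0.2) > 0.3) &
    (boundary_distance(sc$cell_mask, 0.2) < 0.7)
  expect_equal(mean(fr[core_cyt]), 1, tolerance = 0.02)
  expect_equal(mean(fr[core_mem]), 2, tolerance = 0.1)
  expect_warning(simulate_cell_scene(p, list(shape = "disk", radius = 3),
                                     membrane_intensity = 1,
                                     cytosol_intensity = 1,
                                     shell_thickness = 5),
                 "whole cell")
})
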