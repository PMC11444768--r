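test_that("frame count and times follow cadence and duration", {
  expect_equal(n_frames(scene_config()), 289L)  # 24 h at 5 min
  sc <- scene_config(cadence_min = 60, duration_h = 24)
  expect_equal(n_frames(sc), 25L)
  expect_equal(frame_times(sc), 0:24)
  expect_equal(frame_times(scene_config())[2], 5 / 60)
})

test_that("invalid scene and cell configs raise typed errors", {
  expect_error(scene_config(width_px = 0), class = "gelsense_invalid_config")
  expect_error(scene_config(pixel_size_um = -1), class = "gelsense_invalid_config")
  expect_error(scene_config(bit_depth = 12), class = "gelsense_invalid_config")
  expect_error(cell_spec(c(1, 2, 3), 10), class = "gelsense_invalid_config")
  expect_error(cell_spec(c(1, 2), -5), class = "gelsense_invalid_config")
  expect_error(scenario(scene_config()), class = "gelsense_invalid_config")
})

test_that("bead draws are seeded, in bounds, and spatially uniform", {
  sc <- scene_config(seed = 5, bead_count = 5000L)
  b1 <- generate_beads(sc)
  b2 <- generate_beads(sc)
  expect_identical(b1, b2)
  expect_false(identical(b1$x_px, generate_beads(scene_config(seed = 6, bead_count = 5000L))$x_px))
  expect_equal(nrow(b1), 5000L)
  expect_true(all(b1$x_px >= 0 & b1$x_px <= 512))
  expect_true(all(b1$y_px >= 0 & b1$y_px <= 512))
  # Monte Carlo oracle: mean nearest-neighbour distance of a uniform point
  # process of intensity rho is ~ 0.5 / sqrt(rho)
  d <- as.matrix(stats::dist(cbind(b1$x_px, b1$y_px)))
  diag(d) <- Inf
  mean_nn <- mean(apply(d, 1, min))
  expect_lt(abs(mean_nn - 0.5 * 512 / sqrt(5000)) / (0.5 * 512 / sqrt(5000)), 0.1)
})

test_that("cell field is zero at the centre, peaks at one reach, points inward", {
  cells <- cell_spec(c(100, 100), strength_um = 20, reach_um = 80, tau_h = 8)
  at <- function(x, y, t) cell_field(cells, tibble::tibble(x_um = x, y_um = y), t)
  f0 <- at(100, 100, 24)
  expect_equal(c(f0$ux_um, f0$uy_um), c(0, 0))
  # analytic peak: |u| = s (1 - e^{-t/tau}) exp(-1/2) at r = reach
  fpk <- at(180, 100, 24)
  expect_equal(sqrt(fpk$ux_um^2 + fpk$uy_um^2),
               20 * (1 - exp(-3)) * exp(-0.5), tolerance = 1e-12)
  expect_lt(fpk$ux_um, 0)  # east of centre, pulled west
  expect_equal(fpk$uy_um, 0)
  # magnitude at r = reach dominates nearby radii (unimodal profile)
  expect_gt(abs(fpk$ux_um), abs(at(140, 100, 24)$ux_um))
  expect_gt(abs(fpk$ux_um), abs(at(260, 100, 24)$ux_um))
  # temporal ramp: monotone, saturating
  m <- sapply(c(1, 4, 8, 16, 24), function(t) abs(at(180, 100, t)$ux_um))
  expect_true(all(diff(m) > 0))
  expect_equal(c(at(180, 100, 0)$ux_um), 0)
})

test_that("cell fields superpose linearly", {
  c1 <- cell_spec(c(50, 80), 15, 60, 5)
  c2 <- cell_spec(c(200, 150), 25, 90, 10)
  pts <- tibble::tibble(x_um = c(0, 100, 180, 300), y_um = c(0, 120, 40, 260))
  both <- cell_field(dplyr::bind_rows(c1, c2), pts, 12)
  one <- cell_field(c1, pts, 12)
  two <- cell_field(c2, pts, 12)
  expect_equal(both$ux_um, one$ux_um + two$ux_um, tolerance = 1e-12)
  expect_equal(both$uy_um, one$uy_um + two$uy_um, tolerance = 1e-12)
})

test_that("crowding cancels: equal total strength split over more cells lowers p90", {
  # random-direction superposition of many weak pulls partially cancels,
  # so the upper-percentile field magnitude falls as the same contractile
  # budget is split across more cells
  sc <- scene_config(seed = 11)
  grid <- build_grid(10, 8, c(512, 512))
  pts <- tibble::tibble(x_um = grid$x_px * 0.65, y_um = grid$y_px * 0.65)
  p90_for <- function(n_cells, total_strength, seed) {
    cells <- with_seed(seed, tibble::tibble(
      center_x_um = runif(n_cells, -160, 512 * 0.65 + 160),
      center_y_um = runif(n_cells, -160, 512 * 0.65 + 160),
      strength_um = total_strength / n_cells, reach_um = 80, tau_h = 8))
    f <- cell_field(cells, pts, 24)
    unname(quantile(sqrt(f$ux_um^2 + f$uy_um^2), 0.9))
  }
  few <- mean(sapply(1:5, function(s) p90_for(4, 400, s)))
  many <- mean(sapply(1:5, function(s) p90_for(64, 400, s)))
  expect_gt(few, many)
})

test_that("ground truth starts at zero and scales with attenuation", {
  sc <- scene_config(seed = 2, cadence_min = 60, duration_h = 2)
  scn <- scenario(sc, cells = cell_spec(c(166, 166), 20))
  tr <- ground_truth(scn)
  expect_named(tr, c("frame", "t_h", "node_id", "x_px", "y_px", "ux_um", "uy_um"))
  expect_equal(nrow(tr), 3 * 99)
  f1 <- dplyr::filter(tr, frame == 1)
  expect_true(all(f1$ux_um == 0 & f1$uy_um == 0))
  expect_gt(max(abs(dplyr::filter(tr, frame == 3)$ux_um)), 0)
})

test_that("rendering is deterministic and quantized to bit depth", {
  sc <- scene_config(seed = 4, width_px = 128L, height_px = 128L,
                     duration_h = 1, cadence_min = 60, bead_count = 60L)
  scn <- scenario(sc, cells = cell_spec(c(40, 40), 5))
  s1 <- render_stack(scn)
  s2 <- render_stack(scn)
  expect_identical(s1$frames, s2$frames)
  expect_true(all(s1$frames >= 0 & s1$frames <= 1))
  q <- 2^16 - 1
  expect_equal(s1$frames, round(s1$frames * q) / q, tolerance = 1e-12)
  # noise differs between frames (independent per-frame draws)
  expect_gt(mean(abs(s1$frames[, , 1] - s1$frames[, , 2])), 0)
  # a different scene seed changes the images
  scn3 <- scenario(scene_config(seed = 8, width_px = 128L, height_px = 128L,
                                duration_h = 1, cadence_min = 60,
                                bead_count = 60L),
                   cells = cell_spec(c(40, 40), 5))
  expect_false(identical(render_stack(scn3)$frames[, , 1], s1$frames[, , 1]))
})

test_that("rendered spot count matches the bead count (local-maxima oracle)", {
  sc <- scene_config(seed = 3, bead_count = 400L, noise_sigma = 0)
  b <- generate_beads(sc)
  img <- gelsense:::render_frame(sc, b$x_px, b$y_px, 1L)
  n_spots <- local_maxima_count(img, sc$background_level + 0.25 * sc$spot_peak)
  expect_lt(abs(n_spots - 400) / 400, 0.1)  # a few beads merge or clip at edges
})

test_that("a zero-cell stack moves only by noise", {
  sc <- scene_config(seed = 9, width_px = 256L, height_px = 256L,
                     duration_h = 2, cadence_min = 60, bead_count = 200L)
  scn <- scenario(sc, cells = cell_spec(c(1, 1), 1)[0, ])
  st <- render_stack(scn)
  expect_true(all(st$truth$ux_um == 0))
  # mean |difference| of two frames with iid N(0, sigma) noise is
  # 2 sigma / sqrt(pi); clipping at 0 shaves a little off
  mad_frames <- mean(abs(st$frames[, , 1] - st$frames[, , 3]))
  theory <- 2 * sc$noise_sigma / sqrt(pi)
  expect_lt(abs(mad_frames - theory) / theory, 0.25)
})

test_that("z-profile boxcar has exact plateau geometry", {
  pr <- render_zprofile(200, step_um = 2)
  expect_true(all(diff(pr$z_um) == 2))
  expect_equal(attr(pr, "true_thickness_um"), 200)
  # a 200-um slab sampled at 2 um holds exactly 100 samples at the plateau
  expect_equal(sum(pr$intensity == max(pr$intensity)), 100L)
  expect_equal(min(pr$intensity), 0.02)
  expect_error(render_zprofile(8, step_um = 10), class = "gelsense_invalid_config")
  expect_error(render_zprofile(-3), class = "gelsense_invalid_config")
  # noise is seeded
  p1 <- render_zprofile(100, noise_sigma = 0.05, seed = 42)
  expect_identical(p1, render_zprofile(100, noise_sigma = 0.05, seed = 42))
  expect_false(identical(p1$intensity,
                         render_zprofile(100, noise_sigma = 0.05, seed = 43)$intensity))
})
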