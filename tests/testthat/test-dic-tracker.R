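test_that("a 10 x 8 cell grid yields 99 nodes inset from the border", {
  g <- build_grid(10, 8, c(512, 512))
  expect_s3_class(g, "node_grid")
  expect_equal(nrow(g), 99L)
  expect_equal(nrow(build_grid(4, 3, c(512, 512))), 20L)
  p <- track_params()
  inset <- ceiling(p$kernel_size / 2) + p$max_move
  expect_true(all(g$x_px >= inset + 1 & g$x_px <= 512 - inset))
  expect_true(all(g$y_px >= inset + 1 & g$y_px <= 512 - inset))
  expect_equal(g$node_id, seq_len(99))
  expect_error(build_grid(10, 8, c(40, 40)), class = "gelsense_invalid_config")
  expect_error(build_grid(0, 8, c(512, 512)), class = "gelsense_invalid_config")
})

test_that("track params validate and clip the subpixel window to the search", {
  expect_error(track_params(kernel_size = 30), class = "gelsense_invalid_config")
  expect_error(track_params(subpixel_window = 4), class = "gelsense_invalid_config")
  expect_error(track_params(smoothness = -1), class = "gelsense_invalid_config")
  expect_error(track_params(max_move = 0), class = "gelsense_invalid_config")
  expect_equal(track_params(subpixel_window = 9, max_move = 3)$subpixel_window, 7L)
})

test_that("tracking a frame against itself measures ~zero displacement", {
  fx <- shift_fixture()
  f <- track_pair(fx$fa, fx$fa, fx$grid)
  expect_s3_class(f, "displacement_field")
  ok <- f$flag != "clamped"
  expect_gt(sum(ok), 90)
  expect_lt(max(abs(c(f$ux_px[ok], f$uy_px[ok]))), 0.15)
})

test_that("a known subpixel shift is recovered below 0.2 px RMSE", {
  fx <- shift_fixture()
  f <- track_pair(fx$fa, fx$fb, fx$grid)
  ok <- f$flag != "clamped"
  rmse <- sqrt(mean((f$ux_px[ok] - fx$shift[1])^2 + (f$uy_px[ok] - fx$shift[2])^2))
  expect_lt(rmse, 0.2)
  # micron columns are the pixel columns scaled by the calibration
  f2 <- track_pair(fx$fa, fx$fb, fx$grid, pixel_size_um = 0.65)
  expect_equal(f2$ux_um, f2$ux_px * 0.65, tolerance = 1e-12)
})

test_that("reversing the frame order reverses the displacement", {
  fx <- shift_fixture()
  fwd <- track_pair(fx$fa, fx$fb, fx$grid)
  bwd <- track_pair(fx$fb, fx$fa, fx$grid)
  ok <- fwd$flag != "clamped" & bwd$flag != "clamped"
  expect_lt(sqrt(mean((fwd$ux_px[ok] + bwd$ux_px[ok])^2 +
                      (fwd$uy_px[ok] + bwd$uy_px[ok])^2)), 0.3)
})

test_that("smoothness = 0 disables neighbour blending exactly", {
  fx <- shift_fixture()
  raw1 <- track_pair(fx$fa, fx$fb, fx$grid, track_params(smoothness = 0, smooth_grid = 25))
  raw2 <- track_pair(fx$fa, fx$fb, fx$grid, track_params(smoothness = 0, smooth_grid = 80))
  ok <- raw1$flag %in% c("ok", "fallback")
  # with no blending the smoothing length scale cannot matter
  expect_equal(raw1$ux_px[ok], raw2$ux_px[ok], tolerance = 1e-12)
  sm <- track_pair(fx$fa, fx$fb, fx$grid, track_params(smoothness = 5))
  expect_gt(max(abs(sm$ux_px[ok] - raw1$ux_px[ok])), 1e-6)
})

test_that("shifts beyond the search range clamp at the border", {
  img <- smooth_texture(160, seed = 31)
  moved <- shift_image(img, 10, 0)
  g <- build_grid(3, 3, c(160, 160))
  f <- track_pair(img, moved, g)
  expect_true(all(f$flag %in% c("clamped", "low_corr")))
  expect_true(any(f$flag == "clamped"))
})

test_that("accuracy degrades monotonically as noise grows", {
  rmse_at <- function(noise_sigma) {
    sc <- scene_config(seed = 7, duration_h = 1, cadence_min = 60,
                       noise_sigma = noise_sigma)
    beads <- generate_beads(sc)
    fa <- gelsense:::render_frame(sc, beads$x_px, beads$y_px, 11L)
    fb <- gelsense:::render_frame(sc, beads$x_px + 3.30, beads$y_px - 2.10, 12L)
    f <- track_pair(fa, fb, build_grid(10, 8, c(512, 512)))
    ok <- f$flag != "clamped"
    sqrt(mean((f$ux_px[ok] - 3.30)^2 + (f$uy_px[ok] + 2.10)^2))
  }
  r <- vapply(0.5 / c(3, 10, 30), rmse_at, numeric(1))  # SNR 3, 10, 30
  expect_true(all(diff(r) < 0))
  expect_lt(r[2], 0.2)
})

test_that("Lagrangian sequence tracking sums intervals to the total motion", {
  sc <- scene_config(seed = 13, width_px = 256L, height_px = 256L,
                     duration_h = 3, cadence_min = 60, bead_count = 250L)
  beads <- generate_beads(sc)
  step <- c(1.2, 0.8)
  frames <- array(0, dim = c(256, 256, 4))
  for (k in 1:4) {
    frames[, , k] <- gelsense:::render_frame(
      sc, beads$x_px + (k - 1) * step[1], beads$y_px + (k - 1) * step[2],
      derive_seed(13L, k))
  }
  stack <- structure(list(frames = frames, times_h = 0:3, pixel_size_um = 1,
                          scene = sc, truth = NULL, beads = beads),
                     class = "frame_stack")
  g <- build_grid(4, 4, c(256, 256))
  # border-column nodes drift past the safe inset and are frozen, with notice
  expect_warning(fl <- track_sequence(stack, g, pairs = cbind(1:3, 2:4)),
                 "frozen")
  expect_length(fl, 3)
  expect_equal(attr(fl[[2]], "t_b_h"), 2)
  tot_x <- Reduce(`+`, purrr::map(fl, "ux_px"))
  tot_y <- Reduce(`+`, purrr::map(fl, "uy_px"))
  keep <- Reduce(`&`, purrr::map(fl, ~ .x$flag != "clamped"))
  expect_lt(sqrt(mean((tot_x[keep] - 3 * step[1])^2 +
                      (tot_y[keep] - 3 * step[2])^2)), 0.3)
  # the advected node positions moved with the material
  expect_gt(mean(fl[[3]]$x_px - fl[[1]]$x_px), 1.5)
})

test_that("mismatched frame shapes are rejected", {
  expect_error(track_pair(matrix(0, 64, 64), matrix(0, 64, 65),
                          build_grid(1, 1, c(64, 64), track_params(kernel_size = 15, max_move = 3))),
               class = "gelsense_data_error")
})
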