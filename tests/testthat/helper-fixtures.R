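# shared fixtures, built once per test run

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

# 512x512, 800 beads, SNR 10, imposed uniform shift (3.30, -2.10) px
shift_fixture <- function() {
  fixture("shift", function() {
    sc <- scene_config(seed = 7, duration_h = 1, cadence_min = 60)
    beads <- generate_beads(sc)
    list(
      scene = sc,
      grid = build_grid(10, 8, c(sc$height_px, sc$width_px)),
      fa = gelsense:::render_frame(sc, beads$x_px, beads$y_px, 11L),
      fb = gelsense:::render_frame(sc, beads$x_px + 3.30, beads$y_px - 2.10, 12L),
      shift = c(3.30, -2.10)
    )
  })
}

# single contracting cell, hourly frames, tracked; with ground truth
contraction_fixture <- function() {
  fixture("contraction", function() {
    sc <- scene_config(seed = 21, cadence_min = 60)
    scn <- scenario(sc, cells = cell_spec(c(166, 166), 20, 80, 8))
    stack <- render_stack(scn)
    list(scenario = scn, stack = stack, fields = run_track(stack))
  })
}

# brute-force percentile oracle: sort + linear interpolation between
# order statistics (independent of stats::quantile)
quantile_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  if (n == 1) return(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

# simple spot-count oracle: strict 3x3 local maxima above a threshold
local_maxima_count <- function(img, thresh) {
  nr <- nrow(img); nc <- ncol(img)
  inner <- img[2:(nr - 1), 2:(nc - 1)]
  is_max <- inner > thresh
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    is_max <- is_max & (inner >= img[2:(nr - 1) + di, 2:(nc - 1) + dj])
  }
  sum(is_max)
}

# smooth random texture (correlated noise) whose correlation surface is
# broad: used for the out-of-range clamping behaviour
smooth_texture <- function(n, seed, sigma = 3) {
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  img <- matrix(rnorm(n * n), n, n)
  k <- dnorm(-9:9, sd = sigma)
  img <- apply(img, 2, function(col) stats::filter(col, k, circular = TRUE))
  img <- t(apply(img, 1, function(row) stats::filter(row, k, circular = TRUE)))
  img <- img - min(img)
  img / max(img)
}

# integer-pixel image translation with zero fill
shift_image <- function(img, dx, dy) {
  out <- matrix(mean(img), nrow(img), ncol(img))
  nr <- nrow(img); nc <- ncol(img)
  src_r <- seq_len(nr) - dy; src_c <- seq_len(nc) - dx
  ok_r <- src_r >= 1 & src_r <= nr; ok_c <- src_c >= 1 & src_c <= nc
  out[which(ok_r), which(ok_c)] <- img[src_r[ok_r], src_c[ok_c]]
  out
}
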