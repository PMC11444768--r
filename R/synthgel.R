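# Synthetic bead-image generator: seeded time-lapse stacks of PSF-limited
# fluorescent beads on a deforming gel surface, with exact ground truth.

#' Describe a synthetic imaging scene
#'
#' A scene fixes the optics and acquisition of a synthetic time-lapse:
#' image size, pixel calibration, cadence, bead count, spot width, and the
#' additive-noise model. Defaults emulate a 10x time-lapse of 0.5-um
#' fluorospheres imaged every 5 min for 24 h.
#'
#' @param width_px,height_px Image size in pixels.
#' @param pixel_size_um Microns per pixel (default 0.65, a typical 10x
#'   camera calibration).
#' @param cadence_min Minutes between frames (default 5).
#' @param duration_h Total duration in hours (default 24). The stack holds
#'   `floor(duration_h * 60 / cadence_min) + 1` frames.
#' @param bead_count Number of beads rendered (default 800).
#' @param psf_sigma_px Gaussian spot standard deviation in pixels
#'   (default 1.5; beads are sub-resolution point emitters).
#' @param background_level Constant background on the 0..1 intensity scale.
#' @param spot_peak Peak spot intensity above background; the spot
#'   signal-to-noise ratio is `spot_peak / noise_sigma`.
#' @param noise_sigma Additive Gaussian noise standard deviation.
#' @param bit_depth Quantization depth, 8 or 16.
#' @param seed Integer seed; every draw the scene triggers is reproducible.
#' @return An object of class `scene_config` (a named list).
#' @export
scene_config <- function(width_px = 512L, height_px = 512L,
                         pixel_size_um = 0.65, cadence_min = 5,
                         duration_h = 24, bead_count = 800L,
                         psf_sigma_px = 1.5, background_level = 0.05,
                         spot_peak = 0.5, noise_sigma = 0.05,
                         bit_depth = 16L, seed = 1L) {
  if (width_px < 1 || height_px < 1)
    stop_invalid_config("image must have positive area (got %d x %d)", width_px, height_px)
  if (pixel_size_um <= 0) stop_invalid_config("pixel_size_um must be positive")
  if (cadence_min <= 0 || duration_h <= 0)
    stop_invalid_config("cadence_min and duration_h must be positive")
  if (bead_count < 1) stop_invalid_config("bead_count must be >= 1")
  if (psf_sigma_px <= 0) stop_invalid_config("psf_sigma_px must be positive")
  if (background_level < 0 || noise_sigma < 0)
    stop_invalid_config("background_level and noise_sigma must be >= 0")
  if (!bit_depth %in% c(8L, 16L)) stop_invalid_config("bit_depth must be 8 or 16")
  structure(list(
    width_px = as.integer(width_px), height_px = as.integer(height_px),
    pixel_size_um = pixel_size_um, cadence_min = cadence_min,
    duration_h = duration_h, bead_count = as.integer(bead_count),
    psf_sigma_px = psf_sigma_px, background_level = background_level,
    spot_peak = spot_peak, noise_sigma = noise_sigma,
    bit_depth = as.integer(bit_depth), seed = as.integer(seed)
  ), class = "scene_config")
}

#' Number of frames implied by a scene
#' @param scene A [scene_config()].
#' @return Integer frame count, `floor(duration_h * 60 / cadence_min) + 1`.
#' @export
n_frames <- function(scene) {
  as.integer(floor(scene$duration_h * 60 / scene$cadence_min)) + 1L
}

#' Frame times in hours
#' @param scene A [scene_config()].
#' @return Numeric vector of frame times (h), starting at 0.
#' @export
frame_times <- function(scene) {
  (seq_len(n_frames(scene)) - 1) * scene$cadence_min / 60
}

#' Describe one contracting cell
#'
#' A cell is modelled as a radially contracting traction centre: the surface
#' displacement it imparts points toward the cell centre, vanishes at the
#' centre, peaks at one reach length, and decays to zero far away. The
#' amplitude ramps up in time as `1 - exp(-t / tau_h)`.
#'
#' @param center_um Length-2 numeric, cell centre in microns (x, y).
#' @param strength_um Plateau displacement scale s (um); the peak field
#'   magnitude is `s * exp(-1/2)` at distance `reach_um`.
#' @param reach_um Radial scale of the displacement well (um, default 80,
#'   the order of the displacement fields contractile stromal cells imprint).
#' @param tau_h Ramp time constant in hours (default 8).
#' @return A one-row tibble; rows from several calls can be bound together.
#' @export
cell_spec <- function(center_um, strength_um, reach_um = 80, tau_h = 8) {
  if (length(center_um) != 2 || !is.numeric(center_um))
    stop_invalid_config("center_um must be a numeric 2-vector")
  if (strength_um < 0) stop_invalid_config("strength_um must be >= 0")
  if (reach_um <= 0 || tau_h <= 0)
    stop_invalid_config("reach_um and tau_h must be positive")
  tibble(center_x_um = center_um[1], center_y_um = center_um[2],
         strength_um = strength_um, reach_um = reach_um, tau_h = tau_h)
}

#' Draw uniform bead positions for a scene
#'
#' Beads are placed uniformly over the image, independently in x and y,
#' using the scene's seed; positions are sub-pixel floats in pixel units
#' (origin at the top-left, x = column increasing rightward, y = row
#' increasing downward).
#'
#' @param scene A [scene_config()].
#' @return Tibble with columns `bead_id`, `x_px`, `y_px`.
#' @export
generate_beads <- function(scene) {
  stopifnot(inherits(scene, "scene_config"))
  with_seed(derive_seed(scene$seed, 1L), {
    tibble(
      bead_id = seq_len(scene$bead_count),
      x_px = runif(scene$bead_count, 0, scene$width_px),
      y_px = runif(scene$bead_count, 0, scene$height_px)
    )
  })
}

#' Evaluate the superposed cell displacement field
#'
#' The displacement imparted by each cell at a point distance r from its
#' centre has magnitude `s * (1 - exp(-t/tau)) * (r/sigma) * exp(-r^2/(2 sigma^2))`
#' directed toward the cell centre; cells superpose linearly. The field is
#' zero at each cell centre and decays to zero far away, so crowded cells
#' pulling in opposite directions partially cancel.
#'
#' @param cells Tibble of cells (rows from [cell_spec()]).
#' @param points Data frame with columns `x_um`, `y_um`.
#' @param t_h Time in hours (scalar, >= 0).
#' @return `points` with added columns `ux_um`, `uy_um`.
#' @export
cell_field <- function(cells, points, t_h) {
  if (t_h < 0) stop_invalid_config("t_h must be >= 0")
  ux <- numeric(nrow(points)); uy <- numeric(nrow(points))
  if (!is.null(cells) && nrow(cells) > 0) {
    for (i in seq_len(nrow(cells))) {
      dx <- points$x_um - cells$center_x_um[i]
      dy <- points$y_um - cells$center_y_um[i]
      r2 <- dx^2 + dy^2
      sig <- cells$reach_um[i]
      amp <- cells$strength_um[i] * (1 - exp(-t_h / cells$tau_h[i]))
      # -s f(t) exp(-r^2/2s^2)/sigma * (x - c): finite (zero) at r = 0
      w <- amp * exp(-r2 / (2 * sig^2)) / sig
      ux <- ux - w * dx
      uy <- uy - w * dy
    }
  }
  dplyr::mutate(as_tibble(points), ux_um = ux, uy_um = uy)
}

#' Attenuate a displacement field for finite gel thickness
#'
#' On a thin gel bonded to glass the same cell tractions produce smaller
#' displacements because the apparent stiffness is higher. In `mechanics`
#' mode the field is scaled by the thickness attenuation factor
#' `k(h -> infinity) / k(h)` from [attenuation_factor()]; `none` leaves the
#' field unchanged.
#'
#' @param field Data frame with columns `ux_um`, `uy_um`.
#' @param gel A [layer_spec()] (thickness `h_um` is what matters).
#' @param mode `"none"` or `"mechanics"`.
#' @param punch A [punch_spec()] describing the contraction footprint.
#' @return `field` with displacements scaled.
#' @export
apply_attenuation <- function(field, gel, mode = c("none", "mechanics"),
                              punch = punch_spec()) {
  mode <- match.arg(mode)
  if (mode == "none") return(field)
  fac <- attenuation_factor(gel, punch)
  dplyr::mutate(field, ux_um = .data$ux_um * fac, uy_um = .data$uy_um * fac)
}

#' Assemble a synthetic experiment scenario
#'
#' Cells are given either explicitly or as a surface density, in which case
#' the realised count is a seeded Poisson draw over the field of view plus a
#' margin of two reach lengths (cells just outside the frame still deform
#' the imaged surface).
#'
#' @param scene A [scene_config()].
#' @param cells Tibble of [cell_spec()] rows, or `NULL` when a density is given.
#' @param density_cells_per_cm2 Plating density; converted to an expected
#'   count over the (margin-extended) field of view.
#' @param cell_strength_um,cell_reach_um,cell_tau_h Per-cell parameters used
#'   for density-placed cells.
#' @param gel A [layer_spec()] for the substrate.
#' @param attenuation_mode `"none"` or `"mechanics"`.
#' @param punch A [punch_spec()]; the contraction footprint used by
#'   `mechanics` attenuation.
#' @return An object of class `gel_scenario`.
#' @export
scenario <- function(scene, cells = NULL, density_cells_per_cm2 = NULL,
                     cell_strength_um = 20, cell_reach_um = 80, cell_tau_h = 8,
                     gel = layer_spec(), attenuation_mode = c("none", "mechanics"),
                     punch = punch_spec()) {
  attenuation_mode <- match.arg(attenuation_mode)
  if (is.null(cells) && is.null(density_cells_per_cm2))
    stop_invalid_config("give either `cells` or `density_cells_per_cm2`")
  if (!is.null(density_cells_per_cm2)) {
    fov_w_um <- scene$width_px * scene$pixel_size_um
    fov_h_um <- scene$height_px * scene$pixel_size_um
    margin <- 2 * cell_reach_um
    area_cm2 <- (fov_w_um + 2 * margin) * (fov_h_um + 2 * margin) / 1e8
    lambda <- density_cells_per_cm2 * area_cm2
    cells <- with_seed(derive_seed(scene$seed, 2L), {
      n_cells <- rpois(1, lambda)
      if (n_cells == 0) {
        tibble(center_x_um = numeric(), center_y_um = numeric(),
               strength_um = numeric(), reach_um = numeric(), tau_h = numeric())
      } else {
        tibble(
          center_x_um = runif(n_cells, -margin, fov_w_um + margin),
          center_y_um = runif(n_cells, -margin, fov_h_um + margin),
          strength_um = cell_strength_um, reach_um = cell_reach_um,
          tau_h = cell_tau_h
        )
      }
    })
  }
  structure(list(scene = scene, cells = cells,
                 density_cells_per_cm2 = density_cells_per_cm2,
                 gel = gel, attenuation_mode = attenuation_mode,
                 punch = punch),
            class = "gel_scenario")
}

# scale factor the scenario applies to the raw cell field
scenario_attenuation <- function(scn) {
  if (scn$attenuation_mode == "mechanics")
    attenuation_factor(scn$gel, scn$punch)
  else 1
}

#' Exact ground-truth displacement at grid nodes
#'
#' Evaluates the scenario's (attenuated) cell field at the node positions
#' for every frame time. Frame 0 displacements are identically zero.
#'
#' @param scn A [scenario()].
#' @param grid A [build_grid()] node table (defaults to the standard
#'   10 x 8 grid on the scene).
#' @param times_h Frame times (h); defaults to the scene's frame times.
#' @return Tibble with columns `frame`, `t_h`, `node_id`, `x_px`, `y_px`,
#'   `ux_um`, `uy_um`.
#' @export
ground_truth <- function(scn, grid = NULL, times_h = NULL) {
  stopifnot(inherits(scn, "gel_scenario"))
  scene <- scn$scene
  if (is.null(grid))
    grid <- build_grid(10, 8, c(scene$height_px, scene$width_px))
  if (is.null(times_h)) times_h <- frame_times(scene)
  fac <- scenario_attenuation(scn)
  pts <- tibble(x_um = grid$x_px * scene$pixel_size_um,
                y_um = grid$y_px * scene$pixel_size_um)
  purrr::map_dfr(seq_along(times_h), function(k) {
    f <- cell_field(scn$cells, pts, times_h[k])
    tibble(frame = k, t_h = times_h[k],
           node_id = grid$node_id, x_px = grid$x_px, y_px = grid$y_px,
           ux_um = f$ux_um * fac, uy_um = f$uy_um * fac)
  })
}

# render one frame: background + gaussian spots + seeded noise, quantized
render_frame <- function(scene, bead_x, bead_y, noise_seed) {
  w <- scene$width_px; h <- scene$height_px
  img <- matrix(scene$background_level, nrow = h, ncol = w)
  sig <- scene$psf_sigma_px
  half <- ceiling(4 * sig)
  for (b in seq_along(bead_x)) {
    x0 <- bead_x[b]; y0 <- bead_y[b]
    cx <- round(x0); cy <- round(y0)
    if (cx + half < 1 || cx - half > w || cy + half < 1 || cy - half > h) next
    xs <- max(1, cx - half):min(w, cx + half)
    ys <- max(1, cy - half):min(h, cy + half)
    gx <- exp(-((xs - x0)^2) / (2 * sig^2))
    gy <- exp(-((ys - y0)^2) / (2 * sig^2))
    img[ys, xs] <- img[ys, xs] + scene$spot_peak * outer(gy, gx)
  }
  if (scene$noise_sigma > 0) {
    img <- img + with_seed(noise_seed,
                           matrix(rnorm(h * w, 0, scene$noise_sigma), h, w))
  }
  q <- 2^scene$bit_depth - 1
  pmin(pmax(round(img * q) / q, 0), 1)
}

#' Render a synthetic time-lapse bead stack with ground truth
#'
#' Each frame is a constant background plus one Gaussian spot per bead at
#' its displaced position plus seeded additive Gaussian noise, quantized to
#' the scene's bit depth. Beads are displaced by the scenario's cell field
#' evaluated at their t = 0 position (small-displacement Lagrangian
#' approximation). If more than 1% of beads are pushed outside the image a
#' warning is raised and those spots are clipped at the border.
#'
#' @param scn A [scenario()].
#' @param grid Node grid for the ground-truth record (default 10 x 8).
#' @param times_h Frame times; defaults to the scene's cadence.
#' @return List of class `frame_stack` with elements `frames` (array
#'   height x width x time, intensities in 0..1), `times_h`,
#'   `pixel_size_um`, `scene`, plus `truth` (the [ground_truth()] tibble)
#'   and `beads`.
#' @export
render_stack <- function(scn, grid = NULL, times_h = NULL) {
  stopifnot(inherits(scn, "gel_scenario"))
  scene <- scn$scene
  if (is.null(times_h)) times_h <- frame_times(scene)
  beads <- generate_beads(scene)
  fac <- scenario_attenuation(scn)
  truth <- ground_truth(scn, grid, times_h)
  pts <- tibble(x_um = beads$x_px * scene$pixel_size_um,
                y_um = beads$y_px * scene$pixel_size_um)
  frames <- array(0, dim = c(scene$height_px, scene$width_px, length(times_h)))
  n_out <- 0L
  for (k in seq_along(times_h)) {
    f <- cell_field(scn$cells, pts, times_h[k])
    bx <- beads$x_px + f$ux_um * fac / scene$pixel_size_um
    by <- beads$y_px + f$uy_um * fac / scene$pixel_size_um
    out <- bx < 0 | bx > scene$width_px | by < 0 | by > scene$height_px
    n_out <- max(n_out, sum(out))
    frames[, , k] <- render_frame(scene, pmin(pmax(bx, 0), scene$width_px),
                                  pmin(pmax(by, 0), scene$height_px),
                                  derive_seed(scene$seed, 100L + k))
  }
  if (n_out > 0.01 * nrow(beads))
    warn(sprintf("%d of %d beads displaced outside the image; spots clipped",
                 n_out, nrow(beads)))
  structure(list(frames = frames, times_h = times_h,
                 pixel_size_um = scene$pixel_size_um, scene = scene,
                 truth = truth, beads = beads),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d x %d px, %d frames, %.3g um/px, t = %.3g..%.3g h\n",
              d[2], d[1], d[3], x$pixel_size_um,
              min(x$times_h), max(x$times_h)))
  invisible(x)
}

#' Write a frame stack as a multi-page TIFF
#'
#' One page per frame, at the scene's bit depth. Deterministic: the same
#' stack writes byte-identical files.
#'
#' @param stack A `frame_stack`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  pages <- lapply(seq_len(dim(stack$frames)[3]), function(k) stack$frames[, , k])
  bits <- if (!is.null(stack$scene)) stack$scene$bit_depth else 16L
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none",
                  reduce = FALSE)
  invisible(path)
}

#' Read a multi-page TIFF as a frame stack
#'
#' @param path TIFF file path.
#' @param pixel_size_um Microns per pixel for the stack.
#' @param cadence_min Minutes between frames (used to reconstruct times).
#' @return A `frame_stack` (without ground truth).
#' @export
read_stack <- function(path, pixel_size_um, cadence_min) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) frames[, , k] <- pages[[k]]
  structure(list(frames = frames,
                 times_h = (seq_along(pages) - 1) * cadence_min / 60,
                 pixel_size_um = pixel_size_um, scene = NULL,
                 truth = NULL, beads = NULL),
            class = "frame_stack")
}

#' Simulate a confocal z-profile of a gel slab
#'
#' Mean fluorescence intensity versus z for a labelled slab: a boxcar of
#' width `thickness_um` with error-function edges of scale `edge_sigma_um`
#' (a sharp indicator when 0, half-open at the top edge), plus a small
#' baseline and seeded Gaussian noise. The slab top sits at `z_top_um` so
#' both edges are interior to the sampled range.
#'
#' @param thickness_um True slab thickness (um), > 0.
#' @param step_um z-step (um), typically 2 or 10; must be < thickness.
#' @param edge_sigma_um Edge blur scale (um); 0 gives an exact boxcar.
#' @param noise_sigma Additive noise SD on the 0..1 intensity scale.
#' @param seed Integer seed.
#' @param z_top_um z of the slab's upper face; the default
#'   `max(10, 0.15 * thickness_um)` leaves enough out-of-slab padding for
#'   baseline estimation whatever the slab size.
#' @param baseline Background intensity (default 0.02).
#' @param peak Plateau intensity (default 1).
#' @return Tibble with columns `z_um`, `intensity`, and attributes
#'   `true_thickness_um`, `step_um`.
#' @export
render_zprofile <- function(thickness_um, step_um = 2, edge_sigma_um = 0,
                            noise_sigma = 0, seed = 1L,
                            z_top_um = max(10, 0.15 * thickness_um),
                            baseline = 0.02, peak = 1) {
  if (thickness_um <= 0) stop_invalid_config("thickness_um must be positive")
  if (step_um >= thickness_um)
    stop_invalid_config("step_um (%g) must be smaller than thickness_um (%g)",
                        step_um, thickness_um)
  z <- seq(0, thickness_um + 2 * z_top_um, by = step_um)
  z0 <- z_top_um; z1 <- z_top_um + thickness_um
  if (edge_sigma_um <= 0) {
    inten <- baseline + (peak - baseline) * as.numeric(z >= z0 & z < z1)
  } else {
    inten <- baseline + (peak - baseline) *
      (stats::pnorm((z - z0) / edge_sigma_um) - stats::pnorm((z - z1) / edge_sigma_um))
  }
  if (noise_sigma > 0)
    inten <- inten + with_seed(seed, rnorm(length(z), 0, noise_sigma))
  out <- tibble(z_um = z, intensity = pmax(inten, 0))
  attr(out, "true_thickness_um") <- thickness_um
  attr(out, "step_um") <- step_um
  out
}

#' Write ground truth to CSV
#'
#' Columns: frame, node_id, x_px, y_px, ux_um, uy_um. Pixel coordinates use
#' the top-left origin with x = column rightward, y = row downward.
#'
#' @param truth A [ground_truth()] tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  write.csv(truth[, c("frame", "node_id", "x_px", "y_px", "ux_um", "uy_um")],
            path, row.names = FALSE)
  invisible(path)
}
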