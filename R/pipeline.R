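# End-to-end pipeline: named scenario presets mirroring the experimental
# arms, staged runners, and a manifest for reproducibility.

preset_names <- c("none", "soft_thick", "soft_thin",
                  "density_1k", "density_5k", "density_10k", "density_20k",
                  "timecourse")

# the three-cell arrangement shared by the thick/thin comparison, um
fixed_cells <- function(strength_um = 20, reach_um = 80, tau_h = 8) {
  bind_rows(
    cell_spec(c(100, 110), strength_um, reach_um, tau_h),
    cell_spec(c(230, 150), strength_um, reach_um, tau_h),
    cell_spec(c(160, 250), strength_um, reach_um, tau_h)
  )
}

# Density arm: per-cell contractile deformation scales inversely with
# plating density (crowded cells in a tug-of-war with mechanically coupled
# neighbours impart less deformation each; the monolayer's total
# contractile budget is conserved). Anchored so a cell at 1000 cells/cm2
# has the reference strength of 20 um.
density_scenario <- function(scn, density, h_um = 283) {
  scenario(scn, density_cells_per_cm2 = density,
           cell_strength_um = 20 * 1000 / density,
           gel = layer_spec(E = 5.5, nu = 0.499, h_um = h_um),
           attenuation_mode = "mechanics")
}

default_scene <- function(seed) {
  scene_config(width_px = 512L, height_px = 512L, pixel_size_um = 0.65,
               cadence_min = 60, duration_h = 24, bead_count = 800L,
               psf_sigma_px = 1.5, background_level = 0.05,
               spot_peak = 0.5, noise_sigma = 0.05, bit_depth = 16L,
               seed = seed)
}

#' Built-in synthetic scenarios
#'
#' Named scenarios emulating the experimental arms: `soft_thick` /
#' `soft_thin` (identical three-cell fields on 200 vs 50 um soft gels,
#' mechanics attenuation), `density_1k` ... `density_20k` (Poisson-placed
#' cells at 1000-20000 cells/cm2 on a thick soft gel), `timecourse`
#' (a list of day1 / day10 / week7 scenarios with growing density
#' 5000 / 20000 / 60000 cells/cm2), and `none` (zero-cell control for
#' noise-floor calibration). Scenes are 512 x 512 px at 0.65 um/px with
#' 800 beads, hourly frames over 24 h, spot SNR 10.
#'
#' @param name One of the preset names.
#' @param seed Integer seed for the run.
#' @param replicate Replicate index; varies the seeded draws while keeping
#'   the scenario definition fixed.
#' @return A [scenario()], or a named list of scenarios for `timecourse`.
#' @export
scenario_preset <- function(name, seed = 1L, replicate = 1L) {
  if (!name %in% preset_names)
    stop_invalid_config("unknown scenario '%s'; available: %s",
                        name, paste(preset_names, collapse = ", "))
  sseed <- derive_seed(seed, 1000L * replicate + match(name, preset_names))
  scn <- default_scene(sseed)
  thick <- layer_spec(E = 5.5, nu = 0.499, h_um = 200)
  switch(
    name,
    none = scenario(scn, cells = fixed_cells()[0, ], gel = thick,
                    attenuation_mode = "none"),
    soft_thick = scenario(scn, cells = fixed_cells(), gel = thick,
                          attenuation_mode = "mechanics"),
    soft_thin = scenario(scn, cells = fixed_cells(),
                         gel = layer_spec(E = 5.5, nu = 0.499, h_um = 50),
                         attenuation_mode = "mechanics"),
    density_1k = density_scenario(scn, 1000),
    density_5k = density_scenario(scn, 5000),
    density_10k = density_scenario(scn, 10000),
    density_20k = density_scenario(scn, 20000),
    timecourse = {
      dens <- c(day1 = 5000, day10 = 20000, week7 = 60000)
      purrr::imap(dens, function(d, nm) {
        sc <- default_scene(derive_seed(sseed, match(nm, names(dens))))
        density_scenario(sc, d, h_um = 200)
      })
    }
  )
}

#' Simulate a scenario to disk or memory
#'
#' Wraps [render_stack()]; when `out_dir` is given, writes the TIFF stack,
#' the ground-truth CSV and a YAML echo of the scenario.
#'
#' @param scn A [scenario()] or preset name.
#' @param out_dir Optional output directory.
#' @param seed,replicate Used only when `scn` is a preset name.
#' @return The rendered `frame_stack` (with `$truth`).
#' @export
run_simulate <- function(scn, out_dir = NULL, seed = 1L, replicate = 1L) {
  if (is.character(scn)) scn <- scenario_preset(scn, seed, replicate)
  stack <- render_stack(scn)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_stack(stack, file.path(out_dir, "stack.tif"))
    write_ground_truth(stack$truth, file.path(out_dir, "ground_truth.csv"))
    yaml::write_yaml(scenario_echo(scn), file.path(out_dir, "scenario.yaml"))
  }
  stack
}

scenario_echo <- function(scn) {
  list(scene = unclass(scn$scene),
       cells = as.list(as.data.frame(scn$cells)),
       density_cells_per_cm2 = scn$density_cells_per_cm2,
       gel = unclass(scn$gel),
       punch = unclass(scn$punch),
       attenuation_mode = scn$attenuation_mode)
}

#' Track a stack at hourly intervals
#'
#' Builds the standard 10 x 8 node grid (99 nodes), selects chained frame
#' pairs one `pair_interval_h` apart, and tracks them (Lagrangian by
#' default).
#'
#' @param stack A `frame_stack`.
#' @param params A [track_params()].
#' @param cfg A [stats_config()]; its cadence is taken from the stack.
#' @param grid Optional [build_grid()] override.
#' @param lagrangian Passed to [track_sequence()].
#' @param out_dir Optional directory for the fields CSV and params YAML.
#' @return List of `displacement_field` tibbles.
#' @export
run_track <- function(stack, params = track_params(), cfg = stats_config(),
                      grid = NULL, lagrangian = TRUE, out_dir = NULL) {
  cfg$cadence_min <- diff(stack$times_h[1:2]) * 60
  if (is.null(grid))
    grid <- build_grid(10, 8, dim(stack$frames)[1:2], params)
  pairs <- hourly_pairs(stack$times_h, cfg)
  fields <- track_sequence(stack, grid, params,
                           pairs = cbind(pairs$frame_a, pairs$frame_b),
                           lagrangian = lagrangian)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fields(fields, file.path(out_dir, "fields.csv"))
    yaml::write_yaml(unclass(params), file.path(out_dir, "track_params.yaml"))
  }
  fields
}

#' Summarise tracked replicates
#'
#' Accumulates each replicate's interval fields, pools them into the
#' percentile time course, and reports the window mean.
#'
#' @param fields_by_replicate List (one element per replicate) of lists of
#'   `displacement_field` tibbles.
#' @param cfg A [stats_config()].
#' @param out_dir Optional directory for trace/summary CSVs.
#' @return List with `traces` (tibble with `replicate`), `summary`
#'   (a [percentile_timecourse()] table), `window_means` (per replicate)
#'   and `window_mean_um` (pooled).
#' @export
run_summarize <- function(fields_by_replicate, cfg = stats_config(),
                          out_dir = NULL) {
  traces <- purrr::imap_dfr(fields_by_replicate, function(fl, i) {
    mutate(accumulate_displacements(fl, cfg$accumulation_mode), replicate = i)
  })
  summary <- percentile_timecourse(traces, cfg)
  wm <- purrr::map_dbl(unique(traces$replicate), function(r) {
    s1 <- percentile_timecourse(filter(traces, .data$replicate == r), cfg)
    window_average(s1, cfg)
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(traces, file.path(out_dir, "traces.csv"), row.names = FALSE)
    write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
    yaml::write_yaml(unclass(cfg), file.path(out_dir, "stats_config.yaml"))
  }
  list(traces = traces, summary = summary, window_means = wm,
       window_mean_um = window_average(summary, cfg))
}

#' Run the full chain for one or more conditions
#'
#' For every named condition, simulates `n_replicates` seeded replicates,
#' tracks them at hourly intervals, summarises, and collects the grouped
#' window means. When `out_dir` is given, per-condition CSVs, the group
#' table, and a JSON manifest (package version, seeds, file hashes) are
#' written.
#'
#' @param conditions Character vector of preset names (or a named list of
#'   [scenario()] objects).
#' @param n_replicates Replicates per condition (default 3, the triplicate
#'   structure of the experiments).
#' @param seed Master seed.
#' @param cfg A [stats_config()].
#' @param params A [track_params()].
#' @param out_dir Optional output directory.
#' @return List with `group` (the [group_summary()] tibble), `per_condition`
#'   (summaries and window means) and `manifest`.
#' @export
run_all <- function(conditions = c("soft_thick", "soft_thin"),
                    n_replicates = 3, seed = 1L, cfg = stats_config(),
                    params = track_params(), out_dir = NULL) {
  named_scn <- !is.character(conditions)
  cond_names <- if (named_scn) names(conditions) else conditions
  per_condition <- list()
  rows <- list()
  for (ci in seq_along(cond_names)) {
    cname <- cond_names[ci]
    fields_by_rep <- purrr::map(seq_len(n_replicates), function(r) {
      scn <- if (named_scn) conditions[[ci]] else scenario_preset(cname, seed, r)
      stack <- run_simulate(scn)
      run_track(stack, params, cfg)
    })
    res <- run_summarize(fields_by_rep, cfg,
                         out_dir = if (is.null(out_dir)) NULL
                                   else file.path(out_dir, cname))
    per_condition[[cname]] <- res
    rows[[cname]] <- tibble(condition = cname,
                            replicate = seq_along(res$window_means),
                            window_mean_um = res$window_means)
  }
  group <- group_summary(bind_rows(rows))
  manifest <- list(
    package = "gelsense",
    version = as.character(utils::packageVersion("gelsense")),
    seed = seed, n_replicates = n_replicates,
    conditions = cond_names,
    stats_config = unclass(cfg), track_params = unclass(params),
    created = "see file mtimes"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(group, file.path(out_dir, "group_summary.csv"), row.names = FALSE)
    files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
    manifest$md5 <- as.list(tools::md5sum(files))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(group = group, per_condition = per_condition, manifest = manifest)
}

#' Ground-truth window-mean percentile for a scenario
#'
#' Computes the summary statistic directly from the exact displacement
#' field (no rendering or tracking): hourly ground-truth interval
#' differences are accumulated and summarised exactly as tracked data
#' would be. Useful for fast scenario-level comparisons.
#'
#' @param scn A [scenario()] or preset name.
#' @param cfg A [stats_config()].
#' @param seed,replicate Used when `scn` is a preset name.
#' @return Scalar window-mean percentile (um).
#' @export
truth_window_mean <- function(scn, cfg = stats_config(), seed = 1L,
                              replicate = 1L) {
  if (is.character(scn)) scn <- scenario_preset(scn, seed, replicate)
  grid <- build_grid(10, 8, c(scn$scene$height_px, scn$scene$width_px))
  times <- seq(0, scn$scene$duration_h, by = cfg$pair_interval_h)
  tr <- ground_truth(scn, grid, times)
  fields <- purrr::map(2:length(times), function(k) {
    a <- filter(tr, .data$frame == k - 1); b <- filter(tr, .data$frame == k)
    f <- tibble(node_id = a$node_id,
                ux_um = b$ux_um - a$ux_um, uy_um = b$uy_um - a$uy_um)
    attr(f, "t_b_h") <- times[k]
    f
  })
  cum <- accumulate_displacements(fields, cfg$accumulation_mode)
  window_average(percentile_timecourse(cum, cfg), cfg)
}
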