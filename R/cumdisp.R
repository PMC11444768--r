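# Cumulative displacement statistics: hourly pairing, per-node
# accumulation, 90th-percentile time courses, window averages.

#' Statistics configuration
#'
#' @param cadence_min Frame cadence in minutes (default 5).
#' @param pair_interval_h Interval between paired frames in hours
#'   (default 1); must be an integer multiple of the cadence.
#' @param window_start_h,window_end_h Averaging window for the
#'   90th-percentile time course, inclusive (default 8 to 24 h).
#' @param accumulation_mode `"path"` (sum of interval magnitudes,
#'   nondecreasing; default) or `"net"` (magnitude of the vector sum).
#' @param percentile Upper percentile summarised across nodes (default 90).
#' @return An object of class `stats_config`.
#' @export
stats_config <- function(cadence_min = 5, pair_interval_h = 1,
                         window_start_h = 8, window_end_h = 24,
                         accumulation_mode = c("path", "net"),
                         percentile = 90) {
  accumulation_mode <- match.arg(accumulation_mode)
  if (window_start_h >= window_end_h)
    stop_invalid_config("window_start_h must be < window_end_h")
  if (percentile <= 0 || percentile >= 100)
    stop_invalid_config("percentile must be in (0, 100)")
  structure(list(cadence_min = cadence_min, pair_interval_h = pair_interval_h,
                 window_start_h = window_start_h, window_end_h = window_end_h,
                 accumulation_mode = accumulation_mode, percentile = percentile),
            class = "stats_config")
}

#' Chained hourly frame pairs
#'
#' For a uniformly sampled stack, returns the chained pairs one tracking
#' interval apart: with a 5-min cadence and 1-h interval over 24 h (289
#' frames) these are the 24 consecutive hourly intervals.
#'
#' @param times_h Frame times in hours, uniformly spaced.
#' @param cfg A [stats_config()].
#' @return Tibble with columns `pair_id`, `frame_a`, `frame_b`, `t_a_h`,
#'   `t_b_h`.
#' @export
hourly_pairs <- function(times_h, cfg = stats_config()) {
  n <- length(times_h)
  if (n < 2) stop_invalid_config("need at least two frames")
  dt <- diff(times_h)
  if (max(abs(dt - dt[1])) > 1e-9)
    stop_invalid_config("frame times are not uniformly spaced")
  cad_h <- dt[1]
  if (abs(cad_h * 60 - cfg$cadence_min) > 1e-6)
    stop_invalid_config("stack cadence (%.4g min) != configured cadence (%.4g min)",
                        cad_h * 60, cfg$cadence_min)
  k <- cfg$pair_interval_h / cad_h
  if (abs(k - round(k)) > 1e-9 || round(k) < 1)
    stop_invalid_config(
      "pair_interval_h (%g h) is not a whole multiple of the cadence (%g min)",
      cfg$pair_interval_h, cfg$cadence_min)
  k <- as.integer(round(k))
  a <- seq(1L, n - k, by = k)
  tibble(pair_id = seq_along(a), frame_a = a, frame_b = a + k,
         t_a_h = times_h[a], t_b_h = times_h[a + k])
}

#' Accumulate per-interval displacements into cumulative traces
#'
#' Path mode sums interval magnitudes per node (total distance moved,
#' nondecreasing); net mode takes the magnitude of the running vector sum
#' (straight-line distance from start). Path dominates net pointwise.
#'
#' @param fields List of `displacement_field` tibbles (ordered intervals,
#'   identical node sets), e.g. from [track_sequence()].
#' @param mode `"path"` or `"net"`.
#' @param times_h End time of each interval; defaults to the fields'
#'   `t_b_h` attributes, else `1:n` hours.
#' @return Tibble of class `cumulative_trace`: `node_id`, `t_h`, `cum_um`.
#' @export
accumulate_displacements <- function(fields, mode = c("path", "net"),
                                     times_h = NULL) {
  mode <- match.arg(mode)
  if (length(fields) < 1) stop_data_error("no interval fields supplied")
  ids <- fields[[1]]$node_id
  if (is.null(times_h)) {
    times_h <- purrr::map_dbl(fields, function(f) {
      tb <- attr(f, "t_b_h"); if (is.null(tb)) NA_real_ else tb
    })
    if (anyNA(times_h)) times_h <- seq_along(fields)
  }
  for (j in seq_along(fields)) {
    miss <- setdiff(ids, fields[[j]]$node_id)
    if (length(miss) > 0)
      stop_data_error("node %d missing from interval %d", miss[1], j)
  }
  ux <- sapply(fields, function(f) f$ux_um[match(ids, f$node_id)])
  uy <- sapply(fields, function(f) f$uy_um[match(ids, f$node_id)])
  if (is.null(dim(ux))) { ux <- matrix(ux, nrow = 1); uy <- matrix(uy, nrow = 1) }
  cum <- if (mode == "path") {
    t(apply(sqrt(ux^2 + uy^2), 1, cumsum))
  } else {
    sqrt(t(apply(ux, 1, cumsum))^2 + t(apply(uy, 1, cumsum))^2)
  }
  out <- tibble(node_id = rep(ids, times = length(times_h)),
                t_h = rep(times_h, each = length(ids)),
                cum_um = as.vector(cum))
  class(out) <- c("cumulative_trace", class(out))
  out
}

#' Percentile time course with replicate spread
#'
#' At each time point, takes the configured upper percentile (linear
#' interpolation between order statistics) of cumulative displacements
#' pooled across the nodes of all replicates, and the sample standard
#' deviation (n - 1) of the per-replicate percentiles. The SD across
#' pooled nodes is also reported.
#'
#' @param traces A `cumulative_trace` tibble with an additional
#'   `replicate` column, or a list of per-replicate traces.
#' @param cfg A [stats_config()].
#' @return Tibble of class `summary_table`: `t_h`, `p90_um`, `sd_um`
#'   (across replicate percentiles; 0 when n = 1), `sd_nodes_um`,
#'   `n_replicates`.
#' @export
percentile_timecourse <- function(traces, cfg = stats_config()) {
  if (is.list(traces) && !is.data.frame(traces)) {
    traces <- purrr::imap_dfr(traces, function(tr, i) mutate(tr, replicate = i))
  }
  if (!"replicate" %in% names(traces)) traces$replicate <- 1L
  if (nrow(traces) == 0) stop_data_error("empty node set")
  p <- cfg$percentile / 100
  out <- traces |>
    group_by(.data$t_h) |>
    summarise(
      p90_um = quantile(.data$cum_um, p, type = 7, names = FALSE),
      sd_nodes_um = if (dplyr::n() > 1) sd(.data$cum_um) else 0,
      sd_um = {
        reps <- tapply(.data$cum_um, .data$replicate,
                       quantile, probs = p, type = 7, names = FALSE)
        if (length(reps) > 1) sd(reps) else 0
      },
      n_replicates = length(unique(.data$replicate)),
      .groups = "drop"
    ) |>
    select("t_h", "p90_um", "sd_um", "sd_nodes_um", "n_replicates") |>
    arrange(.data$t_h)
  class(out) <- c("summary_table", class(out))
  attr(out, "percentile") <- cfg$percentile
  out
}

#' Window average of the percentile time course
#'
#' Unweighted mean of the percentile values at time points with
#' `window_start_h <= t <= window_end_h` (inclusive).
#'
#' @param summary A [percentile_timecourse()] table.
#' @param cfg A [stats_config()] giving the window.
#' @return Scalar mean (um).
#' @export
window_average <- function(summary, cfg = stats_config()) {
  sel <- summary$t_h >= cfg$window_start_h - 1e-9 &
    summary$t_h <= cfg$window_end_h + 1e-9
  if (!any(sel))
    stop_data_error("no time points in window [%g, %g] h",
                    cfg$window_start_h, cfg$window_end_h)
  mean(summary$p90_um[sel])
}

#' Descriptive group summary of window means
#'
#' @param df Data frame with columns `condition` and `window_mean_um`
#'   (one row per replicate).
#' @return Tibble with one row per condition: `condition`, `mean_um`,
#'   `sd_um` (0 when n = 1), `n`, ordered by condition name.
#' @export
group_summary <- function(df) {
  df |>
    group_by(.data$condition) |>
    summarise(mean_um = mean(.data$window_mean_um),
              sd_um = if (dplyr::n() > 1) sd(.data$window_mean_um) else 0,
              n = dplyr::n(), .groups = "drop") |>
    arrange(.data$condition)
}
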