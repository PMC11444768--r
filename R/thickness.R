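# Gel thickness from confocal z-profiles: half-maximum crossings of the
# fluorescence intensity plateau.

#' Estimate slab thickness from a z intensity profile
#'
#' The baseline is the median of the lowest decile of intensities (robust
#' to autofluorescence offsets); intensities are normalized to
#' `[baseline, max]`; the first upward and last downward crossings of
#' `threshold_frac` are located by linear interpolation between adjacent
#' samples; thickness is their separation. Requires a clear plateau
#' (max > 3x baseline) and exactly one above-threshold run.
#'
#' @param profile Data frame with ascending `z_um` and nonnegative
#'   `intensity` (>= 5 samples), e.g. from [render_zprofile()] or
#'   [read_zprofile()].
#' @param threshold_frac Crossing threshold on the normalized scale
#'   (default 0.5, half maximum).
#' @return Object of class `gel_thickness`: a list with `thickness_um`,
#'   `z_up_um`, `z_down_um`, `baseline`, `peak`, `snr`, `threshold_frac`.
#' @export
estimate_thickness <- function(profile, threshold_frac = 0.5) {
  z <- profile$z_um; inten <- profile$intensity
  if (length(z) < 5) stop_data_error("profile needs at least 5 samples")
  if (is.unsorted(z, strictly = TRUE)) stop_data_error("z_um must be strictly increasing")
  if (threshold_frac <= 0 || threshold_frac >= 1)
    stop_invalid_config("threshold_frac must be in (0, 1)")
  nlow <- max(1L, floor(length(inten) * 0.1))
  srt <- sort(inten)
  baseline <- stats::median(srt[seq_len(nlow)])
  # plateau level from the top decile median: robust to noise extremes,
  # equal to the max on noiseless profiles
  peak <- stats::median(srt[(length(srt) - nlow + 1L):length(srt)])
  if (peak <= 3 * max(baseline, .Machine$double.eps))
    stop_data_error("no slab detected: plateau max (%.3g) is not > 3x baseline (%.3g)",
                    peak, baseline)
  u <- (inten - baseline) / (peak - baseline)
  above <- u >= threshold_frac
  runs <- rle(above)
  run_id <- rep(seq_along(runs$lengths), runs$lengths)
  plateau_runs <- which(runs$values & runs$lengths >= 2)
  if (length(plateau_runs) == 0)
    stop_data_error("no slab detected: no above-threshold plateau")
  if (length(plateau_runs) > 1) {
    ivals <- vapply(plateau_runs, function(rn) {
      idx <- which(run_id == rn)
      sprintf("[%.4g, %.4g]", z[min(idx)], z[max(idx)])
    }, character(1))
    stop_data_error("multiple plateaus detected: candidate intervals %s",
                    paste(ivals, collapse = ", "))
  }
  idx <- which(run_id == plateau_runs)
  i1 <- min(idx); i2 <- max(idx)
  cross_at <- function(ia, ib) {
    # linear interpolation of the threshold crossing between samples ia, ib
    if (u[ib] == u[ia]) return(mean(z[c(ia, ib)]))
    z[ia] + (threshold_frac - u[ia]) / (u[ib] - u[ia]) * (z[ib] - z[ia])
  }
  z_up <- if (i1 == 1) z[1] else cross_at(i1 - 1, i1)
  z_down <- if (i2 == length(z)) z[length(z)] else cross_at(i2, i2 + 1)
  if (i1 == 1 || i2 == length(z))
    warn("plateau touches the profile boundary; thickness may be truncated")
  structure(list(thickness_um = z_down - z_up, z_up_um = z_up,
                 z_down_um = z_down, baseline = baseline, peak = peak,
                 # noise clipped at zero can drive the baseline to ~0;
                 # cap the reported contrast ratio at 1000
                 snr = peak / max(baseline, 0.001 * peak),
                 threshold_frac = threshold_frac),
            class = "gel_thickness")
}

#' @export
print.gel_thickness <- function(x, ...) {
  cat(sprintf("<gel_thickness> %.2f um (crossings %.2f -> %.2f um, SNR %.1f)\n",
              x$thickness_um, x$z_up_um, x$z_down_um, x$snr))
  invisible(x)
}

#' Tidy a thickness estimate
#' @param x A `gel_thickness`.
#' @param ... Unused.
#' @return One-row tibble with the crossings and thickness.
#' @method tidy gel_thickness
#' @export
tidy.gel_thickness <- function(x, ...) {
  tibble(thickness_um = x$thickness_um, z_up_um = x$z_up_um,
         z_down_um = x$z_down_um)
}

#' One-row quality summary of a thickness estimate
#' @param x A `gel_thickness`.
#' @param ... Unused.
#' @return One-row tibble with baseline, peak, SNR and threshold.
#' @method glance gel_thickness
#' @export
glance.gel_thickness <- function(x, ...) {
  tibble(baseline = x$baseline, peak = x$peak, snr = x$snr,
         threshold_frac = x$threshold_frac)
}

#' Read a two-column z-profile CSV
#' @param path CSV with columns `z_um`, `intensity`.
#' @return Tibble with those columns.
#' @export
read_zprofile <- function(path) {
  df <- as_tibble(read.csv(path))
  if (!all(c("z_um", "intensity") %in% names(df)))
    stop_data_error("z-profile CSV must have columns z_um, intensity")
  df
}
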