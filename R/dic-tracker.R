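# Digital image correlation tracker: windowed zero-normalized
# cross-correlation on a node lattice with subpixel quadratic refinement
# and Gaussian field smoothing.

#' Tracking parameters
#'
#' Defaults follow common practice for bead-image DIC on time-lapse
#' hydrogel recordings: a 31-px correlation template, +/-6 px integer
#' search, a 9-px quadratic subpixel fit, and neighbour smoothing with
#' blend weight 5 over a 25-px length scale.
#'
#' @param kernel_size Odd template width in px (>= 3).
#' @param subpixel_window Odd width of the correlation neighbourhood used
#'   for the subpixel quadratic fit.
#' @param smoothness Blend weight of the neighbour-smoothed field;
#'   0 disables smoothing exactly.
#' @param max_move Half-width of the integer search range, px.
#' @param smooth_grid Gaussian smoothing length scale, px.
#' @return An object of class `track_params`.
#' @export
track_params <- function(kernel_size = 31L, subpixel_window = 9L,
                         smoothness = 5, max_move = 6L, smooth_grid = 25) {
  if (kernel_size < 3 || kernel_size %% 2 == 0)
    stop_invalid_config("kernel_size must be an odd integer >= 3")
  if (subpixel_window < 3 || subpixel_window %% 2 == 0)
    stop_invalid_config("subpixel_window must be an odd integer >= 3")
  if (smoothness < 0) stop_invalid_config("smoothness must be >= 0")
  if (max_move < 1) stop_invalid_config("max_move must be >= 1")
  if (smooth_grid <= 0) stop_invalid_config("smooth_grid must be positive")
  structure(list(kernel_size = as.integer(kernel_size),
                 subpixel_window = as.integer(min(subpixel_window, 2L * max_move + 1L)),
                 smoothness = smoothness, max_move = as.integer(max_move),
                 smooth_grid = smooth_grid),
            class = "track_params")
}

#' Build the node lattice for tracking
#'
#' An evenly spaced lattice of `(n_cols_cells + 1) * (n_rows_cells + 1)`
#' nodes (a 10 x 8 grid of cells yields 99 nodes) inset from the image
#' border so every correlation template plus search range fits inside.
#'
#' @param n_cols_cells,n_rows_cells Grid cells along x and y.
#' @param image_shape Integer vector `c(height, width)` in px.
#' @param params A [track_params()]; sets the safety inset.
#' @return Tibble of class `node_grid` with columns `node_id`, `col`,
#'   `row`, `x_px`, `y_px` (1-based pixel coordinates, top-left origin,
#'   x = column rightward, y = row downward).
#' @export
build_grid <- function(n_cols_cells, n_rows_cells, image_shape,
                       params = track_params()) {
  if (n_cols_cells < 1 || n_rows_cells < 1)
    stop_invalid_config("grid must have at least one cell per direction")
  h <- image_shape[1]; w <- image_shape[2]
  inset <- ceiling(params$kernel_size / 2) + params$max_move
  min_dim <- 2 * inset + 2
  if (w < min_dim || h < min_dim)
    stop_invalid_config(
      "image %d x %d too small for kernel_size=%d, max_move=%d; need at least %d x %d",
      w, h, params$kernel_size, params$max_move, min_dim, min_dim)
  xs <- seq(inset + 1, w - inset, length.out = n_cols_cells + 1)
  ys <- seq(inset + 1, h - inset, length.out = n_rows_cells + 1)
  g <- tidyr::expand_grid(row = seq_along(ys), col = seq_along(xs))
  out <- tibble(node_id = seq_len(nrow(g)), col = g$col, row = g$row,
                x_px = xs[g$col], y_px = ys[g$row])
  class(out) <- c("node_grid", class(out))
  attr(out, "params") <- params
  attr(out, "image_shape") <- c(h, w)
  out
}

# zero-normalized cross-correlation of one template against all integer
# offsets in [-M, M]^2; returns list(corr matrix (2M+1)x(2M+1), ok)
zncc_search <- function(frame_a, frame_b, cx, cy, K, M) {
  hk <- (K - 1L) %/% 2L
  tx <- (cx - hk):(cx + hk); ty <- (cy - hk):(cy + hk)
  tmpl <- frame_a[ty, tx]
  tv <- as.vector(tmpl) - mean(tmpl)
  tn <- sqrt(sum(tv^2))
  if (tn == 0) return(NULL)
  # search region in frame_b and all K x K patches via index arithmetic
  reg <- frame_b[(cy - hk - M):(cy + hk + M), (cx - hk - M):(cx + hk + M)]
  nrr <- nrow(reg)
  base <- as.vector(outer((M + 1L):(M + K), (M + 0:(K - 1L)) * nrr, "+"))  # offset (0,0)
  offs <- tidyr::expand_grid(dx = -M:M, dy = -M:M)   # column-major over dy fastest
  shift <- offs$dy + offs$dx * nrr
  P <- matrix(reg[outer(base, shift, "+")], nrow = K * K)
  Pm <- colMeans(P)
  Pc <- sweep(P, 2, Pm)
  pn <- sqrt(colSums(Pc^2))
  cc <- as.vector(tv %*% Pc) / (tn * pmax(pn, .Machine$double.eps))
  cc[pn == 0] <- 0
  list(corr = cc, dx = offs$dx, dy = offs$dy)
}

# integer peak with tie-breaking: max corr, then smallest |offset|,
# then lexicographic (dx, dy)
peak_pick <- function(sr) {
  cmax <- max(sr$corr)
  cand <- which(sr$corr >= cmax - 1e-12)
  if (length(cand) > 1) {
    d2 <- sr$dx[cand]^2 + sr$dy[cand]^2
    cand <- cand[d2 == min(d2)]
    if (length(cand) > 1)
      cand <- cand[order(sr$dx[cand], sr$dy[cand])][1]
  }
  cand[1]
}

# least-squares 2-D quadratic subpixel fit around the integer peak,
# Gaussian-weighted toward the peak so the narrow correlation maximum is
# fitted rather than the flat background ring; centroid fallback when the
# fitted surface is not concave
subpixel_fit <- function(sr, ipk, M, win) {
  hw <- (win - 1L) %/% 2L
  px <- sr$dx[ipk]; py <- sr$dy[ipk]
  sel <- which(abs(sr$dx - px) <= hw & abs(sr$dy - py) <= hw)
  x <- sr$dx[sel] - px; y <- sr$dy[sel] - py; c0 <- sr$corr[sel]
  if (length(sel) >= 6) {
    wsig <- max(0.75, hw / 4)
    wt <- sqrt(exp(-(x^2 + y^2) / (2 * wsig^2)))
    X <- cbind(1, x, y, x^2, y^2, x * y) * wt
    b <- tryCatch(qr.solve(X, c0 * wt), error = function(e) NULL)
    if (!is.null(b)) {
      H <- matrix(c(2 * b[4], b[6], b[6], 2 * b[5]), 2)
      if (H[1, 1] < 0 && det(H) > 0) {
        d <- solve(H, -c(b[2], b[3]))
        if (max(abs(d)) <= hw + 0.5)
          return(list(dx = px + d[1], dy = py + d[2], flag = "ok"))
      }
    }
  }
  w <- c0 - min(c0)
  if (sum(w) == 0) return(list(dx = px, dy = py, flag = "fallback"))
  list(dx = px + sum(w * x) / sum(w), dy = py + sum(w * y) / sum(w),
       flag = "fallback")
}

#' Track displacements between two frames at grid nodes
#'
#' For each node a `kernel_size`-square template from `frame_a` is matched
#' in `frame_b` by zero-normalized cross-correlation over integer offsets
#' within `+/- max_move`, the peak refined by a least-squares quadratic
#' surface over the `subpixel_window` neighbourhood (intensity-weighted
#' centroid fallback when the surface is not concave), and the raw field
#' blended with its Gaussian-weighted (`smooth_grid`) neighbour average
#' using weight `smoothness`.
#'
#' Quality flags: `ok`; `clamped` (integer peak on the search border);
#' `low_corr` (blank template, displacement taken from the smoothed
#' neighbour estimate); `fallback` (centroid subpixel refinement).
#'
#' @param frame_a,frame_b Numeric matrices (same shape).
#' @param grid A [build_grid()] table; `positions` may override node
#'   positions (advected tracking).
#' @param params A [track_params()].
#' @param pixel_size_um Microns per pixel for the `*_um` columns.
#' @param positions Optional tibble (`node_id`, `x_px`, `y_px`) of current
#'   node positions.
#' @return Tibble of class `displacement_field`: `node_id`, `x_px`, `y_px`,
#'   `ux_px`, `uy_px`, `ux_um`, `uy_um`, `corr`, `flag`.
#' @export
track_pair <- function(frame_a, frame_b, grid, params = track_params(),
                       pixel_size_um = 1, positions = NULL) {
  if (!all(dim(frame_a) == dim(frame_b)))
    stop_data_error("frames must have identical shape")
  if (is.null(positions))
    positions <- grid[, c("node_id", "x_px", "y_px")]
  K <- params$kernel_size; M <- params$max_move
  hk <- (K - 1L) %/% 2L
  nr <- nrow(frame_a); nc <- ncol(frame_a)
  nnode <- nrow(positions)
  ux <- uy <- rep(NA_real_, nnode)
  corr <- rep(NA_real_, nnode)
  flag <- rep("ok", nnode)
  for (i in seq_len(nnode)) {
    cx <- round(positions$x_px[i]); cy <- round(positions$y_px[i])
    if (cx - hk - M < 1 || cx + hk + M > nc || cy - hk - M < 1 || cy + hk + M > nr) {
      flag[i] <- "clamped"; ux[i] <- 0; uy[i] <- 0; corr[i] <- NA_real_
      next
    }
    sr <- zncc_search(frame_a, frame_b, cx, cy, K, M)
    if (is.null(sr)) { flag[i] <- "low_corr"; next }
    ipk <- peak_pick(sr)
    corr[i] <- sr$corr[ipk]
    if (abs(sr$dx[ipk]) == M || abs(sr$dy[ipk]) == M) {
      flag[i] <- "clamped"
      ux[i] <- sr$dx[ipk]; uy[i] <- sr$dy[ipk]
      next
    }
    sp <- subpixel_fit(sr, ipk, M, params$subpixel_window)
    if (sp$flag == "fallback") flag[i] <- "fallback"
    ux[i] <- sp$dx; uy[i] <- sp$dy
  }
  # normalized-median outlier test (universal outlier detection): a sparse
  # template can lock onto the wrong bead, so nodes whose raw displacement
  # deviates from the local median by more than 2 robust residuals are
  # treated as unreliable and take the neighbour estimate (flag low_corr)
  reliable <- flag %in% c("ok", "fallback")
  d2 <- as.matrix(stats::dist(cbind(positions$x_px, positions$y_px)))^2
  if (sum(reliable) >= 5) {
    rel_idx <- which(reliable)
    # clamped nodes with a measured (border) value are tested too: an
    # isolated border peak among consistent neighbours is a false match
    for (i in union(rel_idx, which(flag == "clamped" & !is.na(ux)))) {
      nb <- rel_idx[rel_idx != i]
      nb <- nb[order(d2[i, nb])][seq_len(min(8, length(nb)))]
      mx <- stats::median(ux[nb]); my <- stats::median(uy[nb])
      rm_ <- stats::median(sqrt((ux[nb] - mx)^2 + (uy[nb] - my)^2))
      if (sqrt((ux[i] - mx)^2 + (uy[i] - my)^2) / (rm_ + 0.2) > 2)
        flag[i] <- "low_corr"
    }
    reliable <- flag %in% c("ok", "fallback")
  }
  # gaussian-weighted neighbour average of reliable raw displacements
  sux <- ux; suy <- uy
  if (sum(reliable) > 1) {
    W <- exp(-d2 / (2 * params$smooth_grid^2))
    diag(W) <- 0
    W[, !reliable] <- 0
    wsum <- rowSums(W)
    nb_x <- ifelse(wsum > 0, as.vector(W %*% replace(ux, !reliable, 0)) / wsum, NA_real_)
    nb_y <- ifelse(wsum > 0, as.vector(W %*% replace(uy, !reliable, 0)) / wsum, NA_real_)
    s <- params$smoothness
    blend <- reliable & !is.na(nb_x)
    sux[blend] <- (ux[blend] + s * nb_x[blend]) / (1 + s)
    suy[blend] <- (uy[blend] + s * nb_y[blend]) / (1 + s)
    fill <- flag == "low_corr"
    sux[fill] <- ifelse(is.na(nb_x[fill]), 0, nb_x[fill])
    suy[fill] <- ifelse(is.na(nb_y[fill]), 0, nb_y[fill])
  } else {
    sux[is.na(sux)] <- 0; suy[is.na(suy)] <- 0
  }
  out <- tibble(node_id = positions$node_id,
                x_px = positions$x_px, y_px = positions$y_px,
                ux_px = sux, uy_px = suy,
                ux_um = sux * pixel_size_um, uy_um = suy * pixel_size_um,
                corr = corr, flag = flag)
  class(out) <- c("displacement_field", class(out))
  out
}

#' Track a frame sequence pair-by-pair
#'
#' Tracks each consecutive pair in `pairs` (default: every adjacent frame).
#' With `lagrangian = TRUE` (default) node positions are advected by the
#' measured displacement after every interval so the same material point is
#' followed; nodes whose advected template would leave the image are frozen
#' (`clamped`, zero displacement) with a warning. `lagrangian = FALSE`
#' re-centres on the original grid each interval (Eulerian).
#'
#' @param stack A `frame_stack`.
#' @param grid A [build_grid()] table.
#' @param params A [track_params()].
#' @param pairs Two-column matrix/data frame of frame indices (a, b);
#'   defaults to consecutive frames.
#' @param lagrangian Follow material points (default `TRUE`).
#' @return List of `displacement_field` tibbles, one per pair, each with
#'   attributes `frame_a`, `frame_b`, `t_a_h`, `t_b_h`.
#' @export
track_sequence <- function(stack, grid, params = track_params(),
                           pairs = NULL, lagrangian = TRUE) {
  nf <- dim(stack$frames)[3]
  if (is.null(pairs))
    pairs <- cbind(seq_len(nf - 1), 2:nf)
  pairs <- as.matrix(pairs)
  if (nrow(pairs) < 1) stop_data_error("need at least one frame pair")
  pos <- grid[, c("node_id", "x_px", "y_px")]
  K <- params$kernel_size; M <- params$max_move
  hk <- (K - 1L) %/% 2L
  nr <- dim(stack$frames)[1]; nc <- dim(stack$frames)[2]
  frozen <- rep(FALSE, nrow(pos))
  out <- vector("list", nrow(pairs))
  n_frozen_new <- 0L
  for (p in seq_len(nrow(pairs))) {
    fa <- stack$frames[, , pairs[p, 1]]
    fb <- stack$frames[, , pairs[p, 2]]
    fld <- track_pair(fa, fb, grid, params, stack$pixel_size_um, positions = pos)
    fld$ux_px[frozen] <- 0; fld$uy_px[frozen] <- 0
    fld$ux_um[frozen] <- 0; fld$uy_um[frozen] <- 0
    fld$flag[frozen] <- "clamped"
    if (lagrangian) {
      nx <- pos$x_px + fld$ux_px; ny <- pos$y_px + fld$uy_px
      bad <- !frozen & (round(nx) - hk - M < 1 | round(nx) + hk + M > nc |
                          round(ny) - hk - M < 1 | round(ny) + hk + M > nr)
      n_frozen_new <- n_frozen_new + sum(bad)
      adv <- !(frozen | bad)
      pos$x_px[adv] <- nx[adv]
      pos$y_px[adv] <- ny[adv]
      frozen <- frozen | bad
    }
    attr(fld, "frame_a") <- pairs[p, 1]; attr(fld, "frame_b") <- pairs[p, 2]
    attr(fld, "t_a_h") <- stack$times_h[pairs[p, 1]]
    attr(fld, "t_b_h") <- stack$times_h[pairs[p, 2]]
    out[[p]] <- fld
  }
  if (n_frozen_new > 0)
    warn(sprintf("%d node(s) advected out of bounds and frozen", n_frozen_new))
  out
}

#' Write per-interval displacement fields to CSV
#'
#' Columns: frame_a, frame_b, node_id, x_px, y_px, ux_um, uy_um, corr,
#' flag. Coordinates are 1-based, top-left origin, x = column rightward,
#' y = row downward.
#'
#' @param fields List of `displacement_field` tibbles from [track_sequence()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fields <- function(fields, path) {
  rows <- purrr::map_dfr(fields, function(f) {
    tibble(frame_a = attr(f, "frame_a"), frame_b = attr(f, "frame_b"),
           node_id = f$node_id, x_px = f$x_px, y_px = f$y_px,
           ux_um = f$ux_um, uy_um = f$uy_um, corr = f$corr, flag = f$flag)
  })
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
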