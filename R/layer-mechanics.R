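# Apparent stiffness of a rigid circular patch on a bonded elastic layer:
# Fourier-harmonic axisymmetric finite elements (n = 0 normal loading,
# n = 1 tangential), bilinear quads, selective reduced integration on the
# volumetric term, energy-based stiffness k = 2U / delta^2.

#' Elastic layer specification
#'
#' @param E Elastic modulus (kPa; any consistent unit). Default 5.5, the
#'   soft polyacrylamide used in the synthetic scenarios.
#' @param nu Poisson ratio in `[0, 0.5]`. 0.5 is replaced by 0.499 with a
#'   warning (near-incompressible limit the solver can handle). Default
#'   0.499: polyacrylamide is conventionally treated as incompressible.
#' @param h_um Layer thickness (um), > 0; default 200.
#' @param R_lateral_um Radius of a surrounding fixed (zero-displacement)
#'   boundary, or `Inf` for a laterally unconstrained layer (default).
#' @return An object of class `layer_spec`.
#' @export
layer_spec <- function(E = 5.5, nu = 0.499, h_um = 200, R_lateral_um = Inf) {
  if (E <= 0) stop_invalid_config("E must be positive")
  if (nu < 0 || nu > 0.5) stop_invalid_config("nu must be in [0, 0.5]")
  if (nu >= 0.5) {
    warn("nu = 0.5 replaced by 0.499 for the numeric solver")
    nu <- 0.499
  }
  if (h_um <= 0) stop_invalid_config("thickness h_um must be positive")
  if (R_lateral_um <= 0) stop_invalid_config("R_lateral_um must be positive")
  structure(list(E = E, nu = nu, h_um = h_um, R_lateral_um = R_lateral_um),
            class = "layer_spec")
}

#' Loading patch specification
#'
#' An idealised cell adhesion footprint: a rigid circular patch of radius
#' `a_um` displaced vertically (`normal`) or laterally in-plane
#' (`tangential`).
#'
#' @param a_um Patch radius (um), > 0; default 25, the order of a spread
#'   stromal cell's footprint.
#' @param loading `"normal"` or `"tangential"`.
#' @return An object of class `punch_spec`.
#' @export
punch_spec <- function(a_um = 25, loading = c("normal", "tangential")) {
  loading <- match.arg(loading)
  if (a_um <= 0) stop_invalid_config("patch radius a_um must be positive")
  structure(list(a_um = a_um, loading = loading), class = "punch_spec")
}

#' Closed-form half-space punch stiffness
#'
#' Classical flat-punch results for an elastic half-space: normal
#' (frictionless) `k = 2 E a / (1 - nu^2)`; tangential
#' `k = 8 G a / (2 - nu)` with `G = E / (2 (1 + nu))`.
#'
#' @param layer A [layer_spec()] (only `E`, `nu` used).
#' @param punch A [punch_spec()].
#' @return Stiffness (force per unit displacement, units of `E * a_um`).
#' @export
halfspace_stiffness <- function(layer, punch) {
  a <- punch$a_um
  if (punch$loading == "normal") {
    2 * layer$E * a / (1 - layer$nu^2)
  } else {
    G <- layer$E / (2 * (1 + layer$nu))
    8 * G * a / (2 - layer$nu)
  }
}

# geometric 1-D grading: n intervals from `from` to `to`, smallest at `at`
grade_nodes <- function(from, to, n, at = c("start", "end"), g = 1.3) {
  at <- match.arg(at)
  w <- g^(0:(n - 1))
  w <- w / sum(w) * (to - from)
  if (at == "end") w <- rev(w)
  from + cumsum(c(0, w))
}

# strain-displacement matrix at (xi, eta) for a bilinear quad, harmonic n;
# strain order [err, ett, ezz, grz, grt, gtz]
fourier_B <- function(r1, r2, z1, z2, n, xi, eta) {
  ndof <- if (n == 0) 2L else 3L
  hx <- (r2 - r1) / 2; hy <- (z2 - z1) / 2
  N <- c((1 - xi) * (1 - eta), (1 + xi) * (1 - eta),
         (1 + xi) * (1 + eta), (1 - xi) * (1 + eta)) / 4
  dNdr <- c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta)) / (4 * hx)
  dNdz <- c(-(1 - xi), -(1 + xi), (1 + xi), (1 - xi)) / (4 * hy)
  r <- sum(N * c(r1, r2, r2, r1))
  B <- matrix(0, 6, 4 * ndof)
  for (i in 1:4) {
    if (n == 0) {
      iu <- (i - 1) * 2 + 1; iw <- iu + 1
      B[1, iu] <- dNdr[i]
      B[2, iu] <- N[i] / r
      B[3, iw] <- dNdz[i]
      B[4, iu] <- dNdz[i]; B[4, iw] <- dNdr[i]
    } else {
      iu <- (i - 1) * 3 + 1; iv <- iu + 1; iw <- iu + 2
      B[1, iu] <- dNdr[i]
      B[2, iu] <- N[i] / r; B[2, iv] <- n * N[i] / r
      B[3, iw] <- dNdz[i]
      B[4, iu] <- dNdz[i]; B[4, iw] <- dNdr[i]
      B[5, iu] <- -n * N[i] / r; B[5, iv] <- dNdr[i] - N[i] / r
      B[6, iv] <- dNdz[i]; B[6, iw] <- -n * N[i] / r
    }
  }
  list(B = B, r = r)
}

# element stiffness: shear/deviatoric term at 2x2 Gauss, volumetric
# (lambda) term at the 1-point rule to avoid locking near nu = 0.5
fourier_elem_k <- function(r1, r2, z1, z2, n, lam, G) {
  gp <- c(-1, 1) / sqrt(3)
  ndof <- if (n == 0) 2L else 3L
  Ke <- matrix(0, 4 * ndof, 4 * ndof)
  hx <- (r2 - r1) / 2; hy <- (z2 - z1) / 2
  Dmu <- diag(c(2 * G, 2 * G, 2 * G, G, G, G))
  for (xi in gp) for (eta in gp) {
    bb <- fourier_B(r1, r2, z1, z2, n, xi, eta)
    Ke <- Ke + crossprod(bb$B, Dmu %*% bb$B) * bb$r * hx * hy
  }
  Dl <- matrix(0, 6, 6); Dl[1:3, 1:3] <- lam
  bb <- fourier_B(r1, r2, z1, z2, n, 0, 0)
  Ke <- Ke + crossprod(bb$B, Dl %*% bb$B) * bb$r * hx * hy * 4
  Ke * if (n == 0) 2 * pi else pi
}

# one FE solve; returns stiffness k for unit patch displacement
punch_fe_solve <- function(E, nu, a, h, R, loading, lateral_fixed,
                           nr_in, nr_out, nz, g = 1.3) {
  n <- if (loading == "normal") 0L else 1L
  ndof <- if (n == 0) 2L else 3L
  r <- c(grade_nodes(0, a, nr_in, at = "end", g = g),
         grade_nodes(a, R, nr_out, at = "start", g = g)[-1])
  z <- grade_nodes(0, h, nz, at = "end", g = g)
  Nr <- length(r); Nz <- length(z); nn <- Nr * Nz
  nid <- function(ir, iz) (iz - 1L) * Nr + ir
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  G <- E / (2 * (1 + nu))
  nel <- (Nr - 1) * (Nz - 1)
  II <- JJ <- VV <- vector("list", nel)
  e <- 0L
  for (iz in 1:(Nz - 1)) for (ir in 1:(Nr - 1)) {
    e <- e + 1L
    nodes <- c(nid(ir, iz), nid(ir + 1, iz), nid(ir + 1, iz + 1), nid(ir, iz + 1))
    Ke <- fourier_elem_k(r[ir], r[ir + 1], z[iz], z[iz + 1], n, lam, G)
    dofs <- as.vector(t(outer(nodes, 1:ndof, function(nd, d) (nd - 1L) * ndof + d)))
    idx <- expand.grid(i = dofs, j = dofs)
    II[[e]] <- idx$i; JJ[[e]] <- idx$j; VV[[e]] <- as.vector(Ke)
  }
  K <- Matrix::sparseMatrix(i = unlist(II), j = unlist(JJ), x = unlist(VV),
                            dims = c(nn * ndof, nn * ndof))
  dof_of <- function(node, comp) (node - 1L) * ndof + comp
  fixed <- integer(0); fixval <- numeric(0)
  addbc <- function(dofs, vals) {
    fixed <<- c(fixed, dofs); fixval <<- c(fixval, vals)
  }
  base_nodes <- nid(1:Nr, 1L)
  for (d in 1:ndof) addbc(dof_of(base_nodes, d), rep(0, Nr))
  if (lateral_fixed) {
    out_nodes <- nid(Nr, 2:Nz)
    for (d in 1:ndof) addbc(dof_of(out_nodes, d), rep(0, length(out_nodes)))
  }
  ax_nodes <- nid(1L, 2:Nz)
  patch_nodes <- setdiff(nid(which(r <= a * (1 + 1e-9)), Nz), base_nodes)
  if (n == 0) {
    addbc(dof_of(setdiff(ax_nodes, patch_nodes), 1L),
          rep(0, length(setdiff(ax_nodes, patch_nodes))))
    addbc(dof_of(patch_nodes, 2L), rep(1, length(patch_nodes)))  # u_z = 1
    # frictionless: u_r free on patch, but the axis node keeps u_r = 0
    addbc(dof_of(intersect(ax_nodes, patch_nodes), 1L),
          rep(0, length(intersect(ax_nodes, patch_nodes))))
  } else {
    addbc(dof_of(ax_nodes, 3L), rep(0, length(ax_nodes)))        # w = 0 on axis
    addbc(dof_of(patch_nodes, 1L), rep(1, length(patch_nodes)))  # u = 1
    addbc(dof_of(patch_nodes, 2L), rep(-1, length(patch_nodes))) # v = -1
  }
  dup <- duplicated(fixed)
  fixed <- fixed[!dup]; fixval <- fixval[!dup]
  if (n == 1) {
    # axis regularity u + v = 0 at non-patch axis nodes: eliminate v = -u
    ax_free <- setdiff(ax_nodes, patch_nodes)
    slave <- dof_of(ax_free, 2L); master <- dof_of(ax_free, 1L)
    keep <- setdiff(seq_len(nn * ndof), slave)
    Tt <- Matrix::sparseMatrix(i = keep, j = seq_along(keep), x = 1,
                               dims = c(nn * ndof, length(keep)))
    Ts <- Matrix::sparseMatrix(i = slave, j = match(master, keep), x = -1,
                               dims = c(nn * ndof, length(keep)))
    Tm <- Tt + Ts
    Kr <- Matrix::t(Tm) %*% K %*% Tm
    fixed_r <- match(fixed, keep)
    ur <- rep(NA_real_, length(keep)); ur[fixed_r] <- fixval
    free_r <- which(is.na(ur))
    rhs <- -Kr[free_r, fixed_r, drop = FALSE] %*% fixval
    ur[free_r] <- as.vector(Matrix::solve(Kr[free_r, free_r], rhs))
    U <- 0.5 * as.numeric(Matrix::t(ur) %*% Kr %*% ur)
  } else {
    u <- rep(NA_real_, nn * ndof); u[fixed] <- fixval
    free <- which(is.na(u))
    rhs <- -K[free, fixed, drop = FALSE] %*% fixval
    u[free] <- as.vector(Matrix::solve(K[free, free], rhs))
    U <- 0.5 * as.numeric(Matrix::t(u) %*% K %*% u)
  }
  2 * U
}

#' Apparent stiffness of a rigid patch on a finite-thickness layer
#'
#' Solves axisymmetric linear elasticity on `(r, z) in [0, R] x [0, h]`
#' with the base fully bonded (zero displacement), the surface traction
#' free except for a rigid circular patch of radius `a` given unit
#' displacement (vertical for normal loading via the axisymmetric
#' harmonic, lateral in-plane for tangential via the first Fourier
#' harmonic), and the outer boundary fixed when `R_lateral_um` is finite
#' or traction-free at a truncation radius `max(trunc_factor * a, 3 h)`
#' when infinite. The stiffness is the total patch reaction force,
#' recovered from the strain energy.
#'
#' @param layer A [layer_spec()].
#' @param punch A [punch_spec()].
#' @param nr_in,nr_out,nz Element counts across the patch, outside it, and
#'   through the thickness (graded meshes; defaults resolve the patch with
#'   24 elements).
#' @param trunc_factor Truncation radius in patch radii for the laterally
#'   unconstrained case (default 20; enlarged automatically for thick
#'   layers, where a narrow truncated column would flex like a cantilever
#'   under tangential load).
#' @param verify If `TRUE`, repeat the solve on a refined mesh (1.5x
#'   elements) and error if the stiffness changes by more than 2%.
#' @return Stiffness `k` (units of `E * a_um`), with attribute
#'   `k_refined` when `verify = TRUE`.
#' @export
effective_stiffness <- function(layer, punch, nr_in = 24L, nr_out = 34L,
                                nz = 40L, trunc_factor = 20, verify = FALSE) {
  a <- punch$a_um; h <- layer$h_um
  lateral_fixed <- is.finite(layer$R_lateral_um)
  if (lateral_fixed) {
    if (layer$R_lateral_um <= a)
      stop_invalid_config("R_lateral_um must exceed the patch radius")
    R <- layer$R_lateral_um
  } else {
    R <- max(trunc_factor * a, 3 * h)
  }
  k <- punch_fe_solve(layer$E, layer$nu, a, h, R, punch$loading,
                      lateral_fixed, nr_in, nr_out, nz)
  if (verify) {
    k2 <- punch_fe_solve(layer$E, layer$nu, a, h, R, punch$loading,
                         lateral_fixed, ceiling(1.5 * nr_in),
                         ceiling(1.5 * nr_out), ceiling(1.5 * nz))
    if (abs(k2 / k - 1) > 0.02)
      stop_numerical(
        "mesh refinement changed k by %.1f%% (k = %.4g, refined = %.4g) at h/a = %.3g",
        100 * abs(k2 / k - 1), k, k2, h / a)
    attr(k, "k_refined") <- k2
  }
  k
}

#' Stiffness versus thickness curve
#'
#' Tabulates the apparent stiffness over a set of thickness-to-patch-radius
#' ratios, with the ratio to the closed-form half-space value.
#'
#' @param layer A [layer_spec()] template (its `h_um` is overridden).
#' @param punch A [punch_spec()].
#' @param h_over_a Positive ratios to evaluate.
#' @param ... Passed to [effective_stiffness()].
#' @return Tibble of class `stiffness_curve`: `h_over_a`, `h_um`, `k`,
#'   `k_ratio` (`k / k_halfspace`).
#' @export
stiffness_curve <- function(layer, punch, h_over_a = c(0.5, 1, 2, 5, 10, 50),
                            ...) {
  if (length(h_over_a) < 1 || any(h_over_a <= 0))
    stop_invalid_config("h_over_a must be a nonempty positive vector")
  kinf <- halfspace_stiffness(layer, punch)
  rows <- purrr::map_dfr(h_over_a, function(ha) {
    ly <- layer; ly$h_um <- ha * punch$a_um
    k <- effective_stiffness(ly, punch, ...)
    tibble(h_over_a = ha, h_um = ly$h_um, k = as.numeric(k), k_ratio = k / kinf)
  })
  out <- arrange(rows, .data$h_over_a)
  class(out) <- c("stiffness_curve", class(out))
  attr(out, "layer") <- layer; attr(out, "punch") <- punch
  out
}

#' Displacement attenuation factor for a finite-thickness gel
#'
#' The factor `k(h -> infinity) / k(h)` in `(0, 1]` by which the same
#' traction produces smaller displacements on a layer of thickness `h`
#' than on a half-space. Both stiffnesses come from the numeric solver
#' (the thick-limit reference at `h/a = 50`), so discretization bias
#' cancels and the factor tends to 1 for thick gels. Independent of `E`.
#'
#' @param layer A [layer_spec()].
#' @param punch A [punch_spec()].
#' @param ... Passed to [effective_stiffness()].
#' @return Scalar factor in `(0, 1]`.
#' @export
attenuation_factor <- function(layer, punch = punch_spec(), ...) {
  key <- paste(signif(c(layer$nu, layer$h_um / punch$a_um,
                        layer$R_lateral_um / punch$a_um), 8),
               punch$loading, collapse = "|")
  cached <- .atten_cache[[key]]
  if (!is.null(cached)) return(cached)
  ref <- layer; ref$h_um <- 50 * punch$a_um; ref$R_lateral_um <- Inf
  k_ref <- effective_stiffness(ref, punch, ...)
  k_h <- effective_stiffness(layer, punch, ...)
  fac <- min(as.numeric(k_ref) / as.numeric(k_h), 1)
  .atten_cache[[key]] <- fac
  fac
}

.atten_cache <- new.env(parent = emptyenv())

#' Tidy a stiffness curve
#' @param x A `stiffness_curve`.
#' @param ... Unused.
#' @return The curve as a plain tibble.
#' @method tidy stiffness_curve
#' @export
tidy.stiffness_curve <- function(x, ...) {
  as_tibble(x)
}

#' One-row summary of a stiffness curve
#' @param x A `stiffness_curve`.
#' @param ... Unused.
#' @return Tibble with the half-space stiffness, the range of `k_ratio`,
#'   and the number of evaluated thicknesses.
#' @method glance stiffness_curve
#' @export
glance.stiffness_curve <- function(x, ...) {
  punch <- attr(x, "punch"); layer <- attr(x, "layer")
  tibble(k_halfspace = halfspace_stiffness(layer, punch),
         loading = punch$loading,
         max_k_ratio = max(x$k_ratio), min_k_ratio = min(x$k_ratio),
         n_thicknesses = nrow(x))
}
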