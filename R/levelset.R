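#' Energy and evolution configuration
#'
#' Collects the parameters of the localized level-set evolution. The data term
#' is either the localized uniform-modeling (UM, Chan--Vese-type) or the
#' localized mean-separation-style (MS) force; the MS variant divides the
#' interior/exterior misfit sums by the corresponding window areas. `mu`
#' weights the curvature regularization (default 0.1). The evolution is
#' performed in voxel units.
#'
#' @param model `"MS"` (area-normalized, default) or `"UM"`.
#' @param lambda1,lambda2 positive weights of the interior / exterior misfit
#'   terms. Ignored (overwritten) when a classifier regulates them.
#' @param mu curvature weight (>= 0).
#' @param heaviside_eps half-width (voxels) of the compactly supported
#'   C2-polynomial Heaviside/Dirac profile.
#' @param dt fixed explicit time step, or `NULL` (default) for CFL-style
#'   per-iteration normalization `cfl / max|speed|`.
#' @param cfl CFL factor used when `dt` is `NULL`.
#' @param window_rad local-window half-width in voxels (>= 1). Overwritten
#'   each regulation step when a classifier is supplied.
#' @param rd_nu,rd_dtau,rd_substeps reaction--diffusion stabilization:
#'   diffusion weight, sub-step size, and number of explicit sub-steps applied
#'   after each update. `rd_dtau * rd_nu` must satisfy the explicit stability
#'   bound (<= 1/6 on the unit-voxel 6-neighbor Laplacian).
#' @param rd_gain reaction gain: each step multiplies `phi` by `1 + rd_gain`
#'   before clamping, pulling the field toward the `+-phi_cap` wells so the
#'   transition layer keeps a steady width (~`sqrt(rd_dtau * rd_nu /
#'   rd_gain)` voxels) against the diffusive smearing; 0 disables.
#' @param max_iter maximum iterations (default 200).
#' @param conv_tol relative interior-volume-change tolerance; 0 disables the
#'   convergence stop (the loop always runs `max_iter` iterations).
#' @param conv_window iterations over which the volume change must stay below
#'   `conv_tol`.
#' @param query_period classifier query period in iterations.
#' @param phi_cap bound of the transition layer: after every step `phi` is
#'   clamped to `[-phi_cap, phi_cap]` (voxels). Keeps the diffusion-stabilized
#'   field from accumulating a large far-field that would erode the interior;
#'   0 disables clamping.
#' @return An object of class `energy_config`.
#' @export
energy_config <- function(model = c("MS", "UM"), lambda1 = 1, lambda2 = 1,
                          mu = 0.1, heaviside_eps = 1.5, dt = NULL, cfl = 0.45,
                          window_rad = 10, rd_nu = 1, rd_dtau = 0.1,
                          rd_substeps = 1, max_iter = 200, conv_tol = 0,
                          conv_window = 10, query_period = 5, phi_cap = 3,
                          rd_gain = 0.025) {
  model <- match.arg(model)
  if (lambda1 <= 0 || lambda2 <= 0) stop("lambda1 and lambda2 must be > 0")
  if (mu < 0) stop("mu must be >= 0")
  if (heaviside_eps <= 0) stop("heaviside_eps must be > 0")
  if (!is.null(dt) && dt <= 0) stop("dt must be > 0")
  if (window_rad < 1) stop("window_rad must be >= 1")
  if (rd_nu > 0 && rd_dtau * rd_nu > 1 / 6 + 1e-12) {
    stop("rd_dtau * rd_nu = ", rd_dtau * rd_nu,
         " exceeds the explicit diffusion stability bound 1/6")
  }
  structure(list(model = model, lambda1 = lambda1, lambda2 = lambda2, mu = mu,
                 heaviside_eps = heaviside_eps, dt = dt, cfl = cfl,
                 window_rad = as.integer(window_rad), rd_nu = rd_nu,
                 rd_dtau = rd_dtau, rd_substeps = as.integer(rd_substeps),
                 max_iter = as.integer(max_iter), conv_tol = conv_tol,
                 conv_window = as.integer(conv_window),
                 query_period = as.integer(query_period), phi_cap = phi_cap,
                 rd_gain = rd_gain),
            class = "energy_config")
}

#' Signed-distance ball initialization
#'
#' Builds the level-set field \eqn{\phi(x) = \|x - c\| - r} (voxel units):
#' an exact signed distance function whose zero level set is the sphere of
#' radius `radius` around `center`, negative inside.
#'
#' @param shape integer length-3 grid size.
#' @param center ball center in (possibly fractional) voxel coordinates.
#' @param radius ball radius in voxels (> 0).
#' @param spacing unused by the evolution (kept for interface symmetry).
#' @return A 3D numeric array `phi`.
#' @export
init_sdf_ball <- function(shape, center, radius, spacing = c(1, 1, 1)) {
  if (radius <= 0) stop("radius must be > 0")
  shape <- as.integer(shape)
  d <- .dist_to_point(shape, center) - radius
  if (!any(d < 0) && min(d) > sqrt(3)) {
    stop("ball does not intersect the grid")
  }
  d
}

#' Smoothed Heaviside and Dirac profiles
#'
#' Compactly supported C2 (quintic polynomial) regularization of the interior
#' indicator: `smoothed_heaviside` equals 1 for `phi <= -eps` (interior),
#' 0 for `phi >= eps`, and 0.5 at `phi = 0`; it is monotone in `phi`.
#' `smoothed_dirac` is the magnitude of its analytic derivative,
#' `-dH/dphi`: non-negative, symmetric, supported on `|phi| < eps`, and
#' integrating to 1.
#'
#' @param phi numeric vector or array of level-set values.
#' @param eps profile half-width (> 0), voxels.
#' @return Numeric object shaped like `phi`.
#' @export
smoothed_heaviside <- function(phi, eps) {
  if (eps <= 0) stop("eps must be > 0")
  out <- .heaviside_cpp(as.numeric(phi), eps)
  if (!is.null(dim(phi))) dim(out) <- dim(phi)
  out
}

#' @rdname smoothed_heaviside
#' @export
smoothed_dirac <- function(phi, eps) {
  if (eps <= 0) stop("eps must be > 0")
  out <- .dirac_cpp(as.numeric(phi), eps)
  if (!is.null(dim(phi))) dim(out) <- dim(phi)
  out
}

#' Local interior/exterior window statistics
#'
#' For the cubic window of half-width `rad` around one grid point (clipped at
#' the borders), computes the Heaviside-weighted interior mean `u_x`, the
#' exterior mean `v_x`, and the corresponding weight sums `A_in`, `A_out`
#' (`A_in + A_out` equals the window voxel count). If one side of the window
#' is (numerically) empty its mean is substituted by the full-window mean and
#' `degenerate` is flagged.
#'
#' @param volume [scalar_volume()] or 3D array.
#' @param phi level-set array, same shape.
#' @param center integer voxel coordinates (1-based) of the window center.
#' @param rad window half-width in voxels (>= 1).
#' @param eps Heaviside half-width.
#' @return List with `u_x`, `v_x`, `A_in`, `A_out`, `degenerate`.
#' @export
local_window_stats <- function(volume, phi, center, rad, eps = 1.5) {
  vol <- as_volume(volume)$data
  if (!all(dim(vol) == dim(phi))) stop("volume and phi shapes differ")
  if (rad < 1) stop("rad must be >= 1")
  center <- as.integer(round(center))
  d <- dim(vol)
  if (any(center < 1) || any(center > d)) stop("center outside the grid")
  xs <- max(1, center[1] - rad):min(d[1], center[1] + rad)
  ys <- max(1, center[2] - rad):min(d[2], center[2] + rad)
  zs <- max(1, center[3] - rad):min(d[3], center[3] + rad)
  wI <- vol[xs, ys, zs]
  H <- smoothed_heaviside(phi[xs, ys, zs], eps)
  A_in <- sum(H)
  A_out <- length(wI) - A_in
  full <- mean(wI)
  tol <- 1e-9
  degenerate <- FALSE
  if (A_in > tol) u <- sum(H * wI) / A_in else { u <- full; degenerate <- TRUE }
  if (A_out > tol) v <- sum((1 - H) * wI) / A_out else { v <- full; degenerate <- TRUE }
  list(u_x = u, v_x = v, A_in = A_in, A_out = A_out, degenerate = degenerate)
}

# shared point-wise implementation of the banded localized forces
.region_force_points <- function(volume, phi, band_points, rad, lambda1,
                                 lambda2, eps, model) {
  vol <- as_volume(volume)$data
  if (!all(dim(vol) == dim(phi))) stop("volume and phi shapes differ")
  band_points <- matrix(as.integer(round(band_points)), ncol = 3)
  d <- dim(vol)
  tol <- 1e-9
  vapply(seq_len(nrow(band_points)), function(k) {
    p <- band_points[k, ]
    dc <- smoothed_dirac(phi[p[1], p[2], p[3]], eps)
    if (dc == 0) return(0)
    xs <- max(1, p[1] - rad):min(d[1], p[1] + rad)
    ys <- max(1, p[2] - rad):min(d[2], p[2] + rad)
    zs <- max(1, p[3] - rad):min(d[3], p[3] + rad)
    wI <- vol[xs, ys, zs]
    wphi <- phi[xs, ys, zs]
    H <- smoothed_heaviside(wphi, eps)
    D <- smoothed_dirac(wphi, eps)
    N <- length(wI)
    A_in <- sum(H)
    A_out <- N - A_in
    full <- mean(wI)
    u <- if (A_in > tol) sum(H * wI) / A_in else full
    v <- if (A_out > tol) sum((1 - H) * wI) / A_out else full
    su <- sum(D * (wI - u)^2)
    sv <- sum(D * (wI - v)^2)
    if (model == "MS") {
      nin <- if (A_in > tol) A_in else N
      nout <- if (A_out > tol) A_out else N
      dc * (lambda1 * su / nin - lambda2 * sv / nout)
    } else {
      dc * (lambda1 * su - lambda2 * sv)
    }
  }, numeric(1))
}

#' Localized region forces at band points
#'
#' Per-point evolution speed of the banded localized energies. For a point
#' \eqn{x} on (or near) the zero level set, the speed is
#' \deqn{\delta(\phi(x)) \sum_{y \in B(x)} \delta(\phi(y))
#'   [\lambda_1 (I(y)-u_x)^2 / A_{in} - \lambda_2 (I(y)-v_x)^2 / A_{out}]}
#' for the MS model; `um_force` is the same sum without the area
#' normalization. Positive speed grows `phi` (shrinks the interior). The
#' curvature regularization is a separate term ([curvature_term()]).
#'
#' @inheritParams local_window_stats
#' @param band_points integer matrix (n x 3) of voxel coordinates on/near the
#'   zero level set.
#' @param lambda1,lambda2 energy weights.
#' @return Numeric vector of per-point speeds.
#' @export
ms_force <- function(volume, phi, band_points, rad, lambda1, lambda2,
                     eps = 1.5) {
  .region_force_points(volume, phi, band_points, rad, lambda1, lambda2, eps,
                       model = "MS")
}

#' @rdname ms_force
#' @export
um_force <- function(volume, phi, band_points, rad, lambda1, lambda2,
                     eps = 1.5) {
  .region_force_points(volume, phi, band_points, rad, lambda1, lambda2, eps,
                       model = "UM")
}

#' Curvature regularization term
#'
#' \eqn{\mu\,\delta(\phi)\,\mathrm{div}(\nabla\phi/|\nabla\phi|)} by central
#' differences with a gradient-magnitude floor of 1e-8, evaluated on the Dirac
#' band (zero elsewhere). On a ball SDF of radius r the mean curvature is
#' 2/r > 0, so this term shrinks the ball: the standard smoothing direction
#' under the update `phi <- phi + dt * speed`.
#'
#' @param phi level-set array.
#' @param mu curvature weight (>= 0).
#' @param eps Dirac half-width.
#' @return Array shaped like `phi`.
#' @export
curvature_term <- function(phi, mu, eps = 1.5) {
  if (mu < 0) stop("mu must be >= 0")
  .curvature_cpp(phi, dim(phi), mu, eps, 1e-8)
}

#' Reaction-diffusion stabilization of the level-set field
#'
#' Applies `substeps` explicit diffusion sub-steps
#' `phi <- phi + dtau * nu * laplacian(phi)` (zero-flux boundaries). Interleaved
#' into the evolution, this keeps the field smooth near the zero level set and
#' replaces periodic signed-distance reinitialization.
#'
#' @param phi level-set array.
#' @param nu diffusion weight (> 0).
#' @param substeps number of explicit sub-steps.
#' @param dtau sub-step size; `dtau * nu` must be <= 1/6 (explicit stability
#'   bound for the unit-voxel 6-neighbor Laplacian).
#' @return The diffused array.
#' @export
rd_stabilize <- function(phi, nu = 1, substeps = 1, dtau = 0.1) {
  if (nu <= 0) stop("nu must be > 0")
  if (dtau * nu > 1 / 6 + 1e-12) {
    stop("dtau * nu = ", dtau * nu, " exceeds the stability bound 1/6")
  }
  .diffuse_cpp(phi, dim(phi), nu, dtau, as.integer(substeps))
}
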