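#' Specification of a synthetic tumor phantom
#'
#' Describes one VOI-scale phantom: a tumor-like object (sphere, ellipsoid or
#' lobulated union of spheres) of hypo- or hyperdense intensity inside a
#' uniform liver-like background, with partial-volume edge blur, smooth
#' multiplicative texture heterogeneity inside the tumor, and additive
#' Gaussian noise. Intensities are in HU-like units (defaults: background 100,
#' tumor 60, a hypodense lesion).
#'
#' @param shape integer length-3 grid size in voxels (default 80x80x60, the
#'   VOI scale used throughout).
#' @param tumor_kind one of `"sphere"`, `"ellipsoid"`, `"lobulated"`.
#' @param equiv_radius tumor radius in voxels (>= 3); for non-spheres the
#'   radius of the volume-equivalent / parent sphere.
#' @param center voxel coordinates of the tumor center (default: grid center).
#' @param intensity_bg,intensity_fg background / tumor intensity levels.
#' @param texture_sigma amplitude of the smoothed multiplicative heterogeneity
#'   field applied inside the tumor (0 = homogeneous).
#' @param noise_sigma sd of additive Gaussian noise (0 = noiseless).
#' @param edge_blur_sigma Gaussian blur (voxels) applied to the two-level
#'   image before noise; models the partial-volume effect.
#' @param spacing voxel spacing in mm.
#' @param seed integer seed; identical specs give bit-identical phantoms.
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()], [generate_dataset()]
#' @export
phantom_spec <- function(shape = c(80, 80, 60), tumor_kind = "sphere",
                         equiv_radius = 15, center = NULL,
                         intensity_bg = 100, intensity_fg = 60,
                         texture_sigma = 0, noise_sigma = 0,
                         edge_blur_sigma = 1, spacing = c(1, 1, 1), seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 8)) stop("`shape` must be 3 integers >= 8")
  tumor_kind <- match.arg(tumor_kind, c("sphere", "ellipsoid", "lobulated"))
  if (is.null(center)) center <- (shape + 1) / 2
  center <- as.numeric(center)
  if (length(center) != 3) stop("`center` must have length 3")
  if (!is.finite(equiv_radius) || equiv_radius < 3) {
    stop("`equiv_radius` must be >= 3 voxels")
  }
  if (noise_sigma < 0 || texture_sigma < 0 || edge_blur_sigma < 0) {
    stop("noise_sigma, texture_sigma and edge_blur_sigma must be >= 0")
  }
  # extent of the object: lobulated children may stick out up to 1.6 r
  reach <- if (tumor_kind == "lobulated") 1.6 * equiv_radius else equiv_radius
  if (any(center - reach < 1 + 2) || any(center + reach > shape - 2)) {
    stop("tumor (radius ", equiv_radius, ") does not fit in shape ",
         paste(shape, collapse = "x"), " with a 2-voxel margin")
  }
  structure(list(shape = shape, tumor_kind = tumor_kind,
                 equiv_radius = equiv_radius, center = center,
                 intensity_bg = intensity_bg, intensity_fg = intensity_fg,
                 texture_sigma = texture_sigma, noise_sigma = noise_sigma,
                 edge_blur_sigma = edge_blur_sigma, spacing = as.numeric(spacing),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# voxel-center distance array to `center` (voxel units)
.dist_to_point <- function(shape, center, scale = c(1, 1, 1)) {
  dx <- (seq_len(shape[1]) - center[1]) / scale[1]
  dy <- (seq_len(shape[2]) - center[2]) / scale[2]
  dz <- (seq_len(shape[3]) - center[3]) / scale[3]
  sqrt(outer(outer(dx^2, dy^2, `+`), dz^2, `+`))
}

.phantom_mask <- function(spec) {
  s <- spec$shape
  r <- spec$equiv_radius
  if (spec$tumor_kind == "sphere") {
    return(.dist_to_point(s, spec$center) <= r)
  }
  if (spec$tumor_kind == "ellipsoid") {
    # axis ratios drawn from the spec seed, renormalized to preserve volume
    ratios <- with_seed(spec$seed, runif(3, 0.7, 1.4))
    ratios <- ratios / prod(ratios)^(1 / 3)
    return(.dist_to_point(s, spec$center, scale = ratios) <= r)
  }
  # lobulated: parent sphere plus 2-4 children centered on the parent surface
  with_seed(spec$seed + 1L, {
    nchild <- sample(2:4, 1)
    mask <- .dist_to_point(s, spec$center) <= r
    for (i in seq_len(nchild)) {
      u <- rnorm(3)
      u <- u / sqrt(sum(u^2))
      rc <- runif(1, 0.3, 0.6) * r
      cc <- spec$center + u * r
      mask <- mask | (.dist_to_point(s, cc) <= rc)
    }
    mask
  })
}

#' Generate one synthetic tumor phantom
#'
#' Builds the noiseless tumor support as the ground-truth mask, then the
#' intensity volume: two-level image (background / tumor), Gaussian edge blur,
#' multiplicative texture heterogeneity inside the tumor (white noise smoothed
#' at a 4-voxel scale, normalized to unit variance, scaled by
#' `texture_sigma`), and finally additive Gaussian noise. The ground-truth
#' mask is independent of noise and texture settings, and identical specs
#' yield bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `volume` (a [scalar_volume()]), `gt_mask`
#'   (logical 3D array) and `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(shape = c(32, 32, 24), equiv_radius = 8))
#' sum(ph$gt_mask)
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("`spec` must be a phantom_spec")
  s <- spec$shape
  mask <- .phantom_mask(spec)
  vol <- array(spec$intensity_bg, s)
  vol[mask] <- spec$intensity_fg
  if (spec$edge_blur_sigma > 0) {
    vol <- .gaussian_blur3d_cpp(vol, s, rep(spec$edge_blur_sigma, 3))
  }
  with_seed(spec$seed, {
    if (spec$texture_sigma > 0) {
      tex <- array(rnorm(prod(s)), s)
      tex <- .gaussian_blur3d_cpp(tex, s, c(4, 4, 4))
      tex <- tex / sd(tex)
      vol[mask] <- vol[mask] * (1 + spec$texture_sigma * tex[mask])
    }
    if (spec$noise_sigma > 0) {
      vol <- vol + array(rnorm(prod(s), sd = spec$noise_sigma), s)
    }
  })
  dim(vol) <- s
  list(volume = scalar_volume(vol, spacing = spec$spacing),
       gt_mask = mask, spec = spec)
}

#' Generate a reproducible set of random phantoms
#'
#' Draws `n` phantom specifications with parameters uniform in the given
#' ranges and generates each phantom. A range may be a single value (held
#' fixed) or a length-2 `c(lo, hi)` interval.
#'
#' @param n number of phantoms (>= 1).
#' @param ranges named list of ranges for `equiv_radius`, `contrast`
#'   (`intensity_bg - intensity_fg`), `noise_sigma`, `texture_sigma` and
#'   `edge_blur_sigma`; missing entries use the [phantom_spec()] defaults.
#' @param shape,tumor_kind,intensity_bg passed through to every spec.
#' @param seed integer master seed; per-phantom seeds are derived from it.
#' @return A list of `n` results of [generate_phantom()].
#' @export
generate_dataset <- function(n, ranges = list(), shape = c(80, 80, 60),
                             tumor_kind = "sphere", intensity_bg = 100,
                             seed = 1L) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) stop("`n` must be >= 1")
  n <- as.integer(n)
  defaults <- list(equiv_radius = 15, contrast = 40, noise_sigma = 0,
                   texture_sigma = 0, edge_blur_sigma = 1)
  for (nm in names(ranges)) {
    if (!nm %in% names(defaults)) stop("unknown range: ", nm)
    r <- ranges[[nm]]
    if (!length(r) %in% c(1, 2) || any(!is.finite(r))) {
      stop("range `", nm, "` must be 1 or 2 finite numbers")
    }
    if (length(r) == 2 && r[2] < r[1]) stop("range `", nm, "` is empty")
  }
  draw <- function(nm) {
    r <- if (nm %in% names(ranges)) ranges[[nm]] else defaults[[nm]]
    if (length(r) == 1) rep(r, n) else runif(n, r[1], r[2])
  }
  with_seed(seed, {
    rad <- draw("equiv_radius")
    con <- draw("contrast")
    noi <- draw("noise_sigma")
    tex <- draw("texture_sigma")
    blu <- draw("edge_blur_sigma")
    seeds <- sample.int(.Machine$integer.max, n)
  })
  lapply(seq_len(n), function(i) {
    generate_phantom(phantom_spec(
      shape = shape, tumor_kind = tumor_kind, equiv_radius = rad[i],
      intensity_bg = intensity_bg, intensity_fg = intensity_bg - con[i],
      texture_sigma = tex[i], noise_sigma = noi[i], edge_blur_sigma = blu[i],
      seed = seeds[i]))
  })
}
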