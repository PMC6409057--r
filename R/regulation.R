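#' Contour-position probabilities
#'
#' Probability triple for the position of the evolving contour relative to
#' the object boundary: `p1` inside, `p2` near the boundary, `p3` outside.
#' Must lie on the probability simplex (sum 1 within 1e-6).
#'
#' @param p1,p2,p3 probabilities in `[0, 1]`.
#' @return An object of class `position_probs`.
#' @examples
#' position_probs(0.78, 0.14, 0.08)
#' @export
position_probs <- function(p1, p2, p3) {
  p <- c(p1, p2, p3)
  if (any(!is.finite(p)) || any(p < -1e-9) || any(p > 1 + 1e-9)) {
    stop("probabilities must be in [0, 1]")
  }
  if (abs(sum(p) - 1) > 1e-6) {
    stop("probabilities must sum to 1 (got ", format(sum(p)), ")")
  }
  structure(list(p1 = p1, p2 = p2, p3 = p3), class = "position_probs")
}

as_position_probs <- function(p) {
  if (inherits(p, "position_probs")) return(p)
  if (is.numeric(p) && length(p) == 3) return(position_probs(p[1], p[2], p[3]))
  stop("expected a position_probs or a numeric triple")
}

#' Regulation configuration
#'
#' Constants of the dynamic window rule and the initialization search. When
#' the near-boundary probability satisfies `p2_low < p2 < p2_high` the window
#' radius is `rad_near` (8 voxels); otherwise it is driven by `|p1 - p3|`
#' under one of two readings of the printed rule (see [regulate_window()]).
#'
#' @param window_rule `"additive"` (`round(5 + 5 |p1 - p3|)`, the default) or
#'   `"literal"` (`round(25 |p1 - p3|)` clamped to `[rad_min, rad_max]`).
#' @param rad_near radius used in the near-boundary band (default 8).
#' @param rad_min,rad_max clamp for the literal rule.
#' @param p2_low,p2_high near-boundary band (defaults 0.4, 0.6).
#' @param candidate_radii radii tried by [select_initialization()]
#'   (default 6, 10, 20, 30, 40).
#' @param sigma_frac width (as a fraction of the object's equivalent radius)
#'   of the geometric oracle's near-boundary response.
#' @return An object of class `regulation_config`.
#' @export
regulation_config <- function(window_rule = c("additive", "literal"),
                              rad_near = 8, rad_min = 5, rad_max = 25,
                              p2_low = 0.4, p2_high = 0.6,
                              candidate_radii = c(6, 10, 20, 30, 40),
                              sigma_frac = 0.25) {
  window_rule <- match.arg(window_rule)
  if (!(rad_min <= rad_near && rad_near <= rad_max)) {
    stop("need rad_min <= rad_near <= rad_max")
  }
  if (!(0 <= p2_low && p2_low < p2_high && p2_high <= 1)) {
    stop("need 0 <= p2_low < p2_high <= 1")
  }
  structure(list(window_rule = window_rule, rad_near = as.integer(rad_near),
                 rad_min = as.integer(rad_min), rad_max = as.integer(rad_max),
                 p2_low = p2_low, p2_high = p2_high,
                 candidate_radii = as.numeric(candidate_radii),
                 sigma_frac = sigma_frac),
            class = "regulation_config")
}

#' Dynamic regulation of the energy weights
#'
#' Maps contour-position probabilities to the energy weights:
#' \deqn{\lambda_1 = \exp\frac{1+p_1+p_2}{1+p_2+p_3}, \qquad
#'       \lambda_2 = \exp\frac{1+p_2+p_3}{1+p_1+p_2}.}
#' Both lie in \eqn{[e^{1/2}, e^2]}; they are equal (to \eqn{e}) on the
#' symmetric point, swap under `p1 <-> p3`, and `p1 > p3` implies
#' `lambda1 > lambda2` (contraction tendency) and vice versa.
#'
#' @param p a [position_probs()] or numeric triple.
#' @return Named numeric vector `c(lambda1, lambda2)`.
#' @examples
#' regulate_lambdas(position_probs(1/3, 1/3, 1/3)) # both equal e
#' @export
regulate_lambdas <- function(p) {
  p <- as_position_probs(p)
  a <- 1 + p$p1 + p$p2
  b <- 1 + p$p2 + p$p3
  c(lambda1 = exp(a / b), lambda2 = exp(b / a))
}

#' Dynamic regulation of the local-window radius
#'
#' Near the boundary (`p2_low < p2 < p2_high`) the radius is `rad_near`
#' (8 voxels). Otherwise the printed rule reads "5 x 5 x (p1 - p3)", which is
#' ambiguous; two interpretations are provided. `"literal"`:
#' `round(25 |p1 - p3|)` clamped to `[rad_min, rad_max]` — the product read
#' at face value, clamped because it degenerates to 0 when `p1` is near `p3`.
#' `"additive"`: `round(5 + 5 |p1 - p3|)`, range `[5, 10]`. Both grow the
#' window as the contour gets farther from the boundary.
#'
#' @param p a [position_probs()] or numeric triple.
#' @param cfg a [regulation_config()].
#' @return Integer window radius in voxels.
#' @examples
#' regulate_window(position_probs(0.3, 0.5, 0.2)) # near-boundary branch: 8
#' @export
regulate_window <- function(p, cfg = regulation_config()) {
  p <- as_position_probs(p)
  if (cfg$p2_low < p$p2 && p$p2 < cfg$p2_high) {
    return(cfg$rad_near)
  }
  gap <- abs(p$p1 - p$p3)
  if (cfg$window_rule == "literal") {
    as.integer(min(cfg$rad_max, max(cfg$rad_min, round(25 * gap))))
  } else {
    as.integer(round(5 + 5 * gap))
  }
}

#' Geometric oracle for contour-position probabilities
#'
#' Deterministic stand-in for the trained classifier: lets the regulation and
#' the evolution be exercised without any training. The contour's normalized
#' mean signed distance to the ground-truth boundary,
#' `s = mean(signed distance of zero-level-set voxels) / equivalent radius`
#' (negative inside), drives a Gaussian near-boundary response
#' `p2 = exp(-(s / sigma_frac)^2)`; the remaining mass goes to `p1` if
#' `s < 0`, to `p3` if `s > 0`, and is split evenly at `s = 0`.
#'
#' @param phi level-set array (zero level set must be non-empty).
#' @param gt_mask non-empty ground-truth mask.
#' @param sigma_frac response width as a fraction of the equivalent radius.
#' @param sdist optional precomputed signed-distance field of `gt_mask`.
#' @return A [position_probs()].
#' @export
oracle_position_probs <- function(phi, gt_mask, sigma_frac = 0.25,
                                  sdist = NULL) {
  gt_mask <- as_mask(gt_mask)
  if (!any(gt_mask)) stop("gt_mask is empty")
  contour <- .contour_voxels_cpp(phi, dim(phi))
  if (!any(contour)) stop("zero level set is empty")
  if (is.null(sdist)) sdist <- signed_distance_to_boundary(gt_mask)
  s <- mean(sdist[contour]) / equiv_radius(gt_mask)
  p2 <- exp(-(s / sigma_frac)^2)
  rem <- 1 - p2
  if (s < 0) {
    p1 <- rem; p3 <- 0
  } else if (s > 0) {
    p1 <- 0; p3 <- rem
  } else {
    p1 <- rem / 2; p3 <- rem / 2
  }
  position_probs(p1, p2, p3)
}

#' Oracle classifier closure
#'
#' Wraps [oracle_position_probs()] with a precomputed signed-distance field
#' so it satisfies the classifier contract `(volume, phi) -> position_probs`
#' expected by [evolve()] and [select_initialization()].
#'
#' @inheritParams oracle_position_probs
#' @return A function `(volume, phi) -> position_probs`.
#' @export
oracle_classifier <- function(gt_mask, sigma_frac = 0.25) {
  gt_mask <- as_mask(gt_mask)
  sdist <- signed_distance_to_boundary(gt_mask)
  force(sigma_frac)
  function(volume, phi) {
    oracle_position_probs(phi, gt_mask, sigma_frac, sdist = sdist)
  }
}

#' Automatic initialization by maximal near-boundary probability
#'
#' Builds a signed-distance ball per candidate radius at `center`, queries the
#' classifier on each, and returns the candidate with the largest
#' near-boundary probability `p2`; ties go to the smaller radius.
#'
#' @param volume [scalar_volume()] or 3D array.
#' @param center ball center in voxel coordinates (default: grid center).
#' @param candidate_radii radii to try (voxels).
#' @param classifier function `(volume, phi) -> position_probs`.
#' @return List with `phi` (the selected SDF), `radius`, and `candidates`
#'   (data frame of radius and probabilities for every candidate).
#' @export
select_initialization <- function(volume, center = NULL,
                                  candidate_radii = c(6, 10, 20, 30, 40),
                                  classifier) {
  vol <- as_volume(volume)
  d <- dim(vol$data)
  if (is.null(center)) center <- (d + 1) / 2
  if (length(candidate_radii) < 1) stop("need at least one candidate radius")
  radii <- sort(as.numeric(candidate_radii))
  rows <- lapply(radii, function(r) {
    phi <- init_sdf_ball(d, center, r)
    # the candidate must actually produce a contour within the grid
    if (!any(phi < 0) || !any(phi >= 0)) return(NULL)
    p <- classifier(vol, phi)
    data.frame(radius = r, p1 = p$p1, p2 = p$p2, p3 = p$p3)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0) {
    stop("no candidate initialization intersects the grid")
  }
  best <- rows$radius[which.max(rows$p2)] # ties: first = smallest radius
  list(phi = init_sdf_ball(d, center, best), radius = best, candidates = rows)
}
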