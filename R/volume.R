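#' 3D scalar volume with voxel spacing
#'
#' Lightweight container for an intensity volume \eqn{I} over a 3D grid:
#' a numeric array plus physical voxel spacing (mm) and world origin (mm).
#' The level-set machinery operates in voxel units; spacing is used by the
#' surface-distance metrics and preserved through NIfTI I/O.
#'
#' @param data 3D numeric array; all values must be finite.
#' @param spacing positive numeric length-3, voxel spacing in mm.
#' @param origin numeric length-3, world coordinate of voxel (1,1,1) in mm.
#' @return An object of class `scalar_volume` with elements `data`, `spacing`,
#'   `origin`.
#' @examples
#' v <- scalar_volume(array(0, c(8, 8, 4)), spacing = c(0.7, 0.7, 2.5))
#' dim(v$data)
#' @export
scalar_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3) {
    stop("`data` must be a 3D array")
  }
  if (!all(is.finite(data))) stop("volume contains non-finite values")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 positive numbers")
  }
  origin <- as.numeric(origin)
  if (length(origin) != 3) stop("`origin` must have length 3")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat("<scalar_volume> ", paste(dim(x$data), collapse = "x"),
      " voxels, spacing ", paste(format(x$spacing), collapse = "x"),
      " mm, range [", format(min(x$data)), ", ", format(max(x$data)), "]\n",
      sep = "")
  invisible(x)
}

as_volume <- function(x) {
  if (inherits(x, "scalar_volume")) return(x)
  if (is.array(x) && length(dim(x)) == 3) return(scalar_volume(x))
  stop("expected a scalar_volume or a 3D array")
}

# logical 3D mask from anything array-like
as_mask <- function(x) {
  if (inherits(x, "scalar_volume")) x <- x$data
  if (!is.array(x) || length(dim(x)) != 3) stop("mask must be a 3D array")
  m <- x != 0
  dim(m) <- dim(x)
  m
}

# equivalent sphere radius (voxels) of a mask
equiv_radius <- function(mask) {
  n <- sum(mask)
  if (n == 0) stop("mask is empty")
  (3 * n / (4 * pi))^(1 / 3)
}

# signed voxel-unit distance to the mask boundary: negative inside.
signed_distance_to_boundary <- function(mask, spacing = c(1, 1, 1)) {
  mask <- as_mask(mask)
  d <- dim(mask)
  d_to_mask <- .edt_cpp(as.logical(mask), d, as.numeric(spacing))
  d_to_bg <- .edt_cpp(as.logical(!mask), d, as.numeric(spacing))
  sd <- d_to_mask - d_to_bg
  dim(sd) <- d
  sd
}
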