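#' Volumetric overlap metrics
#'
#' DICE similarity (fraction), volumetric overlap error VOE (percent,
#' `(1 - |S intersect G| / |S union G|) * 100`) and relative volume
#' difference RVD (percent, signed, `(|S| - |G|) / |G| * 100`; negative means
#' undersegmentation). An empty segmentation gives `(0, 100, -100)`; an empty
#' ground truth is an error.
#'
#' @param seg,gt binary 3D masks of equal shape.
#' @return List with `dice`, `voe`, `rvd`, `n_seg`, `n_gt`.
#' @examples
#' g <- array(FALSE, c(4, 4, 4)); g[1:3, 1:2, 1] <- TRUE
#' overlap_metrics(g, g)
#' @export
overlap_metrics <- function(seg, gt) {
  seg <- as_mask(seg)
  gt <- as_mask(gt)
  if (!all(dim(seg) == dim(gt))) stop("seg and gt shapes differ")
  ng <- sum(gt)
  if (ng == 0) stop("ground-truth mask is empty")
  ns <- sum(seg)
  inter <- sum(seg & gt)
  union <- ns + ng - inter
  list(dice = 2 * inter / (ns + ng),
       voe = (1 - inter / union) * 100,
       rvd = (ns - ng) / ng * 100,
       n_seg = ns, n_gt = ng)
}

#' Symmetric surface-distance metrics
#'
#' Border voxels (mask voxels with a 6-connected background neighbor) are
#' extracted from both masks; the directed distances from every border voxel
#' of one mask to the nearest border voxel of the other (exact Euclidean, in
#' physical units per `spacing`) are pooled over both directions. ASD is the
#' mean and RMSD the root mean square of the pooled set, so RMSD >= ASD and
#' the result is symmetric in its arguments.
#'
#' @param seg,gt non-empty binary masks of equal shape.
#' @param spacing voxel spacing in mm.
#' @return List with `asd`, `rmsd` (mm).
#' @export
surface_metrics <- function(seg, gt, spacing = c(1, 1, 1)) {
  seg <- as_mask(seg)
  gt <- as_mask(gt)
  if (!all(dim(seg) == dim(gt))) stop("seg and gt shapes differ")
  if (!any(seg) || !any(gt)) stop("surface metrics need non-empty masks")
  d <- dim(seg)
  spacing <- as.numeric(spacing)
  bs <- .border_voxels_cpp(as.logical(seg), d)
  bg <- .border_voxels_cpp(as.logical(gt), d)
  dist_to_bg <- .edt_cpp(bg, d, spacing)
  dist_to_bs <- .edt_cpp(bs, d, spacing)
  pooled <- c(dist_to_bg[bs], dist_to_bs[bg])
  list(asd = mean(pooled), rmsd = sqrt(mean(pooled^2)))
}

#' Full metric report
#'
#' One-row data frame with the five evaluation metrics: DICE (fraction), VOE
#' and RVD (percent), ASD and RMSD (mm), plus the voxel counts. Surface
#' metrics are `NA` when the segmentation is empty.
#'
#' @inheritParams surface_metrics
#' @return A one-row `data.frame`.
#' @export
metric_report <- function(seg, gt, spacing = c(1, 1, 1)) {
  ov <- overlap_metrics(seg, gt)
  sm <- if (ov$n_seg > 0) surface_metrics(seg, gt, spacing) else
    list(asd = NA_real_, rmsd = NA_real_)
  data.frame(dice = ov$dice, voe = ov$voe, rvd = ov$rvd,
             asd = sm$asd, rmsd = sm$rmsd,
             n_seg_voxels = ov$n_seg, n_gt_voxels = ov$n_gt)
}

#' Aggregate metric reports as mean and standard deviation
#'
#' @param reports a data frame of stacked [metric_report()] rows, or a list
#'   of them.
#' @return Data frame with one row per metric: `mean`, `sd`, `n`.
#' @export
aggregate_metrics <- function(reports) {
  if (is.list(reports) && !is.data.frame(reports)) {
    reports <- do.call(rbind, reports)
  }
  cols <- c("dice", "voe", "rvd", "asd", "rmsd")
  data.frame(metric = cols,
             mean = vapply(cols, function(cl) mean(reports[[cl]], na.rm = TRUE),
                           numeric(1)),
             sd = vapply(cols, function(cl) sd(reports[[cl]], na.rm = TRUE),
                         numeric(1)),
             n = nrow(reports), row.names = NULL)
}
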