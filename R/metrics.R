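#' Metric configuration
#'
#' Controls [evaluate_pair()]. The surface Dice tolerance defaults to "one
#' voxel", resolved under anisotropic spacing as the maximum spacing
#' component so that a one-voxel shift along any axis stays within tolerance;
#' an explicit tolerance in mm can be given instead.
#'
#' @param surface_tolerance_mode `"one_voxel"` or `"explicit_mm"`.
#' @param surface_tolerance_mm positive tolerance in mm (required when
#'   explicit).
#' @param levels character vector of level names to evaluate, or `"all"`.
#' @param include_union also evaluate all levels pooled as one binary mask.
#' @return An object of class `metric_config`.
#' @export
metric_config <- function(surface_tolerance_mode = c("one_voxel",
                                                     "explicit_mm"),
                          surface_tolerance_mm = NULL,
                          levels = "all", include_union = TRUE) {
  mode <- match.arg(surface_tolerance_mode)
  if (mode == "explicit_mm") {
    if (is.null(surface_tolerance_mm) || surface_tolerance_mm <= 0)
      stop("surface_tolerance_mm must be a positive distance (mm)")
  }
  structure(list(surface_tolerance_mode = mode,
                 surface_tolerance_mm = surface_tolerance_mm,
                 levels = levels, include_union = isTRUE(include_union)),
            class = "metric_config")
}

resolve_tolerance <- function(config, spacing) {
  if (config$surface_tolerance_mode == "one_voxel") max(spacing)
  else config$surface_tolerance_mm
}

as_mask <- function(x) {
  if (inherits(x, "label_volume")) x <- x$array
  if (is.null(dim(x)) || length(dim(x)) != 3L)
    stop("mask must be a 3D array")
  array(x != 0, dim = dim(x))
}

check_same_grid <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("masks must be on identical grids: ",
         paste(dim(a), collapse = "x"), " vs ", paste(dim(b), collapse = "x"))
}

#' Volumetric Dice score
#'
#' `2|A n B| / (|A| + |B|)` over voxel sets. If both masks are empty the
#' score is undefined and `NA` is returned (excluded from means); an empty
#' mask against a non-empty one scores 0.
#'
#' @param a,b binary masks (3D logical/0-1 arrays or binary
#'   [label_volume()]s) on the same grid.
#' @return Dice fraction in \[0, 1\], or `NA` if both masks are empty.
#' @export
volumetric_dice <- function(a, b) {
  a <- as_mask(a); b <- as_mask(b)
  check_same_grid(a, b)
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) return(NA_real_)
  2 * sum(a & b) / (na + nb)
}

# Boundary voxels: foreground voxels with a 6-neighbour background voxel
# (the volume border counts as background).
boundary_mask <- function(mask) {
  interior <- mask
  for (axis in 1:3)
    interior <- interior & shift_axis(mask, axis, 1L) &
      shift_axis(mask, axis, -1L)
  mask & !interior
}

boundary_points <- function(mask) {
  idx <- which(boundary_mask(mask))
  if (!length(idx)) return(matrix(integer(0), ncol = 3L))
  arrayInd(idx, dim(mask))
}

# For each row of index matrix P, the minimum physical distance to the rows
# of Q. Distances are built from per-axis index differences (exact integers)
# scaled by spacing, which avoids the catastrophic cancellation a Gram-matrix
# expansion would introduce for distances right at the tolerance.
min_point_dists <- function(P, Q, spacing) {
  n <- nrow(P)
  if (n == 0L) return(numeric(0))
  if (nrow(Q) == 0L) return(rep(Inf, n))
  out <- numeric(n)
  chunk <- max(1L, as.integer(2e6 / nrow(Q)))
  for (start in seq.int(1L, n, by = chunk)) {
    ii <- start:min(start + chunk - 1L, n)
    d2 <- (outer(P[ii, 1], Q[, 1], `-`) * spacing[1])^2 +
      (outer(P[ii, 2], Q[, 2], `-`) * spacing[2])^2 +
      (outer(P[ii, 3], Q[, 3], `-`) * spacing[3])^2
    out[ii] <- sqrt(apply(d2, 1L, min))
  }
  out
}

#' Surface Dice score at a tolerance
#'
#' Fraction of the two masks' boundary surfaces lying within `tolerance_mm`
#' of the other mask's boundary, symmetrised as
#' `(matched_a + matched_b) / (surface_a + surface_b)`. Surfaces are
#' represented by boundary voxel centres and distances are physical (via
#' `spacing`); this voxel-centre approximation is the comparability caveat
#' against surfel-based implementations.
#'
#' @inheritParams volumetric_dice
#' @param tolerance_mm positive tolerance in mm.
#' @param spacing voxel spacing in mm (length 3).
#' @return Fraction in \[0, 1\], or `NA` if both masks are empty.
#' @export
surface_dice <- function(a, b, tolerance_mm, spacing) {
  a <- as_mask(a); b <- as_mask(b)
  check_same_grid(a, b)
  stopifnot(tolerance_mm > 0)
  if (!any(a) && !any(b)) return(NA_real_)
  Pa <- boundary_points(a)
  Pb <- boundary_points(b)
  matched_a <- sum(min_point_dists(Pa, Pb, spacing) <= tolerance_mm)
  matched_b <- sum(min_point_dists(Pb, Pa, spacing) <= tolerance_mm)
  (matched_a + matched_b) / (nrow(Pa) + nrow(Pb))
}

#' Maximum Hausdorff distance
#'
#' The larger of the two directed maximum surface distances between the
#' masks, in mm (voxel-centre boundary representation). Symmetric in its
#' arguments. `NA` if either mask is empty (undefined).
#'
#' @inheritParams surface_dice
#' @return Distance in mm, or `NA` if either mask is empty.
#' @export
hausdorff_max <- function(a, b, spacing) {
  a <- as_mask(a); b <- as_mask(b)
  check_same_grid(a, b)
  if (!any(a) || !any(b)) return(NA_real_)
  Pa <- boundary_points(a)
  Pb <- boundary_points(b)
  max(max(min_point_dists(Pa, Pb, spacing)),
      max(min_point_dists(Pb, Pa, spacing)))
}

#' Evaluate a candidate segmentation against a reference
#'
#' Computes volumetric Dice, surface Dice and maximum Hausdorff distance per
#' level, for the union of all evaluated levels pooled as one binary mask,
#' and as the case mean over defined per-level values. Undefined values
#' (empty-vs-empty Dice, Hausdorff with an empty mask) are reported as `NA`
#' and excluded from the case mean.
#'
#' @param candidate,reference [label_volume()]s on the same grid.
#' @param taxonomy a [level_taxonomy()].
#' @param config a [metric_config()].
#' @return A `metrics_report`: list with `per_level` (data.frame), `union`
#'   (named numeric), `case_mean` (named numeric), and `tolerance_mm`.
#' @export
evaluate_pair <- function(candidate, reference, taxonomy,
                          config = metric_config()) {
  validate_labels(candidate, taxonomy)
  validate_labels(reference, taxonomy)
  check_same_grid(candidate$array, reference$array)
  if (!isTRUE(all.equal(candidate$spacing, reference$spacing)))
    stop("candidate and reference must share voxel spacing")
  spacing <- reference$spacing
  tol <- resolve_tolerance(config, spacing)
  lev <- if (identical(config$levels, "all")) taxonomy$entries$name
         else config$levels
  labels <- taxonomy_labels(taxonomy, lev)

  one <- function(ma, mb) c(
    volumetric_dice = volumetric_dice(ma, mb),
    surface_dice = surface_dice(ma, mb, tol, spacing),
    hausdorff_max_mm = hausdorff_max(ma, mb, spacing)
  )
  per <- t(vapply(labels, function(l)
    one(candidate$array == l, reference$array == l), numeric(3)))
  per_level <- data.frame(level = lev, per, row.names = NULL)

  union <- if (config$include_union) {
    one(array(candidate$array %in% labels, dim(candidate$array)),
        array(reference$array %in% labels, dim(reference$array)))
  } else NULL

  case_mean <- colMeans(per, na.rm = TRUE)
  structure(list(per_level = per_level, union = union,
                 case_mean = case_mean, tolerance_mm = tol),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Metrics report (surface tolerance ", signif(x$tolerance_mm, 4),
      " mm)\n", sep = "")
  cat("Case mean over defined levels:\n")
  print(round(x$case_mean, 4))
  if (!is.null(x$union)) {
    cat("Union of levels:\n")
    print(round(x$union, 4))
  }
  cat("Per level:\n")
  pl <- x$per_level
  pl[-1] <- lapply(pl[-1], round, 4)
  print(pl, row.names = FALSE)
  invisible(x)
}

#' Write a metrics report as CSV
#'
#' One row per level plus a `__union__` row; columns `case`, `level`,
#' `volumetric_dice`, `surface_dice`, `hausdorff_max_mm`.
#'
#' @param report a `metrics_report` from [evaluate_pair()].
#' @param path output CSV path.
#' @param case case identifier written in the `case` column.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(report, path, case = "case") {
  df <- cbind(case = case, report$per_level)
  if (!is.null(report$union)) {
    u <- as.list(report$union)
    df <- rbind(df, data.frame(case = case, level = "__union__",
                               volumetric_dice = u$volumetric_dice,
                               surface_dice = u$surface_dice,
                               hausdorff_max_mm = u$hausdorff_max_mm))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
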