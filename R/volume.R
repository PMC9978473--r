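#' Label volume container
#'
#' A `label_volume` holds a 3D integer label map together with its voxel
#' spacing in mm and two axis conventions: `slice_axis`, the array axis that
#' indexes CT slices (cranial to caudal with increasing index), and `lr_axis`,
#' the patient left-right axis. Axial CT stacks stored the usual way have the
#' slice axis last and the left-right axis first, which are the defaults.
#' Voxel indices follow R's 1-based array convention throughout; physical
#' distances are always derived via `spacing`.
#'
#' @param array 3D integer array of label values.
#' @param spacing numeric length-3, voxel size in mm per array axis; all
#'   components strictly positive.
#' @param slice_axis integer in 1:3, axis indexing CT slices (default 3).
#' @param lr_axis integer in 1:3, patient left-right axis (default 1); must
#'   differ from `slice_axis`.
#' @param taxonomy optional [level_taxonomy()]; when supplied, all values are
#'   validated against `{background} U labels`.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(array, spacing, slice_axis = 3L, lr_axis = 1L,
                         taxonomy = NULL) {
  if (length(dim(array)) != 3L)
    stop("label volume must be a 3D array, got ",
         length(dim(array)), " dimensions")
  if (any(array != round(array)))
    stop("label volume must be integer-valued")
  storage.mode(array) <- "integer"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive values (mm)")
  slice_axis <- as.integer(slice_axis); lr_axis <- as.integer(lr_axis)
  if (!slice_axis %in% 1:3 || !lr_axis %in% 1:3)
    stop("slice_axis and lr_axis must be in 1:3")
  if (slice_axis == lr_axis) stop("slice_axis and lr_axis must differ")
  vol <- structure(
    list(array = array, spacing = spacing,
         slice_axis = slice_axis, lr_axis = lr_axis),
    class = "label_volume"
  )
  if (!is.null(taxonomy)) validate_labels(vol, taxonomy)
  vol
}

#' Validate a label volume against a taxonomy
#'
#' @param volume a `label_volume`.
#' @param taxonomy a `level_taxonomy`.
#' @return The volume, invisibly; errors listing offending values otherwise.
#' @export
validate_labels <- function(volume, taxonomy) {
  allowed <- c(taxonomy$background_value, taxonomy$entries$label_value)
  present <- sort(unique(as.vector(volume$array)))
  bad <- setdiff(present, allowed)
  if (length(bad))
    stop("label volume contains value(s) not in the taxonomy: ",
         paste(bad, collapse = ", "))
  invisible(volume)
}

#' Intensity (CT-like) volume container
#'
#' @param array 3D numeric array.
#' @param spacing numeric length-3, strictly positive (mm).
#' @param slice_axis,lr_axis axis conventions as in [label_volume()].
#' @return An object of class `intensity_volume`.
#' @export
intensity_volume <- function(array, spacing, slice_axis = 3L, lr_axis = 1L) {
  if (length(dim(array)) != 3L)
    stop("intensity volume must be a 3D array")
  storage.mode(array) <- "double"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive values (mm)")
  slice_axis <- as.integer(slice_axis); lr_axis <- as.integer(lr_axis)
  if (slice_axis == lr_axis) stop("slice_axis and lr_axis must differ")
  structure(
    list(array = array, spacing = spacing,
         slice_axis = slice_axis, lr_axis = lr_axis),
    class = "intensity_volume"
  )
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$array)
  vals <- sort(unique(as.vector(x$array)))
  cat("Label volume ", paste(d, collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  cat("  slice axis:", x$slice_axis, " left-right axis:", x$lr_axis, "\n")
  cat("  values present:", paste(utils::head(vals, 25), collapse = ", "),
      if (length(vals) > 25) "...", "\n")
  invisible(x)
}

#' @export
print.intensity_volume <- function(x, ...) {
  d <- dim(x$array)
  cat("Intensity volume ", paste(d, collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm, range [", signif(min(x$array), 4), ", ",
      signif(max(x$array), 4), "]\n", sep = "")
  invisible(x)
}

# Per-slice non-background voxel counts along the slice axis.
slice_counts <- function(volume, background = 0L) {
  fg <- volume$array != background
  apply(fg, volume$slice_axis, sum)
}

# Extract / replace slice k (index along slice_axis) of a 3D array.
get_slice <- function(arr, axis, k) {
  switch(axis, arr[k, , ], arr[, k, ], arr[, , k])
}
set_slice <- function(arr, axis, k, value) {
  switch(axis,
         { arr[k, , ] <- value; arr },
         { arr[, k, ] <- value; arr },
         { arr[, , k] <- value; arr })
}
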