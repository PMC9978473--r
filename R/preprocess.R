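#' Foreground-masking parameters
#'
#' Parameters of the Otsu-based CT foreground masking pipeline, with the
#' published defaults: otsu percentile threshold 0.01, threshold correction
#' factor 0.3, closing size 9 and dilation size 2.
#'
#' @param otsu_percentile_threshold fraction in \[0, 0.5); intensities are
#'   clipped to this percentile range before thresholding.
#' @param threshold_correction_factor positive scalar multiplied onto the
#'   Otsu threshold (values below 1 lower the threshold, admitting more
#'   tissue).
#' @param closing_size odd integer width (voxels) of the cubic structuring
#'   element for morphological closing.
#' @param dilate_size non-negative integer dilation radius (voxels) applied
#'   to the final mask.
#' @return An object of class `preprocess_params`.
#' @export
preprocess_params <- function(otsu_percentile_threshold = 0.01,
                              threshold_correction_factor = 0.3,
                              closing_size = 9L,
                              dilate_size = 2L) {
  if (otsu_percentile_threshold < 0 || otsu_percentile_threshold >= 0.5)
    stop("otsu_percentile_threshold must be in [0, 0.5)")
  if (threshold_correction_factor <= 0)
    stop("threshold_correction_factor must be positive")
  closing_size <- as.integer(closing_size)
  if (closing_size < 1L || closing_size %% 2L == 0L)
    stop("closing_size must be an odd integer >= 1")
  dilate_size <- as.integer(dilate_size)
  if (dilate_size < 0L) stop("dilate_size must be >= 0")
  structure(list(otsu_percentile_threshold = otsu_percentile_threshold,
                 threshold_correction_factor = threshold_correction_factor,
                 closing_size = closing_size, dilate_size = dilate_size),
            class = "preprocess_params")
}

#' Otsu threshold of a sample of intensities
#'
#' Classic Otsu thresholding on a 256-bin histogram spanning the sample
#' range: returns the bin boundary maximising the between-class variance.
#' Deterministic; ties resolve to the lowest such boundary.
#'
#' @param intensities numeric vector with at least two distinct values.
#' @return The threshold (scalar, same units as the input).
#' @export
otsu_threshold <- function(intensities) {
  x <- as.numeric(intensities)
  x <- x[is.finite(x)]
  rng <- range(x)
  if (length(x) < 2L || rng[1] == rng[2])
    stop("otsu_threshold: need at least two distinct values")
  nbins <- 256L
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)$counts
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(nbins + 1L)]) / 2
  w0 <- cumsum(p)[-nbins]
  w1 <- 1 - w0
  m0 <- cumsum(p * mids)[-nbins]
  mu_t <- sum(p * mids)
  # between-class variance at each candidate boundary (after bin 1..255)
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, nbins - 1L)
  bcv[valid] <- (mu_t * w0[valid] - m0[valid])^2 / (w0[valid] * w1[valid])
  k <- which.max(bcv)
  breaks[k + 1L]
}

#' Compute a CT foreground mask
#'
#' Removes external equipment (immobilisation mask remnants, mask holder,
#' table) from a CT-like volume: intensities are clipped to the
#' `[p, 1 - p]` percentile range, an Otsu threshold is computed on the
#' clipped values and scaled by the correction factor, the volume is
#' binarised, morphologically closed with a cubic element, reduced to its
#' largest 26-connected component, and finally dilated. The result is a
#' binary (0/1) [label_volume()] on the same grid.
#'
#' @param volume an [intensity_volume()].
#' @param params a [preprocess_params()] object.
#' @return A binary [label_volume()] (1 = foreground).
#' @export
foreground_mask <- function(volume, params = preprocess_params()) {
  stopifnot(inherits(volume, "intensity_volume"),
            inherits(params, "preprocess_params"))
  x <- volume$array
  p <- params$otsu_percentile_threshold
  if (p > 0) {
    q <- stats::quantile(x, c(p, 1 - p), names = FALSE)
    x <- pmin(pmax(x, q[1]), q[2])
  }
  if (min(x) == max(x))
    stop("foreground_mask: volume is constant after clipping")
  thr <- otsu_threshold(as.vector(x)) * params$threshold_correction_factor
  mask <- array(x > thr, dim = dim(x))
  if (!any(mask))
    stop("foreground_mask: no voxel above the scaled threshold")
  r_close <- (params$closing_size - 1L) %/% 2L
  if (r_close > 0L) mask <- binary_close(mask, r_close)
  lab <- label_components(mask)
  ncomp <- max(lab)
  if (ncomp > 1L) {
    sizes <- tabulate(lab[lab > 0L], nbins = ncomp)
    mask <- lab == which.max(sizes)
  }
  if (params$dilate_size > 0L) mask <- binary_dilate(mask, params$dilate_size)
  label_volume(array(as.integer(mask), dim = dim(mask)), volume$spacing,
               slice_axis = volume$slice_axis, lr_axis = volume$lr_axis)
}

#' Apply a binary mask to an intensity volume
#'
#' @param image an [intensity_volume()].
#' @param mask a binary [label_volume()] on the identical grid.
#' @param fill_value value assigned outside the mask.
#' @return The masked [intensity_volume()].
#' @export
apply_mask <- function(image, mask, fill_value = 0) {
  stopifnot(inherits(image, "intensity_volume"),
            inherits(mask, "label_volume"))
  if (!identical(dim(image$array), dim(mask$array)) ||
      !isTRUE(all.equal(image$spacing, mask$spacing)))
    stop("image and mask must share the same grid (dimensions and spacing)")
  image$array[mask$array == 0L] <- fill_value
  image
}

#' Crop a volume to an index range
#'
#' Plain index-range crop (the counterpart of a manual cubic region-of-
#' interest fit against anatomical landmarks, which requires a human and is
#' not automated here). Ranges are inclusive, 1-based, per array axis.
#'
#' @param volume a [label_volume()] or [intensity_volume()].
#' @param i_range,j_range,k_range integer length-2 `(from, to)` per axis;
#'   `NULL` keeps the full extent.
#' @return The cropped volume (same class); spacing unchanged.
#' @export
crop_volume <- function(volume, i_range = NULL, j_range = NULL,
                        k_range = NULL) {
  d <- dim(volume$array)
  rng <- function(r, n, axis) {
    if (is.null(r)) return(seq_len(n))
    r <- as.integer(r)
    if (length(r) != 2L || r[1] < 1L || r[2] > n || r[1] > r[2])
      stop("invalid crop range for axis ", axis, ": [", r[1], ", ", r[2],
           "] with extent ", n)
    r[1]:r[2]
  }
  volume$array <- volume$array[rng(i_range, d[1], 1), rng(j_range, d[2], 2),
                               rng(k_range, d[3], 3), drop = FALSE]
  volume
}

# ---- separable binary morphology ------------------------------------------
# Cubic structuring elements only. For dilation, outside the volume counts as
# background; erosion (via complement) consequently treats outside as
# foreground, so closing does not eat structures touching the volume border.

shift_axis <- function(mask, axis, s) {
  d <- dim(mask)
  out <- array(FALSE, d)
  n <- d[axis]
  if (abs(s) >= n) return(out)
  src <- if (s >= 0) 1:(n - s) else (1 - s):n
  dst <- src + s
  switch(axis,
         out[dst, , ] <- mask[src, , ],
         out[, dst, ] <- mask[, src, ],
         out[, , dst] <- mask[, , src])
  out
}

binary_dilate <- function(mask, r) {
  for (axis in 1:3) {
    acc <- mask
    for (s in seq_len(r)) acc <- acc | shift_axis(mask, axis, s) |
        shift_axis(mask, axis, -s)
    mask <- acc
  }
  mask
}

binary_erode <- function(mask, r) {
  !binary_dilate(!mask, r)
}

binary_close <- function(mask, r) {
  binary_erode(binary_dilate(mask, r), r)
}
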