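#' Left-right mirroring augmentation with label adaption
#'
#' Flips a label volume along its patient left-right axis and swaps each
#' left-laterality label value with its paired right-laterality value (and
#' vice versa), so anatomical sidedness remains correct in the mirrored
#' training sample. Midline labels and background are unchanged. Intended for
#' offline augmentation: the voxel array is flipped and the header affine of
#' any written file is not altered.
#'
#' @param volume a [label_volume()].
#' @param taxonomy a [level_taxonomy()]; must declare a mirror pair for every
#'   lateral label present in the volume.
#' @return The mirrored [label_volume()].
#' @export
mirror_augment <- function(volume, taxonomy) {
  validate_labels(volume, taxonomy)
  e <- taxonomy$entries
  lateral <- e$name[e$laterality %in% c("left", "right")]
  present <- unique(as.vector(volume$array))
  lateral_present <- intersect(taxonomy_labels(taxonomy, lateral), present)
  paired <- unlist(lapply(taxonomy$mirror_pairs, taxonomy_labels,
                          tax = taxonomy))
  unpaired <- setdiff(lateral_present, paired)
  if (length(unpaired))
    stop("no mirror pair for lateral label value(s): ",
         paste(unpaired, collapse = ", "))

  arr <- flip_axis(volume$array, volume$lr_axis)
  # build the left<->right label permutation
  maxv <- max(c(as.vector(arr), taxonomy$entries$label_value, 0L))
  perm <- seq_len(maxv + 1L) - 1L  # identity on 0..max
  for (p in taxonomy$mirror_pairs) {
    lv <- taxonomy_labels(taxonomy, p)
    perm[lv[1] + 1L] <- lv[2]
    perm[lv[2] + 1L] <- lv[1]
  }
  volume$array <- array(as.integer(perm[arr + 1L]), dim = dim(arr))
  volume
}

#' Mirror an intensity volume
#'
#' Flips the voxel array along the left-right axis; spacing is unchanged.
#' The paired image for [mirror_augment()] when augmenting offline.
#'
#' @param volume an [intensity_volume()].
#' @return The mirrored [intensity_volume()].
#' @export
mirror_intensity <- function(volume) {
  stopifnot(inherits(volume, "intensity_volume"))
  volume$array <- flip_axis(volume$array, volume$lr_axis)
  volume
}

flip_axis <- function(arr, axis) {
  d <- dim(arr)
  idx <- rep(list(quote(expr = )), 3L)
  idx[[axis]] <- rev(seq_len(d[axis]))
  do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
}
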