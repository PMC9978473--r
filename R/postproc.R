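#' Slice-adjustment parameters
#'
#' Thresholds governing the boundary-slice trimming step of
#' [slice_plane_adjust()]. The defaults are the published operating point:
#' slices with 10 or fewer foreground voxels, or whose foreground count drops
#' by 80% or more relative to the neighbouring slice nearer the volume centre
#' while the next slice outward is empty, are replaced by background.
#'
#' @param min_foreground_voxels non-negative integer; boundary slices with
#'   this many non-background voxels or fewer are cleared (default 10).
#' @param drop_fraction fraction in (0, 1]; a boundary slice whose foreground
#'   count has dropped by at least this fraction relative to its inner
#'   neighbour (and whose outer neighbour is empty) is cleared (default 0.8).
#' @param apply_boundary_trim logical; disable to run conflict resolution
#'   only.
#' @return An object of class `adjustment_params`.
#' @export
adjustment_params <- function(min_foreground_voxels = 10L,
                              drop_fraction = 0.8,
                              apply_boundary_trim = TRUE) {
  min_foreground_voxels <- as.integer(min_foreground_voxels)
  if (is.na(min_foreground_voxels) || min_foreground_voxels < 0L)
    stop("min_foreground_voxels must be >= 0")
  if (!is.numeric(drop_fraction) || drop_fraction <= 0 || drop_fraction > 1)
    stop("drop_fraction must be in (0, 1]")
  structure(list(min_foreground_voxels = min_foreground_voxels,
                 drop_fraction = as.numeric(drop_fraction),
                 apply_boundary_trim = isTRUE(apply_boundary_trim)),
            class = "adjustment_params")
}

chain_label_sets <- function(taxonomy) {
  lapply(taxonomy$exclusivity_chains, taxonomy_labels, tax = taxonomy)
}

#' Resolve within-chain conflicts on each CT slice
#'
#' Levels listed in the same exclusivity chain are craniocaudally adjacent by
#' definition and therefore mutually exclusive on any one CT slice. For every
#' slice (iterated cranial to caudal) and every chain, if two or more chain
#' members have voxels on the slice, the member predicted for the most voxels
#' on that slice wins and the conflicting voxels are relabelled to it. Ties
#' go to the more cranial chain member. Voxels of labels outside the chain,
#' and slices without within-chain conflict, are untouched; the total number
#' of non-background voxels never changes.
#'
#' @param volume a [label_volume()].
#' @param taxonomy a [level_taxonomy()]; the volume is validated against it.
#' @return The adjusted [label_volume()].
#' @export
resolve_slice_conflicts <- function(volume, taxonomy) {
  validate_labels(volume, taxonomy)
  arr <- volume$array
  ax <- volume$slice_axis
  chains <- chain_label_sets(taxonomy)
  if (!length(chains)) return(volume)
  for (k in seq_len(dim(arr)[ax])) {
    sl <- get_slice(arr, ax, k)
    changed <- FALSE
    for (ch in chains) {
      counts <- vapply(ch, function(l) sum(sl == l), integer(1))
      present <- which(counts > 0L)
      if (length(present) < 2L) next
      # which.max returns the first maximum; chain order is cranial-first,
      # so ties resolve to the more cranial member
      winner <- present[which.max(counts[present])]
      losers <- ch[setdiff(present, winner)]
      sl[sl %in% losers] <- ch[winner]
      changed <- TRUE
    }
    if (changed) arr <- set_slice(arr, ax, k, sl)
  }
  volume$array <- arr
  volume
}

#' Trim low-count boundary slices to background
#'
#' Enforces slice-plane consistency of the cranial boundary of the topmost
#' levels and the caudal boundary of the bottommost levels: working inward
#' from each end of the foreground extent, a slice is replaced entirely by
#' background if (a) it has `min_foreground_voxels` or fewer non-background
#' voxels, or (b) its non-background count has dropped by `drop_fraction` or
#' more relative to the neighbouring slice nearer the volume centre and the
#' next slice outward contains no foreground. Each run stops at the first
#' slice satisfying neither condition; interior slices are never modified.
#' All counts are evaluated on the input volume.
#'
#' @param volume a [label_volume()].
#' @param params an [adjustment_params()] object.
#' @param background background label value (default 0).
#' @return The trimmed [label_volume()].
#' @export
trim_boundary_slices <- function(volume, params = adjustment_params(),
                                 background = 0L) {
  stopifnot(inherits(volume, "label_volume"),
            inherits(params, "adjustment_params"))
  counts <- slice_counts(volume, background)
  n <- length(counts)
  fg <- which(counts > 0L)
  if (!length(fg)) return(volume)
  first <- fg[1]; last <- fg[length(fg)]
  count_at <- function(k) if (k < 1L || k > n) 0L else counts[k]

  trims <- function(k, inward) {
    inner <- count_at(k + inward)
    if (counts[k] <= params$min_foreground_voxels) return(TRUE)
    if (count_at(k - inward) == 0L && inner > 0L &&
        counts[k] <= (1 - params$drop_fraction) * inner) return(TRUE)
    FALSE
  }

  trimmed <- integer(0)
  s <- first
  while (s <= last && trims(s, inward = 1L)) {
    trimmed <- c(trimmed, s)
    s <- s + 1L
  }
  cranial_stop <- s  # first surviving slice
  s <- last
  while (s >= cranial_stop && trims(s, inward = -1L)) {
    trimmed <- c(trimmed, s)
    s <- s - 1L
  }
  for (k in trimmed)
    volume$array <- set_slice(volume$array, volume$slice_axis, k,
                              as.integer(background))
  volume
}

#' Slice-plane adjustment postprocessing
#'
#' The full adjustment: [resolve_slice_conflicts()] followed by
#' [trim_boundary_slices()] (when `params$apply_boundary_trim` is `TRUE`).
#' After adjustment, craniocaudal boundaries between chain levels and the
#' outer boundaries of the topmost/bottommost levels are consistent with the
#' CT slice plane: [count_slice_inconsistencies()] is 0 on the result.
#'
#' @inheritParams resolve_slice_conflicts
#' @param params an [adjustment_params()] object.
#' @return The adjusted [label_volume()].
#' @export
slice_plane_adjust <- function(volume, taxonomy,
                               params = adjustment_params()) {
  out <- resolve_slice_conflicts(volume, taxonomy)
  if (params$apply_boundary_trim)
    out <- trim_boundary_slices(out, params,
                                background = taxonomy$background_value)
  out
}

#' Keep only the largest connected component per class
#'
#' For each selected class, retains the largest 26-connected 3D component and
#' relabels every other component of that class to background. Spurious
#' isolated islands of a level prediction are thereby removed. A tie in
#' component size is broken deterministically in favour of the component
#' containing the lexicographically smallest voxel index.
#'
#' @param volume a [label_volume()].
#' @param taxonomy a [level_taxonomy()].
#' @param classes character vector of level names to clean, or `NULL` for all.
#' @return The cleaned [label_volume()].
#' @export
keep_largest_component <- function(volume, taxonomy, classes = NULL) {
  validate_labels(volume, taxonomy)
  labels <- taxonomy_labels(taxonomy, classes)
  bg <- as.integer(taxonomy$background_value)
  for (l in labels) {
    mask <- volume$array == l
    if (!any(mask)) next
    lab <- label_components(mask)
    ncomp <- max(lab)
    if (ncomp <= 1L) next
    sizes <- tabulate(lab[lab > 0L], nbins = ncomp)
    best <- which(sizes == max(sizes))
    if (length(best) > 1L) {
      mins <- component_min_index(lab, ncomp)[best, , drop = FALSE]
      ord <- order(mins[, 1], mins[, 2], mins[, 3])
      best <- best[ord[1]]
    }
    volume$array[mask & lab != best] <- bg
  }
  volume
}

#' Count slice-plane inconsistencies
#'
#' Diagnostic for the property [slice_plane_adjust()] enforces: the number of
#' (slice, chain) pairs on which two or more members of the same exclusivity
#' chain co-occur. 0 if and only if the volume is slice-plane consistent.
#'
#' @inheritParams resolve_slice_conflicts
#' @return Non-negative integer count.
#' @export
count_slice_inconsistencies <- function(volume, taxonomy) {
  validate_labels(volume, taxonomy)
  arr <- volume$array
  ax <- volume$slice_axis
  chains <- chain_label_sets(taxonomy)
  total <- 0L
  for (k in seq_len(dim(arr)[ax])) {
    sl <- get_slice(arr, ax, k)
    for (ch in chains) {
      n_present <- sum(vapply(ch, function(l) any(sl == l), logical(1)))
      if (n_present >= 2L) total <- total + 1L
    }
  }
  total
}
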