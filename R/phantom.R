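#' Synthetic neck phantom specification
#'
#' Geometry of the synthetic ground-truth phantom: two lateral columns of
#' stacked elliptical level slabs (one per side, following each side's
#' exclusivity chain cranial to caudal), a second lateral column pair for the
#' bilateral levels outside the chains, and an optional midline column. The
#' default spacing matches a typical planning-CT regime (1.14 x 1.14 mm
#' pixels, 3 mm slices) so that tolerance logic is exercised under realistic
#' anisotropy. The left-right grid extent must be odd so that the phantom is
#' exactly mirror-symmetric about the midline.
#'
#' @param grid_shape integer length-3 array dimensions (lr, ap, slices).
#' @param spacing voxel spacing in mm (default `c(1.14, 1.14, 3)`).
#' @param slices_per_level slab thickness in slices (>= 2, default 6).
#' @param inplane_radius_voxels disk radius of each slab in voxels.
#' @param lateral_offset_voxels distance from the midline to each lateral
#'   column centre, in voxels.
#' @param midline_levels_present include the midline level column.
#' @param seed integer seed (used by the intensity phantom's noise; the
#'   label ground truth is fully deterministic).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(49L, 32L, 36L),
                         spacing = c(1.14, 1.14, 3.0),
                         slices_per_level = 6L,
                         inplane_radius_voxels = 5L,
                         lateral_offset_voxels = 12L,
                         midline_levels_present = TRUE,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 4L))
  if (grid_shape[1] %% 2L == 0L)
    stop("left-right grid extent must be odd for exact mirror symmetry")
  slices_per_level <- as.integer(slices_per_level)
  if (slices_per_level < 2L) stop("slices_per_level must be >= 2")
  structure(list(grid_shape = grid_shape, spacing = as.numeric(spacing),
                 slices_per_level = slices_per_level,
                 inplane_radius_voxels = as.integer(inplane_radius_voxels),
                 lateral_offset_voxels = as.integer(lateral_offset_voxels),
                 midline_levels_present = isTRUE(midline_levels_present),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Corruption model for "raw CNN prediction"-like volumes
#'
#' The three defect classes slice-plane postprocessing targets: boundary
#' jitter (voxels on within-chain boundary slices flipped to the adjacent
#' chain member, breaking slice-plane consistency while leaving the union
#' foreground untouched), spurious isolated islands, and low-count fringe
#' slices appended beyond the cranial/caudal foreground ends.
#'
#' @param boundary_jitter_prob probability in \[0, 1\] that a voxel on a
#'   within-chain boundary slice flips to the adjacent chain member
#'   (default 0.1).
#' @param island_count number of spurious islands (default 2).
#' @param island_size_voxels voxels per island (default 3).
#' @param fringe_slices slices appended beyond each foreground end
#'   (default 2).
#' @param fringe_voxels foreground voxels per fringe slice (default 6; at or
#'   below the trimming threshold of the published operating point).
#' @param seed integer seed; corruption is reproducible.
#' @return An object of class `corruption_spec`.
#' @export
corruption_spec <- function(boundary_jitter_prob = 0.1,
                            island_count = 2L,
                            island_size_voxels = 3L,
                            fringe_slices = 2L,
                            fringe_voxels = 6L,
                            seed = 1L) {
  if (boundary_jitter_prob < 0 || boundary_jitter_prob > 1)
    stop("boundary_jitter_prob must be in [0, 1]")
  if (island_count < 0L || island_size_voxels < 1L)
    stop("island_count must be >= 0 and island_size_voxels >= 1")
  if (fringe_slices < 0L || fringe_voxels < 0L)
    stop("fringe_slices and fringe_voxels must be >= 0")
  structure(list(boundary_jitter_prob = as.numeric(boundary_jitter_prob),
                 island_count = as.integer(island_count),
                 island_size_voxels = as.integer(island_size_voxels),
                 fringe_slices = as.integer(fringe_slices),
                 fringe_voxels = as.integer(fringe_voxels),
                 seed = as.integer(seed)),
            class = "corruption_spec")
}

phantom_margin <- 4L

# array of the slice index (along `axis`) of every voxel
slice_ind <- function(d, axis) {
  perm <- array(rep(seq_len(d[axis]),
                    each = prod(d[seq_len(axis - 1L)]),
                    times = prod(d[seq_len(3L)[-seq_len(axis)]])),
                dim = d)
  perm
}

phantom_layout <- function(spec, taxonomy) {
  d <- spec$grid_shape
  r <- spec$inplane_radius_voxels
  mid <- (d[1] + 1L) %/% 2L
  c_left <- mid - spec$lateral_offset_voxels
  c_right <- mid + spec$lateral_offset_voxels
  cj1 <- r + 2L
  cj2 <- cj1 + 2L * r + 4L
  if (c_left - r < 1L || c_right + r > d[1])
    stop("lateral columns exceed the grid along the left-right axis")
  if (cj2 + r > d[2])
    stop("columns exceed the grid along the second in-plane axis")

  chains <- taxonomy$exclusivity_chains
  if (length(chains) < 2L)
    stop("phantom requires taxonomy with a left and a right exclusivity chain")
  side_of <- function(nm) unique(taxonomy$entries$laterality[
    match(nm, taxonomy$entries$name)])
  left_chain <- chains[[which(vapply(chains, function(ch)
    identical(side_of(ch), "left"), logical(1)))[1]]]
  right_chain <- chains[[which(vapply(chains, function(ch)
    identical(side_of(ch), "right"), logical(1)))[1]]]

  in_chain <- unlist(chains)
  extra_pairs <- Filter(function(p) !any(p %in% in_chain),
                        taxonomy$mirror_pairs)
  midline <- if (spec$midline_levels_present)
    taxonomy$entries$name[taxonomy$entries$laterality == "midline"]
  else character(0)

  columns <- list(
    list(ci = c_left, cj = cj1, levels = left_chain),
    list(ci = c_right, cj = cj1, levels = right_chain),
    list(ci = c_left, cj = cj2,
         levels = vapply(extra_pairs, `[`, character(1), 1L)),
    list(ci = c_right, cj = cj2,
         levels = vapply(extra_pairs, `[`, character(1), 2L))
  )
  if (length(midline))
    columns <- c(columns, list(list(ci = mid, cj = cj1, levels = midline)))
  columns <- Filter(function(col) length(col$levels) > 0L, columns)

  max_levels <- max(vapply(columns, function(col) length(col$levels),
                           integer(1)))
  if (2L * phantom_margin + max_levels * spec$slices_per_level > d[3])
    stop("level slabs exceed the grid along the slice axis")
  list(columns = columns, start_slice = phantom_margin + 1L)
}

#' Generate the phantom ground-truth label volume
#'
#' Deterministic, slice-plane consistent by construction
#' ([count_slice_inconsistencies()] is 0), and exactly mirror-symmetric:
#' [mirror_augment()] returns the identical volume.
#'
#' @param spec a [phantom_spec()].
#' @param taxonomy a [level_taxonomy()] (default [default_taxonomy()]).
#' @return A [label_volume()].
#' @export
generate_ground_truth <- function(spec = phantom_spec(),
                                  taxonomy = default_taxonomy()) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  lay <- phantom_layout(spec, taxonomy)
  arr <- array(0L, d)
  r2 <- spec$inplane_radius_voxels^2
  ij <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2])))
  for (col in lay$columns) {
    disk <- ij[(ij[, 1] - col$ci)^2 + (ij[, 2] - col$cj)^2 <= r2, ,
               drop = FALSE]
    k0 <- lay$start_slice
    for (nm in col$levels) {
      lv <- taxonomy_labels(taxonomy, nm)
      for (k in k0:(k0 + spec$slices_per_level - 1L))
        arr[cbind(disk, k)] <- lv
      k0 <- k0 + spec$slices_per_level
    }
  }
  label_volume(arr, spec$spacing, slice_axis = 3L, lr_axis = 1L,
               taxonomy = taxonomy)
}

#' Corrupt a ground-truth volume into a "raw prediction"
#'
#' Applies the three seeded defect classes of [corruption_spec()] to a
#' ground-truth volume. Boundary jitter only relabels voxels between
#' adjacent chain members (the pooled foreground is unchanged); islands are
#' placed in background, 26-disconnected from all true structures and from
#' each other; fringe slices are appended beyond the cranial and caudal
#' foreground ends.
#'
#' @param gt a [label_volume()] ground truth.
#' @param cspec a [corruption_spec()].
#' @param taxonomy a [level_taxonomy()].
#' @param island_class level name receiving the islands; defaults to the
#'   first bilateral level outside every exclusivity chain (never in
#'   within-slice conflict with true structures).
#' @return The corrupted [label_volume()].
#' @export
corrupt <- function(gt, cspec, taxonomy = default_taxonomy(),
                    island_class = NULL) {
  stopifnot(inherits(gt, "label_volume"), inherits(cspec, "corruption_spec"))
  validate_labels(gt, taxonomy)
  arr <- gt$array
  d <- dim(arr)
  ax <- gt$slice_axis
  bg <- as.integer(taxonomy$background_value)

  with_seed(cspec$seed, {
    # -- boundary jitter across within-chain level interfaces
    if (cspec$boundary_jitter_prob > 0) {
      for (ch in chain_label_sets(taxonomy)) {
        for (m in seq_len(length(ch) - 1L)) {
          a <- ch[m]; b <- ch[m + 1L]
          ka <- which(apply(gt$array == a, ax, any))
          kb <- which(apply(gt$array == b, ax, any))
          if (!length(ka) || !length(kb)) next
          flip <- function(k, from, to) {
            sl <- get_slice(arr, ax, k)
            idx <- which(sl == from)
            if (!length(idx)) return()
            hit <- idx[stats::runif(length(idx)) < cspec$boundary_jitter_prob]
            if (length(hit)) {
              sl[hit] <- to
              arr <<- set_slice(arr, ax, k, sl)
            }
          }
          flip(max(ka), a, b)  # caudal-most slice of the upper level
          flip(min(kb), b, a)  # cranial-most slice of the lower level
        }
      }
    }

    # -- spurious islands, disconnected from everything
    if (cspec$island_count > 0L) {
      if (is.null(island_class)) {
        in_chain <- unlist(taxonomy$exclusivity_chains)
        lateral <- taxonomy$entries$name[
          taxonomy$entries$laterality %in% c("left", "right")]
        cand <- setdiff(lateral, in_chain)
        island_class <- if (length(cand)) cand[1] else taxonomy$entries$name[1]
      }
      lv <- taxonomy_labels(taxonomy, island_class)
      forbidden <- binary_dilate(arr != bg, 2L)
      # islands only appear inside the craniocaudal extent of the true
      # structures (spurious dots arise near predictions, and the boundary
      # trimming rules must stay blind to them)
      fg_slices <- which(apply(gt$array != bg, ax, any))
      outside <- slice_ind(d, ax) < min(fg_slices) |
        slice_ind(d, ax) > max(fg_slices)
      sz <- cspec$island_size_voxels
      for (n in seq_len(cspec$island_count)) {
        # island = run of sz voxels along axis 2 at an allowed position
        ok <- which(!forbidden & !outside)
        placed <- FALSE
        for (cand_lin in sample(ok, min(length(ok), 500L))) {
          ci <- arrayInd(cand_lin, d)
          if (ci[2] + sz - 1L > d[2]) next
          run <- cbind(ci[1], ci[2]:(ci[2] + sz - 1L), ci[3])
          if (any(forbidden[run])) next
          arr[run] <- lv
          forbidden <- forbidden | binary_dilate(arr == lv, 2L)
          placed <- TRUE
          break
        }
        if (!placed)
          stop("no background room to place island ", n)
      }
    }

    # -- fringe slices beyond the foreground extent
    if (cspec$fringe_slices > 0L && cspec$fringe_voxels > 0L) {
      counts <- apply(gt$array != bg, ax, sum)
      fgk <- which(counts > 0L)
      if (length(fgk)) {
        first <- fgk[1]; last <- fgk[length(fgk)]
        if (first - cspec$fringe_slices < 1L ||
            last + cspec$fringe_slices > d[ax])
          stop("no room for fringe slices beyond the foreground extent")
        add_fringe <- function(edge_k, dir) {
          sl <- get_slice(gt$array, ax, edge_k)
          idx <- which(sl != bg)
          for (s in seq_len(cspec$fringe_slices)) {
            pick <- sample(idx, min(cspec$fringe_voxels, length(idx)))
            new_sl <- get_slice(arr, ax, edge_k + dir * s)
            new_sl[pick] <- sl[pick]
            arr <<- set_slice(arr, ax, edge_k + dir * s, new_sl)
          }
        }
        add_fringe(first, -1L)
        add_fringe(last, +1L)
      }
    }
  })

  gt$array <- arr
  gt
}

#' Generate a CT-like intensity phantom
#'
#' A high-intensity body ellipsoid on low background, plus detached thin
#' shell arcs imitating residual immobilisation-mask/mask-holder parts at
#' intermediate intensity (above the corrected foreground threshold but
#' disconnected from the body, so removal relies on the largest-component
#' step). Deterministic given `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return An [intensity_volume()].
#' @export
make_intensity_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  ctr <- c((d[1] + 1) / 2, 0.66 * d[2], (d[3] + 1) / 2)
  semi <- pmax(2, c(0.30 * d[1], 0.26 * d[2], 0.38 * d[3]))
  g <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3]))
  rr <- sqrt(((g$i - ctr[1]) / semi[1])^2 + ((g$j - ctr[2]) / semi[2])^2 +
               ((g$k - ctr[3]) / semi[3])^2)
  body <- rr <= 1
  # detached thin "mask holder" plate, anterior of the body with a gap wider
  # than the default closing element can bridge
  arcs <- g$j >= 2 & g$j <= 3 &
    abs(g$i - ctr[1]) <= 0.25 * d[1] & abs(g$k - ctr[3]) <= 0.25 * d[3]
  with_seed(spec$seed, {
    vals <- stats::rnorm(nrow(g), mean = 10, sd = 1.5)
    vals[body] <- stats::rnorm(sum(body), mean = 100, sd = 5)
    vals[arcs] <- stats::rnorm(sum(arcs), mean = 60, sd = 5)
    intensity_volume(array(vals, dim = d), spec$spacing)
  })
}
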