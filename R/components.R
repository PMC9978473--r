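# 3D connected-component labelling, 26-connectivity, frontier BFS.
# Returns an integer array: 0 outside the mask, component id (1..n) inside.
label_components <- function(mask) {
  d <- dim(mask)
  stopifnot(length(d) == 3L)
  lab <- array(0L, d)
  fg <- which(mask)
  if (!length(fg)) return(lab)
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  off <- off[rowSums(abs(off)) > 0L, , drop = FALSE]  # 26 neighbours
  comp <- 0L
  for (s in fg) {
    if (lab[s] > 0L) next
    comp <- comp + 1L
    lab[s] <- comp
    frontier <- s
    while (length(frontier)) {
      ci <- arrayInd(frontier, d)
      n <- nrow(ci)
      nb_i <- rep(ci[, 1], each = 26L) + rep(off[, 1], times = n)
      nb_j <- rep(ci[, 2], each = 26L) + rep(off[, 2], times = n)
      nb_k <- rep(ci[, 3], each = 26L) + rep(off[, 3], times = n)
      ok <- nb_i >= 1L & nb_i <= d[1] & nb_j >= 1L & nb_j <= d[2] &
        nb_k >= 1L & nb_k <= d[3]
      lin <- nb_i[ok] + (nb_j[ok] - 1L) * d[1] + (nb_k[ok] - 1L) * d[1] * d[2]
      lin <- unique(lin[mask[lin] & lab[lin] == 0L])
      if (length(lin)) lab[lin] <- comp
      frontier <- lin
    }
  }
  lab
}

# Lexicographically smallest (i, j, k) voxel index of each component,
# returned as a matrix with one row per component id.
component_min_index <- function(lab, ncomp) {
  out <- matrix(NA_integer_, nrow = ncomp, ncol = 3L)
  idx <- which(lab > 0L)
  ci <- arrayInd(idx, dim(lab))
  comp <- lab[idx]
  ord <- order(comp, ci[, 1], ci[, 2], ci[, 3])
  first <- ord[!duplicated(comp[ord])]
  out[comp[first], ] <- ci[first, , drop = FALSE]
  out
}
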