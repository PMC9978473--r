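# Independent brute-force oracles and small fixtures shared across tests.
# Oracles deliberately use plain loops / exhaustive enumeration, not the
# package's vectorised code paths.

# A small 4-level taxonomy: one midline level, one mirrored pair outside any
# chain, and a two-member craniocaudal chain per side.
tiny_taxonomy <- function() {
  level_taxonomy(
    entries = data.frame(
      name = c("mid", "A_left", "A_right", "B_left", "B_right",
               "C_left", "C_right"),
      label_value = 1:7,
      laterality = c("midline", "left", "right", "left", "right",
                     "left", "right")),
    mirror_pairs = list(c("A_left", "A_right"), c("B_left", "B_right"),
                        c("C_left", "C_right")),
    exclusivity_chains = list(c("A_left", "B_left"), c("A_right", "B_right"))
  )
}

tiny_volume <- function(arr, spacing = c(1, 1, 1)) {
  label_volume(arr, spacing)
}

# Dice by explicit voxel-index set operations.
oracle_dice <- function(a, b) {
  ia <- which(a != 0)
  ib <- which(b != 0)
  if (length(ia) + length(ib) == 0) return(NA_real_)
  2 * length(intersect(ia, ib)) / (length(ia) + length(ib))
}

# Boundary voxels by per-voxel 6-neighbour inspection.
oracle_boundary <- function(mask) {
  d <- dim(mask)
  out <- matrix(numeric(0), ncol = 3)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!mask[i, j, k]) next
    nb <- list(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
               c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    on_boundary <- FALSE
    for (p in nb) {
      outside <- any(p < 1) || p[1] > d[1] || p[2] > d[2] || p[3] > d[3]
      if (outside || !mask[p[1], p[2], p[3]]) { on_boundary <- TRUE; break }
    }
    if (on_boundary) out <- rbind(out, c(i, j, k))
  }
  out
}

oracle_pairwise_min <- function(P, Q, spacing) {
  if (nrow(Q) == 0) return(rep(Inf, nrow(P)))
  vapply(seq_len(nrow(P)), function(r) {
    dmin <- Inf
    for (s in seq_len(nrow(Q))) {
      dd <- sqrt(sum(((P[r, ] - Q[s, ]) * spacing)^2))
      if (dd < dmin) dmin <- dd
    }
    dmin
  }, numeric(1))
}

oracle_surface_dice <- function(a, b, tol, spacing) {
  if (!any(a) && !any(b)) return(NA_real_)
  Pa <- oracle_boundary(a)
  Pb <- oracle_boundary(b)
  ma <- sum(oracle_pairwise_min(Pa, Pb, spacing) <= tol)
  mb <- sum(oracle_pairwise_min(Pb, Pa, spacing) <= tol)
  (ma + mb) / (nrow(Pa) + nrow(Pb))
}

oracle_hausdorff <- function(a, b, spacing) {
  Pa <- oracle_boundary(a)
  Pb <- oracle_boundary(b)
  max(max(oracle_pairwise_min(Pa, Pb, spacing)),
      max(oracle_pairwise_min(Pb, Pa, spacing)))
}

# Exact two-sided signed-rank p by full enumeration of all 2^n sign
# assignments of the (midrank-tied) absolute ranks.
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_le <- mean(v_all <= v_obs + 1e-9)
  p_ge <- mean(v_all >= v_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Otsu by naive exhaustive search over the 255 interior bin boundaries.
oracle_otsu <- function(x, nbins = 256) {
  rng <- range(x)
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1)
  mids <- (breaks[-1] + breaks[-(nbins + 1)]) / 2
  cnt <- graphics::hist(x, breaks = breaks, plot = FALSE)$counts
  best <- -Inf; best_k <- NA
  for (k in 1:(nbins - 1)) {
    n0 <- sum(cnt[1:k]); n1 <- sum(cnt) - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(cnt[1:k] * mids[1:k]) / n0
    mu1 <- sum(cnt[(k + 1):nbins] * mids[(k + 1):nbins]) / n1
    bcv <- n0 * n1 * (mu0 - mu1)^2
    if (bcv > best) { best <- bcv; best_k <- k }
  }
  breaks[best_k + 1]
}

# Random small binary mask pair for metric oracle tests.
random_mask_pair <- function(d = c(7, 6, 5), p = 0.3) {
  a <- array(stats::runif(prod(d)) < p, dim = d)
  b <- array(stats::runif(prod(d)) < p, dim = d)
  list(a = a, b = b)
}
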