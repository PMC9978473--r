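# tiny_taxonomy chains: A_left(2) -> B_left(4) per side, A_right(3) -> B_right(5)

test_that("conflict resolution relabels the within-chain minority to the majority", {
  arr <- array(0L, c(6, 6, 4))
  # slice 2: 6 voxels of A_left (label 2) and 2 voxels of B_left (label 4)
  arr[1:6, 1, 2] <- 2L
  arr[1:2, 2, 2] <- 4L
  out <- resolve_slice_conflicts(tiny_volume(arr), tiny_taxonomy())
  sl <- out$array[, , 2]
  expect_equal(sum(sl == 2L), 8L)
  expect_equal(sum(sl == 4L), 0L)
  # all other slices untouched
  expect_identical(out$array[, , -2], arr[, , -2])
})

test_that("left and right chains never conflict with each other", {
  arr <- array(0L, c(6, 6, 4))
  arr[1:4, 1, 2] <- 2L  # A_left
  arr[1:4, 2, 2] <- 3L  # A_right, same count, different chain
  out <- resolve_slice_conflicts(tiny_volume(arr), tiny_taxonomy())
  expect_identical(out$array, arr)
})

test_that("conflict resolution conserves the non-background voxel count and ties go cranial", {
  tax <- tiny_taxonomy()
  set.seed(11)
  for (rep in 1:10) {
    arr <- array(0L, c(5, 5, 6))
    n <- prod(dim(arr))
    arr[sample(n, 40)] <- sample(c(2L, 4L), 40, replace = TRUE)
    arr[sample(n, 10)] <- 1L  # midline voxels, never in a chain
    vol <- tiny_volume(arr)
    out <- resolve_slice_conflicts(vol, tax)
    expect_equal(sum(out$array != 0L), sum(arr != 0L))
    expect_equal(count_slice_inconsistencies(out, tax), 0L)
    # midline voxels are bitwise untouched
    expect_identical(out$array == 1L, arr == 1L)
  }
  # exact tie: the more cranial chain member wins
  arr <- array(0L, c(4, 4, 3))
  arr[1:3, 1, 1] <- 2L
  arr[1:3, 2, 1] <- 4L
  out <- resolve_slice_conflicts(tiny_volume(arr), tax)
  expect_equal(sum(out$array == 2L), 6L)
})

test_that("boundary trimming follows the voxel-count and drop rules", {
  tax <- tiny_taxonomy()
  mk <- function(counts) {
    # build a volume whose per-slice foreground counts equal `counts`
    arr <- array(0L, c(12, 12, length(counts)))
    for (k in seq_along(counts)) {
      if (counts[k] == 0) next
      sl <- array(0L, c(12, 12))
      sl[seq_len(counts[k])] <- 2L
      arr[, , k] <- sl
    }
    tiny_volume(arr)
  }
  counts_of <- function(vol) apply(vol$array != 0L, 3, sum)

  # topmost foreground slice with exactly the threshold count is cleared
  v <- mk(c(0, 10, 100, 100, 0))
  out <- trim_boundary_slices(v, adjustment_params())
  expect_equal(counts_of(out), c(0, 0, 100, 100, 0))

  # one voxel above the threshold and no >=80% drop from the inner
  # neighbour: slice survives
  v <- mk(c(0, 11, 13, 100, 0))
  out <- trim_boundary_slices(v, adjustment_params())
  expect_equal(counts_of(out), c(0, 11, 13, 100, 0))

  # caudal 85% drop with empty outward neighbour: 15 <= (1-0.8)*100
  v <- mk(c(0, 100, 100, 100, 15, 0))
  out <- trim_boundary_slices(v, adjustment_params())
  expect_equal(counts_of(out), c(0, 100, 100, 100, 0, 0))

  # 79% drop is not enough: 21 > (1-0.8)*100
  v <- mk(c(0, 100, 100, 100, 21, 0))
  out <- trim_boundary_slices(v, adjustment_params())
  expect_equal(counts_of(out), c(0, 100, 100, 100, 21, 0))

  # cranial drop rule fires (12 <= 0.2*100, outward empty) but the run stops
  # there because the next slice's outward neighbour was non-empty on input;
  # caudal slice survives both rules (11 > 10, 11 > 0.2*15)
  v <- mk(c(0, 12, 100, 100, 15, 11, 0))
  out <- trim_boundary_slices(v, adjustment_params())
  expect_equal(counts_of(out), c(0, 0, 100, 100, 15, 11, 0))

  # consecutive small boundary slices are all cleared, interior intact
  v <- mk(c(3, 7, 100, 100, 5, 2))
  out <- trim_boundary_slices(v, adjustment_params())
  expect_equal(counts_of(out), c(0, 0, 100, 100, 0, 0))

  # interior low-count slices are never modified
  v <- mk(c(0, 100, 4, 100, 0))
  out <- trim_boundary_slices(v, adjustment_params())
  expect_equal(counts_of(out), c(0, 100, 4, 100, 0))
})

test_that("slice_plane_adjust is idempotent and consistent on corrupted phantoms", {
  tax <- default_taxonomy()
  gt <- generate_ground_truth(phantom_spec(), tax)
  for (seed in 1:5) {
    pred <- corrupt(gt, corruption_spec(boundary_jitter_prob = 0.4,
                                        seed = seed), tax)
    adj1 <- slice_plane_adjust(pred, tax)
    expect_equal(count_slice_inconsistencies(adj1, tax), 0L)
    adj2 <- slice_plane_adjust(adj1, tax)
    expect_identical(adj2$array, adj1$array)
  }
  # clean ground truth is a fixed point
  expect_identical(slice_plane_adjust(gt, tax)$array, gt$array)
})

test_that("keep_largest_component removes islands and breaks ties lexicographically", {
  tax <- tiny_taxonomy()
  arr <- array(0L, c(10, 10, 6))
  arr[2:5, 2:5, 2:3] <- 2L          # main blob of A_left: 32 voxels
  arr[9, 9, 5] <- 2L                # isolated island
  arr[8, 1, 1] <- 2L                # second isolated island
  out <- keep_largest_component(tiny_volume(arr), tax)
  expect_equal(sum(out$array == 2L), 32L)
  expect_equal(out$array[9, 9, 5], 0L)
  expect_equal(out$array[8, 1, 1], 0L)

  # single component is untouched
  single <- array(0L, c(4, 4, 4)); single[2:3, 2:3, 2:3] <- 1L
  expect_identical(keep_largest_component(tiny_volume(single), tax)$array,
                   single)

  # equal sizes: the component with the lexicographically smallest voxel wins
  tie <- array(0L, c(10, 4, 4))
  tie[2:3, 2, 2] <- 1L
  tie[8:9, 2, 2] <- 1L
  out <- keep_largest_component(tiny_volume(tie), tax)
  expect_equal(which(out$array == 1L), which(tie == 1L)[1:2])

  # only the requested classes are cleaned
  both <- array(0L, c(10, 4, 4))
  both[2:3, 2, 2] <- 1L; both[8, 2, 2] <- 1L
  both[2:3, 3, 2] <- 2L; both[8, 3, 2] <- 2L
  out <- keep_largest_component(tiny_volume(both), tax, classes = "mid")
  expect_equal(sum(out$array == 1L), 2L)  # cleaned
  expect_equal(sum(out$array == 2L), 3L)  # untouched
})

test_that("count_slice_inconsistencies counts (slice, chain) conflicts", {
  tax <- tiny_taxonomy()
  arr <- array(0L, c(6, 6, 4))
  expect_equal(count_slice_inconsistencies(tiny_volume(arr), tax), 0L)
  arr[1, 1, 2] <- 2L; arr[2, 1, 2] <- 4L      # one conflicting slice, left
  expect_equal(count_slice_inconsistencies(tiny_volume(arr), tax), 1L)
  arr[1, 2, 3] <- 3L; arr[2, 2, 3] <- 5L      # plus one on the right chain
  expect_equal(count_slice_inconsistencies(tiny_volume(arr), tax), 2L)
})
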