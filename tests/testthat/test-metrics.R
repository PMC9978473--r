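test_that("volumetric Dice follows the set formula and empty-mask rules", {
  a <- array(FALSE, c(4, 4, 4)); b <- a
  a[1:2, 1, 1] <- TRUE           # |a| = 2
  b[2:3, 1, 1] <- TRUE           # |b| = 2, overlap 1
  expect_equal(volumetric_dice(a, b), 0.5)
  expect_equal(volumetric_dice(a, a), 1)
  disjoint <- array(FALSE, c(4, 4, 4)); disjoint[4, 4, 4] <- TRUE
  expect_equal(volumetric_dice(a, disjoint), 0)
  empty <- array(FALSE, c(4, 4, 4))
  expect_true(is.na(volumetric_dice(empty, empty)))
  expect_equal(volumetric_dice(a, empty), 0)
  expect_error(volumetric_dice(a, array(FALSE, c(3, 4, 4))), "grid")
})

test_that("metrics agree with brute-force enumeration on random mask pairs", {
  set.seed(99)
  spacing_opts <- list(c(1, 1, 1), c(1.14, 1.14, 3))
  n_checked <- 0
  for (rep in 1:110) {
    mp <- random_mask_pair()
    spacing <- spacing_opts[[1 + rep %% 2]]
    expect_equal(volumetric_dice(mp$a, mp$b), oracle_dice(mp$a, mp$b))
    if (any(mp$a) && any(mp$b)) {
      tol <- max(spacing)
      expect_equal(surface_dice(mp$a, mp$b, tol, spacing),
                   oracle_surface_dice(mp$a, mp$b, tol, spacing))
      expect_equal(hausdorff_max(mp$a, mp$b, spacing),
                   oracle_hausdorff(mp$a, mp$b, spacing))
      # symmetry
      expect_equal(hausdorff_max(mp$b, mp$a, spacing),
                   hausdorff_max(mp$a, mp$b, spacing))
      expect_equal(surface_dice(mp$b, mp$a, tol, spacing),
                   surface_dice(mp$a, mp$b, tol, spacing))
    }
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 100)
})

test_that("surface Dice hits its closed-form cases and is monotone in tolerance", {
  d <- c(10, 10, 10)
  a <- array(FALSE, d); b <- array(FALSE, d)
  a[3:5, 3:5, 3:5] <- TRUE
  b[4:6, 3:5, 3:5] <- TRUE  # shifted one voxel along axis 1
  spacing <- c(2, 1, 1)
  expect_equal(surface_dice(a, b, tolerance_mm = 2, spacing = spacing), 1)
  expect_equal(surface_dice(a, a, 1, spacing), 1)
  far <- array(FALSE, d); far[9:10, 9:10, 9:10] <- TRUE
  expect_equal(surface_dice(a, far, 1, c(1, 1, 1)), 0)
  tols <- c(0.5, 1, 1.5, 2, 3, 5)
  set.seed(4)
  mp <- random_mask_pair(c(8, 8, 6), p = 0.25)
  vals <- vapply(tols, function(t)
    surface_dice(mp$a, mp$b, t, c(1, 1, 1)), numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("Hausdorff uses physical spacing", {
  d <- c(6, 6, 6)
  a <- array(FALSE, d); b <- array(FALSE, d)
  a[3, 3, 3] <- TRUE
  b[3, 3, 4] <- TRUE  # one slice apart
  expect_equal(hausdorff_max(a, b, c(1.14, 1.14, 3)), 3)
  expect_equal(hausdorff_max(a, a, c(1, 1, 1)), 0)
  expect_true(is.na(hausdorff_max(a, array(FALSE, d), c(1, 1, 1))))
})

test_that("evaluate_pair reports per level, union and case mean", {
  tax <- tiny_taxonomy()
  arr <- array(0L, c(8, 8, 8))
  arr[2:4, 2:4, 2:3] <- 2L
  arr[2:4, 2:4, 4:5] <- 4L
  arr[6:7, 6:7, 2:4] <- 1L
  ref <- tiny_volume(arr)
  # identical pair: all defined metrics perfect
  rep0 <- evaluate_pair(ref, ref, tax)
  defined <- !is.na(rep0$per_level$volumetric_dice)
  expect_true(all(rep0$per_level$volumetric_dice[defined] == 1))
  expect_true(all(rep0$per_level$surface_dice[defined] == 1))
  expect_true(all(rep0$per_level$hausdorff_max_mm[
    !is.na(rep0$per_level$hausdorff_max_mm)] == 0))
  expect_equal(unname(rep0$union["volumetric_dice"]), 1)
  expect_equal(unname(rep0$case_mean["volumetric_dice"]), 1)

  # candidate missing one entire level: that level 0, union < 1
  cand <- ref
  cand$array[cand$array == 1L] <- 0L
  rep1 <- evaluate_pair(cand, ref, tax)
  expect_equal(rep1$per_level$volumetric_dice[rep1$per_level$level == "mid"],
               0)
  expect_lt(unname(rep1$union["volumetric_dice"]), 1)
  # absent-on-both levels are undefined, not zero
  expect_true(is.na(rep1$per_level$volumetric_dice[
    rep1$per_level$level == "C_left"]))

  # one-voxel tolerance resolves to the max spacing component
  expect_equal(rep0$tolerance_mm, max(ref$spacing))
})

test_that("label-swap-only corruption leaves union metrics perfect while per-level degrades", {
  tax <- tiny_taxonomy()
  arr <- array(0L, c(8, 8, 10))
  arr[2:5, 2:5, 2:4] <- 2L
  arr[2:5, 2:5, 5:7] <- 4L
  ref <- tiny_volume(arr)
  swapped <- ref
  sl <- swapped$array[, , 5]
  sl[sl == 4L] <- 2L  # boundary slice relabelled across the chain
  swapped$array[, , 5] <- sl
  rep <- evaluate_pair(swapped, ref, tax)
  expect_equal(unname(rep$union["volumetric_dice"]), 1)
  expect_equal(unname(rep$union["surface_dice"]), 1)
  expect_equal(unname(rep$union["hausdorff_max_mm"]), 0)
  expect_lt(unname(rep$case_mean["volumetric_dice"]), 1)
})

test_that("metric config validates explicit tolerances", {
  expect_error(metric_config("explicit_mm"), "positive")
  cfg <- metric_config("explicit_mm", surface_tolerance_mm = 2.5)
  expect_equal(levelpost:::resolve_tolerance(cfg, c(1, 1, 3)), 2.5)
})
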