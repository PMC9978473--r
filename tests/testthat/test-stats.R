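test_that("exact signed-rank p-values match full sign enumeration for n <= 12", {
  set.seed(7)
  for (n in 2:12) {
    for (rep in 1:5) {
      # mix of tie-free and tied differences
      d <- if (rep %% 2 == 0) round(rnorm(n), 1) else rnorm(n)
      d[d == 0] <- 0.1
      res <- wilcoxon_signed_rank(d, rep(0, n))
      expect_true(res$exact)
      expect_equal(res$p.value, oracle_signed_rank_p(d),
                   tolerance = 1e-12,
                   label = paste0("n=", n, " rep=", rep))
    }
  }
})

test_that("signed-rank handles canonical cases", {
  # n = 6, all positive, no ties: two-sided p = 2/64
  res <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6), rep(0, 6))
  expect_equal(res$p.value, 2 / 64)
  expect_equal(res$V, 21)
  # identical conditions: degenerate, p = 1
  res <- wilcoxon_signed_rank(1:5, 1:5)
  expect_true(res$degenerate)
  expect_equal(res$p.value, 1)
  # swapping negates the centred statistic, p unchanged
  set.seed(2)
  x <- rnorm(15); y <- rnorm(15)
  r1 <- wilcoxon_signed_rank(x, y)
  r2 <- wilcoxon_signed_rank(y, x)
  expect_equal(r1$statistic, -r2$statistic)
  expect_equal(r1$p.value, r2$p.value)
  # zero differences are dropped
  res <- wilcoxon_signed_rank(c(5, 5, 1, 2, 3), c(5, 5, 0, 0, 0))
  expect_equal(res$n, 3)
  expect_equal(res$n_zero, 2)
  # agrees with stats::wilcox.test when that is exact (no ties, small n)
  set.seed(8)
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(wilcoxon_signed_rank(x, y)$p.value,
               stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value)
})

test_that("large-sample signed-rank approximation is close to the exact value", {
  set.seed(31)
  x <- rnorm(24); y <- rnorm(24, 0.3)
  exact <- wilcoxon_signed_rank(x, y)                 # n = 24 <= 25: exact
  approx <- wilcoxon_signed_rank(x, y, exact_max_n = 10)
  expect_false(approx$exact)
  expect_equal(approx$p.value, exact$p.value, tolerance = 0.05)
})

test_that("rank-sum statistic and p behave as expected", {
  res <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 6)  # minimum possible rank sum for x
  expect_true(res$exact)
  # enumeration: P(rank sum <= 6) = 1/C(6,3), two-sided doubles it
  expect_equal(res$p.value, 2 / choose(6, 3))
  # identical groups: p = 1 within tolerance
  expect_gte(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p.value, 0.95)
  # label swap leaves p unchanged
  set.seed(5)
  x <- rnorm(8); y <- rnorm(9, 0.5)
  expect_equal(wilcoxon_rank_sum(x, y)$p.value,
               wilcoxon_rank_sum(y, x)$p.value)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("paired dispersion test detects scale differences and ignores shifts", {
  set.seed(12)
  x <- rnorm(20)
  # pure location shift: identical deviations, degenerate (integer-valued
  # data so the shifted median is computed exactly)
  xi <- sample(1:100, 20)
  res <- paired_dispersion_test(paired_sample(1:20, xi, xi + 3))
  expect_true(res$degenerate)
  expect_equal(res$p.value, 1)
  # tripled dispersion in condition B: positive statistic, small p
  y <- 3 * (x - median(x)) + median(x)
  res <- paired_dispersion_test(paired_sample(1:20, x, y))
  expect_gt(res$statistic, 0)
  expect_lt(res$p.value, 0.01)
  # swapping conditions negates the statistic
  res_sw <- paired_dispersion_test(paired_sample(1:20, y, x))
  expect_equal(res_sw$statistic, -res$statistic)
  expect_error(paired_dispersion_test(paired_sample(1:2, c(1, 2), c(3, 4))),
               "at least 2|at least 3")
})

test_that("blinded manifest is a seeded bijection over presentations", {
  man <- generate_blinded_manifest(paste0("case", 1:4), c("expert", "dl"),
                                   n_raters = 2, levels = c("II_l", "II_r"),
                                   seed = 42)
  m <- man$manifest
  expect_equal(nrow(m), 2 * 4 * 2 * 2)
  # every (case, set) pair appears exactly once per rater (as a presentation)
  per <- unique(m[, c("rater", "presentation", "case", "contour_set_alias")])
  tab <- table(per$rater, per$case, per$contour_set_alias)
  expect_true(all(tab == 1))
  # same seed reproduces; different seeds differ somewhere
  man2 <- generate_blinded_manifest(paste0("case", 1:4), c("expert", "dl"),
                                    2, c("II_l", "II_r"), seed = 42)
  expect_identical(man$manifest, man2$manifest)
  orders <- vapply(1:100, function(s) {
    mi <- generate_blinded_manifest(paste0("case", 1:4), c("expert", "dl"),
                                    2, c("II_l", "II_r"), seed = s)$manifest
    paste(mi$case, mi$contour_set_alias, collapse = "|")
  }, character(1))
  expect_gt(length(unique(orders)), 90)
  # blinding key covers every true set once
  expect_setequal(man$key$contour_set, c("expert", "dl"))
  expect_error(generate_blinded_manifest(c("a", "a"), "s", 1, "l", 1),
               "duplicate")
})

test_that("summarize_ratings reports per-set summaries and paired comparisons", {
  grid <- expand.grid(rater = c("r1", "r2"), case = paste0("c", 1:6),
                      level = c("lvA", "lvB"), stringsAsFactors = FALSE)
  a <- cbind(grid, contour_set_alias = "set_1", rating = 80)
  b <- cbind(grid, contour_set_alias = "set_2", rating = 85)
  out <- summarize_ratings(rbind(a, b))
  s1 <- out$per_set[out$per_set$set == "set_1", ]
  expect_equal(s1$mean, 80); expect_equal(s1$median, 80)
  expect_equal(s1$q3 - s1$q1, 0)
  cmp <- out$comparisons
  expect_equal(cmp$mean_difference, -5)
  # constant +5 shift in every case: all differences one-signed
  expect_lt(cmp$statistic, 0)

  # simple arithmetic check on a 3-case set
  g <- data.frame(rater = "r", case = c("c1", "c2", "c3"),
                  contour_set_alias = "s", level = "l",
                  rating = c(70, 80, 90))
  out2 <- summarize_ratings(g)
  expect_equal(out2$per_set$mean, 80)
  expect_equal(out2$per_set$median, 80)

  bad <- g; bad$rating[1] <- 150
  expect_error(summarize_ratings(bad), "0, 100")
})
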