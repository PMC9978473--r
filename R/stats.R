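#' Paired sample container
#'
#' Per-case values of the same quantity under two conditions (e.g. mean Dice
#' per test case with and without slice-plane adjustment).
#'
#' @param ids unique case identifiers.
#' @param x,y numeric per-case values for conditions A and B (same length as
#'   `ids`, at least 2).
#' @return An object of class `paired_sample`.
#' @export
paired_sample <- function(ids, x, y) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("case ids must be unique")
  if (length(x) != length(ids) || length(y) != length(ids))
    stop("ids, x and y must have equal length")
  if (length(ids) < 2L) stop("need at least 2 paired cases")
  structure(list(ids = ids, x = as.numeric(x), y = as.numeric(y)),
            class = "paired_sample")
}

# Exact null distribution of the signed-rank sum V over random signs,
# on the doubled-rank integer scale (midranks may be half-integers).
# Returns P(2V = w) for w = 0 .. sum(2r) as a vector indexed by w + 1.
signed_rank_null <- function(r2) {
  total <- sum(r2)
  f <- numeric(total + 1L)
  f[1] <- 1
  for (ri in r2) {
    g <- f
    g[(ri + 1L):(total + 1L)] <- g[(ri + 1L):(total + 1L)] +
      f[1:(total + 1L - ri)]
    f <- g
  }
  f / 2^length(r2)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired differences. Zero differences are
#' dropped (Wilcoxon's original convention). For n <= 25 non-zero pairs the
#' exact null distribution of the rank sum is enumerated by shift
#' convolution, which handles midrank ties exactly; for larger n a normal
#' approximation with tie and continuity correction is used. The reported
#' `statistic` is the centred rank sum `V - n(n+1)/4`, which is negated when
#' the two conditions are swapped; the raw positive-rank sum `V` is also
#' returned.
#'
#' @param x a [paired_sample()], or numeric values for condition A.
#' @param y numeric values for condition B (ignored when `x` is a
#'   `paired_sample`).
#' @param exact_max_n largest n for which the exact null is enumerated.
#' @return List with `statistic` (centred), `V`, `p.value`, `n` (non-zero
#'   pairs), `n_zero`, `exact`, `degenerate`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max_n = 25L) {
  if (inherits(x, "paired_sample")) {
    d <- x$x - x$y
  } else {
    if (is.null(y)) stop("supply y, or a paired_sample as x")
    if (length(x) != length(y)) stop("x and y must have equal length")
    d <- as.numeric(x) - as.numeric(y)
  }
  d <- d[is.finite(d)]
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = 0, V = 0, p.value = 1, n = 0L, n_zero = n_zero,
                exact = TRUE, degenerate = TRUE))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  centred <- V - n * (n + 1) / 4
  if (n <= exact_max_n) {
    r2 <- as.integer(round(2 * r))
    null <- signed_rank_null(r2)
    w <- as.integer(round(2 * V))
    p_le <- sum(null[seq_len(w + 1L)])
    p_ge <- sum(null[(w + 1L):length(null)])
    p <- min(1, 2 * min(p_le, p_ge))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (V - mu - 0.5 * sign(V - mu)) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    exact <- FALSE
  }
  list(statistic = centred, V = V, p.value = p, n = n, n_zero = n_zero,
       exact = exact, degenerate = FALSE)
}

#' Wilcoxon rank-sum test for two independent groups
#'
#' Exact when both groups are small (`m + n <= 20`) and tie-free (delegated
#' to [stats::wilcox.test()]); otherwise a normal approximation with tie and
#' continuity correction. The reported statistic is the rank sum of `x` in
#' the pooled ranking.
#'
#' @param x,y numeric values of the two groups (both non-empty).
#' @return List with `statistic` (rank sum of `x`), `U`, `p.value`, `exact`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  m <- length(x); n <- length(y); N <- m + n
  r <- rank(c(x, y))
  Rx <- sum(r[seq_len(m)])
  U <- Rx - m * (m + 1) / 2
  has_ties <- anyDuplicated(c(x, y)) > 0L
  if (N <= 20L && !has_ties) {
    p <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    exact <- TRUE
  } else {
    mu <- m * n / 2
    ties <- table(r)
    sigma2 <- m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu - 0.5 * sign(U - mu)) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    exact <- FALSE
  }
  list(statistic = Rx, U = U, p.value = p, exact = exact)
}

#' Paired test for equal dispersion (Brown-Forsythe-style)
#'
#' Robust paired comparison of the dispersions of two conditions: per case,
#' absolute deviations from each condition's median are formed
#' (`|x - median(x)|`, `|y - median(y)|`) and their paired differences are
#' tested with the signed-rank procedure. The statistic is the centred
#' signed-rank sum of `dev_y - dev_x`: positive when condition B is more
#' dispersed, negated when the conditions are swapped. A pure location shift
#' (`y = x + c`) gives identical deviations and is degenerate (p = 1).
#'
#' @param sample a [paired_sample()] with at least 3 cases.
#' @return As [wilcoxon_signed_rank()], plus `dev_x`, `dev_y`.
#' @export
paired_dispersion_test <- function(sample) {
  stopifnot(inherits(sample, "paired_sample"))
  if (length(sample$ids) < 3L) stop("need at least 3 paired cases")
  dev_x <- abs(sample$x - stats::median(sample$x))
  dev_y <- abs(sample$y - stats::median(sample$y))
  res <- wilcoxon_signed_rank(dev_y, dev_x)
  res$dev_x <- dev_x
  res$dev_y <- dev_y
  res
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a blinded, randomised rating manifest
#'
#' Builds the presentation plan for a blinded expert rating study: each rater
#' is shown every (case, contour set) combination exactly once, in an
#' independently randomised order, with contour-set identities replaced by
#' blinded aliases; each presentation collects one rating per level on a
#' continuous 0-100 scale (guidance categories: 0-25 complete recontouring
#' necessary, 26-50 major editing, 51-75 minor editing, >75 clinically
#' usable). Total rating slots = raters x cases x levels x contour sets.
#'
#' @param case_ids,contour_set_ids,levels non-empty vectors of unique ids.
#' @param n_raters positive integer.
#' @param seed integer seed; the same seed reproduces the manifest exactly.
#' @return A `blinded_manifest`: list with `manifest` (data.frame: `rater`,
#'   `presentation`, `case`, `contour_set_alias`, `level`, `rating` = `NA`),
#'   `key` (alias -> true contour set; to be kept from raters), `scale`,
#'   `guidance`, and `seed`.
#' @export
generate_blinded_manifest <- function(case_ids, contour_set_ids, n_raters,
                                      levels, seed) {
  for (v in list(case_ids, contour_set_ids, levels)) {
    if (!length(v)) stop("id lists must be non-empty")
    if (anyDuplicated(v))
      stop("duplicate ids: ", paste(unique(v[duplicated(v)]), collapse = ", "))
  }
  n_raters <- as.integer(n_raters)
  if (is.na(n_raters) || n_raters < 1L) stop("n_raters must be >= 1")
  case_ids <- as.character(case_ids)
  contour_set_ids <- as.character(contour_set_ids)
  levels <- as.character(levels)

  with_seed(seed, {
    aliases <- paste0("set_", seq_along(contour_set_ids))
    key <- data.frame(alias = aliases,
                      contour_set = sample(contour_set_ids),
                      stringsAsFactors = FALSE)
    pres <- expand.grid(case = case_ids, contour_set_alias = aliases,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    parts <- lapply(seq_len(n_raters), function(r) {
      ord <- sample.int(nrow(pres))
      p <- pres[ord, , drop = FALSE]
      data.frame(rater = paste0("rater_", r),
                 presentation = rep(seq_len(nrow(p)), each = length(levels)),
                 case = rep(p$case, each = length(levels)),
                 contour_set_alias = rep(p$contour_set_alias,
                                         each = length(levels)),
                 level = rep(levels, times = nrow(p)),
                 rating = NA_real_,
                 stringsAsFactors = FALSE)
    })
    manifest <- do.call(rbind, parts)
    rownames(manifest) <- NULL
    structure(list(manifest = manifest, key = key,
                   scale = c(0, 100),
                   guidance = c("0-25: complete recontouring necessary",
                                "26-50: major manual editing necessary",
                                "51-75: minor manual editing necessary",
                                ">75: segmentation clinically usable"),
                   seed = seed),
              class = "blinded_manifest")
  })
}

#' @export
print.blinded_manifest <- function(x, ...) {
  m <- x$manifest
  cat("Blinded rating manifest:", nrow(m), "rating slots (",
      length(unique(m$rater)), "raters x", length(unique(m$case)),
      "cases x", length(unique(m$level)), "levels x",
      nrow(x$key), "contour sets ), seed", x$seed, "\n")
  cat("Rating scale:", x$scale[1], "-", x$scale[2], "continuous;",
      "guidance categories:\n")
  for (g in x$guidance) cat("  ", g, "\n")
  invisible(x)
}

#' Summarise blinded ratings
#'
#' Per contour set: case-level means (mean rating per case across raters and
#' levels), then mean, median and interquartile range across cases, plus
#' pairwise paired signed-rank comparisons between contour sets on the case
#' means. No multiple-testing correction is applied (unadjusted p-values).
#'
#' @param ratings data.frame with columns `rater`, `case`,
#'   `contour_set_alias` (or `contour_set`), `level`, `rating`; ratings must
#'   lie in \[0, 100\].
#' @return List with `per_set` (data.frame: set, mean, median, q1, q3, n
#'   cases) and `comparisons` (pairwise signed-rank results on case means).
#' @export
summarize_ratings <- function(ratings) {
  set_col <- if ("contour_set_alias" %in% names(ratings)) "contour_set_alias"
             else "contour_set"
  need <- c("case", set_col, "rating")
  miss <- setdiff(need, names(ratings))
  if (length(miss)) stop("ratings missing column(s): ",
                         paste(miss, collapse = ", "))
  r <- ratings$rating
  if (any(!is.finite(r)) || any(r < 0 | r > 100))
    stop("ratings must be finite and within [0, 100]")

  case_means <- stats::aggregate(ratings$rating,
                                 by = list(set = ratings[[set_col]],
                                           case = ratings$case),
                                 FUN = mean)
  names(case_means)[3] <- "mean_rating"
  sets <- sort(unique(case_means$set))
  per_set <- do.call(rbind, lapply(sets, function(s) {
    v <- case_means$mean_rating[case_means$set == s]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(set = s, mean = mean(v), median = q[2],
               q1 = q[1], q3 = q[3], n_cases = length(v),
               stringsAsFactors = FALSE)
  }))
  comparisons <- NULL
  if (length(sets) >= 2L) {
    combs <- utils::combn(sets, 2L)
    comparisons <- do.call(rbind, lapply(seq_len(ncol(combs)), function(i) {
      a <- combs[1, i]; b <- combs[2, i]
      ca <- case_means[case_means$set == a, ]
      cb <- case_means[case_means$set == b, ]
      common <- intersect(ca$case, cb$case)
      ht <- wilcoxon_signed_rank(
        ca$mean_rating[match(common, ca$case)],
        cb$mean_rating[match(common, cb$case)])
      data.frame(set_a = a, set_b = b,
                 mean_difference = mean(ca$mean_rating[match(common, ca$case)] -
                                          cb$mean_rating[match(common, cb$case)]),
                 statistic = ht$statistic, p.value = ht$p.value,
                 n = ht$n, stringsAsFactors = FALSE)
    }))
  }
  list(per_set = per_set, comparisons = comparisons, case_means = case_means)
}
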