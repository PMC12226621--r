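test_that("mpe vanishes at equality and follows the magnification law", {
  p <- test_phantom()
  g <- p$geom
  base <- p$base
  expect_equal(mpe(base, base, p$vessels, g), 0)
  # detector-parallel translation through the isocenter plane
  for (delta in c(5, 15)) {
    shifted <- rt_compose(rigid_transform(diag(3), c(delta, 0, 0)), base)
    m <- mpe(base, shifted, p$vessels, g)
    pred <- delta * (g$source_to_detector / g$source_to_isocenter) / g$pixel_spacing
    expect_equal(m, pred, tolerance = 0.01 * pred)
    expect_equal(mpe(base, shifted, p$vessels, g, unit = "mm"),
                 m * g$pixel_spacing)
  }
})

test_that("mpe agrees with the homogeneous-projection oracle and is symmetric", {
  p <- test_phantom()
  g <- p$geom
  corners <- vesselreg:::volume_corners(p$vessels)
  set.seed(13)
  for (i in 1:20) {
    A <- rt_compose(p$base, random_pose(0.1, 10))
    B <- rt_compose(p$base, random_pose(0.1, 10))
    m <- mpe(A, B, p$vessels, g)
    ref <- mean(sqrt(rowSums((oracle_project(corners, A, g) -
                              oracle_project(corners, B, g))^2)))
    expect_equal(m, ref, tolerance = 1e-9)
    expect_equal(m, mpe(B, A, p$vessels, g), tolerance = 1e-12)
  }
})

test_that("mpe rejects fiducials behind the source", {
  p <- test_phantom()
  behind <- rigid_transform(diag(3), c(0, 0, -2 * p$geom$source_to_isocenter))
  expect_error(mpe(p$base, behind, p$vessels, p$geom), "behind")
})

test_that("success rates reproduce the reported fractions", {
  set.seed(2)
  vals20 <- c(stats::runif(14, 0, 4.9), stats::runif(6, 5.1, 40))
  expect_equal(success_rate(vals20, 5), 0.70)
  vals94 <- c(stats::runif(37, 0, 4.9), stats::runif(57, 5.1, 60))
  expect_equal(success_rate(vals94, 5), 37 / 94)
  expect_equal(success_rate(c(10, 20), 5), 0)
  expect_error(success_rate(numeric(0), 5), "at least one")
  # monotone in the threshold
  th <- sort(stats::runif(10, 0, 60))
  sr <- vapply(th, function(t) success_rate(vals94, t), 0)
  expect_true(all(diff(sr) >= 0))
})

test_that("equal-count binning splits records as specified", {
  set.seed(10)
  rec100 <- data.frame(mpe_before = stats::runif(100, 0, 60),
                       mpe_after = stats::runif(100, 0, 30))
  h <- capture_range_histogram(rec100, 10)
  expect_equal(h$count, rep(10, 10))
  expect_equal(sum(h$count), 100)
  expect_true(all(diff(h$lo) > 0))
  expect_true(all(h$hi >= h$lo))
  # per-bin medians: no registration effect -> median of the bin's inputs
  rec <- data.frame(mpe_before = 1:20, mpe_after = 1:20)
  h2 <- capture_range_histogram(rec, 4)
  expect_equal(h2$median_after, c(3, 8, 13, 18))
  # 30-record fixture with hand-computed medians, remainder on leading bins
  before <- sample(1:30)
  after <- ifelse(before <= 8, 1, ifelse(before <= 16, 5,
                  ifelse(before <= 23, 2, 10)))
  h3 <- capture_range_histogram(data.frame(mpe_before = before,
                                           mpe_after = after), 4)
  expect_equal(h3$count, c(8, 8, 7, 7))
  expect_equal(h3$lo, c(1, 9, 17, 24))
  expect_equal(h3$hi, c(8, 16, 23, 30))
  expect_equal(h3$median_after, c(1, 5, 2, 10))
  expect_error(capture_range_histogram(rec[1:3, ], 4), "fewer")
})

test_that("divergence point requires all subsequent bins to fail", {
  h <- data.frame(bin = 1:6, lo = c(0, 10, 20, 30, 40, 50),
                  hi = c(9, 19, 29, 39, 49, 59),
                  median_after = c(2, 3, 4, 8, 9, 12), count = 5)
  expect_equal(divergence_point(h, 5), 30)
  h$median_after <- c(2, 3, 4, 3, 2, 1)
  expect_equal(divergence_point(h, 5), Inf)
  # transient spike with recovery is not a divergence
  h$median_after <- c(2, 9, 3, 2, 2, 2)
  expect_equal(divergence_point(h, 5), Inf)
  h$median_after <- c(2, 9, 3, 2, 6, 7)
  expect_equal(divergence_point(h, 5), 40)
})

test_that("preference tallying matches the reading-protocol arithmetic", {
  # 14 registrations x 3 pair types = 42 comparisons
  pair_types <- data.frame(
    left_method = c("three_stage", "three_stage", "two_stage"),
    right_method = c("two_stage", "reference", "reference"))
  records <- do.call(rbind, lapply(1:14, function(i) pair_types))
  set.seed(1)
  records$score <- sample(1:5, 42, replace = TRUE)
  tal <- tally_preferences(records)
  expect_equal(tal$n_comparisons, 42)
  expect_equal(sum(tal$preferred) + tal$ties, 42)
  # all-tie scores: no preferences, tests report no difference
  rec3 <- records; rec3$score <- 3
  tal3 <- tally_preferences(rec3)
  expect_equal(sum(tal3$preferred), 0)
  expect_equal(tal3$ties, 42L)
  expect_true(all(tal3$tests$p_value == 1))
  # totals of 13/9/6 preferences leave 42 - 28 = 14 ties
  expect_equal(42 - (13 + 9 + 6), 14)
  expect_error(tally_preferences(records, methods = c("two_stage", "reference")),
               "unknown")
})

test_that("the exact signed-rank null matches full enumeration for n = 3", {
  x <- c(1.5, -2.5, 3.5)              # distinct magnitudes, ranks 1..3
  res <- signed_rank_test(x)
  # enumerate all 8 sign assignments of ranks {1,2,3}
  sums <- apply(expand.grid(0:1, 0:1, 0:1), 1, function(s) sum(s * 1:3))
  p_exact <- 2 * min(mean(sums <= res$statistic), mean(sums >= res$statistic))
  expect_equal(res$p_value, min(1, p_exact))
  # and against the closed-form null for tie-free data
  set.seed(8)
  y <- stats::rnorm(12)
  ours <- signed_rank_test(y)
  ref <- stats::wilcox.test(y, exact = TRUE)
  expect_equal(ours$statistic, unname(ref$statistic))
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
})
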