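test_that("rigid transforms validate their invariants", {
  expect_error(rigid_transform(matrix(1, 3, 3)), "orthonormal")
  flip <- diag(c(-1, 1, 1))
  expect_error(rigid_transform(flip), "determinant")
  T1 <- rigid_transform(so3_exp(c(0.1, 0.2, 0.3)), c(1, -2, 3))
  expect_lt(max(abs(crossprod(T1$rotation) - diag(3))), 1e-9)
  idy <- rt_compose(T1, rt_invert(T1))
  expect_lt(max(abs(as_matrix(idy) - diag(4))), 1e-9)
})

test_that("composition matches the homogeneous 4x4 matrix product", {
  # identity cases
  T1 <- rigid_transform(so3_exp(c(0.4, -0.2, 0.1)), c(5, 6, -7))
  expect_equal(as_matrix(rt_compose(rt_identity(), T1)), as_matrix(T1))
  # Rz(90) after Rx(90) applied to (1,0,0)
  Rz <- se3_exp(c(0, 0, pi / 2, 0, 0, 0))
  Rx <- se3_exp(c(pi / 2, 0, 0, 0, 0, 0))
  p <- as.numeric(rt_apply(rt_compose(Rz, Rx), c(1, 0, 0)))
  expect_equal(p, c(0, 1, 0), tolerance = 1e-12)
  # brute-force 4x4 product oracle on random pairs
  set.seed(11)
  for (i in 1:20) {
    A <- random_pose(); B <- random_pose()
    expect_equal(as_matrix(rt_compose(A, B)), as_matrix(A) %*% as_matrix(B),
                 tolerance = 1e-12)
  }
})

test_that("exp/log are mutually inverse on the principal branch", {
  expect_equal(as_matrix(se3_exp(numeric(6))), diag(4))
  v <- se3_log(rigid_transform(so3_exp(c(0, 0, 0.3)), c(0, 0, 0)))
  expect_equal(v, c(0, 0, 0.3, 0, 0, 0), tolerance = 1e-12)
  v0 <- c(0.1, 0.2, 0.3, 5, -3, 2)
  expect_lt(max(abs(se3_log(se3_exp(v0)) - v0)), 1e-8)
  # 1000 seeded round trips with rotation magnitude up to 3.0 rad
  set.seed(42)
  worst <- 0
  for (i in 1:1000) {
    w <- stats::rnorm(3); w <- w / sqrt(sum(w^2)) * stats::runif(1, 0, 3.0)
    v <- c(w, stats::rnorm(3, 0, 50))
    worst <- max(worst, max(abs(se3_log(se3_exp(v)) - v)))
  }
  expect_lt(worst, 1e-8)
  expect_error(so3_log(so3_exp(c(pi, 0, 0))), "branch")
})

test_that("geodesic losses match their closed forms", {
  T1 <- rigid_transform(so3_exp(c(0.2, -0.5, 0.3)), c(4, 5, 6))
  expect_equal(geodesic_loss(T1, T1), 0)
  expect_equal(double_geodesic_loss(T1, T1, 1000), 0)
  # translation-only offsets
  T2 <- rigid_transform(T1$rotation, T1$translation + c(3, 4, 0))
  expect_equal(geodesic_loss(T1, T2), 5.0, tolerance = 1e-12)
  T3 <- rigid_transform(T1$rotation, T1$translation + c(0, 0, 7))
  expect_equal(double_geodesic_loss(T1, T3, 123), 7.0, tolerance = 1e-12)
  expect_equal(double_geodesic_loss(T1, T3, 4567), 7.0, tolerance = 1e-12)
  # rotation-only offsets: arccos-of-trace angle, f-scaled for the double loss
  set.seed(3)
  for (i in 1:5) {
    ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
    T4 <- rigid_transform(T1$rotation %*% so3_exp(0.2 * ax), T1$translation)
    expect_equal(geodesic_loss(T1, T4), 0.2, tolerance = 1e-9)
  }
  T5 <- rigid_transform(T1$rotation %*% so3_exp(c(0.01, 0, 0)), T1$translation)
  expect_equal(double_geodesic_loss(T1, T5, 1000), 10.0, tolerance = 1e-6)
  expect_error(double_geodesic_loss(T1, T5, -5), "positive")
})

test_that("losses are symmetric, non-negative, zero only at equality", {
  set.seed(99)
  for (i in 1:100) {
    A <- random_pose(); B <- random_pose()
    g <- geodesic_loss(A, B); g2 <- double_geodesic_loss(A, B, 800)
    expect_gte(g, 0); expect_gte(g2, 0)
    expect_equal(g, geodesic_loss(B, A), tolerance = 1e-12)
    expect_equal(g2, double_geodesic_loss(B, A, 800), tolerance = 1e-12)
    if (g == 0) expect_lt(max(abs(as_matrix(A) - as_matrix(B))), 1e-9)
    # left-invariance of the rotation term: theta depends only on Ra' Rb
    C <- random_pose()
    CA <- rt_compose(C, A); CB <- rt_compose(C, B)
    thetaAB <- geodesic_loss(rigid_transform(A$rotation),
                             rigid_transform(B$rotation))
    thetaCACB <- geodesic_loss(rigid_transform(CA$rotation),
                               rigid_transform(CB$rotation))
    expect_equal(thetaAB, thetaCACB, tolerance = 1e-9)
  }
})

test_that("geodesic loss gradients agree with finite differences", {
  set.seed(8)
  for (i in 1:10) {
    v <- c(stats::rnorm(3, 0, 0.4), stats::rnorm(3, 0, 20))
    tgt <- random_pose()
    for (f in list(NULL, 800)) {
      fn <- function(v) if (is.null(f)) geodesic_loss(se3_exp(v), tgt)
                        else double_geodesic_loss(se3_exp(v), tgt, f)
      ga <- vesselreg:::geodesic_loss_grad(v, tgt, f)
      gfd <- sapply(1:6, function(j) {
        e <- numeric(6); e[j] <- 1e-6
        (fn(v + e) - fn(v - e)) / 2e-6
      })
      expect_equal(ga, gfd, tolerance = 1e-4)
    }
  }
})

test_that("transforms round-trip through text and JSON serialization", {
  T1 <- rigid_transform(so3_exp(c(0.3, 0.1, -0.2)), c(1.5, -2.25, 3.125))
  for (ext in c("txt", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_transform(T1, path)
    T2 <- read_transform(path)
    expect_equal(as_matrix(T2), as_matrix(T1), tolerance = 1e-12)
  }
})
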