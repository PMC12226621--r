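test_that("the phantom is deterministic and respects its parameters", {
  p1 <- generate_vessel_phantom(phantom_params(seed = 9))
  p2 <- generate_vessel_phantom(phantom_params(seed = 9))
  expect_identical(p1$veins$values, p2$veins$values)
  expect_identical(p1$arteries$values, p2$arteries$values)
  p3 <- generate_vessel_phantom(phantom_params(seed = 10))
  expect_false(identical(p1$veins$values, p3$veins$values))
  empty <- generate_vessel_phantom(phantom_params(n_vein_arcs = 0, seed = 1))
  expect_equal(sum(empty$veins$values), 0)
  expect_gt(sum(empty$arteries$values), 0)
})

test_that("default phantom veins form a few large components", {
  ph <- test_phantom()$phantom
  expect_gt(sum(ph$veins$values), 0)
  lab <- label_components(ph$veins)
  largest <- sum(lab == 1)
  expect_gte(largest, 0.5 * sum(ph$veins$values > 0))
  # veins are thicker structures: they survive an opening that would erase
  # the arteries
  expect_gt(sum(isolate_veins(ph$veins, vein_isolation_params(1, 100, 6))$values), 0)
})

test_that("offset sampling is seeded, bounded and centered", {
  p <- offset_sampler_params(seed = 4)
  expect_equal(as_matrix(sample_offset(offset_sampler_params(0, 0))), diag(4))
  expect_equal(as_matrix(sample_offset(p)), as_matrix(sample_offset(p)))
  draws <- sample_offset(offset_sampler_params(c(15, 15, 15), c(30, 30, 30),
                                               seed = 5), n = 1000)
  tang <- t(vapply(draws, se3_log, numeric(6)))
  rot_deg <- tang[, 1:3] * 180 / pi
  expect_true(all(abs(rot_deg) <= 15 + 1e-9))
  expect_true(all(abs(tang[, 4:6]) <= 30 + 1e-9))
  expect_true(all(abs(colMeans(rot_deg)) < 1))
  expect_true(all(apply(rot_deg, 2, max) > 13))   # ranges actually reached
})

test_that("training pairs encode the inverse offset", {
  p <- test_phantom()
  # identity offset: images coincide, target is the identity
  pair0 <- make_training_pair(p$veins, p$base, rt_identity(), p$geom, step = 2.5)
  expect_identical(pair0$fixed$values, pair0$moving$values)
  expect_equal(as_matrix(pair0$target), diag(4))
  set.seed(19)
  for (i in 1:5) {
    off <- sample_offset(offset_sampler_params(seed = 600 + i))
    pair <- make_training_pair(p$veins, p$base, off, p$geom, step = 2.5)
    expect_equal(as_matrix(rt_compose(pair$target, off)), diag(4),
                 tolerance = 1e-9)
    expect_true(all(pair$fixed$values %in% c(0, 1)))
  }
})

test_that("in-plane translation shifts the moving image by the magnification", {
  p <- test_phantom()
  g <- p$geom
  delta <- 12   # mm, in-plane
  off <- rigid_transform(diag(3), c(delta, 0, 0))
  pair <- make_training_pair(p$veins, p$base, off, g, step = 1.25)
  centroid <- function(img) {
    w <- img$values / sum(img$values)
    c(sum(row(img$values) * w), sum(col(img$values) * w))
  }
  shift <- centroid(pair$moving) - centroid(pair$fixed)
  pred_px <- delta * (g$source_to_detector / g$source_to_isocenter) / g$pixel_spacing
  expect_lt(abs(shift[2] - pred_px), 1)
  expect_lt(abs(shift[1]), 1)
})

test_that("image overlap decays with the double-geodesic magnitude of the offset", {
  # in-plane translational offsets: the regime where detector-plane motion
  # (hence overlap) is proportional to the pose distance; depth translation
  # and rotation about the volume center move the silhouette far less than
  # their f-scaled geodesic magnitude suggests
  p <- test_phantom()
  f <- p$geom$source_to_detector
  set.seed(23)
  d <- g2 <- numeric(0)
  for (i in 1:50) {
    off <- sample_offset(offset_sampler_params(c(0, 0, 0), c(20, 20, 0),
                                               seed = 800 + i))
    pair <- tryCatch(make_training_pair(p$veins, p$base, off, p$geom, step = 2.5),
                     vesselreg_allzero_drr = function(e) NULL)
    if (is.null(pair)) next
    d <- c(d, dice_coef(pair$fixed, pair$moving))
    g2 <- c(g2, double_geodesic_loss(rt_identity(), off, f))
  }
  expect_gt(length(d), 40)
  expect_lt(stats::cor(d, g2, method = "spearman"), -0.5)
})

test_that("minip is the pointwise minimum and single frames pass through", {
  f1 <- projection_2d(matrix(3, 4, 4), 1)
  f2 <- projection_2d(matrix(1, 4, 4), 1)
  f3 <- projection_2d(matrix(2, 4, 4), 1)
  m <- minip(list(f1, f2, f3))
  expect_equal(m$values, matrix(1, 4, 4))
  expect_equal(m$kind, "minip")
  expect_equal(minip(list(f1))$values, f1$values)
  set.seed(3)
  fr <- lapply(1:4, function(i) projection_2d(matrix(stats::runif(16), 4, 4), 1))
  mm <- minip(fr)$values
  for (f in fr) expect_true(all(mm <= f$values + 1e-15))
  expect_error(minip(list()), "at least one")
  expect_error(minip(list(f1, projection_2d(matrix(1, 3, 3), 1))), "shape")
})

test_that("synthetic DSA frames reconstruct the vessel image in the MinIP", {
  p <- test_phantom()
  frames <- make_synthetic_dsa(p$vessels, p$base, p$geom, n_frames = 5, seed = 2)
  m <- minip(frames)
  drr <- render_drr(p$vessels, p$base, p$geom)
  expect_lt(ncc(m$values, drr$values), -0.99)  # inverted contrast
})

test_that("binarization follows the strict-threshold contract", {
  img <- projection_2d(matrix(c(0, 5, 2, 0), 2, 2), 1)
  expect_equal(binarize(img, 1)$values, matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(sum(binarize(img, max(img$values))$values), 0)
  z <- projection_2d(matrix(0, 3, 3), 1)
  expect_equal(sum(binarize(z, 0)$values), 0)
})
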