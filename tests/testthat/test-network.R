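tiny_cfg <- function(...) init_net_config(backbone = "tiny", input_size = 32,
                                          seed = 5, ...)

test_that("the composite loss combines Dice and geodesic terms as specified", {
  T1 <- se3_exp(c(0.1, 0, 0, 5, 0, 0))
  img <- projection_2d(matrix(c(1, 1, 0, 0), 2, 2), 1)
  # perfect pose and perfect overlap
  expect_equal(composite_loss(T1, T1, img, img, 1000, 0.1), 0, tolerance = 1e-6)
  # equal-area masks with 50% intersection at matched pose: Dice loss 0.5
  other <- projection_2d(matrix(c(1, 0, 1, 0), 2, 2), 1)
  expect_equal(composite_loss(T1, T1, img, other, 1000, 0.1), 0.5,
               tolerance = 1e-6)
  # lambda = 0 reduces to the Dice term alone
  T2 <- se3_exp(c(0.2, 0, 0, -5, 3, 0))
  expect_equal(composite_loss(T1, T2, img, other, 1000, 0),
               dice_loss(img, other))
  # lambda weighting matches its closed form
  expect_equal(composite_loss(T1, T2, img, other, 800, 0.25),
               dice_loss(img, other) +
                 0.25 * (double_geodesic_loss(T1, T2, 800) +
                         geodesic_loss(T1, T2)))
})

test_that("network initialization is seeded and zero-epoch training is a no-op", {
  n1 <- init_network(tiny_cfg())
  n2 <- init_network(tiny_cfg())
  expect_identical(n1$params, n2$params)
  p <- test_phantom()
  pair <- make_training_pair(p$veins, p$base, rt_identity(), p$geom, step = 2.5)
  net <- train_init_network(list(pair), tiny_cfg(epochs = 0), p$geom, p$veins)
  expect_identical(net$params, init_network(tiny_cfg(epochs = 0))$params)
  expect_length(net$history, 0)
})

test_that("an untrained (zero-headed) network returns the base pose", {
  p <- test_phantom()
  net <- init_network(tiny_cfg())
  drr <- render_drr(p$veins, p$base, p$geom, step = 2.5)
  dsa <- binarize(drr, 1e-6 * max(drr$values))
  pose <- predict_initial_pose(net, p$veins, dsa, p$base, p$geom)
  expect_equal(as_matrix(pose), as_matrix(p$base), tolerance = 1e-12)
  # a perturbed network still returns a finite valid transform
  net$params[["head.rot.W"]][] <- stats::rnorm(length(net$params[["head.rot.W"]]))
  net$params[["head.trans.W"]][] <- stats::rnorm(length(net$params[["head.trans.W"]]))
  pose2 <- predict_initial_pose(net, p$veins, dsa, p$base, p$geom)
  expect_true(all(is.finite(as_matrix(pose2))))
  expect_error(predict_initial_pose(net, p$veins,
                                    projection_2d(drr$values, p$geom$pixel_spacing),
                                    p$base, p$geom), "binary")
})

test_that("network backpropagation matches finite differences", {
  cfg <- tiny_cfg()
  net <- init_network(cfg)
  # give the heads nonzero weights so gradients flow into the backbone
  set.seed(2)
  net$params[["head.rot.W"]][] <- stats::rnorm(length(net$params[["head.rot.W"]]), 0, 0.1)
  net$params[["head.trans.W"]][] <- stats::rnorm(length(net$params[["head.trans.W"]]), 0, 0.1)
  x <- array(stats::runif(32 * 32 * 2), c(32, 32, 2))
  dv <- stats::rnorm(6)
  fw <- vesselreg:::net_forward(net, x, want_cache = TRUE)
  grads <- vesselreg:::net_backward(net, fw, dv)
  loss_of <- function(net) sum(vesselreg:::net_forward(net, x)$v * dv)
  for (nm in c("stem.W", "s1.down.c1.W", "s2.down.proj.W", "head.rot.W",
               "s2.down.c2.b")) {
    gp <- grads[[nm]]
    idx <- sample(length(gp), min(4, length(gp)))
    for (i in idx) {
      e <- net; e$params[[nm]][i] <- e$params[[nm]][i] + 1e-5
      e2 <- net; e2$params[[nm]][i] <- e2$params[[nm]][i] - 1e-5
      fd <- (loss_of(e) - loss_of(e2)) / 2e-5
      expect_equal(unname(gp[i]), fd, tolerance = 1e-4)
    }
  }
})

test_that("a short training run decreases the loss and is reproducible", {
  p <- test_phantom()
  g <- phantom_geometry(48, 4)      # small detector for speed
  base <- radiological_pose(g)
  pairs <- make_training_set(p$veins, base, 6,
                             offset_sampler_params(seed = 31), g, step = 2.5)
  cfg <- tiny_cfg(epochs = 6, learning_rate = 5e-3, render_step = 2.5,
                  batch_size = 3)
  net <- train_init_network(pairs, cfg, g, p$veins)
  expect_length(net$history, 6)
  expect_lt(net$history[6], net$history[1])
  net2 <- train_init_network(pairs, cfg, g, p$veins)
  expect_identical(net$params, net2$params)
  # lambda enters only through the loss: same seed, same data order
  cfg0 <- tiny_cfg(epochs = 1, lambda_weight = 0, render_step = 2.5,
                   batch_size = 3)
  net0 <- train_init_network(pairs, cfg0, g, p$veins)
  expect_false(identical(net0$params, net$params))
})

test_that("memorizing a single pair lets the network undo its offset", {
  p <- test_phantom()
  g <- phantom_geometry(64, 3)
  base <- radiological_pose(g)
  off <- sample_offset(offset_sampler_params(seed = 21))
  pair <- make_training_pair(p$veins, base, off, g, step = 2.5)
  cfg <- init_net_config(backbone = "tiny", input_size = 64, epochs = 60,
                         learning_rate = 5e-3, seed = 5, render_step = 2.5,
                         batch_size = 1)
  net <- train_init_network(list(pair), cfg, g, p$veins)
  expect_lt(utils::tail(net$history, 1), 0.25 * net$history[1])
  # inference on the memorized configuration: DSA at the registered pose,
  # starting from the perturbed pose, must move back toward the target
  start <- pair$moving_pose
  truth <- base
  t_init <- predict_initial_pose(net, p$veins, pair$fixed, start, g)
  m_before <- mpe(truth, start, p$vessels, g)
  m_after <- mpe(truth, t_init, p$vessels, g)
  expect_lt(m_after, m_before)
})

test_that("checkpoints round-trip through disk", {
  net <- init_network(tiny_cfg())
  net$history <- c(1, 0.5)
  path <- withr::local_tempfile(fileext = ".rds")
  save_network(net, path)
  net2 <- load_network(path)
  expect_identical(net2$params, net$params)
  expect_identical(net2$history, net$history)
  expect_identical(unclass(net2$config), unclass(net$config))
})
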