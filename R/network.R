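# ---- initialization network ------------------------------------------------
#
# A small residual CNN regresses the 6 pose tangent parameters (axis-angle
# rotation, translation) from a 2-channel (moving DRR, fixed DSA) image pair.
# Convolutions are evaluated as im2col + BLAS matrix products with manual
# backpropagation; no external deep-learning runtime is used.

#' Configuration of the initialization network
#'
#' @param backbone \code{"resnet18"} (default: an 18-layer residual CNN),
#'   \code{"resnet10"} or \code{"tiny"}; smaller backbones are intended for
#'   CPU-scale smoke training.
#' @param input_size square input side in pixels (>= 32); mismatched images
#'   are resampled bilinearly (binary inputs re-binarized at 0.5).
#' @param lambda_weight weight of the geodesic loss terms in the composite
#'   training objective.
#' @param learning_rate Adam step size.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param seed integer seed controlling initialization and data order.
#' @param rot_scale,trans_scale fixed output scales applied to the raw
#'   rotation (radians) and translation (mm) heads.
#' @param render_step renderer step (mm) used for the differentiable re-render
#'   of the moving DRR during training.
#' @param soft_kappa softness (mm of integrated path) of the saturating map
#'   \code{1 - exp(-drr / soft_kappa)} that stands in for binarization on the
#'   differentiable path.
#' @return An object of class \code{init_net_config}.
#' @export
init_net_config <- function(backbone = "resnet18", input_size = 64,
                            lambda_weight = 0.1, learning_rate = 1e-3,
                            epochs = 10, batch_size = 8, seed = 1L,
                            rot_scale = 0.3, trans_scale = 40,
                            render_step = NULL, soft_kappa = 1.0) {
  stopifnot(lambda_weight >= 0, input_size >= 32)
  structure(list(backbone = backbone, input_size = as.integer(input_size),
                 lambda_weight = lambda_weight, learning_rate = learning_rate,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 seed = as.integer(seed), rot_scale = rot_scale,
                 trans_scale = trans_scale, render_step = render_step,
                 soft_kappa = soft_kappa),
            class = "init_net_config")
}

backbone_spec <- function(name) {
  switch(name,
    tiny = list(stem = 8, stages = list(c(w = 16, n = 1), c(w = 32, n = 1))),
    resnet10 = list(stem = 16, stages = list(c(w = 32, n = 1), c(w = 64, n = 1),
                                             c(w = 128, n = 1))),
    resnet18 = list(stem = 64, stages = list(c(w = 64, n = 2), c(w = 128, n = 2),
                                             c(w = 256, n = 2), c(w = 512, n = 2))),
    stop("unknown backbone: ", name))
}

# ---- im2col convolution primitives ----------------------------------------

.im2col_cache <- new.env(parent = emptyenv())

im2col_idx <- function(H, W, C, k, stride, pad) {
  key <- paste(H, W, C, k, stride, pad, sep = "_")
  hit <- .im2col_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2 * pad; Wp <- W + 2 * pad
  Ho <- (Hp - k) %/% stride + 1L; Wo <- (Wp - k) %/% stride + 1L
  base_r <- rep(seq(0L, by = stride, length.out = Ho), times = Wo)
  base_c <- rep(seq(0L, by = stride, length.out = Wo), each = Ho)
  cols <- vector("list", k * k * C)
  i <- 0L
  for (ch in 0:(C - 1)) for (dc in 0:(k - 1)) for (dr in 0:(k - 1)) {
    i <- i + 1L
    cols[[i]] <- (base_r + dr) + Hp * (base_c + dc) + Hp * Wp * ch + 1L
  }
  idx <- do.call(cbind, cols)
  out <- list(idx = idx, Ho = Ho, Wo = Wo, Hp = Hp, Wp = Wp)
  .im2col_cache[[key]] <- out
  out
}

pad_input <- function(x, pad) {
  if (pad == 0) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  xp
}

conv_fw <- function(x, W, b, stride, pad) {
  d <- dim(x)
  k <- attr(W, "k")
  ii <- im2col_idx(d[1], d[2], d[3], k, stride, pad)
  xp <- pad_input(x, pad)
  xcol <- matrix(xp[ii$idx], nrow = nrow(ii$idx))
  y <- xcol %*% W
  y <- sweep(y, 2, b, "+")
  list(y = array(y, c(ii$Ho, ii$Wo, ncol(W))),
       cache = list(xcol = xcol, ii = ii, dims = d, stride = stride, pad = pad))
}

conv_bw <- function(cache, dy, W) {
  dYm <- matrix(dy, ncol = dim(dy)[3])
  dW <- crossprod(cache$xcol, dYm)
  db <- colSums(dYm)
  dxcol <- tcrossprod(dYm, W)
  ii <- cache$ii
  dxp <- numeric(ii$Hp * ii$Wp * cache$dims[3])
  for (j in seq_len(ncol(ii$idx))) {
    tgt <- ii$idx[, j]
    dxp[tgt] <- dxp[tgt] + dxcol[, j]
  }
  dxp <- array(dxp, c(ii$Hp, ii$Wp, cache$dims[3]))
  p <- cache$pad
  dx <- if (p > 0) dxp[p + seq_len(cache$dims[1]), p + seq_len(cache$dims[2]), ,
                       drop = FALSE]
        else dxp
  list(dx = dx, dW = dW, db = db)
}

make_conv_param <- function(k, cin, cout, scale = 1) {
  W <- matrix(stats::rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))) * scale,
              k * k * cin, cout)
  attr(W, "k") <- k
  W
}

# ---- network construction --------------------------------------------------

build_arch <- function(config) {
  spec <- backbone_spec(config$backbone)
  blocks <- list(list(kind = "stem", name = "stem", cin = 2, cout = spec$stem,
                      stride = 2L))
  cin <- spec$stem
  for (s in seq_along(spec$stages)) {
    w <- spec$stages[[s]]["w"]; nblk <- spec$stages[[s]]["n"]
    blocks[[length(blocks) + 1L]] <-
      list(kind = "down", name = sprintf("s%d.down", s), cin = cin, cout = w,
           stride = 2L)
    if (nblk > 1) for (b in 2:nblk)
      blocks[[length(blocks) + 1L]] <-
        list(kind = "res", name = sprintf("s%d.b%d", s, b), cin = w, cout = w,
             stride = 1L)
    cin <- w
  }
  list(blocks = blocks, feat = cin)
}

#' Initialize the pose-regression network
#'
#' Weights use He initialization; the second convolution of every residual
#' block is down-scaled so each block starts near the identity, and the two
#' output heads are zero-initialized so an untrained network predicts the
#' zero tangent vector (i.e. returns the base pose unchanged).
#'
#' @param config An \code{init_net_config}.
#' @return An object of class \code{init_network}.
#' @export
init_network <- function(config = init_net_config()) {
  arch <- build_arch(config)
  params <- list()
  withr::with_seed(config$seed, {
    for (blk in arch$blocks) {
      nm <- blk$name
      if (blk$kind == "stem") {
        params[[paste0(nm, ".W")]] <- make_conv_param(3, blk$cin, blk$cout)
        params[[paste0(nm, ".b")]] <- numeric(blk$cout)
      } else {
        params[[paste0(nm, ".c1.W")]] <- make_conv_param(3, blk$cin, blk$cout)
        params[[paste0(nm, ".c1.b")]] <- numeric(blk$cout)
        params[[paste0(nm, ".c2.W")]] <- make_conv_param(3, blk$cout, blk$cout,
                                                         scale = 0.1)
        params[[paste0(nm, ".c2.b")]] <- numeric(blk$cout)
        if (blk$kind == "down") {
          params[[paste0(nm, ".proj.W")]] <- make_conv_param(1, blk$cin, blk$cout)
          params[[paste0(nm, ".proj.b")]] <- numeric(blk$cout)
        }
      }
    }
    params[["head.rot.W"]] <- matrix(0, arch$feat, 3)
    params[["head.rot.b"]] <- numeric(3)
    params[["head.trans.W"]] <- matrix(0, arch$feat, 3)
    params[["head.trans.b"]] <- numeric(3)
  })
  structure(list(config = config, arch = arch, params = params),
            class = "init_network")
}

net_forward <- function(net, x, want_cache = FALSE) {
  p <- net$params
  caches <- list()
  for (blk in net$arch$blocks) {
    nm <- blk$name
    if (blk$kind == "stem") {
      cf <- conv_fw(x, p[[paste0(nm, ".W")]], p[[paste0(nm, ".b")]],
                    blk$stride, 1)
      y <- pmax(cf$y, 0)
      if (want_cache) caches[[nm]] <- list(conv = cf$cache, mask = cf$y > 0)
      x <- y
    } else {
      c1 <- conv_fw(x, p[[paste0(nm, ".c1.W")]], p[[paste0(nm, ".c1.b")]],
                    blk$stride, 1)
      h1 <- pmax(c1$y, 0)
      c2 <- conv_fw(h1, p[[paste0(nm, ".c2.W")]], p[[paste0(nm, ".c2.b")]], 1, 1)
      skip <- if (blk$kind == "down") {
        pr <- conv_fw(x, p[[paste0(nm, ".proj.W")]], p[[paste0(nm, ".proj.b")]],
                      blk$stride, 0)
        pr
      } else NULL
      z <- c2$y + if (is.null(skip)) x else skip$y
      y <- pmax(z, 0)
      if (want_cache)
        caches[[nm]] <- list(c1 = c1$cache, m1 = c1$y > 0, c2 = c2$cache,
                             proj = if (!is.null(skip)) skip$cache,
                             mz = z > 0)
      x <- y
    }
  }
  feat <- apply(x, 3, mean)                      # global average pooling
  rot_raw <- as.numeric(crossprod(p[["head.rot.W"]], feat)) + p[["head.rot.b"]]
  trans_raw <- as.numeric(crossprod(p[["head.trans.W"]], feat)) + p[["head.trans.b"]]
  v <- c(rot_raw * net$config$rot_scale, trans_raw * net$config$trans_scale)
  out <- list(v = v, feat = feat, last = x)
  if (want_cache) out$caches <- caches
  out
}

net_backward <- function(net, fw, dv) {
  p <- net$params
  grads <- list()
  drot <- dv[1:3] * net$config$rot_scale
  dtrans <- dv[4:6] * net$config$trans_scale
  grads[["head.rot.W"]] <- outer(fw$feat, drot)
  grads[["head.rot.b"]] <- drot
  grads[["head.trans.W"]] <- outer(fw$feat, dtrans)
  grads[["head.trans.b"]] <- dtrans
  dfeat <- as.numeric(p[["head.rot.W"]] %*% drot + p[["head.trans.W"]] %*% dtrans)
  d <- dim(fw$last)
  dx <- array(rep(dfeat / (d[1] * d[2]), each = d[1] * d[2]), d)
  for (blk in rev(net$arch$blocks)) {
    nm <- blk$name
    cc <- fw$caches[[nm]]
    if (blk$kind == "stem") {
      dy <- dx * cc$mask
      bw <- conv_bw(cc$conv, dy, p[[paste0(nm, ".W")]])
      grads[[paste0(nm, ".W")]] <- bw$dW
      grads[[paste0(nm, ".b")]] <- bw$db
      dx <- bw$dx
    } else {
      dz <- dx * cc$mz
      b2 <- conv_bw(cc$c2, dz, p[[paste0(nm, ".c2.W")]])
      grads[[paste0(nm, ".c2.W")]] <- b2$dW
      grads[[paste0(nm, ".c2.b")]] <- b2$db
      dh1 <- b2$dx * cc$m1
      b1 <- conv_bw(cc$c1, dh1, p[[paste0(nm, ".c1.W")]])
      grads[[paste0(nm, ".c1.W")]] <- b1$dW
      grads[[paste0(nm, ".c1.b")]] <- b1$db
      if (blk$kind == "down") {
        bp <- conv_bw(cc$proj, dz, p[[paste0(nm, ".proj.W")]])
        grads[[paste0(nm, ".proj.W")]] <- bp$dW
        grads[[paste0(nm, ".proj.b")]] <- bp$db
        dx <- b1$dx + bp$dx
      } else {
        dx <- b1$dx + dz
      }
    }
  }
  grads
}

# ---- Adam ------------------------------------------------------------------

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_update <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    upd <- lr * mh / (sqrt(vh) + eps)
    attrs <- attributes(params[[nm]])
    params[[nm]] <- params[[nm]] - upd
    attributes(params[[nm]]) <- attrs
  }
  list(params = params, state = state)
}

# ---- composite training loss -----------------------------------------------

#' Composite pose-and-overlap training loss
#'
#' \code{DiceLoss(moving_rendered, fixed) + lambda (Lgeo2(pred, target; f) +
#' Lgeo(pred, target))}: the Dice term scores the overlap of the moving DRR
#' re-rendered at the predicted pose against the fixed image, while the two
#' geodesic terms supervise the pose directly (the double geodesic converts
#' rotational error to detector millimetres through \code{f}).
#'
#' @param pred,target \code{rigid_transform}s (prediction and ground truth).
#' @param moving_rendered \code{projection_2d}: DRR rendered at the predicted
#'   pose.
#' @param fixed \code{projection_2d}: the fixed (DSA-like) image.
#' @param f source-to-detector distance (mm).
#' @param lambda_weight non-negative geodesic weight.
#' @return Non-negative scalar.
#' @export
composite_loss <- function(pred, target, moving_rendered, fixed, f,
                           lambda_weight) {
  stopifnot(lambda_weight >= 0)
  dice_loss(moving_rendered, fixed) +
    lambda_weight * (double_geodesic_loss(pred, target, f) +
                     geodesic_loss(pred, target))
}

# ---- image resampling ------------------------------------------------------

#' Bilinear image resize
#'
#' @param values numeric matrix.
#' @param out_rows,out_cols target size.
#' @param rebinarize threshold the result at 0.5 (for binary inputs).
#' @return Resized matrix.
#' @export
resize_image <- function(values, out_rows, out_cols, rebinarize = FALSE) {
  H <- nrow(values); W <- ncol(values)
  r <- (seq_len(out_rows) - 0.5) / out_rows * H - 0.5
  c <- (seq_len(out_cols) - 0.5) / out_cols * W - 0.5
  r0 <- clamp(floor(r), 0, H - 1); c0 <- clamp(floor(c), 0, W - 1)
  r1 <- pmin(r0 + 1, H - 1); c1 <- pmin(c0 + 1, W - 1)
  fr <- clamp(r - r0, 0, 1); fc <- clamp(c - c0, 0, 1)
  v00 <- values[cbind(rep(r0 + 1, length(c0)), rep(c0 + 1, each = length(r0)))]
  v10 <- values[cbind(rep(r1 + 1, length(c0)), rep(c0 + 1, each = length(r0)))]
  v01 <- values[cbind(rep(r0 + 1, length(c1)), rep(c1 + 1, each = length(r0)))]
  v11 <- values[cbind(rep(r1 + 1, length(c1)), rep(c1 + 1, each = length(r0)))]
  FR <- rep(fr, length(c0)); FC <- rep(fc, each = length(r0))
  out <- matrix((1 - FR) * (1 - FC) * v00 + FR * (1 - FC) * v10 +
                (1 - FR) * FC * v01 + FR * FC * v11, out_rows, out_cols)
  if (rebinarize) out <- (out > 0.5) * 1
  out
}

net_input <- function(net, moving, fixed) {
  s <- net$config$input_size
  mv <- as_values(moving); fx <- as_values(fixed)
  bin <- all(mv %in% c(0, 1)) && all(fx %in% c(0, 1))
  if (!all(dim(mv) == c(s, s))) mv <- resize_image(mv, s, s, rebinarize = bin)
  if (!all(dim(fx) == c(s, s))) fx <- resize_image(fx, s, s, rebinarize = bin)
  array(c(mv, fx), c(s, s, 2))
}

# ---- training --------------------------------------------------------------

#' Train the initialization network on synthetic pairs
#'
#' Minibatch Adam on the composite loss. For every sample the moving DRR is
#' re-rendered at the currently predicted pose through the differentiable
#' renderer (saturated by \code{1 - exp(-drr/kappa)} as a smooth stand-in for
#' binarization), so the Dice term backpropagates through the rendering into
#' the pose prediction; the geodesic terms are differentiated in closed form.
#'
#' @param pairs list of training pairs from \code{\link{make_training_set}}.
#' @param config An \code{init_net_config}.
#' @param geom A \code{carm_geometry}.
#' @param volume binary \code{volume_grid} of the vein mask used to re-render
#'   moving DRRs.
#' @return An \code{init_network} with a \code{history} field holding the
#'   per-epoch mean composite loss.
#' @export
train_init_network <- function(pairs, config, geom, volume) {
  stopifnot(length(pairs) >= 1)
  net <- init_network(config)
  net$history <- numeric(0)
  if (config$epochs == 0L) return(net)
  f <- geom$source_to_detector
  lam <- config$lambda_weight
  kap <- config$soft_kappa
  rstep <- config$render_step %||% (min(volume_spacing(volume)) / 2)
  state <- adam_state(net$params)
  withr::with_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(length(pairs))
      ep_losses <- numeric(0)
      for (start in seq(1, length(ord), by = config$batch_size)) {
        bidx <- ord[start:min(start + config$batch_size - 1L, length(ord))]
        grads_sum <- NULL
        for (i in bidx) {
          pair <- pairs[[i]]
          x <- net_input(net, pair$moving, pair$fixed)
          fw <- net_forward(net, x, want_cache = TRUE)
          v <- fw$v
          pred <- se3_exp(v)
          drr <- render_drr(volume, rt_compose(pair$moving_pose, pred), geom,
                            step = rstep)
          soft <- 1 - exp(-drr$values / kap)
          dg <- dice_loss_with_grad(soft, as_values(pair$fixed))
          loss <- dg$value + lam * (double_geodesic_loss(pred, pair$target, f) +
                                    geodesic_loss(pred, pair$target))
          if (!is.finite(loss))
            stop("non-finite training loss at epoch ", ep,
                 " (sample ", i, "); prediction v = ",
                 paste(signif(v, 4), collapse = ", "))
          ep_losses <- c(ep_losses, loss)
          d_drr <- dg$grad * exp(-drr$values / kap) / kap
          gv <- drr_pose_gradient(volume, pair$moving_pose, v, geom, d_drr,
                                  step = rstep)
          gv <- gv + lam * (geodesic_loss_grad(v, pair$target, f) +
                            geodesic_loss_grad(v, pair$target))
          g <- net_backward(net, fw, gv)
          grads_sum <- if (is.null(grads_sum)) g
                       else mapply(function(a, b) a + b, grads_sum, g,
                                   SIMPLIFY = FALSE)
        }
        grads_sum <- lapply(grads_sum, function(g) g / length(bidx))
        upd <- adam_update(net$params, grads_sum, state, config$learning_rate)
        net$params <- upd$params
        state <- upd$state
      }
      net$history <- c(net$history, mean(ep_losses))
    }
  })
  net
}

#' Predict the initial pose for a CTA/DSA pair
#'
#' Renders the binarized vein DRR at the base (radiological) pose, feeds the
#' (moving, fixed) pair through the network, interprets the 6-vector output
#' as a pose tangent and returns \code{base_pose} composed with its
#' exponential: the initial pose of the multistage pipeline.
#'
#' @param network trained \code{init_network}.
#' @param volume_veins binary \code{volume_grid} of the CTA vein mask.
#' @param fixed binary \code{projection_2d}: the DSA vein segmentation.
#' @param base_pose A \code{rigid_transform} (the radiological pose).
#' @param geom A \code{carm_geometry}.
#' @return A \code{rigid_transform}.
#' @export
predict_initial_pose <- function(network, volume_veins, fixed, base_pose, geom) {
  stopifnot(inherits(network, "init_network"))
  if (!all(as_values(fixed) %in% c(0, 1)))
    stop("fixed image must be a binary vein segmentation")
  drr <- render_drr(volume_veins, base_pose, geom,
                    step = network$config$render_step %||%
                      (min(volume_spacing(volume_veins)) / 2))
  moving <- binarize(drr, 1e-6 * max(drr$values))
  x <- net_input(network, moving, fixed)
  v <- net_forward(network, x)$v
  rt_compose(base_pose, se3_exp(v))
}

#' Save / load network weights
#'
#' Checkpoints are R serialization files holding the configuration and the
#' parameter list.
#'
#' @param network An \code{init_network}.
#' @param path checkpoint file path (\code{.rds}).
#' @return \code{load_network} returns an \code{init_network}.
#' @export
save_network <- function(network, path) {
  saveRDS(list(config = network$config, params = network$params,
               history = network$history), path)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  obj <- readRDS(path)
  net <- init_network(obj$config)
  net$params <- obj$params
  net$history <- obj$history
  net
}
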