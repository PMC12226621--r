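# Independent oracles and shared fixtures, written in plain (vectorized) R
# and deliberately not reusing the package's computational paths.

# Brute-force fine-step ray integrator over the trilinearly interpolated
# volume: the reference for render_drr.
oracle_drr <- function(volume, pose, geom, nsub = 96) {
  d <- dim(volume$values)
  w2v <- solve(volume$voxel_to_world)
  f <- geom$source_to_detector; di <- geom$source_to_isocenter
  ps <- geom$pixel_spacing; pp <- geom$principal_point
  S <- c(0, 0, -di)
  out <- matrix(0, geom$detector_rows, geom$detector_cols)
  corners_h <- cbind(as.matrix(expand.grid(i = c(0, d[1] - 1), j = c(0, d[2] - 1),
                                           k = c(0, d[3] - 1))), 1)
  cw_all <- corners_h %*% t(volume$voxel_to_world)
  cw <- colMeans(cw_all)[1:3]
  rad <- sqrt(max(rowSums(sweep(cw_all[, 1:3, drop = FALSE], 2, cw)^2)))
  rad <- rad + 2 * max(sqrt(colSums(volume$voxel_to_world[1:3, 1:3]^2)))
  cc <- as.numeric(pose$rotation %*% cw + pose$translation)
  step <- min(sqrt(colSums(volume$voxel_to_world[1:3, 1:3]^2))) / nsub
  for (r in seq_len(geom$detector_rows)) {
    for (cl in seq_len(geom$detector_cols)) {
      P <- c((cl - 1 - pp[2]) * ps, (r - 1 - pp[1]) * ps, f - di)
      D <- P - S; dir <- D / sqrt(sum(D^2))
      tc <- sum(dir * (cc - S))
      t0 <- max(1e-6, tc - rad); t1 <- tc + rad
      if (t1 <= t0) next
      n <- ceiling((t1 - t0) / step); h <- (t1 - t0) / n
      tt <- t0 + (seq_len(n) - 0.5) * h
      Xc <- cbind(S[1] + tt * dir[1], S[2] + tt * dir[2], S[3] + tt * dir[3])
      Xw <- sweep(Xc, 2, pose$translation) %*% pose$rotation
      Vx <- Xw %*% t(w2v[1:3, 1:3])
      Vx <- sweep(Vx, 2, -w2v[1:3, 4])
      out[r, cl] <- h * sum(oracle_trilinear(volume$values, Vx))
    }
  }
  out
}

oracle_trilinear <- function(vals, vx) {
  d <- dim(vals)
  i0 <- floor(vx[, 1]); j0 <- floor(vx[, 2]); k0 <- floor(vx[, 3])
  fx <- vx[, 1] - i0; fy <- vx[, 2] - j0; fz <- vx[, 3] - k0
  gv <- function(ii, jj, kk) {
    ok <- ii >= 0 & ii < d[1] & jj >= 0 & jj < d[2] & kk >= 0 & kk < d[3]
    v <- numeric(length(ii))
    v[ok] <- vals[ii[ok] + d[1] * jj[ok] + d[1] * d[2] * kk[ok] + 1]
    v
  }
  gv(i0, j0, k0) * (1 - fx) * (1 - fy) * (1 - fz) +
    gv(i0 + 1, j0, k0) * fx * (1 - fy) * (1 - fz) +
    gv(i0, j0 + 1, k0) * (1 - fx) * fy * (1 - fz) +
    gv(i0 + 1, j0 + 1, k0) * fx * fy * (1 - fz) +
    gv(i0, j0, k0 + 1) * (1 - fx) * (1 - fy) * fz +
    gv(i0 + 1, j0, k0 + 1) * fx * (1 - fy) * fz +
    gv(i0, j0 + 1, k0 + 1) * (1 - fx) * fy * fz +
    gv(i0 + 1, j0 + 1, k0 + 1) * fx * fy * fz
}

# Explicit homogeneous-matrix projection of world points, independent of
# project_points.
oracle_project <- function(pts, pose, geom) {
  m <- diag(4); m[1:3, 1:3] <- pose$rotation; m[1:3, 4] <- pose$translation
  ph <- cbind(pts, 1) %*% t(m)
  denom <- ph[, 3] + geom$source_to_isocenter
  f <- geom$source_to_detector
  cbind(row = (f * ph[, 2] / denom) / geom$pixel_spacing + geom$principal_point[1],
        col = (f * ph[, 1] / denom) / geom$pixel_spacing + geom$principal_point[2])
}

# Random rotation via QR decomposition (independent of so3_exp).
oracle_random_rotation <- function() {
  qr_d <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

random_pose <- function(rot_sd = 0.3, trans_sd = 10) {
  se3_exp(c(stats::rnorm(3, 0, rot_sd), stats::rnorm(3, 0, trans_sd)))
}

# A small smooth (non-binary) phantom for gradient checks.
smooth_phantom <- function(n = 32, spacing = 4.5) {
  ax <- seq(-1, 1, length.out = n)
  gg <- expand.grid(x = ax, y = ax, z = ax)
  vals <- array(exp(-4 * (gg$x^2 + gg$y^2 + gg$z^2)) *
                  (1 + 0.5 * sin(3 * gg$x) * cos(2 * gg$y)), c(n, n, n))
  volume_grid(vals, spacing = rep(spacing, 3))
}

# Cached phantom + geometry shared by the heavier tests.
test_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ph <- generate_vessel_phantom(phantom_params(seed = 3))
      cache <<- list(phantom = ph, veins = ph$veins,
                     vessels = full_vessel_mask(ph),
                     geom = phantom_geometry(),
                     base = radiological_pose(phantom_geometry()))
    }
    cache
  }
})

# Draw an offset from `sampler_seed` streams until the pre-registration MPE
# (pixels) falls inside [lo, hi]; returns the offset and the true pose.
offset_with_mpe <- function(base, volume, geom, lo, hi, seed,
                            rot = c(5, 5, 5), trans = c(30, 30, 30)) {
  k <- 0L
  repeat {
    k <- k + 1L
    off <- sample_offset(offset_sampler_params(rotation_range = rot,
                                               translation_range = trans,
                                               seed = seed * 1000L + k))
    truth <- rt_compose(base, off)
    m <- tryCatch(mpe(truth, base, volume, geom), error = function(e) NA)
    if (!is.na(m) && m >= lo && m <= hi)
      return(list(offset = off, truth = truth, mpe = m))
    if (k > 500L) stop("could not draw an offset in the requested MPE range")
  }
}
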