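# ---- synthetic cerebral-vessel phantom -------------------------------------

#' Parameters of the synthetic cerebral-vessel phantom
#'
#' The phantom emulates the two vascular compartments the registration
#' pipeline relies on: large veins sweeping semicircular arcs near the skull
#' surface (the sinuses that contour the skull and anchor the learning-based
#' initialization), and a thinner branching arterial tree in the interior.
#'
#' @param grid_size voxels per axis (>= 32).
#' @param voxel_spacing isotropic voxel spacing (mm).
#' @param skull_radius radius (mm) of the sphere shell carrying the vein arcs.
#' @param n_vein_arcs number of vein arcs.
#' @param vein_radius vein tube radius (mm); must exceed \code{artery_radius}.
#' @param n_artery_branches number of root branches of the arterial tree.
#' @param artery_radius artery tube radius (mm).
#' @param seed integer seed; the phantom is deterministic given the seed.
#' @return An object of class \code{phantom_params}.
#' @export
phantom_params <- function(grid_size = 64, voxel_spacing = 2.5,
                           skull_radius = 70, n_vein_arcs = 5,
                           vein_radius = 3.5, n_artery_branches = 3,
                           artery_radius = 1.6, seed = 1L) {
  stopifnot(grid_size >= 32, skull_radius > 0, vein_radius > 0,
            artery_radius > 0, vein_radius > artery_radius)
  structure(list(grid_size = as.integer(grid_size),
                 voxel_spacing = voxel_spacing, skull_radius = skull_radius,
                 n_vein_arcs = as.integer(n_vein_arcs),
                 vein_radius = vein_radius,
                 n_artery_branches = as.integer(n_artery_branches),
                 artery_radius = artery_radius, seed = as.integer(seed)),
            class = "phantom_params")
}

# Stamp spheres of radius r (mm) at the given world points into a binary array.
stamp_tube <- function(vals, pts_world, w2v, radius_mm, spacing) {
  d <- dim(vals)
  r_vox <- radius_mm / spacing
  r <- ceiling(r_vox)
  g <- as.matrix(expand.grid(-r:r, -r:r, -r:r))
  g <- g[rowSums(g^2) <= r_vox^2 + 1e-9, , drop = FALSE]
  vox <- cbind(pts_world, 1) %*% t(w2v)
  vox <- round(vox[, 1:3, drop = FALSE]) + 1   # 1-based indices
  clipped <- FALSE
  for (i in seq_len(nrow(vox))) {
    pts <- sweep(g, 2, vox[i, ], "+")
    ok <- pts[, 1] >= 1 & pts[, 1] <= d[1] & pts[, 2] >= 1 & pts[, 2] <= d[2] &
          pts[, 3] >= 1 & pts[, 3] <= d[3]
    if (!all(ok)) clipped <- TRUE
    if (any(ok)) vals[pts[ok, , drop = FALSE]] <- 1
  }
  attr(vals, "clipped") <- clipped
  vals
}

#' Generate the synthetic vein and artery masks
#'
#' Vein arcs are great-circle arcs of the \code{skull_radius} sphere with
#' azimuthally jittered, seeded orientations, swept with tubes of
#' \code{vein_radius}; arteries form a recursively bifurcating tree (depth 3)
#' growing upward from a single inlet inside the sphere. Both masks share a
#' centered, isotropic voxel-to-world affine (grid midpoint at the world
#' origin). Masks may overlap; structures reaching the grid boundary are
#' clipped with a warning.
#'
#' @param params A \code{phantom_params}.
#' @return list with binary \code{volume_grid}s \code{veins} and
#'   \code{arteries}.
#' @export
generate_vessel_phantom <- function(params = phantom_params()) {
  stopifnot(inherits(params, "phantom_params"))
  withr::with_seed(params$seed, {
    n <- params$grid_size
    sp <- params$voxel_spacing
    tmpl <- volume_grid(array(0, c(n, n, n)), spacing = rep(sp, 3))
    w2v <- solve(tmpl$voxel_to_world)
    veins <- tmpl$values
    clipped <- FALSE
    if (params$n_vein_arcs > 0) {
      for (a in seq_len(params$n_vein_arcs)) {
        # arc plane: random unit normal, biased toward the vertical so arcs
        # contour the upper skull like the sagittal/transverse sinuses
        nrm <- c(stats::rnorm(1, 0, 0.4), stats::rnorm(1, 0, 1), stats::rnorm(1, 0, 0.4))
        nrm <- nrm / sqrt(sum(nrm^2))
        e1 <- pracma_null(nrm)
        phi0 <- stats::runif(1, 0, 2 * pi)
        span <- stats::runif(1, 0.8 * pi, pi)       # roughly semicircular
        rad <- params$skull_radius * stats::runif(1, 0.92, 1.0)
        tt <- seq(phi0, phi0 + span, by = 0.4 * sp / rad)
        pts <- outer(cos(tt), e1[, 1]) + outer(sin(tt), e1[, 2])
        pts <- rad * pts
        veins <- stamp_tube(veins, pts, w2v, params$vein_radius, sp)
        clipped <- clipped || attr(veins, "clipped")
      }
    }
    arteries <- tmpl$values
    if (params$n_artery_branches > 0) {
      inlet <- c(0, -0.55 * params$skull_radius, 0)  # bottom of the head
      grow <- function(p0, dir, len, depth) {
        tt <- seq(0, len, by = 0.4 * sp)
        pts <- sweep(outer(tt, dir), 2, p0, "+")
        arteries <<- stamp_tube(arteries, pts, w2v, params$artery_radius, sp)
        clipped <<- clipped || attr(arteries, "clipped")
        p1 <- p0 + len * dir
        if (depth <= 0) return(invisible())
        for (b in 1:2) {
          nd <- dir + stats::rnorm(3, 0, 0.45)
          nd[2] <- abs(nd[2]) * sign(dir[2])        # keep growing upward
          nd <- nd / sqrt(sum(nd^2))
          grow(p1, nd, len * 0.7, depth - 1)
        }
      }
      for (b in seq_len(params$n_artery_branches)) {
        d0 <- c(stats::rnorm(1, 0, 0.3), 1, stats::rnorm(1, 0, 0.3))
        d0 <- d0 / sqrt(sum(d0^2))
        grow(inlet, d0, params$skull_radius * 0.45, 2)
      }
    }
    if (clipped) warning("phantom tubes clipped at the grid boundary")
    list(veins = volume_grid(array(as.numeric(veins > 0), dim(veins)),
                             tmpl$voxel_to_world),
         arteries = volume_grid(array(as.numeric(arteries > 0), dim(arteries)),
                                tmpl$voxel_to_world))
  })
}

# two orthonormal vectors spanning the plane orthogonal to n (3 x 2 matrix)
pracma_null <- function(nrm) {
  ref <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * nrm) * nrm
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(nrm[2] * e1[3] - nrm[3] * e1[2],
          nrm[3] * e1[1] - nrm[1] * e1[3],
          nrm[1] * e1[2] - nrm[2] * e1[1])
  cbind(e1, e2)
}

#' Combined vessel phantom
#'
#' Union of the vein and artery masks: the stand-in for a full CTA vessel
#' segmentation.
#'
#' @param phantom list returned by \code{\link{generate_vessel_phantom}}.
#' @return A binary \code{volume_grid}.
#' @export
full_vessel_mask <- function(phantom) {
  volume_grid(array(as.numeric(phantom$veins$values + phantom$arteries$values > 0),
                    dim(phantom$veins$values)),
              phantom$veins$voxel_to_world)
}

# ---- pose-offset sampler ---------------------------------------------------

#' Parameters of the random pose-offset sampler
#'
#' Training offsets perturb a registered pose by a random rigid transform;
#' each rotation component (axis-angle, degrees) and each translation
#' component (mm) is drawn uniformly in its signed range. Per-axis
#' anisotropic ranges are supported because real offsets are anisotropic
#' (patients "slouch", making anterior-posterior offsets larger).
#'
#' @param rotation_range per-axis rotation half-range, degrees (length 1 or 3).
#' @param translation_range per-axis translation half-range, mm (length 1 or 3).
#' @param seed integer seed.
#' @return An object of class \code{offset_sampler_params}.
#' @export
offset_sampler_params <- function(rotation_range = c(15, 15, 15),
                                  translation_range = c(30, 30, 30),
                                  seed = 1L) {
  rotation_range <- rep_len(as.numeric(rotation_range), 3L)
  translation_range <- rep_len(as.numeric(translation_range), 3L)
  stopifnot(all(rotation_range >= 0), all(translation_range >= 0))
  structure(list(rotation_range = rotation_range,
                 translation_range = translation_range, seed = as.integer(seed)),
            class = "offset_sampler_params")
}

#' Sample random rigid pose offsets
#'
#' @param params An \code{offset_sampler_params}.
#' @param n number of offsets to draw.
#' @return A single \code{rigid_transform} when \code{n = 1}, else a list.
#' @export
sample_offset <- function(params, n = 1L) {
  stopifnot(inherits(params, "offset_sampler_params"))
  out <- withr::with_seed(params$seed, {
    lapply(seq_len(n), function(i) {
      w <- stats::runif(3, -params$rotation_range, params$rotation_range) * pi / 180
      u <- stats::runif(3, -params$translation_range, params$translation_range)
      se3_exp(c(w, u))
    })
  })
  if (n == 1L) out[[1]] else out
}

# ---- training pairs --------------------------------------------------------

#' Build one synthetic training pair
#'
#' The fixed image stands in for the DSA: the binarized DRR of the vein mask
#' at the registered pose. The moving image is the binarized DRR at the
#' registered pose composed with the random offset. The regression target is
#' the inverse of the offset, so a network predicting it learns to undo the
#' perturbation. Binarization threshold is \code{1e-6} of the image maximum:
#' any traversed vessel mass counts, emulating a binary DSA segmentation.
#'
#' @param veins binary \code{volume_grid} of the vein mask.
#' @param registered_pose the reference-standard pose.
#' @param offset perturbing \code{rigid_transform}.
#' @param geom A \code{carm_geometry}.
#' @param step renderer step (mm), passed to \code{\link{render_drr}}.
#' @return list with \code{fixed}, \code{moving} (binary
#'   \code{projection_2d}), \code{target} (= \code{rt_invert(offset)}),
#'   \code{moving_pose} and \code{registered_pose}. An all-zero DRR on either
#'   side raises an error of class \code{vesselreg_allzero_drr} so callers
#'   can resample.
#' @export
make_training_pair <- function(veins, registered_pose, offset, geom, step = NULL) {
  assert_binary_volume(veins, "vein volume")
  moving_pose <- rt_compose(registered_pose, offset)
  fixed_drr <- render_drr(veins, registered_pose, geom, step = step)
  moving_drr <- render_drr(veins, moving_pose, geom, step = step)
  if (all(fixed_drr$values == 0) || all(moving_drr$values == 0))
    stop(structure(class = c("vesselreg_allzero_drr", "error", "condition"),
                   list(message = "training pair rejected: all-zero DRR",
                        call = sys.call())))
  list(fixed = binarize(fixed_drr, 1e-6 * max(fixed_drr$values)),
       moving = binarize(moving_drr, 1e-6 * max(moving_drr$values)),
       target = rt_invert(offset),
       moving_pose = moving_pose,
       registered_pose = registered_pose)
}

#' Build a training set of synthetic pairs
#'
#' Draws offsets from the sampler and assembles training pairs, resampling
#' (with a log message) whenever a pair is rejected for an all-zero DRR.
#'
#' @param veins binary \code{volume_grid}.
#' @param registered_pose the reference pose.
#' @param n number of pairs.
#' @param sampler An \code{offset_sampler_params}.
#' @param geom A \code{carm_geometry}.
#' @param step renderer step (mm).
#' @return list of training pairs (each as in
#'   \code{\link{make_training_pair}}, plus the drawn \code{offset}).
#' @export
make_training_set <- function(veins, registered_pose, n, sampler, geom,
                              step = NULL) {
  offsets <- sample_offset(sampler, n = 2L * n + 10L)  # headroom for rejects
  pairs <- vector("list", n)
  k <- 0L
  for (off in offsets) {
    if (k >= n) break
    pair <- tryCatch(make_training_pair(veins, registered_pose, off, geom,
                                        step = step),
                     vesselreg_allzero_drr = function(e) {
                       message("resampling a rejected all-zero training pair")
                       NULL
                     })
    if (!is.null(pair)) {
      pair$offset <- off
      k <- k + 1L
      pairs[[k]] <- pair
    }
  }
  if (k < n) stop("could not assemble the requested number of training pairs")
  pairs
}

# ---- synthetic DSA sequence ------------------------------------------------

#' Synthesize a DSA frame sequence from the phantom
#'
#' Produces an inverted-contrast frame stack from a DRR of the full vessel
#' mask at the given pose: vessels are dark on a bright background, with
#' per-frame random opacification scaling, so that the per-pixel minimum over
#' frames (the MinIP) recovers the fully opacified vessel image.
#'
#' @param vessels binary \code{volume_grid}.
#' @param pose acquisition pose.
#' @param geom A \code{carm_geometry}.
#' @param n_frames number of frames.
#' @param seed integer seed.
#' @return list of \code{projection_2d} frames.
#' @export
make_synthetic_dsa <- function(vessels, pose, geom, n_frames = 5, seed = 1L) {
  drr <- render_drr(vessels, pose, geom)
  p <- drr$values / max(max(drr$values), 1e-12)
  withr::with_seed(seed, {
    lapply(seq_len(n_frames), function(k) {
      w <- stats::runif(1, 0.5, 1)
      projection_2d(1 - w * p, geom$pixel_spacing)
    })
  })
}
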