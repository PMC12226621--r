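# ---- vein isolation from a CTA vessel segmentation -------------------------

#' Parameters for vein isolation
#'
#' @param opening_radius radius (voxels) of the ball structuring element for
#'   the morphological opening; 0 skips the opening.
#' @param min_component_size components smaller than this many voxels are
#'   discarded.
#' @param keep_top_k at most this many largest components are kept.
#' @return An object of class \code{vein_isolation_params}.
#' @export
vein_isolation_params <- function(opening_radius = 1, min_component_size = 500,
                                  keep_top_k = 4) {
  stopifnot(opening_radius >= 0, min_component_size >= 1, keep_top_k >= 1)
  structure(list(opening_radius = opening_radius,
                 min_component_size = min_component_size,
                 keep_top_k = keep_top_k), class = "vein_isolation_params")
}

ball_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- as.matrix(expand.grid(-r:r, -r:r, -r:r))
  g[rowSums(g^2) <= radius^2 + 1e-9, , drop = FALSE]
}

shift_array <- function(a, off) {
  d <- dim(a)
  out <- array(0, d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    o <- off[ax]
    if (abs(o) >= d[ax]) return(out)
    if (o >= 0) { dst[[ax]] <- (1 + o):d[ax]; src[[ax]] <- 1:(d[ax] - o) }
    else        { dst[[ax]] <- 1:(d[ax] + o); src[[ax]] <- (1 - o):d[ax] }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

erode3d <- function(a, offsets) {
  out <- array(TRUE, dim(a))
  for (i in seq_len(nrow(offsets))) out <- out & shift_array(a, offsets[i, ]) > 0
  out
}

dilate3d <- function(a, offsets) {
  out <- array(FALSE, dim(a))
  for (i in seq_len(nrow(offsets))) out <- out | shift_array(a, offsets[i, ]) > 0
  out
}

#' Label connected components of a binary volume
#'
#' 26-connectivity labeling; labels are assigned in decreasing order of
#' component size (label 1 is the largest component).
#'
#' @param mask binary 3D array or \code{volume_grid}.
#' @return Integer array of the same shape; 0 is background.
#' @export
label_components <- function(mask) {
  vals <- if (inherits(mask, "volume_grid")) mask$values else mask
  cpp_label_components(vals > 0, dim(vals))
}

#' Isolate the large veins from a vessel segmentation
#'
#' The large cerebral veins (the sinuses contouring the skull) are isolated
#' from a full CTA vessel segmentation by a morphological opening with a ball
#' structuring element, followed by 26-connectivity component labeling that
#' discards small components and keeps only the largest few. Thin arterial
#' branches are erased by the opening; the surviving large components are the
#' vein candidates used to anchor the initialization network.
#'
#' @param vessel_mask binary \code{volume_grid}.
#' @param params A \code{vein_isolation_params}.
#' @return A binary \code{volume_grid}, a subset of the opened input mask.
#' @export
isolate_veins <- function(vessel_mask, params = vein_isolation_params()) {
  stopifnot(inherits(vessel_mask, "volume_grid"))
  assert_binary_volume(vessel_mask, "vessel mask")
  a <- vessel_mask$values > 0
  if (!any(a)) {
    warning("empty vessel mask; returning an empty vein mask")
    return(volume_grid(array(0, dim(a)), vessel_mask$voxel_to_world))
  }
  if (params$opening_radius > 0) {
    off <- ball_offsets(params$opening_radius)
    a <- dilate3d(erode3d(a, off), off)
  }
  lab <- cpp_label_components(a, dim(a))
  if (any(lab > 0)) {
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= params$min_component_size)
    keep <- keep[keep <= params$keep_top_k]  # labels are size-ordered
    a <- array(lab %in% keep, dim(a))
  }
  volume_grid(array(as.numeric(a), dim(a)), vessel_mask$voxel_to_world)
}

# ---- DSA input checks ------------------------------------------------------

#' Validate (and normalize) a DSA vessel segmentation
#'
#' Asserts that the image is binary with foreground = 1. Two-valued images on
#' other scales (e.g. \{0, 255\}) are rescaled; genuinely non-binary images
#' are thresholded at 0.5 with a warning. Degenerate all-foreground or
#' all-background images raise a quality error.
#'
#' @param image A \code{projection_2d}.
#' @return A binary \code{projection_2d} of kind \code{"dsa_segmentation"}.
#' @export
validate_dsa_segmentation <- function(image) {
  stopifnot(inherits(image, "projection_2d"))
  v <- image$values
  u <- sort(unique(as.numeric(v)))
  if (length(u) == 1L)
    stop("degenerate DSA segmentation: image is all ",
         if (u > 0) "foreground" else "background")
  if (length(u) == 2L) {
    v <- (v == u[2]) * 1
  } else if (!all(u %in% c(0, 1))) {
    warning("DSA segmentation is not binary; thresholding at 0.5 of its range")
    v <- (v > (min(u) + max(u)) / 2) * 1
  }
  if (all(v == 1) || all(v == 0))
    stop("degenerate DSA segmentation after normalization")
  projection_2d(v, image$pixel_spacing, kind = "dsa_segmentation")
}
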