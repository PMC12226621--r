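# ---- digitally reconstructed radiographs -----------------------------------

default_render_step <- function(vol, step) {
  if (!is.null(step)) return(step)
  min(volume_spacing(vol)) / 16
}

#' Render a DRR from a volume at a pose
#'
#' Each detector pixel holds the line integral (mm-weighted) of the volume
#' along the ray from the X-ray source to that pixel's center, with the
#' volume placed into the C-arm frame by \code{pose}. Integration uses
#' fixed-step midpoint sampling of the trilinearly interpolated volume, which
#' makes the image a smooth function of the pose tangent parameters; the
#' matching analytic gradient is available through
#' \code{\link{drr_pose_gradient}}.
#'
#' @param volume A \code{volume_grid}.
#' @param pose A \code{rigid_transform} (volume world to C-arm frame).
#' @param geom A \code{carm_geometry}.
#' @param step ray sampling step (mm); default is one sixteenth of the
#'   smallest voxel spacing, which keeps the quadrature error below 0.1
#'   percent of the image maximum for binary vessel masks. Optimization
#'   loops use coarser steps (half a voxel) where speed matters more than
#'   quadrature accuracy.
#' @return A \code{projection_2d} of kind \code{"drr"}. If the volume lies
#'   entirely outside the source-detector frustum the image is all zero and a
#'   warning is raised.
#' @export
render_drr <- function(volume, pose, geom, step = NULL) {
  stopifnot(inherits(volume, "volume_grid"), inherits(pose, "rigid_transform"),
            inherits(geom, "carm_geometry"))
  step <- default_render_step(volume, step)
  cr <- volume_center_radius(volume)
  rad <- cr$radius + max(volume_spacing(volume))  # cover trilinear support
  w2v <- solve(volume$voxel_to_world)
  img <- cpp_render_drr(as.numeric(volume$values), dim(volume$values), w2v,
                        pose$rotation, pose$translation,
                        geom$source_to_detector, geom$source_to_isocenter,
                        geom$detector_rows, geom$detector_cols,
                        geom$pixel_spacing, geom$principal_point[1],
                        geom$principal_point[2], cr$center, rad, step)
  if (all(img == 0) && any(volume$values != 0)) {
    prj <- suppressWarnings(project_points(volume_corners(volume), pose, geom))
    inside <- !is.na(prj[, 1]) &
      prj[, 1] >= 0 & prj[, 1] <= geom$detector_rows - 1 &
      prj[, 2] >= 0 & prj[, 2] <= geom$detector_cols - 1
    if (!any(inside))
      warning("volume lies entirely outside the source-detector frustum; DRR is all zero")
  }
  projection_2d(img, geom$pixel_spacing, kind = "drr")
}

#' Analytic pose gradient of a scalar function of a DRR
#'
#' For a pose parametrized as \code{base_pose} composed with
#' \code{se3_exp(v)}, returns the gradient with respect to the 6 tangent
#' parameters \code{v} of any scalar loss \code{L} of the rendered image,
#' given the upstream per-pixel derivatives \code{dL/dpixel}. The gradient is
#' exact for the fixed-step trilinear quadrature that \code{render_drr}
#' evaluates (it matches central finite differences of the same rendering).
#'
#' @param volume A \code{volume_grid}.
#' @param base_pose A \code{rigid_transform}; the rendered pose is
#'   \code{rt_compose(base_pose, se3_exp(v))}.
#' @param v numeric length-6 tangent vector at which to differentiate.
#' @param geom A \code{carm_geometry}.
#' @param d_loss_d_pixel matrix of upstream derivatives, detector shaped.
#' @param step ray sampling step (mm), as in \code{\link{render_drr}}.
#' @return numeric length-6 gradient (rotation radians, translation mm).
#' @export
drr_pose_gradient <- function(volume, base_pose, v, geom, d_loss_d_pixel,
                              step = NULL) {
  step <- default_render_step(volume, step)
  pose <- rt_compose(base_pose, se3_exp(v))
  cr <- volume_center_radius(volume)
  rad <- cr$radius + max(volume_spacing(volume))
  w2v <- solve(volume$voxel_to_world)
  s <- cpp_drr_backward(as.numeric(volume$values), dim(volume$values), w2v,
                        pose$rotation, pose$translation,
                        geom$source_to_detector, geom$source_to_isocenter,
                        geom$detector_rows, geom$detector_cols,
                        geom$pixel_spacing, geom$principal_point[1],
                        geom$principal_point[2], cr$center, rad, step,
                        as.matrix(d_loss_d_pixel))
  Rw <- so3_exp(v[1:3])
  Jr <- so3_right_jacobian(v[1:3])
  c(as.numeric(crossprod(Jr, s[1:3])), -as.numeric(Rw %*% s[4:6]))
}
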