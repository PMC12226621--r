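# ---- C-arm geometry --------------------------------------------------------

#' C-arm acquisition geometry
#'
#' Defines the projective camera of the acquisition. The C-arm frame has its
#' origin at the isocenter; the X-ray source sits at
#' \code{(0, 0, -source_to_isocenter)} and the detector plane is orthogonal
#' to the z axis at distance \code{source_to_detector} from the source.
#' Detector pixel (0, 0) is the top-left corner; row indices increase
#' downward (+y), column indices increase with +x; pixel indices are 0-based.
#'
#' @param source_to_detector source-to-detector distance \code{f} (mm).
#' @param detector_rows,detector_cols detector size in pixels.
#' @param pixel_spacing detector pixel pitch (mm/pixel).
#' @param principal_point length-2 \code{c(row, col)} of the principal point
#'   in pixels; defaults to the detector center.
#' @param primary_angle,secondary_angle acquisition angles in degrees
#'   (primary: LAO/RAO rotation about the patient longitudinal axis;
#'   secondary: cranio-caudal angulation).
#' @param source_to_isocenter source-to-isocenter distance (mm); defaults to
#'   \code{source_to_detector / 2}.
#' @return An object of class \code{carm_geometry}.
#' @export
carm_geometry <- function(source_to_detector, detector_rows, detector_cols,
                          pixel_spacing, principal_point = NULL,
                          primary_angle = 0, secondary_angle = 0,
                          source_to_isocenter = source_to_detector / 2) {
  if (source_to_detector <= 0 || pixel_spacing <= 0)
    stop("source_to_detector and pixel_spacing must be positive")
  if (source_to_isocenter <= 0 || source_to_isocenter >= source_to_detector)
    stop("source_to_isocenter must lie strictly between 0 and source_to_detector")
  if (is.null(principal_point))
    principal_point <- c((detector_rows - 1) / 2, (detector_cols - 1) / 2)
  structure(list(source_to_detector = as.numeric(source_to_detector),
                 detector_rows = as.integer(detector_rows),
                 detector_cols = as.integer(detector_cols),
                 pixel_spacing = as.numeric(pixel_spacing),
                 principal_point = as.numeric(principal_point),
                 primary_angle = as.numeric(primary_angle),
                 secondary_angle = as.numeric(secondary_angle),
                 source_to_isocenter = as.numeric(source_to_isocenter)),
            class = "carm_geometry")
}

#' @export
print.carm_geometry <- function(x, ...) {
  cat(sprintf("C-arm geometry: f = %.1f mm, iso = %.1f mm, %d x %d px @ %.3f mm, angles (%g, %g) deg\n",
              x$source_to_detector, x$source_to_isocenter, x$detector_rows,
              x$detector_cols, x$pixel_spacing, x$primary_angle, x$secondary_angle))
  invisible(x)
}

#' Read / write C-arm geometry as JSON
#' @param path JSON file path.
#' @return \code{read_geometry} returns a \code{carm_geometry}.
#' @export
read_geometry <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(carm_geometry, obj[intersect(names(obj),
          names(formals(carm_geometry)))])
}

#' @rdname read_geometry
#' @param geom A \code{carm_geometry}.
#' @export
write_geometry <- function(geom, path) {
  jsonlite::write_json(unclass(geom), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

# ---- radiological pose -----------------------------------------------------

#' Baseline pose from the C-arm angles
#'
#' Builds the rotation implied by the recorded primary and secondary angles,
#' with zero translation. The patient longitudinal (cranio-caudal) axis is
#' the world y axis. The primary angle rotates about it such that +90 degrees
#' carries the world +x axis onto the viewing (+z) axis; the secondary angle
#' is then applied extrinsically about the world x axis.
#'
#' @param geom A \code{carm_geometry}.
#' @return A \code{rigid_transform} with zero translation.
#' @export
radiological_pose <- function(geom) {
  pri <- geom$primary_angle * pi / 180
  sec <- geom$secondary_angle * pi / 180
  Rpri <- matrix(c(cos(pri), 0, -sin(pri),
                   0, 1, 0,
                   sin(pri), 0, cos(pri)), 3, 3, byrow = TRUE)
  Rsec <- matrix(c(1, 0, 0,
                   0, cos(sec), -sin(sec),
                   0, sin(sec), cos(sec)), 3, 3, byrow = TRUE)
  rigid_transform(Rsec %*% Rpri, c(0, 0, 0))
}

# ---- point projection ------------------------------------------------------

#' Perspective projection of 3D points onto the detector
#'
#' Transforms world points into the C-arm frame by \code{pose} and projects
#' them from the X-ray source onto the detector plane. Shares its geometry
#' with \code{\link{render_drr}}: a unit point mass projects to the pixel at
#' which the rendered image of that point peaks.
#'
#' @param points n x 3 matrix (or length-3 vector) of world points, mm.
#' @param pose A \code{rigid_transform}.
#' @param geom A \code{carm_geometry}.
#' @return n x 2 matrix with columns \code{row}, \code{col}: 0-based detector
#'   pixel coordinates. Points at or behind the source project to \code{NA}
#'   rows (with a warning).
#' @export
project_points <- function(points, pose, geom) {
  pts <- rbind2mat(points)
  pc <- rt_apply(pose, pts)
  denom <- pc[, 3] + geom$source_to_isocenter   # distance from source along z
  bad <- denom <= 1e-9
  if (any(bad)) warning(sprintf("%d point(s) at or behind the X-ray source excluded", sum(bad)))
  f <- geom$source_to_detector
  xdet <- f * pc[, 1] / denom
  ydet <- f * pc[, 2] / denom
  out <- cbind(row = ydet / geom$pixel_spacing + geom$principal_point[1],
               col = xdet / geom$pixel_spacing + geom$principal_point[2])
  out[bad, ] <- NA_real_
  out
}
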