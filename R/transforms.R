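#' @useDynLib vesselreg, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# ---- SE(3) rigid transforms ------------------------------------------------

#' Create a rigid transform
#'
#' A rigid transform maps volume world coordinates (mm) into the C-arm frame:
#' \code{x_cam = R x_world + t}. The rotation is stored as a 3x3 orthonormal
#' matrix, the translation as a 3-vector in millimetres.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation numeric length-3 translation (mm).
#' @return An object of class \code{rigid_transform} with fields
#'   \code{rotation} and \code{translation}.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || length(translation) != 3L)
    stop("rigid_transform needs a 3x3 rotation and a length-3 translation")
  if (!all(is.finite(rotation)) || !all(is.finite(translation)))
    stop("non-finite values in rigid transform")
  err_orth <- max(abs(crossprod(rotation) - diag(3)))
  if (err_orth > 1e-6)
    stop(sprintf("invalid transform: rotation not orthonormal (error %.3g)", err_orth))
  if (abs(det(rotation) - 1) > 1e-6)
    stop("invalid transform: rotation determinant is not +1")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Identity rigid transform
#' @return The identity \code{rigid_transform}.
#' @export
rt_identity <- function() rigid_transform()

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform (world -> C-arm)\n")
  m <- as_matrix(x)
  print(round(m, 6))
  invisible(x)
}

#' Compose two rigid transforms
#'
#' Returns the transform that applies \code{b} first, then \code{a}
#' (homogeneous matrix product \code{a \%*\% b}).
#'
#' @param a,b \code{rigid_transform} objects.
#' @return A \code{rigid_transform}.
#' @export
rt_compose <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform"), inherits(b, "rigid_transform"))
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param x A \code{rigid_transform}.
#' @return The inverse \code{rigid_transform}.
#' @export
rt_invert <- function(x) {
  stopifnot(inherits(x, "rigid_transform"))
  rigid_transform(t(x$rotation), -as.numeric(t(x$rotation) %*% x$translation))
}

#' Apply a rigid transform to points
#' @param x A \code{rigid_transform}.
#' @param pts n x 3 matrix (or length-3 vector) of points, mm.
#' @return n x 3 matrix of transformed points.
#' @export
rt_apply <- function(x, pts) {
  pts <- rbind2mat(pts)
  sweep(pts %*% t(x$rotation), 2, -x$translation)
}

rbind2mat <- function(pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3, byrow = TRUE)
  as.matrix(pts)
}

#' Homogeneous 4x4 matrix of a rigid transform
#' @param x A \code{rigid_transform}.
#' @return 4x4 homogeneous matrix.
#' @export
as_matrix <- function(x) UseMethod("as_matrix")

#' @export
as_matrix.rigid_transform <- function(x) {
  m <- diag(4)
  m[1:3, 1:3] <- x$rotation
  m[1:3, 4] <- x$translation
  m
}

#' Rigid transform from a 4x4 homogeneous matrix
#' @param m 4x4 matrix whose upper-left 3x3 block is a rotation.
#' @return A \code{rigid_transform}.
#' @export
rt_from_matrix <- function(m) {
  m <- as.matrix(m)
  stopifnot(all(dim(m) == c(4L, 4L)))
  rigid_transform(m[1:3, 1:3], m[1:3, 4])
}

# ---- skew / Rodrigues helpers ---------------------------------------------

skew <- function(w) {
  matrix(c(0, w[3], -w[2],
           -w[3], 0, w[1],
           w[2], -w[1], 0), 3, 3)
}

#' Rotation matrix from an axis-angle vector (Rodrigues formula)
#' @param w length-3 axis-angle vector (radians).
#' @return 3x3 rotation matrix.
#' @export
so3_exp <- function(w) {
  th <- sqrt(sum(w^2))
  K <- skew(w)
  if (th < 1e-10) return(diag(3) + K + 0.5 * K %*% K)
  A <- sin(th) / th
  B <- (1 - cos(th)) / th^2
  diag(3) + A * K + B * K %*% K
}

#' Axis-angle vector of a rotation matrix (principal branch)
#' @param R 3x3 rotation matrix with rotation angle < pi.
#' @return length-3 axis-angle vector (radians).
#' @export
so3_log <- function(R) {
  tr <- sum(diag(R))
  cth <- clamp((tr - 1) / 2, -1, 1)
  th <- acos(cth)
  if (th < 1e-10) {
    # first-order: R ~ I + [w]_x
    return(0.5 * c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]))
  }
  if (th > pi - 1e-6)
    stop("rotation angle at the pi branch cut; axis-angle logarithm is ambiguous")
  axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / (2 * sin(th))
  th * axis
}

#' Right Jacobian of SO(3)
#'
#' Maps additive perturbations of the axis-angle vector to right-multiplied
#' rotation increments: \code{so3_exp(w + dw) = so3_exp(w) so3_exp(Jr dw)}
#' to first order.
#'
#' @param w length-3 axis-angle vector.
#' @return 3x3 Jacobian matrix.
#' @export
so3_right_jacobian <- function(w) {
  th <- sqrt(sum(w^2))
  K <- skew(w)
  if (th < 1e-6) return(diag(3) - 0.5 * K + K %*% K / 6)
  diag(3) - (1 - cos(th)) / th^2 * K + (th - sin(th)) / th^3 * K %*% K
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# ---- exp / log on poses ----------------------------------------------------

#' Exponential map: tangent vector to rigid transform
#'
#' The pose tangent space used throughout the package is
#' \code{c(rotation_part, translation_part)}: an axis-angle rotation vector
#' (radians) and a direct translation (mm). This is the SO(3) x R^3
#' parametrization: the translation passes through unchanged.
#'
#' @param v numeric length-6 tangent vector \code{c(w, u)}.
#' @return A \code{rigid_transform}.
#' @export
se3_exp <- function(v) {
  v <- as.numeric(v)
  stopifnot(length(v) == 6L)
  rigid_transform(so3_exp(v[1:3]), v[4:6])
}

#' Logarithm map: rigid transform to tangent vector
#' @param x A \code{rigid_transform} with rotation angle < pi.
#' @return numeric length-6 tangent vector.
#' @export
se3_log <- function(x) {
  stopifnot(inherits(x, "rigid_transform"))
  c(so3_log(x$rotation), x$translation)
}

# ---- geodesic losses (training objectives) ---------------------------------

rotation_angle <- function(Ra, Rb) {
  acos(clamp((sum(diag(crossprod(Ra, Rb))) - 1) / 2, -1, 1))
}

#' Geodesic pose distance
#'
#' \code{sqrt(theta^2 + ||t_a - t_b||^2)} where \code{theta} (radians) is the
#' relative rotation angle \code{acos((trace(Ra' Rb) - 1)/2)}. Symmetric,
#' non-negative, zero iff the poses coincide.
#'
#' @param a,b \code{rigid_transform} objects.
#' @return Non-negative scalar.
#' @export
geodesic_loss <- function(a, b) {
  th <- rotation_angle(a$rotation, b$rotation)
  sqrt(th^2 + sum((a$translation - b$translation)^2))
}

#' Double geodesic pose distance
#'
#' The rotation angle is converted to millimetres through the
#' source-to-detector distance \code{f} before combining with the
#' translational distance: \code{sqrt((f theta)^2 + ||t_a - t_b||^2)}.
#' Expressing the angular error at detector scale balances the two
#' components for projective registration.
#'
#' @param a,b \code{rigid_transform} objects.
#' @param f source-to-detector distance (mm), positive.
#' @return Non-negative scalar (mm).
#' @export
double_geodesic_loss <- function(a, b, f) {
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f) || f <= 0)
    stop("source-to-detector distance f must be a positive scalar")
  th <- rotation_angle(a$rotation, b$rotation)
  sqrt((f * th)^2 + sum((a$translation - b$translation)^2))
}

# Analytic gradient of the two geodesic losses with respect to the tangent
# vector v where a = se3_exp(v); b is the fixed target.  Used during network
# training.  Returns a length-6 vector.
geodesic_loss_grad <- function(v, b, f = NULL) {
  w <- v[1:3]; u <- v[4:6]
  Rw <- so3_exp(w)
  A <- crossprod(b$rotation, Rw)            # Rb' Rw
  cth <- clamp((sum(diag(A)) - 1) / 2, -1, 1)
  th <- acos(cth)
  dt <- u - b$translation
  scale2 <- if (is.null(f)) 1 else f^2
  L <- sqrt(scale2 * th^2 + sum(dt^2))
  if (L < 1e-12) return(numeric(6))
  g <- numeric(6)
  g[4:6] <- dt / L
  sth <- sin(th)
  if (th > 1e-8 && sth > 1e-8) {
    s <- c(A[3, 2] - A[2, 3], A[1, 3] - A[3, 1], A[2, 1] - A[1, 2])
    dth_ddelta <- s / (2 * sth)             # right perturbation of Rw
    Jr <- so3_right_jacobian(w)
    g[1:3] <- (scale2 * th / L) * as.numeric(crossprod(Jr, dth_ddelta))
  }
  g
}

# ---- serialization ---------------------------------------------------------

#' Write a rigid transform to disk
#'
#' Two plain-text formats are supported: a 4-line x 4-float homogeneous
#' matrix (\code{"text"}) and JSON with \code{rotation} / \code{translation}
#' fields (\code{"json"}, chosen automatically for a \code{.json} path).
#'
#' @param x A \code{rigid_transform}.
#' @param path output file path.
#' @param format \code{"auto"}, \code{"text"} or \code{"json"}.
#' @return \code{path}, invisibly.
#' @export
write_transform <- function(x, path, format = c("auto", "text", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "text"
  if (format == "json") {
    jsonlite::write_json(list(rotation = x$rotation, translation = x$translation),
                         path, digits = NA, matrix = "rowmajor")
  } else {
    m <- as_matrix(x)
    writeLines(apply(m, 1, function(r) paste(format(r, digits = 17), collapse = " ")),
               path)
  }
  invisible(path)
}

#' Read a rigid transform from disk
#'
#' Accepts both formats written by \code{\link{write_transform}}.
#'
#' @param path file path (plain-text 4x4 matrix or JSON).
#' @return A \code{rigid_transform}.
#' @export
read_transform <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("^\\s*\\{", first)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!is.null(obj$rotation))
      return(rigid_transform(matrix(unlist(obj$rotation), 3, 3, byrow = !is.matrix(obj$rotation)),
                             unlist(obj$translation)))
    return(rt_from_matrix(matrix(unlist(obj), 4, 4, byrow = !is.matrix(obj))))
  }
  rows <- lapply(readLines(path, warn = FALSE), function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  })
  rows <- rows[vapply(rows, length, 1L) > 0]
  rt_from_matrix(do.call(rbind, rows))
}
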