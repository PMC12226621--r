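# ---- voxel grids -----------------------------------------------------------

#' Create a 3D voxel grid
#'
#' Wraps a 3D scalar array (attenuation in arbitrary units, or a \{0, 1\}
#' mask) together with a voxel-to-world affine. The affine maps 0-based
#' voxel indices \code{(i, j, k)} to world millimetres.
#'
#' @param values 3D numeric/logical array; all dimensions must be >= 2.
#' @param voxel_to_world 4x4 affine (mm); when \code{NULL}, an axis-aligned
#'   affine with the given \code{spacing} is built, centered so that the grid
#'   midpoint sits at the world origin (the isocenter under the identity pose).
#' @param spacing length-3 voxel spacing (mm), used when
#'   \code{voxel_to_world} is \code{NULL}.
#' @return An object of class \code{volume_grid} with fields \code{values}
#'   and \code{voxel_to_world}.
#' @export
volume_grid <- function(values, voxel_to_world = NULL, spacing = c(1, 1, 1)) {
  values <- as.array(values)
  if (is.logical(values)) values <- array(as.numeric(values), dim(values))
  if (length(dim(values)) != 3L || any(dim(values) < 2L))
    stop("volume values must be a 3D array with all dimensions >= 2")
  if (is.null(voxel_to_world)) {
    spacing <- rep_len(as.numeric(spacing), 3L)
    voxel_to_world <- diag(c(spacing, 1))
    voxel_to_world[1:3, 4] <- -spacing * (dim(values) - 1) / 2
  }
  voxel_to_world <- as.matrix(voxel_to_world)
  stopifnot(all(dim(voxel_to_world) == c(4L, 4L)))
  if (det(voxel_to_world[1:3, 1:3]) <= 0)
    stop("voxel_to_world affine must have a positive-determinant linear part")
  structure(list(values = values, voxel_to_world = voxel_to_world),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("Volume grid %d x %d x %d, spacing ~ (%s) mm%s\n", d[1], d[2], d[3],
              paste(round(volume_spacing(x), 3), collapse = ", "),
              if (is_binary_volume(x)) " [binary]" else ""))
  invisible(x)
}

volume_spacing <- function(vol) {
  A <- vol$voxel_to_world[1:3, 1:3]
  sqrt(colSums(A^2))
}

is_binary_volume <- function(vol) all(vol$values %in% c(0, 1))

assert_binary_volume <- function(vol, what = "volume") {
  if (!is_binary_volume(vol))
    stop(sprintf("%s must be binary (values in {0, 1})", what))
  invisible(vol)
}

# world coordinates of the 8 corners of the voxel-index bounding box
volume_corners <- function(vol) {
  d <- dim(vol$values)
  idx <- as.matrix(expand.grid(i = c(0, d[1] - 1), j = c(0, d[2] - 1),
                               k = c(0, d[3] - 1)))
  h <- cbind(idx, 1) %*% t(vol$voxel_to_world)
  h[, 1:3, drop = FALSE]
}

volume_center_radius <- function(vol) {
  corners <- volume_corners(vol)
  ctr <- colMeans(corners)
  list(center = ctr,
       radius = sqrt(max(rowSums(sweep(corners, 2, ctr)^2))))
}

#' Read / write a volume as NIfTI
#'
#' The NIfTI sform/qform is used as the voxel-to-world affine (applied to
#' 0-based voxel indices, in the image's native axis convention).
#'
#' @param path a \code{.nii} or \code{.nii.gz} file.
#' @return \code{read_volume} returns a \code{volume_grid}.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), class = NULL)
  vals <- array(as.numeric(img), dim(img))   # drop RNifti attributes
  volume_grid(vals, voxel_to_world = unclass(matrix(aff, 4, 4)))
}

#' @rdname read_volume
#' @param vol A \code{volume_grid}.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$values)
  img <- RNifti::`sform<-`(img, structure(vol$voxel_to_world, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

# ---- detector-space images -------------------------------------------------

#' Create a 2D detector-space image
#'
#' @param values 2D numeric matrix (rows x cols, row 0 at the top).
#' @param pixel_spacing pixel pitch (mm/pixel).
#' @param kind one of \code{"drr"}, \code{"dsa_segmentation"}, \code{"minip"}.
#' @return An object of class \code{projection_2d}.
#' @export
projection_2d <- function(values, pixel_spacing,
                          kind = c("drr", "dsa_segmentation", "minip")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (kind == "dsa_segmentation" && !all(values %in% c(0, 1)))
    stop("a DSA segmentation image must be binary")
  structure(list(values = values, pixel_spacing = as.numeric(pixel_spacing),
                 kind = kind), class = "projection_2d")
}

#' @export
print.projection_2d <- function(x, ...) {
  cat(sprintf("Projection [%s] %d x %d px @ %.3f mm, range [%.3g, %.3g]\n",
              x$kind, nrow(x$values), ncol(x$values), x$pixel_spacing,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Threshold an image into a binary mask
#'
#' Pixels strictly greater than \code{threshold} become 1, all others 0; the
#' result carries the \code{"dsa_segmentation"} kind so it can stand in for a
#' binary DSA segmentation.
#'
#' @param image A \code{projection_2d}.
#' @param threshold finite scalar.
#' @return A binary \code{projection_2d}.
#' @export
binarize <- function(image, threshold) {
  stopifnot(inherits(image, "projection_2d"), is.finite(threshold))
  projection_2d((image$values > threshold) * 1, image$pixel_spacing,
                kind = "dsa_segmentation")
}

#' Minimum-intensity projection over DSA frames
#'
#' Per-pixel minimum across the frames of a DSA run; with contrast rendering
#' vessels dark, the MinIP aggregates every opacified vessel into one image.
#'
#' @param frames list of \code{projection_2d} objects of identical shape
#'   (or a 3D array, frame-major in the third dimension, plus
#'   \code{pixel_spacing}).
#' @param pixel_spacing used only when \code{frames} is an array.
#' @return A \code{projection_2d} of kind \code{"minip"}.
#' @export
minip <- function(frames, pixel_spacing = NULL) {
  if (is.array(frames) && length(dim(frames)) == 3L) {
    stopifnot(!is.null(pixel_spacing))
    frames <- lapply(seq_len(dim(frames)[3]),
                     function(k) projection_2d(frames[, , k], pixel_spacing))
  }
  if (!is.list(frames) || length(frames) == 0L)
    stop("minip needs at least one frame")
  shp <- dim(frames[[1]]$values)
  vals <- frames[[1]]$values
  for (fr in frames[-1]) {
    if (!all(dim(fr$values) == shp)) stop("all DSA frames must share one shape")
    vals <- pmin(vals, fr$values)
  }
  projection_2d(vals, frames[[1]]$pixel_spacing, kind = "minip")
}

#' Read / write 2D images
#'
#' PNG images are read with \code{png} (multichannel images are averaged to
#' one channel); NIfTI paths are handled through \code{RNifti}. Multi-frame
#' DSA runs can be read from multi-page TIFF or 3D NIfTI with
#' \code{read_frames}.
#'
#' @param path image file path.
#' @param pixel_spacing pixel pitch (mm/pixel) to attach.
#' @param kind image kind, see \code{\link{projection_2d}}.
#' @return \code{read_projection} returns a \code{projection_2d};
#'   \code{read_frames} a list of them.
#' @export
read_projection <- function(path, pixel_spacing, kind = "drr") {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    vals <- as.array(RNifti::readNifti(path))
    if (length(dim(vals)) > 2L) vals <- vals[, , 1]
  } else {
    vals <- png::readPNG(path)
    if (length(dim(vals)) == 3L) vals <- apply(vals, c(1, 2), mean)
  }
  projection_2d(vals, pixel_spacing, kind = kind)
}

#' @rdname read_projection
#' @param image A \code{projection_2d}; values are rescaled to [0, 1] for PNG.
#' @export
write_projection <- function(image, path) {
  v <- image$values
  rng <- range(v)
  if (rng[2] > rng[1]) v <- (v - rng[1]) / (rng[2] - rng[1])
  png::writePNG(v, path)
  invisible(path)
}

#' @rdname read_projection
#' @export
read_frames <- function(path, pixel_spacing) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    arr <- as.array(RNifti::readNifti(path))
    stopifnot(length(dim(arr)) == 3L)
    return(lapply(seq_len(dim(arr)[3]),
                  function(k) projection_2d(arr[, , k], pixel_spacing)))
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- apply(p, c(1, 2), mean)
    projection_2d(p, pixel_spacing)
  })
}
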