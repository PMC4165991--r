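#' Rigid transform (4x4 homogeneous matrix)
#'
#' Wraps a 4x4 homogeneous forward transformation carrying a B-scan plane
#' into physical space: a proper rotation block plus a translation in mm.
#'
#' @param matrix 4x4 numeric matrix. The upper-left 3x3 block must be
#'   orthonormal with determinant +1 (tolerance `1e-6`); the last row must
#'   be `(0, 0, 0, 1)`.
#' @return An object of class `rigid_transform` (the validated matrix).
#' @export
#' @examples
#' rigid_transform(diag(4))
rigid_transform <- function(matrix) {
  if (!is.matrix(matrix) || !all(dim(matrix) == c(4L, 4L)))
    stop("invalid transform: expected a 4x4 matrix", call. = FALSE)
  if (!all(is.finite(matrix)))
    stop("invalid transform: non-finite entries", call. = FALSE)
  if (max(abs(matrix[4L, ] - c(0, 0, 0, 1))) > 1e-6)
    stop("invalid transform: last row must be (0,0,0,1)", call. = FALSE)
  R <- matrix[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6)
    stop("invalid transform: rotation block not orthonormal with det +1",
         call. = FALSE)
  structure(matrix, class = "rigid_transform")
}

#' Build a rigid transform from rotation and translation
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 translation in mm.
#' @return A [rigid_transform()].
#' @export
make_pose <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  m <- diag(4)
  m[1:3, 1:3] <- rotation
  m[1:3, 4L] <- translation
  rigid_transform(m)
}

#' Elementary rotation matrices
#'
#' @param angle rotation angle in degrees.
#' @return 3x3 rotation matrix about the named axis.
#' @export
rot_x <- function(angle) {
  a <- angle * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3L, 3L)
}

#' @rdname rot_x
#' @export
rot_y <- function(angle) {
  a <- angle * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3L, 3L)
}

#' @rdname rot_x
#' @export
rot_z <- function(angle) {
  a <- angle * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3L, 3L)
}

#' Tracked B-scan frame
#'
#' One 2D grayscale B-scan (rows x cols matrix, intensities on the 8-bit
#' 0-255 scale) plus the rigid pose placing its local z = 0 plane in
#' physical space and the (square) pixel size in mm/pixel. Pixel `(u, v)`
#' (u = 0-based column, v = 0-based row) sits at in-plane millimetre
#' coordinates `(u * spacing, v * spacing, 0)`.
#'
#' @param image numeric matrix of finite, non-negative intensities.
#' @param pose a [rigid_transform()].
#' @param spacing pixel size in mm/pixel, > 0.
#' @param frame_id integer identifier.
#' @return An object of class `tracked_frame`.
#' @export
tracked_frame <- function(image, pose, spacing, frame_id = 0L) {
  if (!is.matrix(image) || length(image) == 0L)
    stop("image must be a non-empty matrix", call. = FALSE)
  if (!all(is.finite(image)) || any(image < 0))
    stop("image intensities must be finite and >= 0", call. = FALSE)
  if (!inherits(pose, "rigid_transform")) pose <- rigid_transform(pose)
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("spacing must be a positive scalar (mm/pixel)", call. = FALSE)
  structure(list(image = image, pose = pose, spacing = spacing,
                 frame_id = as.integer(frame_id)),
            class = "tracked_frame")
}

#' Regular voxel grid
#'
#' Geometry plus voxel payload of a reconstruction volume. Voxel `(i,j,k)`
#' (0-based) has its centre at `origin + c(i,j,k) * spacing` mm; the grid's
#' world box extends half a voxel beyond the outermost centres.
#'
#' @param origin length-3 position (mm) of the centre of voxel (0,0,0).
#' @param spacing length-3 voxel size in mm (a scalar is recycled).
#' @param dims length-3 positive integer dimensions (nx, ny, nz).
#' @param values optional 3D array of voxel values (defaults to zeros).
#' @param filled optional 3D logical mask of voxels holding data.
#' @param counts optional 3D integer array of per-voxel contribution counts.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(origin, spacing, dims, values = NULL, filled = NULL,
                        counts = NULL) {
  origin <- as.numeric(origin)
  spacing <- rep_len(as.numeric(spacing), 3L)
  dims <- as.integer(round(dims))
  if (length(origin) != 3L || !all(is.finite(origin)))
    stop("origin must be a finite 3-vector", call. = FALSE)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be positive", call. = FALSE)
  if (length(dims) != 3L || any(dims < 1L))
    stop("dims must be three integers >= 1", call. = FALSE)
  if (is.null(values)) values <- array(0, dim = dims)
  if (is.null(filled)) filled <- array(FALSE, dim = dims)
  if (is.null(counts)) counts <- array(0L, dim = dims)
  stopifnot(all(dim(values) == dims), all(dim(filled) == dims),
            all(dim(counts) == dims))
  if (!all(is.finite(values))) stop("values must be finite", call. = FALSE)
  structure(list(origin = origin, spacing = spacing, dims = dims,
                 values = values, filled = filled, counts = counts),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid %d x %d x %d, spacing %s mm, origin %s mm, %d/%d filled>\n",
              x$dims[1], x$dims[2], x$dims[3],
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ","),
              sum(x$filled), prod(x$dims)))
  invisible(x)
}

#' Map a B-scan pixel to physical space
#'
#' Applies the frame pose to the in-plane point
#' `(u * spacing, v * spacing, 0)`. No rounding is involved.
#'
#' @param pose a [rigid_transform()].
#' @param pixel length-2 `(u, v)` 0-based pixel indices (u = column,
#'   v = row), or an n x 2 matrix of them.
#' @param spacing pixel size in mm/pixel, > 0.
#' @return A length-3 position in mm (or n x 3 matrix).
#' @export
map_pixel_to_physical <- function(pose, pixel, spacing) {
  if (!inherits(pose, "rigid_transform")) pose <- rigid_transform(pose)
  stopifnot(spacing > 0)
  if (is.matrix(pixel)) {
    stopifnot(ncol(pixel) == 2L, all(pixel >= 0))
    pts <- cbind(pixel[, 1L] * spacing, pixel[, 2L] * spacing, 0, 1)
    out <- pts %*% t(unclass(pose))
    return(out[, 1:3, drop = FALSE])
  }
  stopifnot(length(pixel) == 2L, all(pixel >= 0))
  p <- unclass(pose) %*% c(pixel[1L] * spacing, pixel[2L] * spacing, 0, 1)
  as.numeric(p[1:3])
}

#' Convert a physical point to voxel indices
#'
#' Rounds `(point - origin) / spacing` to the nearest voxel per axis, with
#' half-way ties going toward the lower index. Out-of-grid points are
#' signalled by returning `NA` indices rather than by an error, so bulk
#' bin-filling can skip and count them.
#'
#' @param point length-3 position in mm.
#' @param grid a [volume_grid()].
#' @return Length-3 integer 0-based voxel indices, or `c(NA, NA, NA)` if
#'   the point falls outside the grid.
#' @export
physical_to_voxel <- function(point, grid) {
  stopifnot(inherits(grid, "volume_grid"), length(point) == 3L)
  idx <- as.integer(ceiling((point - grid$origin) / grid$spacing - 0.5))
  if (any(idx < 0L) || any(idx >= grid$dims)) return(rep(NA_integer_, 3L))
  idx
}

#' Continuous voxel coordinates of physical points
#'
#' @param points n x 3 matrix of positions in mm.
#' @param grid a [volume_grid()].
#' @return n x 3 matrix of continuous voxel-unit coordinates.
#' @keywords internal
physical_to_continuous <- function(points, grid) {
  sweep(sweep(points, 2L, grid$origin, "-"), 2L, grid$spacing, "/")
}

frame_corners_mm <- function(frame) {
  nr <- nrow(frame$image); nc <- ncol(frame$image)
  corners <- rbind(c(0, 0), c(nc - 1L, 0), c(0, nr - 1L), c(nc - 1L, nr - 1L))
  map_pixel_to_physical(frame$pose, corners, frame$spacing)
}

#' Axis-aligned grid bounding a set of tracked frames
#'
#' Builds an empty [volume_grid()] whose box covers the mapped corners of
#' every frame: the origin is the per-axis minimum corner and
#' `dims = ceil(extent / spacing) + 1`.
#'
#' @param frames list of [tracked_frame()] objects (at least one).
#' @param spacing voxel size in mm (scalar or length 3).
#' @return An empty [volume_grid()] covering all frames.
#' @export
compute_bounding_grid <- function(frames, spacing) {
  if (length(frames) == 0L) stop("empty frame list", call. = FALSE)
  spacing <- rep_len(as.numeric(spacing), 3L)
  corners <- do.call(rbind, lapply(frames, frame_corners_mm))
  lo <- apply(corners, 2L, min)
  hi <- apply(corners, 2L, max)
  dims <- as.integer(ceiling((hi - lo) / spacing - 1e-9)) + 1L
  volume_grid(origin = lo, spacing = spacing, dims = dims)
}
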