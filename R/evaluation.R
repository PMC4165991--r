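#' Reslice a volume along an oriented plane
#'
#' Samples the volume by trilinear interpolation at the physical position
#' of every pixel of a virtual B-scan with the given pose, shape and pixel
#' spacing. Pixels mapping outside the volume are masked invalid (their
#' value is 0 in the returned image).
#'
#' @param volume a [volume_grid()].
#' @param pose a [rigid_transform()] placing the plane.
#' @param shape `(rows, cols)` of the output image.
#' @param spacing pixel size in mm/pixel.
#' @return A list with `image` (rows x cols matrix) and logical `valid`
#'   mask of the same shape.
#' @export
reslice <- function(volume, pose, shape, spacing) {
  stopifnot(inherits(volume, "volume_grid"), length(shape) == 2L,
            spacing > 0)
  if (!inherits(pose, "rigid_transform")) pose <- rigid_transform(pose)
  res <- cpp_reslice(as.numeric(volume$values), volume$dims, volume$origin,
                     volume$spacing, unclass(pose),
                     as.integer(shape[1L]), as.integer(shape[2L]), spacing)
  list(image = res$image, valid = res$valid)
}

#' Root mean square error between two images
#'
#' `sqrt(mean((I_o - I_r)^2))` over the pixels marked valid.
#'
#' @param i_o,i_r numeric matrices of identical shape.
#' @param mask logical matrix of the same shape selecting the pixels to
#'   score (default: all).
#' @return Non-negative scalar RMSE in intensity units.
#' @export
rmse <- function(i_o, i_r, mask = NULL) {
  if (!all(dim(i_o) == dim(i_r)))
    stop("image shapes differ", call. = FALSE)
  if (is.null(mask)) mask <- array(TRUE, dim = dim(i_o))
  if (!all(dim(mask) == dim(i_o)))
    stop("mask shape differs from images", call. = FALSE)
  if (!any(mask)) stop("mask selects no pixels", call. = FALSE)
  sqrt(mean((i_o[mask] - i_r[mask])^2))
}

#' Leave-one-slice-out evaluation of a reconstruction method
#'
#' The quantitative protocol: one B-scan is removed from the sweep, the
#' volume is reconstructed from the remaining frames on a grid bounding
#' the full set, the volume is resliced at the removed frame's pose, and
#' the reslice is scored against the removed frame by [rmse()] over the
#' pixels that map inside the volume. A faithful reconstructor
#' interpolates the removed slice accurately from its neighbours.
#'
#' @param frames list of at least two [tracked_frame()] objects.
#' @param method one of `"kr"`, `"vnn"`, `"pnn"`, `"dw"`.
#' @param removed_index 1-based index into `frames` of the slice to hold
#'   out.
#' @param grid_spacing voxel size in mm of the reconstruction grid.
#' @param config a [kr_config()] (used for `method = "kr"`).
#' @param dw_radius,hfs_window baseline parameters, as in
#'   [reconstruct_sweep()].
#' @return A list of class `eval_result`: `method`, `removed_frame_id`,
#'   `rmse`, `n_pixels` (scored), `n_excluded` (out-of-volume pixels).
#' @export
leave_one_out <- function(frames, method = c("kr", "vnn", "pnn", "dw"),
                          removed_index, grid_spacing = 1,
                          config = kr_config(), dw_radius = 3,
                          hfs_window = 3L) {
  method <- match.arg(method)
  if (length(frames) < 2L)
    stop("need at least two frames", call. = FALSE)
  removed_index <- as.integer(removed_index)
  if (removed_index < 1L || removed_index > length(frames))
    stop("removed_index out of range", call. = FALSE)

  target <- frames[[removed_index]]
  rest <- frames[-removed_index]
  grid <- compute_bounding_grid(frames, grid_spacing)
  rec <- reconstruct_sweep(rest, method, grid = grid, config = config,
                           dw_radius = dw_radius, hfs_window = hfs_window)
  rs <- reslice(rec$volume, target$pose, dim(target$image), target$spacing)
  err <- rmse(target$image, rs$image, rs$valid)
  structure(list(method = method, removed_frame_id = target$frame_id,
                 rmse = err, n_pixels = sum(rs$valid),
                 n_excluded = sum(!rs$valid)),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result %s: removed frame %d, RMSE %.6f over %d px (%d excluded)>\n",
              x$method, x$removed_frame_id, x$rmse, x$n_pixels, x$n_excluded))
  invisible(x)
}

#' @export
as.data.frame.eval_result <- function(x, ...) {
  data.frame(method = x$method, removed_frame_id = x$removed_frame_id,
             rmse = x$rmse, n_pixels = x$n_pixels,
             n_excluded = x$n_excluded)
}
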