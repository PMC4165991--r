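#' Voxel nearest neighbour reconstruction
#'
#' Every voxel takes the intensity of the Euclidean-nearest sample in the
#' cloud. Exact distance ties break by lowest `frame_id`, then by input
#' order. VNN preserves raw pixel texture but cannot smooth, so distant
#' voxels inherit whichever slice happens to be closest.
#'
#' @param cloud a non-empty [sample_cloud()] in the grid's voxel units.
#' @param grid a [volume_grid()] supplying the geometry.
#' @return A fully filled [volume_grid()].
#' @export
reconstruct_vnn <- function(cloud, grid) {
  stopifnot(inherits(cloud, "sample_cloud"), inherits(grid, "volume_grid"))
  if (nrow(cloud$positions) == 0L) stop("empty sample cloud", call. = FALSE)
  vals <- cpp_vnn(cloud$positions, cloud$intensities, cloud$frame_ids,
                  grid$dims)
  volume_grid(grid$origin, grid$spacing, grid$dims,
              values = array(vals, dim = grid$dims),
              filled = array(TRUE, dim = grid$dims),
              counts = grid$counts)
}

#' Pixel nearest neighbour reconstruction (distribution + hole filling)
#'
#' The distribution step is identical to [distribute()] with the average
#' policy. The hole-filling step then assigns each still-empty voxel the
#' unweighted mean of the filled voxels inside its `hfs_window` cube,
#' computed in one pass from the distribution result; if empty voxels
#' remain, the pass is repeated with the window grown by 2 until none
#' remain or the window exceeds the largest grid dimension.
#'
#' @param frames list of [tracked_frame()] objects.
#' @param grid target [volume_grid()].
#' @param hfs_window odd integer edge of the hole-filling cube (default 3).
#' @return A [volume_grid()].
#' @export
reconstruct_pnn <- function(frames, grid, hfs_window = 3L) {
  if (length(frames) == 0L) stop("empty frame list", call. = FALSE)
  hfs_window <- as.integer(hfs_window)
  if (hfs_window < 1L || hfs_window %% 2L == 0L)
    stop("hfs_window must be an odd integer >= 1", call. = FALSE)
  ds <- distribute(frames, grid)
  res <- cpp_pnn_fill(as.numeric(ds$grid$values), as.logical(ds$grid$filled),
                      grid$dims, hfs_window)
  volume_grid(grid$origin, grid$spacing, grid$dims,
              values = array(res$values, dim = grid$dims),
              filled = array(res$filled, dim = grid$dims),
              counts = ds$grid$counts)
}

#' Inverse-distance weighted reconstruction
#'
#' Each voxel is the inverse-distance weighted mean `sum(Y_i/d_i) /
#' sum(1/d_i)` over samples within `radius` voxel units of its centre
#' (weight exponent 1). A sample closer than `1e-9` supplies its value
#' exactly (nearest such sample, `frame_id` tie-break). Voxels with no
#' sample in range are left unfilled at 0.
#'
#' @param cloud a non-empty [sample_cloud()] in the grid's voxel units.
#' @param grid a [volume_grid()] supplying the geometry.
#' @param radius neighbourhood radius in voxel units, > 0 (default 3).
#' @return A [volume_grid()].
#' @export
reconstruct_dw <- function(cloud, grid, radius = 3) {
  stopifnot(inherits(cloud, "sample_cloud"), inherits(grid, "volume_grid"))
  if (nrow(cloud$positions) == 0L) stop("empty sample cloud", call. = FALSE)
  if (!is.numeric(radius) || radius <= 0)
    stop("radius must be > 0", call. = FALSE)
  res <- cpp_dw(cloud$positions, cloud$intensities, cloud$frame_ids,
                grid$dims, radius)
  volume_grid(grid$origin, grid$spacing, grid$dims,
              values = array(res$values, dim = grid$dims),
              filled = array(res$filled, dim = grid$dims),
              counts = grid$counts)
}

#' Reconstruct a tracked sweep with a named method
#'
#' Convenience wrapper running bin-filling and the chosen reconstructor on
#' a grid bounding the frames (or a caller-supplied grid).
#'
#' @param frames list of [tracked_frame()] objects.
#' @param method one of `"kr"`, `"vnn"`, `"pnn"`, `"dw"`.
#' @param grid optional target [volume_grid()]; by default
#'   [compute_bounding_grid()] of the frames at `grid_spacing`.
#' @param grid_spacing voxel size in mm used when `grid` is `NULL`.
#' @param config a [kr_config()] for `method = "kr"`.
#' @param dw_radius radius (voxel units) for `method = "dw"`.
#' @param hfs_window hole-filling window for `method = "pnn"`.
#' @return A list with `volume` (the reconstructed [volume_grid()]),
#'   `cloud`, `binfill` (the distribution-step grid) and `n_skipped`.
#' @export
reconstruct_sweep <- function(frames, method = c("kr", "vnn", "pnn", "dw"),
                              grid = NULL, grid_spacing = 1,
                              config = kr_config(), dw_radius = 3,
                              hfs_window = 3L) {
  method <- match.arg(method)
  if (length(frames) == 0L) stop("empty frame list", call. = FALSE)
  if (is.null(grid)) grid <- compute_bounding_grid(frames, grid_spacing)
  bf <- distribute(frames, grid)
  volume <- switch(method,
    kr = reconstruct_kr(bf$cloud, bf$grid, config),
    vnn = reconstruct_vnn(bf$cloud, grid),
    pnn = reconstruct_pnn(frames, grid, hfs_window),
    dw = reconstruct_dw(bf$cloud, grid, dw_radius))
  list(volume = volume, cloud = bf$cloud, binfill = bf$grid,
       n_skipped = bf$n_skipped)
}
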