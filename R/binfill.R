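#' Sparse sample cloud
#'
#' The scattered samples produced by bin-filling: continuous voxel-unit
#' positions (voxel centres sit at integer coordinates), their intensities,
#' and the id of the frame each pixel came from.
#'
#' @param positions n x 3 numeric matrix of voxel-unit positions.
#' @param intensities length-n numeric vector of finite intensities.
#' @param frame_ids length-n integer vector (provenance).
#' @return An object of class `sample_cloud`.
#' @export
sample_cloud <- function(positions, intensities, frame_ids) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L)
    stop("positions must be an n x 3 matrix", call. = FALSE)
  n <- nrow(positions)
  if (length(intensities) != n || length(frame_ids) != n)
    stop("positions, intensities and frame_ids must have equal length",
         call. = FALSE)
  if (n > 0 && (!all(is.finite(intensities)) || !all(is.finite(positions))))
    stop("cloud positions and intensities must be finite", call. = FALSE)
  structure(list(positions = positions,
                 intensities = as.numeric(intensities),
                 frame_ids = as.integer(frame_ids)),
            class = "sample_cloud")
}

#' @export
print.sample_cloud <- function(x, ...) {
  cat(sprintf("<sample_cloud: %d samples from %d frames>\n",
              nrow(x$positions), length(unique(x$frame_ids))))
  invisible(x)
}

#' Bin-fill tracked frames into a voxel grid
#'
#' The first reconstruction stage: every pixel of every frame is mapped
#' through its pose into physical space and snapped to the nearest voxel.
#' Voxels hit by several pixels take the average of their contributions
#' (order-independent up to floating-point addition order). Pixels falling
#' outside the grid are skipped and counted. Alongside the snapped grid,
#' the continuous (unrounded) voxel-space position of every in-bounds
#' pixel is collected into a [sample_cloud()] for the regression stage.
#'
#' @param frames list of [tracked_frame()] objects.
#' @param grid target [volume_grid()] (its values are replaced).
#' @param policy collision policy; only `"average"` is supported.
#' @return A list with elements `grid` (filled [volume_grid()]), `cloud`
#'   (the [sample_cloud()]) and `n_skipped` (out-of-grid pixel count).
#' @export
distribute <- function(frames, grid, policy = "average") {
  if (length(frames) == 0L) stop("empty frame list", call. = FALSE)
  if (!identical(policy, "average"))
    stop("unsupported policy: ", policy, call. = FALSE)
  stopifnot(inherits(grid, "volume_grid"))
  for (f in frames) stopifnot(inherits(f, "tracked_frame"))

  res <- cpp_distribute(
    images = lapply(frames, `[[`, "image"),
    poses = lapply(frames, function(f) unclass(f$pose)),
    spacings = vapply(frames, `[[`, numeric(1), "spacing"),
    frame_ids = vapply(frames, `[[`, integer(1), "frame_id"),
    origin = grid$origin, gspacing = grid$spacing, dims = grid$dims)

  n <- res$n_samples
  out_grid <- volume_grid(grid$origin, grid$spacing, grid$dims,
                          values = array(res$values, dim = grid$dims),
                          filled = array(res$filled, dim = grid$dims),
                          counts = array(res$counts, dim = grid$dims))
  cloud <- sample_cloud(res$positions[seq_len(n), , drop = FALSE],
                        res$intensities[seq_len(n)],
                        res$frame_ids[seq_len(n)])
  list(grid = out_grid, cloud = cloud, n_skipped = res$n_skipped)
}

#' Export a sample cloud as a plain table
#'
#' Writes (or returns) the cloud as a 5-column table `x, y, z, intensity,
#' frame_id` in voxel units, mainly for debugging.
#'
#' @param cloud a [sample_cloud()].
#' @param path optional CSV path; when `NULL` the data frame is returned.
#' @return The data frame, invisibly when written to file.
#' @export
export_cloud <- function(cloud, path = NULL) {
  stopifnot(inherits(cloud, "sample_cloud"))
  df <- data.frame(x = cloud$positions[, 1L], y = cloud$positions[, 2L],
                   z = cloud$positions[, 3L],
                   intensity = cloud$intensities,
                   frame_id = cloud$frame_ids)
  if (is.null(path)) return(df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
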