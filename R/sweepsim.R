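#' Sweep simulation parameters
#'
#' Describes a simulated freehand sweep: a stack of parallel base poses
#' marching along the z axis, perturbed per frame by random tilts and
#' offsets (the freehand irregularity), with multiplicative speckle-like
#' noise on the sampled intensities.
#'
#' @param n_frames number of B-scans in the sweep (>= 1).
#' @param frame_shape `(rows, cols)` of each B-scan.
#' @param spacing pixel size in mm/pixel.
#' @param base_step nominal spacing in mm between successive frames.
#' @param tilt_jitter std, in degrees, of the random per-frame rotations
#'   about each axis.
#' @param offset_jitter std, in mm, of the random per-frame translations.
#' @param noise_sigma speckle strength (multiplicative noise std as a
#'   fraction of the local intensity).
#' @param seed integer seed; all randomness in the sweep derives from it.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(n_frames = 40L, frame_shape = c(64L, 64L),
                       spacing = 1.0, base_step = 1.5, tilt_jitter = 2,
                       offset_jitter = 0.3, noise_sigma = 0.1, seed = 7L) {
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) stop("n_frames must be >= 1", call. = FALSE)
  if (any(c(tilt_jitter, offset_jitter, noise_sigma) < 0))
    stop("jitter and noise parameters must be >= 0", call. = FALSE)
  stopifnot(spacing > 0, base_step >= 0, length(frame_shape) == 2L)
  structure(list(n_frames = n_frames,
                 frame_shape = as.integer(frame_shape), spacing = spacing,
                 base_step = base_step, tilt_jitter = tilt_jitter,
                 offset_jitter = offset_jitter, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "sweep_spec")
}

#' Render a digital phantom volume
#'
#' Renders geometric primitives (spheres, ellipsoids, axis-thick slabs)
#' onto a constant background, back to front: later primitives overwrite
#' earlier ones where they overlap. Primitive geometry is given in the
#' grid's physical coordinates (mm).
#'
#' @param dims 3 integers, each >= 8.
#' @param primitives non-empty list; each element is a list with `type`
#'   (`"sphere"`, `"ellipsoid"` or `"slab"`), `value`, and geometry
#'   fields: `center`/`radius` for spheres, `center`/`semiaxes` for
#'   ellipsoids, `normal`/`offset`/`thickness` for slabs (the slab is the
#'   set of points whose signed distance along the unit normal lies within
#'   `offset +/- thickness/2`).
#' @param seed integer seed (rendering is deterministic; the seed is part
#'   of the phantom's identity and is stored as an attribute).
#' @param background background intensity.
#' @param spacing voxel size in mm (scalar or length 3).
#' @param origin physical position of voxel (0,0,0).
#' @return A fully filled [volume_grid()] with attribute `"background"`.
#' @export
make_phantom <- function(dims, primitives, seed = 0L, background = 20,
                         spacing = 1, origin = c(0, 0, 0)) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 8L))
    stop("dims must be three integers >= 8", call. = FALSE)
  if (length(primitives) == 0L)
    stop("empty primitive list", call. = FALSE)
  spacing <- rep_len(as.numeric(spacing), 3L)
  gx <- origin[1L] + (seq_len(dims[1L]) - 1) * spacing[1L]
  gy <- origin[2L] + (seq_len(dims[2L]) - 1) * spacing[2L]
  gz <- origin[3L] + (seq_len(dims[3L]) - 1) * spacing[3L]
  px <- array(gx, dim = dims)
  py <- aperm(array(gy, dim = dims[c(2L, 1L, 3L)]), c(2L, 1L, 3L))
  pz <- aperm(array(gz, dim = dims[c(3L, 1L, 2L)]), c(2L, 3L, 1L))
  vals <- array(background, dim = dims)
  for (pr in primitives) {
    inside <- switch(pr$type,
      sphere = {
        (px - pr$center[1L])^2 + (py - pr$center[2L])^2 +
          (pz - pr$center[3L])^2 <= pr$radius^2
      },
      ellipsoid = {
        ((px - pr$center[1L]) / pr$semiaxes[1L])^2 +
          ((py - pr$center[2L]) / pr$semiaxes[2L])^2 +
          ((pz - pr$center[3L]) / pr$semiaxes[3L])^2 <= 1
      },
      slab = {
        nrm <- pr$normal / sqrt(sum(pr$normal^2))
        d <- px * nrm[1L] + py * nrm[2L] + pz * nrm[3L]
        abs(d - pr$offset) <= pr$thickness / 2
      },
      stop("unknown primitive type: ", pr$type, call. = FALSE))
    vals[inside] <- pr$value
  }
  out <- volume_grid(origin, spacing, dims, values = vals,
                     filled = array(TRUE, dim = dims),
                     counts = array(1L, dim = dims))
  attr(out, "background") <- background
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Default 64-cube phantom with spherical inclusions
#'
#' A 64 x 64 x 64 voxel phantom at 1 mm isotropic spacing: three bright
#' spheres of different sizes and intensities plus a dim slab, on a
#' background of 20 — a scaled-down stand-in for a tissue-mimicking
#' abdominal phantom.
#'
#' @return A [volume_grid()] phantom.
#' @export
default_phantom <- function() {
  make_phantom(
    dims = c(64L, 64L, 64L),
    primitives = list(
      list(type = "slab", normal = c(0, 1, 0), offset = 50, thickness = 6,
           value = 60),
      list(type = "sphere", center = c(31.5, 31.5, 31.5), radius = 12,
           value = 200),
      list(type = "sphere", center = c(16, 20, 24), radius = 6, value = 120),
      list(type = "sphere", center = c(46, 44, 20), radius = 8, value = 80)),
    background = 20)
}

#' Trilinear interpolation of a volume at physical points
#'
#' @param grid a [volume_grid()].
#' @param points n x 3 matrix of physical positions (mm).
#' @return A list with `values` (NA outside the grid) and logical
#'   `valid`.
#' @keywords internal
interp_trilinear <- function(grid, points) {
  cont <- physical_to_continuous(points, grid)
  d <- grid$dims
  valid <- cont[, 1L] >= 0 & cont[, 1L] <= d[1L] - 1 &
           cont[, 2L] >= 0 & cont[, 2L] <= d[2L] - 1 &
           cont[, 3L] >= 0 & cont[, 3L] <= d[3L] - 1
  vals <- rep(NA_real_, nrow(points))
  if (any(valid)) {
    cc <- cont[valid, , drop = FALSE]
    i0 <- pmin(pmax(floor(cc[, 1L]), 0), max(d[1L] - 2, 0))
    j0 <- pmin(pmax(floor(cc[, 2L]), 0), max(d[2L] - 2, 0))
    k0 <- pmin(pmax(floor(cc[, 3L]), 0), max(d[3L] - 2, 0))
    fx <- cc[, 1L] - i0; fy <- cc[, 2L] - j0; fz <- cc[, 3L] - k0
    i1 <- pmin(i0 + 1, d[1L] - 1); j1 <- pmin(j0 + 1, d[2L] - 1)
    k1 <- pmin(k0 + 1, d[3L] - 1)
    at <- function(i, j, k) grid$values[cbind(i + 1, j + 1, k + 1)]
    vals[valid] <-
      at(i0, j0, k0) * (1 - fx) * (1 - fy) * (1 - fz) +
      at(i1, j0, k0) * fx       * (1 - fy) * (1 - fz) +
      at(i0, j1, k0) * (1 - fx) * fy       * (1 - fz) +
      at(i1, j1, k0) * fx       * fy       * (1 - fz) +
      at(i0, j0, k1) * (1 - fx) * (1 - fy) * fz +
      at(i1, j0, k1) * fx       * (1 - fy) * fz +
      at(i0, j1, k1) * (1 - fx) * fy       * fz +
      at(i1, j1, k1) * fx       * fy       * fz
  }
  list(values = vals, valid = valid)
}

#' Apply multiplicative speckle-like noise
#'
#' `out = image * (1 + sigma * g)` with `g` i.i.d. standard normal per
#' pixel, then clipped to be non-negative. Deterministic given the seed.
#'
#' @param image 2D numeric matrix.
#' @param sigma noise strength, >= 0.
#' @param seed integer seed.
#' @return The noisy matrix, everywhere >= 0.
#' @export
add_speckle <- function(image, sigma, seed = 0L) {
  if (!is.numeric(sigma) || sigma < 0)
    stop("sigma must be >= 0", call. = FALSE)
  if (sigma == 0) return(image)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  g <- matrix(stats::rnorm(length(image)), nrow(image), ncol(image))
  pmax(image * (1 + sigma * g), 0)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulate a tracked freehand sweep through a phantom
#'
#' Frame k's pose starts from a base pose whose plane is normal to the z
#' axis, centred over the phantom and advanced `k * base_step` mm along z,
#' then is perturbed by seeded random tilts (degrees) about all three axes
#' and offsets (mm); rotations pivot about the frame centre so a tilt does
#' not also swing the frame away. Pixel intensities are sampled from the
#' phantom by trilinear interpolation and speckle noise is applied.
#' Everything is deterministic given `spec$seed`.
#'
#' @param phantom a [volume_grid()] ground-truth volume.
#' @param spec a [sweep_spec()].
#' @param background intensity for pixels falling outside the phantom
#'   (default: the phantom's `"background"` attribute, else 0). A warning
#'   is raised if an entire frame leaves the phantom.
#' @return A list of [tracked_frame()] objects.
#' @export
simulate_sweep <- function(phantom, spec, background = NULL) {
  stopifnot(inherits(phantom, "volume_grid"), inherits(spec, "sweep_spec"))
  if (is.null(background))
    background <- attr(phantom, "background") %||% 0
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)

  nr <- spec$frame_shape[1L]; nc <- spec$frame_shape[2L]
  # frame centre in local mm coordinates; the base pose places it over the
  # phantom centre at the frame's z station
  c_local <- c((nc - 1) / 2 * spec$spacing, (nr - 1) / 2 * spec$spacing, 0)
  pcenter <- phantom$origin + (phantom$dims - 1) * phantom$spacing / 2
  z0 <- phantom$origin[3L] +
    ((phantom$dims[3L] - 1) * phantom$spacing[3L] -
       (spec$n_frames - 1) * spec$base_step) / 2

  # all jitter drawn up front in a fixed order so frame k's pose does not
  # depend on how many pixels earlier frames had
  tilts <- matrix(stats::rnorm(3 * spec$n_frames, 0, spec$tilt_jitter),
                  spec$n_frames, 3L)
  offsets <- matrix(stats::rnorm(3 * spec$n_frames, 0, spec$offset_jitter),
                    spec$n_frames, 3L)
  frame_seeds <- sample.int(.Machine$integer.max, spec$n_frames)

  uv <- cbind(rep(seq_len(nc) - 1L, each = nr),
              rep(seq_len(nr) - 1L, times = nc))

  frames <- vector("list", spec$n_frames)
  for (k in seq_len(spec$n_frames)) {
    Rw <- rot_z(tilts[k, 3L]) %*% rot_y(tilts[k, 2L]) %*% rot_x(tilts[k, 1L])
    c_world <- c(pcenter[1L], pcenter[2L], z0 + (k - 1) * spec$base_step) +
      offsets[k, ]
    pose <- make_pose(Rw, c_world - Rw %*% c_local)
    pts <- map_pixel_to_physical(pose, uv, spec$spacing)
    smp <- interp_trilinear(phantom, pts)
    if (!any(smp$valid) )
      warning("frame ", k - 1L, " lies entirely outside the phantom")
    v <- smp$values
    v[!smp$valid] <- background
    img <- matrix(v, nr, nc)
    img <- add_speckle(img, spec$noise_sigma, frame_seeds[k])
    frames[[k]] <- tracked_frame(img, pose, spec$spacing, frame_id = k - 1L)
  }
  frames
}

`%||%` <- function(a, b) if (is.null(a)) b else a
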