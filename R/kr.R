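#' Kernel regression configuration
#'
#' Parameters of the local polynomial kernel regression estimator. The
#' defaults (order 1, window 15 voxels, bandwidth 0.5 voxel units) are the
#' settings used throughout the package's reference experiments.
#'
#' @param order polynomial order N of the local fit: 0 (constant,
#'   Nadaraya-Watson), 1 (linear) or 2 (quadratic).
#' @param window edge length R, in voxels, of the cube neighbourhood
#'   centred on the target voxel; odd integer >= 1. Samples within
#'   Chebyshev distance `(R - 1) / 2` of the voxel centre participate.
#' @param bandwidth Gaussian kernel bandwidth h in voxel units, > 0.
#' @param kernel kernel family; only `"gaussian"` is supported.
#' @param min_samples minimum neighbour count for a full-order fit;
#'   defaults to the basis length (1, 4 or 10) so the weighted
#'   least-squares system is determined.
#' @param cond_limit condition-number ceiling for the normal equations;
#'   beyond it the fit is declared ill-posed and the fallback applies.
#' @param fallback what to do for voxels whose full-order system is
#'   underdetermined or ill-conditioned: `"order_zero"` (kernel-weighted
#'   mean of the neighbours) or `"leave_empty"` (value 0, unfilled).
#' @param preserve_filled if `TRUE`, voxels already filled by bin-filling
#'   keep their binned value and only empty voxels are estimated. By
#'   default every voxel is re-estimated, which also smooths speckle at
#'   sampled locations.
#' @return An object of class `kr_config`.
#' @export
kr_config <- function(order = 1L, window = 15L, bandwidth = 0.5,
                      kernel = "gaussian", min_samples = NULL,
                      cond_limit = 1e8, fallback = "order_zero",
                      preserve_filled = FALSE) {
  order <- as.integer(order)
  window <- as.integer(window)
  if (!order %in% 0:2) stop("order must be 0, 1 or 2", call. = FALSE)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be an odd integer >= 1", call. = FALSE)
  if (!is.numeric(bandwidth) || bandwidth <= 0)
    stop("invalid bandwidth: must be > 0", call. = FALSE)
  kernel <- match.arg(kernel, "gaussian")
  fallback <- match.arg(fallback, c("order_zero", "leave_empty"))
  blen <- c(1L, 4L, 10L)[order + 1L]
  if (is.null(min_samples)) min_samples <- blen
  min_samples <- as.integer(min_samples)
  if (min_samples < 1L) stop("min_samples must be >= 1", call. = FALSE)
  structure(list(order = order, window = window, bandwidth = bandwidth,
                 kernel = kernel, min_samples = min_samples,
                 cond_limit = cond_limit, fallback = fallback,
                 preserve_filled = isTRUE(preserve_filled),
                 basis_length = blen),
            class = "kr_config")
}

#' Gaussian kernel weight
#'
#' `exp(-||u||^2 / (2 h^2))`: symmetric, maximal (= 1) at zero offset and
#' strictly decreasing in the offset norm. The kernel's normalisation
#' constant is omitted throughout the package because any constant factor
#' cancels in the weighted least-squares solution.
#'
#' @param u length-3 offset in voxel units, or an n x 3 matrix of offsets.
#' @param h bandwidth in voxel units, > 0.
#' @return Non-negative weight(s).
#' @export
kernel_weight <- function(u, h) {
  if (!is.numeric(h) || length(h) != 1L || h <= 0)
    stop("invalid bandwidth: must be > 0", call. = FALSE)
  if (is.matrix(u)) {
    stopifnot(ncol(u) == 3L, all(is.finite(u)))
    return(exp(-rowSums(u^2) / (2 * h^2)))
  }
  stopifnot(length(u) == 3L, all(is.finite(u)))
  exp(-sum(u^2) / (2 * h^2))
}

#' Polynomial basis vector of a sample offset
#'
#' Monomials of the offset `delta = X_i - X` up to total degree N, in the
#' fixed order `1, d1, d2, d3, d1^2, d2^2, d3^2, d1 d2, d1 d3, d2 d3`.
#'
#' @param delta length-3 offset.
#' @param order polynomial order N in `0:2`.
#' @return Numeric vector of length 1, 4 or 10.
#' @export
basis_vector <- function(delta, order) {
  if (!order %in% 0:2) stop("unsupported order: ", order, call. = FALSE)
  stopifnot(length(delta) == 3L)
  d1 <- delta[1L]; d2 <- delta[2L]; d3 <- delta[3L]
  switch(order + 1L,
         1,
         c(1, d1, d2, d3),
         c(1, d1, d2, d3, d1^2, d2^2, d3^2, d1 * d2, d1 * d3, d2 * d3))
}

basis_matrix <- function(deltas, order) {
  if (order == 0L) return(matrix(1, nrow(deltas), 1L))
  t(apply(deltas, 1L, basis_vector, order = order))
}

#' Local polynomial estimate at one target position
#'
#' Fits the order-N polynomial through the neighbour samples by weighted
#' least squares, with Gaussian weights centred on the target, and returns
#' the fitted value at the target (the intercept of the centred fit). The
#' caller supplies the neighbours (all samples within the window cube of
#' the target); this function does no spatial search. Weights are rescaled
#' so the nearest sample has weight 1 — a constant factor that leaves the
#' least-squares solution unchanged but keeps tiny bandwidths numerically
#' meaningful.
#'
#' If fewer than `min_samples` neighbours are available, or the normal
#' equations are ill-conditioned beyond `cond_limit`, the configured
#' fallback applies: the order-zero kernel-weighted mean (`"order_zero"`)
#' or an empty result (`"leave_empty"`). An empty neighbour set always
#' yields an empty result.
#'
#' @param target length-3 position in voxel units.
#' @param neighbors a [sample_cloud()] subset local to the target.
#' @param config a [kr_config()].
#' @return A list with `value` (the estimate, 0 when empty) and `status`
#'   (one of `"ok"`, `"fallback"`, `"empty"`).
#' @export
local_estimate <- function(target, neighbors, config = kr_config()) {
  stopifnot(inherits(neighbors, "sample_cloud"),
            inherits(config, "kr_config"), length(target) == 3L)
  n <- nrow(neighbors$positions)
  if (n == 0L) return(list(value = 0, status = "empty"))

  deltas <- sweep(neighbors$positions, 2L, as.numeric(target), "-")
  d2 <- rowSums(deltas^2)
  w <- exp(-(d2 - min(d2)) / (2 * config$bandwidth^2))
  y <- neighbors$intensities

  nw_mean <- function() sum(w * y) / sum(w)

  if (n >= config$min_samples) {
    if (config$order == 0L)
      return(list(value = nw_mean(), status = "ok"))
    X <- basis_matrix(deltas, config$order)
    A <- crossprod(X, w * X)
    rc <- rcond(A)
    if (is.finite(rc) && rc > 1 / config$cond_limit) {
      beta <- solve(A, crossprod(X, w * y))
      return(list(value = beta[1L], status = "ok"))
    }
  }
  if (config$fallback == "order_zero")
    list(value = nw_mean(), status = "fallback")
  else
    list(value = 0, status = "empty")
}

#' Kernel regression reconstruction of a full volume
#'
#' The second reconstruction stage: every voxel value is the local
#' polynomial estimate at its centre over the cloud samples lying within
#' the `window`-cube around it (see [local_estimate()]). Voxels whose
#' estimate comes back empty are set to 0 and left out of the filled
#' mask. With `preserve_filled = TRUE` in the config, bin-filled voxels
#' keep the grid's current value instead of being re-estimated.
#'
#' @param cloud a non-empty [sample_cloud()] in the grid's voxel units.
#' @param grid a [volume_grid()] supplying the geometry (and, for
#'   `preserve_filled`, the bin-filled values and mask).
#' @param config a [kr_config()].
#' @return A [volume_grid()] with estimated `values` and `filled` mask;
#'   attribute `"kr_stats"` carries the ok / fallback / empty voxel
#'   counts.
#' @export
reconstruct_kr <- function(cloud, grid, config = kr_config()) {
  stopifnot(inherits(cloud, "sample_cloud"), inherits(grid, "volume_grid"),
            inherits(config, "kr_config"))
  if (nrow(cloud$positions) == 0L)
    stop("empty sample cloud", call. = FALSE)
  halfw <- (config$window - 1L) %/% 2L
  preserve <- if (config$preserve_filled) as.logical(grid$filled) else logical(0)
  res <- cpp_kr_reconstruct(cloud$positions, cloud$intensities, grid$dims,
                            config$order, halfw, config$bandwidth,
                            config$min_samples, config$cond_limit,
                            as.integer(config$fallback == "leave_empty"),
                            preserve, as.numeric(grid$values))
  out <- volume_grid(grid$origin, grid$spacing, grid$dims,
                     values = array(res$values, dim = grid$dims),
                     filled = array(res$filled, dim = grid$dims),
                     counts = grid$counts)
  attr(out, "kr_stats") <- c(ok = res$n_ok, fallback = res$n_fallback,
                             empty = res$n_empty)
  out
}
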