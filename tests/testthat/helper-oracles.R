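# Independent brute-force oracles and small fixtures shared by the tests.
# These deliberately avoid the package's own code paths: the WLS oracle
# builds its design matrix inline, the nearest-neighbour oracle is an
# exhaustive scan, and the RMSE oracle is an explicit pixel loop.

random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

# weighted normal equations solved directly with raw Gaussian weights
oracle_wls <- function(target, positions, y, order, h) {
  d <- sweep(positions, 2L, target, "-")
  w <- exp(-rowSums(d^2) / (2 * h^2))
  X <- switch(order + 1L,
    matrix(1, nrow(d), 1L),
    cbind(1, d),
    cbind(1, d, d^2, d[, 1L] * d[, 2L], d[, 1L] * d[, 3L],
          d[, 2L] * d[, 3L]))
  A <- t(X) %*% (w * X)
  b <- t(X) %*% (w * y)
  drop(solve(A, b))[1L]
}

oracle_nearest <- function(target, positions, y, frame_ids) {
  d2 <- rowSums(sweep(positions, 2L, target, "-")^2)
  cand <- which(d2 == min(d2))
  cand <- cand[order(frame_ids[cand], cand)]
  y[cand[1L]]
}

oracle_rmse <- function(a, b, mask) {
  s <- 0; n <- 0L
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a))) {
    if (mask[i, j]) {
      s <- s + (a[i, j] - b[i, j])^2
      n <- n + 1L
    }
  }
  sqrt(s / n)
}

random_cloud <- function(n, lo = -3, hi = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sample_cloud(matrix(runif(3 * n, lo, hi), n, 3L),
               runif(n, 0, 255), sample.int(5L, n, replace = TRUE) - 1L)
}

# small noiseless sweep through a 16^3 one-sphere phantom
tiny_phantom <- function() {
  make_phantom(c(16L, 16L, 16L),
               list(list(type = "sphere", center = c(7.5, 7.5, 7.5),
                         radius = 5, value = 150)),
               background = 10)
}

tiny_sweep <- function(n_frames = 8L, noise_sigma = 0, tilt_jitter = 0,
                       offset_jitter = 0, seed = 42L) {
  simulate_sweep(tiny_phantom(),
                 sweep_spec(n_frames = n_frames, frame_shape = c(16L, 16L),
                            spacing = 1, base_step = 1.5,
                            tilt_jitter = tilt_jitter,
                            offset_jitter = offset_jitter,
                            noise_sigma = noise_sigma, seed = seed))
}

# axis-aligned identity-rotation stack whose pixels coincide with the
# voxel centres of a unit-spacing grid
aligned_stack <- function(n_frames, shape = c(8L, 8L), step = 1,
                          values = NULL, seed = 3L) {
  set.seed(seed)
  lapply(seq_len(n_frames), function(k) {
    img <- if (is.null(values))
      matrix(round(runif(prod(shape), 0, 255)), shape[1L], shape[2L])
    else matrix(values, shape[1L], shape[2L])
    tracked_frame(img, make_pose(diag(3), c(0, 0, (k - 1) * step)),
                  spacing = 1, frame_id = k - 1L)
  })
}
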