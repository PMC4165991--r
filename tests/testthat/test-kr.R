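test_that("Gaussian kernel weight has the stated shape", {
  expect_equal(kernel_weight(c(0, 0, 0), 2), 1.0)
  expect_equal(kernel_weight(c(1, 0, 0), 1), exp(-0.5))
  expect_equal(kernel_weight(c(0, 3, 4), 5), exp(-0.5))  # ||u|| = h
  set.seed(31)
  for (i in 1:10) {
    u <- rnorm(3); h <- runif(1, 0.2, 3)
    expect_equal(kernel_weight(u, h), kernel_weight(-u, h))
  }
  # strictly decreasing in the offset norm
  expect_gt(kernel_weight(c(1, 0, 0), 1), kernel_weight(c(1.5, 0, 0), 1))
  expect_error(kernel_weight(c(0, 0, 0), 0), "bandwidth")
  expect_error(kernel_weight(c(0, 0, 0), -1), "bandwidth")
})

test_that("basis vectors enumerate the monomials in fixed order", {
  expect_equal(basis_vector(c(9, 9, 9), 0L), 1)
  expect_equal(basis_vector(c(1, 2, 3), 1L), c(1, 1, 2, 3))
  expect_equal(basis_vector(c(1, 0, 0), 2L),
               c(1, 1, 0, 0, 1, 0, 0, 0, 0, 0))
  d <- c(2, -1, 3)
  expect_equal(basis_vector(d, 2L),
               c(1, 2, -1, 3, 4, 1, 9, -2, 6, -3))
  expect_error(basis_vector(c(0, 0, 0), 3L), "order")
})

test_that("local estimates reproduce trivial cases", {
  cfg0 <- kr_config(order = 0L)
  one <- sample_cloud(matrix(c(0.4, 0.1, 0), 1L, 3L), 7, 0L)
  res <- local_estimate(c(0, 0, 0), one, cfg0)
  expect_equal(res$value, 7)
  expect_equal(res$status, "ok")

  set.seed(32)
  for (order in 0:2) {
    cl <- random_cloud(25, seed = 32 + order)
    cl$intensities[] <- 42
    res <- local_estimate(c(0.5, -0.5, 1), cl, kr_config(order = order,
                                                         bandwidth = 1.5))
    expect_equal(res$value, 42, tolerance = 1e-9)
  }
})

test_that("local linear fits reproduce degree-1 fields exactly", {
  set.seed(33)
  pos <- matrix(runif(60, -3, 3), 20L, 3L)
  f <- function(p) 2 * p[, 1L] + 3 * p[, 2L] - p[, 3L] + 5
  cl <- sample_cloud(pos, f(pos), rep(0L, 20L))
  for (h in c(0.5, 1, 4)) {
    target <- c(0.3, -0.2, 0.9)
    res <- local_estimate(target, cl, kr_config(order = 1L, bandwidth = h))
    expect_equal(res$status, "ok")
    expect_lt(abs(res$value - f(matrix(target, 1L))), 1e-6)
  }
})

test_that("local estimates match the brute-force WLS oracle", {
  set.seed(34)
  for (i in 1:30) {
    order <- i %% 3L
    n <- sample(12:30, 1L)
    cl <- random_cloud(n)
    h <- runif(1, 1, 2.5)
    target <- runif(3, -1, 1)
    got <- local_estimate(target, cl, kr_config(order = order, bandwidth = h))
    want <- oracle_wls(target, cl$positions, cl$intensities, order, h)
    expect_lt(abs(got$value - want), 1e-8)
  }
})

test_that("sparse or degenerate neighbourhoods trigger the fallback", {
  # 3 samples cannot determine a 4-term linear fit
  cl <- random_cloud(3, seed = 35)
  res <- local_estimate(c(0, 0, 0), cl, kr_config(order = 1L, bandwidth = 2))
  expect_equal(res$status, "fallback")
  d2 <- rowSums(cl$positions^2)
  w <- exp(-(d2 - min(d2)) / (2 * 4))
  expect_equal(res$value, sum(w * cl$intensities) / sum(w), tolerance = 1e-12)

  res2 <- local_estimate(c(0, 0, 0), cl,
                         kr_config(order = 1L, bandwidth = 2,
                                   fallback = "leave_empty"))
  expect_equal(res2$status, "empty")
  expect_equal(res2$value, 0)

  # coplanar samples leave the out-of-plane slope unidentified
  pos <- cbind(runif(12, -2, 2), runif(12, -2, 2), 0)
  flat <- sample_cloud(pos, runif(12), rep(0L, 12L))
  res3 <- local_estimate(c(0, 0, 0.5), flat,
                         kr_config(order = 1L, bandwidth = 2))
  expect_equal(res3$status, "fallback")

  none <- sample_cloud(matrix(numeric(0), 0L, 3L), numeric(0), integer(0))
  expect_equal(local_estimate(c(0, 0, 0), none, kr_config())$status, "empty")
})

test_that("order-0 estimates are the Nadaraya-Watson mean and bounded", {
  set.seed(36)
  for (i in 1:10) {
    cl <- random_cloud(15)
    h <- runif(1, 0.3, 2)
    target <- runif(3, -1, 1)
    got <- local_estimate(target, cl, kr_config(order = 0L, bandwidth = h))
    w <- kernel_weight(sweep(cl$positions, 2L, target, "-"), h)
    expect_lt(abs(got$value - sum(w * cl$intensities) / sum(w)), 1e-10)
    expect_gte(got$value, min(cl$intensities) - 1e-12)
    expect_lte(got$value, max(cl$intensities) + 1e-12)
  }
})

test_that("estimates are translation invariant and linear in intensity", {
  set.seed(37)
  cl <- random_cloud(20)
  target <- c(0.2, 0.4, -0.1)
  for (order in 0:2) {
    cfg <- kr_config(order = order, bandwidth = 1.2)
    base <- local_estimate(target, cl, cfg)$value
    shift <- c(5, -3, 11)
    cl2 <- sample_cloud(sweep(cl$positions, 2L, shift, "+"),
                        cl$intensities, cl$frame_ids)
    expect_lt(abs(local_estimate(target + shift, cl2, cfg)$value - base),
              1e-9)
    cl3 <- sample_cloud(cl$positions, 2.5 * cl$intensities, cl$frame_ids)
    expect_lt(abs(local_estimate(target, cl3, cfg)$value - 2.5 * base),
              1e-8)
  }
})

test_that("bandwidth limits recover the plain mean and nearest neighbour", {
  set.seed(38)
  cl <- random_cloud(25)
  target <- c(0.1, 0.2, 0.3)
  # at h = 100 the weights are flat to within ~2e-3 over a [-3,3] cloud
  wide <- local_estimate(target, cl, kr_config(order = 0L, bandwidth = 100))
  expect_lt(abs(wide$value - mean(cl$intensities)), 2e-2)
  exact <- local_estimate(target, cl, kr_config(order = 0L, bandwidth = 1e4))
  expect_lt(abs(exact$value - mean(cl$intensities)), 1e-6)
  narrow <- local_estimate(target, cl, kr_config(order = 0L,
                                                 bandwidth = 1e-3))
  expect_equal(narrow$value,
               oracle_nearest(target, cl$positions, cl$intensities,
                              cl$frame_ids))
})

test_that("full-volume KR matches a per-voxel local_estimate loop", {
  set.seed(39)
  dims <- c(9L, 8L, 7L)
  n <- 350L
  pos <- cbind(runif(n, 0, dims[1L] - 1), runif(n, 0, dims[2L] - 1),
               runif(n, 0, dims[3L] - 1))
  cl <- sample_cloud(pos, runif(n, 0, 255), rep_len(0:3, n))
  g <- volume_grid(c(0, 0, 0), 1, dims)
  cfg <- kr_config(order = 1L, window = 5L, bandwidth = 1.0)
  vol <- reconstruct_kr(cl, g, cfg)
  hw <- (cfg$window - 1) / 2
  for (i in 0:(dims[1L] - 1)) for (j in 0:(dims[2L] - 1))
    for (k in 0:(dims[3L] - 1)) {
      keep <- abs(pos[, 1L] - i) <= hw & abs(pos[, 2L] - j) <= hw &
        abs(pos[, 3L] - k) <= hw
      sub <- sample_cloud(pos[keep, , drop = FALSE], cl$intensities[keep],
                          cl$frame_ids[keep])
      ref <- local_estimate(c(i, j, k), sub, cfg)
      expect_lt(abs(vol$values[i + 1, j + 1, k + 1] - ref$value), 1e-8)
      expect_equal(vol$filled[i + 1, j + 1, k + 1], ref$status != "empty")
    }
})

test_that("voxels with empty neighbourhoods follow the fallback policy", {
  # one sample in a corner; far voxels see nothing within the window
  cl <- sample_cloud(matrix(c(0, 0, 0), 1L, 3L), 99, 0L)
  g <- volume_grid(c(0, 0, 0), 1, c(9L, 3L, 3L))
  cfg <- kr_config(order = 0L, window = 3L, fallback = "leave_empty")
  vol <- reconstruct_kr(cl, g, cfg)
  expect_equal(vol$values[1, 1, 1], 99)
  expect_true(vol$filled[1, 1, 1])
  expect_equal(vol$values[9, 1, 1], 0)
  expect_false(vol$filled[9, 1, 1])
  expect_error(reconstruct_kr(sample_cloud(matrix(numeric(0), 0L, 3L),
                                           numeric(0), integer(0)),
                              g, cfg), "empty")
})

test_that("polynomial fields are reconstructed exactly up to the order", {
  set.seed(40)
  dims <- c(8L, 8L, 8L)
  n <- 700L
  pos <- cbind(runif(n, -1, dims[1L]), runif(n, -1, dims[2L]),
               runif(n, -1, dims[3L]))
  polys <- list(
    function(p) rep(7, nrow(p)),
    function(p) 1 + 0.5 * p[, 1L] - 0.25 * p[, 2L] + p[, 3L],
    function(p) 2 + p[, 1L] - p[, 2L] + 0.5 * p[, 3L] +
      0.1 * p[, 1L]^2 - 0.2 * p[, 2L]^2 + 0.05 * p[, 3L]^2 +
      0.3 * p[, 1L] * p[, 2L] - 0.1 * p[, 1L] * p[, 3L] +
      0.2 * p[, 2L] * p[, 3L])
  g <- volume_grid(c(0, 0, 0), 1, dims)
  centres <- as.matrix(expand.grid(x = 0:7, y = 0:7, z = 0:7))
  for (order in 0:2) {
    f <- polys[[order + 1L]]
    cl <- sample_cloud(pos, f(pos), rep(0L, n))
    cfg <- kr_config(order = order, window = 15L, bandwidth = 1.2)
    vol <- reconstruct_kr(cl, g, cfg)
    truth <- array(f(centres), dim = dims)
    expect_lt(max(abs(vol$values - truth)), 1e-6)
  }
})

test_that("preserve_filled keeps bin-filled voxels untouched", {
  frames <- aligned_stack(3L, shape = c(6L, 6L), step = 2)
  g <- compute_bounding_grid(frames, 1)
  bf <- distribute(frames, g)
  cfg <- kr_config(order = 1L, window = 5L, preserve_filled = TRUE)
  vol <- reconstruct_kr(bf$cloud, bf$grid, cfg)
  expect_equal(vol$values[bf$grid$filled], bf$grid$values[bf$grid$filled])
  # in-between planes are estimated, not left at zero
  expect_true(all(vol$filled))
})

test_that("kr_config validates its fields", {
  expect_error(kr_config(order = 3), "order")
  expect_error(kr_config(window = 4), "window")
  expect_error(kr_config(bandwidth = 0), "bandwidth")
  expect_error(kr_config(min_samples = 0), "min_samples")
  expect_equal(kr_config(order = 2)$min_samples, 10L)
})
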