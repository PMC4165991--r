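test_that("VNN copies the nearest sample and honours tie-breaks", {
  g <- volume_grid(c(0, 0, 0), 1, c(3L, 3L, 1L))
  cl <- sample_cloud(rbind(c(1, 1, 0), c(2.4, 1, 0)), c(50, 90), c(1L, 0L))
  vol <- reconstruct_vnn(cl, g)
  expect_equal(vol$values[2, 2, 1], 50)   # coincident sample
  expect_equal(vol$values[3, 2, 1], 90)   # nearest is the second sample

  single <- sample_cloud(matrix(c(0.2, 0.7, 0), 1L, 3L), 123, 5L)
  vol1 <- reconstruct_vnn(single, g)
  expect_true(all(vol1$values == 123))

  # equidistant samples: lowest frame_id wins
  tie <- sample_cloud(rbind(c(0, 1, 0), c(2, 1, 0)), c(10, 20), c(1L, 0L))
  vol2 <- reconstruct_vnn(tie, g)
  expect_equal(vol2$values[2, 2, 1], 20)
  tie2 <- sample_cloud(rbind(c(0, 1, 0), c(2, 1, 0)), c(10, 20), c(0L, 1L))
  expect_equal(reconstruct_vnn(tie2, g)$values[2, 2, 1], 10)

  expect_error(reconstruct_vnn(sample_cloud(matrix(numeric(0), 0L, 3L),
                                            numeric(0), integer(0)), g),
               "empty")
})

test_that("VNN agrees with exhaustive search and invents no values", {
  set.seed(51)
  g <- volume_grid(c(0, 0, 0), 1, c(6L, 5L, 4L))
  for (rep in 1:5) {
    n <- sample(5:40, 1L)
    cl <- sample_cloud(cbind(runif(n, 0, 5), runif(n, 0, 4), runif(n, 0, 3)),
                       runif(n, 0, 255), sample.int(4L, n, TRUE) - 1L)
    vol <- reconstruct_vnn(cl, g)
    expect_true(all(vol$values %in% cl$intensities))
    for (i in 0:5) for (j in 0:4) for (k in 0:3) {
      want <- oracle_nearest(c(i, j, k), cl$positions, cl$intensities,
                             cl$frame_ids)
      expect_equal(vol$values[i + 1, j + 1, k + 1], want)
    }
  }
})

test_that("PNN distribution step equals distribute and holes fill by means", {
  frames <- aligned_stack(3L, shape = c(5L, 5L), step = 2)
  g <- compute_bounding_grid(frames, 1)
  bf <- distribute(frames, g)
  vol <- reconstruct_pnn(frames, g, hfs_window = 3L)
  # distribution step: filled voxels carry the binned values
  expect_equal(vol$values[bf$grid$filled], bf$grid$values[bf$grid$filled])
  # hole between slices: mean of the filled voxels in the 3-cube
  expect_equal(vol$values[3, 3, 2],
               mean(c(bf$grid$values[2:4, 2:4, 1],
                      bf$grid$values[2:4, 2:4, 3])))
  expect_true(all(vol$filled))
  expect_error(reconstruct_pnn(list(), g), "empty")
})

test_that("hole filling is the identity on a fully filled grid", {
  frames <- aligned_stack(4L, shape = c(4L, 4L), step = 1)
  g <- compute_bounding_grid(frames, 1)
  bf <- distribute(frames, g)
  expect_true(all(bf$grid$filled))
  vol <- reconstruct_pnn(frames, g, hfs_window = 3L)
  expect_equal(vol$values, bf$grid$values)
})

test_that("PNN leaves no empty voxels even across wide gaps", {
  frames <- aligned_stack(2L, shape = c(4L, 4L), step = 11)
  g <- compute_bounding_grid(frames, 1)
  vol <- reconstruct_pnn(frames, g, hfs_window = 3L)
  expect_true(all(vol$filled))
})

test_that("DW weights by inverse distance inside the radius", {
  g <- volume_grid(c(0, 0, 0), 1, c(3L, 3L, 1L))
  cl <- sample_cloud(rbind(c(1, 0, 0), c(1, 2, 0)), c(10, 20), c(0L, 1L))
  vol <- reconstruct_dw(cl, g, radius = 3)
  expect_equal(vol$values[2, 2, 1], 15)  # equidistant: equal weights
  # coincident sample wins exactly
  cl2 <- sample_cloud(rbind(c(1, 1, 0), c(1, 2, 0)), c(77, 20), c(0L, 1L))
  expect_equal(reconstruct_dw(cl2, g, radius = 3)$values[2, 2, 1], 77)
  # out-of-radius voxels stay unfilled at zero
  far <- sample_cloud(matrix(c(0, 0, 0), 1L, 3L), 50, 0L)
  vol3 <- reconstruct_dw(far, g, radius = 1)
  expect_false(vol3$filled[3, 3, 1])
  expect_equal(vol3$values[3, 3, 1], 0)
  expect_error(reconstruct_dw(cl, g, radius = 0), "radius")
})

test_that("DW matches a direct weighted-sum oracle and stays bounded", {
  set.seed(52)
  g <- volume_grid(c(0, 0, 0), 1, c(5L, 5L, 3L))
  for (rep in 1:5) {
    n <- sample(10:60, 1L)
    cl <- sample_cloud(cbind(runif(n, 0, 4), runif(n, 0, 4), runif(n, 0, 2)),
                       runif(n, 0, 255), sample.int(3L, n, TRUE) - 1L)
    radius <- runif(1, 1, 3)
    vol <- reconstruct_dw(cl, g, radius)
    for (i in 0:4) for (j in 0:4) for (k in 0:2) {
      d <- sqrt(rowSums(sweep(cl$positions, 2L, c(i, j, k), "-")^2))
      sel <- d <= radius
      if (!any(sel)) {
        expect_false(vol$filled[i + 1, j + 1, k + 1])
        next
      }
      want <- if (any(d[sel] < 1e-9)) {
        zi <- which(sel & d < 1e-9)
        cl$intensities[zi[order(d[zi], cl$frame_ids[zi], zi)][1L]]
      } else {
        sum(cl$intensities[sel] / d[sel]) / sum(1 / d[sel])
      }
      expect_lt(abs(vol$values[i + 1, j + 1, k + 1] - want), 1e-9)
      expect_gte(vol$values[i + 1, j + 1, k + 1],
                 min(cl$intensities[sel]) - 1e-9)
      expect_lte(vol$values[i + 1, j + 1, k + 1],
                 max(cl$intensities[sel]) + 1e-9)
    }
  }
})

test_that("baselines are invariant to sample order", {
  set.seed(53)
  n <- 40L
  cl <- sample_cloud(cbind(runif(n, 0, 4), runif(n, 0, 4), runif(n, 0, 2)),
                     runif(n, 0, 255), seq_len(n) - 1L)
  g <- volume_grid(c(0, 0, 0), 1, c(5L, 5L, 3L))
  perm <- sample.int(n)
  clp <- sample_cloud(cl$positions[perm, ], cl$intensities[perm],
                      cl$frame_ids[perm])
  expect_equal(reconstruct_vnn(clp, g)$values, reconstruct_vnn(cl, g)$values)
  expect_lt(max(abs(reconstruct_dw(clp, g, 2)$values -
                    reconstruct_dw(cl, g, 2)$values)), 1e-9)
})
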