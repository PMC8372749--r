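test_that("self mutual information equals marginal entropy", {
  v <- small_volume(seed = 3)
  # independent marginal entropy from the same winsorized binning
  idx <- mmii:::bin_indices(as.numeric(v$data), 32L)
  p <- tabulate(idx, 32L) / length(idx)
  h <- -sum(p[p > 0] * log2(p[p > 0]))
  expect_equal(mutual_information(v, v), h, tolerance = 1e-12)
})

test_that("mutual information is symmetric and near zero for independence", {
  set.seed(4)
  a <- image_volume(array(runif(1e5), c(50, 50, 40)))
  b <- image_volume(array(runif(1e5), c(50, 50, 40)))
  expect_lt(abs(mutual_information(a, b) - mutual_information(b, a)), 1e-9)
  expect_lt(mutual_information(a, b), 0.05)
  expect_gte(mutual_information(a, b), 0)
})

test_that("mutual information is invariant under bijective relabeling", {
  v <- small_volume(seed = 5)
  relab <- v
  relab$data <- max(v$data) - v$data   # strictly monotone bijection of bins
  expect_equal(mutual_information(v, relab), mutual_information(v, v),
               tolerance = 1e-9)
  expect_error(mutual_information(v, relab, bins = 1), "bins")
})

test_that("constant images give zero mutual information", {
  v <- small_volume(seed = 6)
  const <- image_volume(array(1, dim(v$data)), v$affine)
  expect_equal(mutual_information(v, const), 0, tolerance = 1e-9)
})

test_that("resample with identity transform on its own grid is exact", {
  v <- small_volume()
  out <- resample(v, rigid_transform(), v)
  expect_equal(out$data, v$data)
})

test_that("integer-voxel translation with nearest interpolation shifts", {
  v <- small_volume(c(12, 12, 12))
  t <- rigid_transform(rbind(cbind(diag(3), c(3, 0, 0)), c(0, 0, 0, 1)))
  out <- resample(v, t, v, interp = "nearest")
  expect_equal(out$data[4:12, , ], v$data[1:9, , ])
  expect_true(all(out$data[1:3, , ] == 0))
})

test_that("a transform moving the volume fully out of field yields zeros", {
  v <- small_volume()
  t <- rigid_transform(rbind(cbind(diag(3), c(1e4, 0, 0)), c(0, 0, 0, 1)))
  expect_true(all(resample(v, t, v)$data == 0))
})

test_that("transfer_map applies exactly the carrier transform", {
  carrier <- small_volume(c(14, 14, 14), seed = 7)
  derived <- image_volume(array(rnorm(14^3), c(14, 14, 14)), carrier$affine)
  t <- rigid_from_params(c(2.5, -1, 0.5, 4, 0, -3))
  ref <- small_volume(c(14, 14, 14), seed = 8)
  expect_identical(transfer_map(t, carrier, ref, carrier = carrier)$data,
                   resample(carrier, t, ref)$data)
  # grid mismatch between derived and carrier is refused
  shifted <- derived
  shifted$affine[1, 4] <- shifted$affine[1, 4] + 1
  expect_error(transfer_map(t, shifted, ref, carrier = carrier),
               "carrier")
  # a point marked in carrier and derived lands on the same base voxel
  carrier$data[] <- 0; derived$data[] <- 0
  carrier$data[7, 8, 6] <- 1; derived$data[7, 8, 6] <- 1
  a <- transfer_map(t, carrier, ref, interp = "nearest")$data
  b <- transfer_map(t, derived, ref, carrier = carrier,
                    interp = "nearest")$data
  expect_identical(which(a == 1), which(b == 1))
})

test_that("composing a transform with its inverse restores the grid", {
  v <- small_volume(c(12, 12, 12), seed = 9)
  t <- rigid_transform(rbind(cbind(diag(3), c(4, -2, 1)), c(0, 0, 0, 1)))
  fwd <- resample(v, t, v, interp = "nearest")
  back <- resample(fwd, invert_transform(t), v, interp = "nearest")
  # interior voxels that stay in-field through both passes
  core <- back$data[5:8, 5:8, 5:8]
  expect_equal(core, v$data[5:8, 5:8, 5:8])
})

test_that("registering a volume to itself returns the identity", {
  t1 <- make_t1_phantom(phantom_spec(seed = 12))$volume
  rr <- register_rigid(t1, t1)
  err <- transform_error(rr$transform, rigid_transform())
  expect_lt(err$translation_mm, 0.1)
  expect_lt(err$rotation_deg, 0.1)
  expect_gte(rr$metric_after, rr$metric_before - 1e-9)
})

test_that("a known rigid perturbation is recovered", {
  t1 <- make_t1_phantom(phantom_spec(seed = 13))$volume
  truth <- rigid_from_params(c(3, -2, 4, 0, 0, 5),
                             center = mmii:::fov_center(t1))
  moving <- resample(t1, invert_transform(truth), t1)
  rr <- register_rigid(moving, t1)
  err <- transform_error(rr$transform, truth)
  expect_lt(err$translation_mm, 0.5)
  expect_lt(err$rotation_deg, 0.5)
  expect_gte(rr$metric_after, rr$metric_before - 1e-9)
})
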