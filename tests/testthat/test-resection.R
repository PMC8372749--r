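base_grid <- function(dims = c(48, 48, 48), spacing = 1)
  image_volume(array(100, dims), diag(c(rep(spacing, 3), 1)),
               modality = "t1")

test_that("no markers produce an empty mask and empty mesh", {
  m <- markers_to_mask(point_set(), 2, base_grid())
  expect_equal(sum(m$mask), 0)
  mesh <- mask_to_voxel_mesh(m)
  expect_equal(nrow(mesh$faces), 0L)
  expect_equal(export_burned_mask(base_grid(), m)$data, base_grid()$data)
})

test_that("a single marker voxelizes to the sphere volume", {
  b <- base_grid()
  m <- markers_to_mask(point_set("m", 24, 24, 24), 5, b, closing = FALSE)
  vol <- sum(m$mask) * prod(voxel_spacing(b))
  expect_lt(abs(vol - 4 / 3 * pi * 125) / (4 / 3 * pi * 125), 0.1)
})

test_that("the mask stays within the dilated marker bounding box", {
  b <- base_grid()
  mk <- point_set(c("a", "b", "c"), c(15, 20, 25), c(15, 18, 22),
                  c(20, 20, 20), group = "s")
  m <- markers_to_mask(mk, 3, b)
  reach <- 3 + 1.5 + max(voxel_spacing(b))
  idx <- which(m$mask > 0, arr.ind = TRUE) - 1
  w <- voxel_to_world(b, idx)
  expect_true(all(w[, 1] >= 15 - reach & w[, 1] <= 25 + reach))
  expect_true(all(w[, 2] >= 15 - reach & w[, 2] <= 22 + reach))
  expect_true(all(w[, 3] >= 20 - reach & w[, 3] <= 20 + reach))
})

test_that("enlarging the brush never removes mask voxels", {
  b <- base_grid()
  mk <- point_set(c("a", "b"), c(18, 28), c(20, 24), c(24, 24), group = "s")
  m1 <- markers_to_mask(mk, 2, b)
  m2 <- markers_to_mask(mk, 4, b)
  expect_true(all(m2$mask[m1$mask > 0] > 0))
})

test_that("voxel meshes have the brute-force face counts and close up", {
  one <- structure(list(mask = array(0L, c(5, 5, 5)), affine = diag(4),
                        brush_radius = 1, markers = point_set()),
                   class = "resection_mask")
  one$mask[3, 3, 3] <- 1L
  m1 <- mask_to_voxel_mesh(one)
  expect_equal(nrow(m1$faces), 6L)
  expect_equal(nrow(m1$vertices), 8L)
  two <- one; two$mask[] <- 0L; two$mask[2:3, 2:3, 2:3] <- 1L
  m2 <- mask_to_voxel_mesh(two)
  expect_equal(nrow(m2$faces), 24L)
  # closed surface: every edge shared by exactly two faces
  edge_counts <- function(mesh) {
    e <- rbind(mesh$faces[, c(1, 2)], mesh$faces[, c(2, 3)],
               mesh$faces[, c(3, 4)], mesh$faces[, c(4, 1)])
    table(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  }
  expect_true(all(edge_counts(m2) == 2))
  b <- base_grid()
  blob <- markers_to_mask(point_set("m", 24, 24, 24), 4, b)
  expect_true(all(edge_counts(mask_to_voxel_mesh(blob)) == 2))
  f <- tempfile(fileext = ".obj")
  write_mesh_obj(m2, f)
  lines <- readLines(f)
  expect_equal(sum(startsWith(lines, "f ")), 24L)
})

test_that("containment labels agree with the analytic sphere test", {
  b <- base_grid()
  center <- c(24, 24, 24)
  m <- markers_to_mask(point_set("m", 24, 24, 24), 5, b, closing = FALSE)
  set.seed(61)
  pts <- cbind(runif(60, 14, 34), runif(60, 14, 34), runif(60, 14, 34))
  ps <- point_set(paste0("p", 1:60), pts[, 1], pts[, 2], pts[, 3])
  got <- mask_contains(m, ps)
  # compare against distance from each point's containing voxel centre
  vox <- round(world_to_voxel(b, pts))
  dist_vox <- sqrt(rowSums(sweep(voxel_to_world(b, vox), 2, center)^2))
  expect_identical(got$inside, dist_vox <= 5)
  expect_equal(attr(got, "fraction_inside"), mean(got$inside))
})

test_that("out-of-field points are labeled outside with a warning", {
  b <- base_grid()
  m <- markers_to_mask(point_set("m", 24, 24, 24), 5, b)
  expect_warning(got <- mask_contains(m, point_set("far", 900, 0, 0)),
                 "outside")
  expect_false(got$inside)
})

test_that("burned masks re-threshold to the original mask", {
  b <- make_t1_phantom(phantom_spec(seed = 62))$volume
  dice <- numeric(0)
  for (seed in 1:10) {
    set.seed(seed)
    n <- 4
    mk <- point_set(paste0("m", 1:n), runif(n, -25, 25), runif(n, -25, 25),
                    runif(n, -20, 20), group = rep(c("s1", "s2"),
                                                   length.out = n))
    m <- markers_to_mask(mk, 4, b)
    burned <- export_burned_mask(b, m)
    rec <- burned$data > max(b$data)
    dice <- c(dice, 2 * sum(rec & m$mask > 0) / (sum(rec) + sum(m$mask)))
  }
  expect_true(all(dice >= 0.99))
})

test_that("misaligned masks are refused at export", {
  b <- base_grid()
  m <- markers_to_mask(point_set("m", 24, 24, 24), 5, b)
  other <- base_grid(c(32, 32, 32))
  expect_error(export_burned_mask(other, m), "aligned")
})
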