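test_that("phantom specs validate their geometry", {
  expect_error(phantom_spec(dims = c(16, 64, 64)), ">= 32")
  expect_error(phantom_spec(voxel_size = 0), "> 0")
  expect_error(phantom_spec(acpc_dist = 35), "AC-PC")
  spec <- phantom_spec()
  expect_equal(sqrt(sum((spec$ac - spec$pc)^2)), 23)
})

test_that("generators are deterministic under a fixed seed", {
  a <- make_t1_phantom(phantom_spec(seed = 71))
  b <- make_t1_phantom(phantom_spec(seed = 71))
  expect_identical(a$volume$data, b$volume$data)
  c <- make_t1_phantom(phantom_spec(seed = 72))
  expect_false(identical(a$volume$data, c$volume$data))
  p1 <- make_perfusion_pair(phantom_spec(seed = 71))
  p2 <- make_perfusion_pair(phantom_spec(seed = 71))
  expect_identical(p1$ictal$data, p2$ictal$data)
  v1 <- make_vessel_mask(phantom_spec(seed = 71))
  v2 <- make_vessel_mask(phantom_spec(seed = 71))
  expect_identical(v1$mask$data, v2$mask$data)
  ct1 <- make_implant_ct(phantom_spec(seed = 71))
  ct2 <- make_implant_ct(phantom_spec(seed = 71))
  expect_identical(ct1$volume$data, ct2$volume$data)
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(make_t1_phantom(phantom_spec(seed = 5)))
  expect_identical(runif(1), before)
})

test_that("T1 truth records the landmarks and brain geometry", {
  ph <- make_t1_phantom(phantom_spec(seed = 73))
  expect_equal(sqrt(sum((ph$truth$ac - ph$truth$pc)^2)), 23)
  expect_true(all(c("anterior", "posterior", "superior", "inferior",
                    "left", "right") %in% names(ph$truth$bounds)))
  expect_type(ph$truth$bounds, "list")
  # the bounds describe a frame the talairach module accepts
  fr <- build_frame(ph$truth$ac, ph$truth$pc, ph$truth$ms, ph$truth$bounds)
  expect_s3_class(fr, "talairach_frame")
})

test_that("truth records serialize losslessly through JSON", {
  ph <- make_t1_phantom(phantom_spec(seed = 74))
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(ph$truth, f, auto_unbox = TRUE, digits = NA)
  r <- jsonlite::fromJSON(f)
  expect_equal(r$ac, ph$truth$ac)
  expect_equal(unlist(r$bounds), unlist(ph$truth$bounds))
  expect_equal(r$brain_volume_ml, ph$truth$brain_volume_ml)
})

test_that("null perfusion phantoms rarely produce suprathreshold clusters", {
  hits <- 0L
  for (seed in 1:10) {
    spec <- phantom_spec(seed = seed, blob_specs = list())
    perf <- make_perfusion_pair(spec)
    zm <- compute_siscom(perf$ictal, perf$interictal, perf$mask)
    if (nrow(threshold_clusters(zm, 2, 10)) == 0L) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})

test_that("a hyperperfusion blob is recovered near its true centre", {
  spec <- phantom_spec(seed = 75)
  perf <- make_perfusion_pair(spec)
  zm <- compute_siscom(perf$ictal, perf$interictal, perf$mask)
  cl <- threshold_clusters(zm, 2, 10)
  expect_gte(nrow(cl), 1L)
  truth <- spec$blob_specs[[1]]$center
  err <- sqrt(sum((as.numeric(cl[1, c("centroid_x", "centroid_y",
                                      "centroid_z")]) - truth)^2))
  expect_lt(err, 2)
})

test_that("out-of-brain perfusion blobs are rejected", {
  spec <- phantom_spec(seed = 76,
                       blob_specs = list(list(center = c(80, 0, 0),
                                              radius = 8, delta = 0.15)))
  expect_error(make_perfusion_pair(spec), "outside the brain")
})

test_that("the implant CT truth is consistent with its plan", {
  spec <- phantom_spec(seed = 77)
  ct <- make_implant_ct(spec)
  expect_equal(nrow(ct$truth$contacts), 24L)
  plan <- spec$implant_plan
  vox <- spec$ct_voxel_size
  for (el in plan$name) {
    rows <- ct$truth$contacts[ct$truth$contacts$electrode == el, ]
    expect_equal(nrow(rows), 8L)
    a <- mmii:::traj_entry(plan[plan$name == el, ], 1)
    b <- mmii:::traj_target(plan[plan$name == el, ], 1)
    d <- mmii:::point_segment_distance(as.matrix(rows[, c("x", "y", "z")]),
                                       a, b)$dist
    expect_lt(max(d), 5 * 0.2 * vox)   # colinear within the jitter bound
  }
})

test_that("vessel centerlines lie inside the vessel mask", {
  ves <- make_vessel_mask(phantom_spec(seed = 78))
  vol <- ves$mask
  v <- round(world_to_voxel(vol, ps_coords(ves$centerlines)))
  inside <- vol$data[cbind(v[, 1], v[, 2], v[, 3]) + 1] > 0
  expect_true(all(inside))
  expect_error(make_vessel_mask(
    phantom_spec(seed = 78, vessel_spec = list(n_tubes = 1, radius = 0.5,
                                               tortuosity = 0))),
    "radius")
})

test_that("a full phantom case writes every artifact", {
  dir <- file.path(tempdir(), "phantom-case")
  truth <- write_phantom_case(phantom_spec(seed = 79), dir)
  expect_true(all(file.exists(file.path(
    dir, c("t1.nii.gz", "ictal.nii.gz", "interictal.nii.gz",
           "brain_mask.nii.gz", "ct.nii.gz", "vessels.nii.gz",
           "plan.json", "truth.json")))))
  expect_equal(truth$seed, 79L)
  plan <- read_plan(file.path(dir, "plan.json"))
  expect_equal(nrow(plan), 3L)
  unlink(dir, recursive = TRUE)
})
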