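test_that("trajectory construction derives length and unit direction", {
  t <- plan_trajectory("LA", c(0, 0, 0), c(0, 0, 50))
  expect_equal(t$length, 50)
  expect_equal(sum(trajectory_direction(t)^2), 1, tolerance = 1e-12)
  expect_error(plan_trajectory("X", c(1, 2, 3), c(1, 2, 3)), "coincide")
  expect_error(plan_trajectory("", c(0, 0, 0), c(1, 0, 0)), "nonempty")
  expect_error(trajectory_plan(plan_trajectory("A", c(0, 0, 0), c(1, 0, 0)),
                               plan_trajectory("A", c(0, 0, 0), c(0, 1, 0))),
               "duplicate")
})

test_that("plans round trip through JSON and CSV", {
  plan <- trajectory_plan(
    plan_trajectory("LA", c(-50, 20, 10), c(-10, 20, 10)),
    plan_trajectory("RB", c(50, -5, 0), c(12, -5, 0)))
  plan$n_contacts <- 8L
  plan$spacing <- 3.5
  for (ext in c(".json", ".csv")) {
    f <- tempfile(fileext = ext)
    write_plan(plan, f)
    r <- read_plan(f)
    expect_equal(r$name, plan$name)
    expect_equal(r$entry_x, plan$entry_x)
    expect_equal(r$target_z, plan$target_z)
    expect_equal(r$n_contacts, plan$n_contacts)
  }
})

test_that("an empty vessel mask passes with infinite clearance", {
  empty <- image_volume(array(0, c(16, 16, 16)))
  t <- plan_trajectory("T", c(0, 0, 0), c(10, 10, 10))
  sr <- vessel_clearance(t, empty)
  expect_true(sr$pass)
  expect_identical(sr$min_vessel_distance, Inf)
  expect_identical(sr$entry_zone_distance, Inf)
})

test_that("clearance to a parallel straight vessel matches the offset", {
  spec <- phantom_spec(seed = 41,
                       vessel_spec = list(n_tubes = 1, radius = 2,
                                          tortuosity = 0,
                                          tubes = list(rbind(c(10, -40, 5),
                                                             c(10, 40, 5)))))
  vm <- make_vessel_mask(spec)
  t <- plan_trajectory("T", c(15, -30, 5), c(15, 30, 5))  # offset 5 mm
  sr <- vessel_clearance(t, vm$mask)
  half_diag <- sqrt(sum(voxel_spacing(vm$mask)^2)) / 2
  expect_lt(abs(sr$min_vessel_distance - 5), half_diag)
  expect_true(sr$pass)  # 5 mm >= default 3 mm clearance
})

test_that("clearance distances agree with brute force on small masks", {
  set.seed(42)
  for (rep in 1:3) {
    m <- array(0, c(24, 24, 24))
    m[sample(length(m), 40)] <- 1
    vm <- image_volume(m, diag(c(1.5, 1.5, 1.5, 1)))
    t <- plan_trajectory("T", runif(3, 0, 10), runif(3, 20, 33))
    sr <- vessel_clearance(t, vm)
    oracle <- oracle_min_segment_distance(vm, mmii:::traj_entry(t, 1),
                                          mmii:::traj_target(t, 1))
    expect_equal(sr$min_vessel_distance, oracle, tolerance = 1e-9)
  }
})

test_that("the entry zone minimum is restricted to the first 15 mm", {
  m <- array(0, c(40, 40, 40))
  vm <- image_volume(m, diag(4))
  vm$data[21, 21, 35] <- 1   # near the target end (voxel 0-based (20,20,34))
  t <- plan_trajectory("T", c(20, 20, 0), c(20, 20, 34))
  sr <- vessel_clearance(t, vm)
  expect_equal(sr$min_vessel_distance, 0, tolerance = 1e-9)
  # within the first 15 mm, the closest approach is 34 - 15 = 19 mm away
  expect_equal(sr$entry_zone_distance, 19, tolerance = 1e-9)
  expect_false(sr$pass)
})

test_that("target coverage flags covered and uncovered points", {
  plan <- trajectory_plan(
    plan_trajectory("A", c(0, 0, 0), c(0, 0, 30)),
    plan_trajectory("B", c(20, 0, 0), c(20, 0, 30)))
  targets <- point_set(c("on", "near", "far"),
                       c(0, 2, 10), c(0, 0, 10), c(15, 10, 15))
  cov <- target_coverage(plan, targets, radius = 5)
  expect_true(cov$covered[1])
  expect_equal(cov$min_distance[1], 0, tolerance = 1e-12)
  expect_true(cov$covered[2])
  expect_equal(cov$closest_trajectory[2], "A")
  expect_false(cov$covered[3])
  # dense-sampling oracle for the distances
  for (i in seq_len(nrow(targets))) {
    p <- as.numeric(targets[i, c("x", "y", "z")])
    d_or <- min(vapply(seq(0, 1, by = 0.1 / 30), function(s)
      sqrt(sum((p - (c(0, 0, 0) + s * c(0, 0, 30)))^2)), numeric(1)))
    d_or <- min(d_or, min(vapply(seq(0, 1, by = 0.1 / 30), function(s)
      sqrt(sum((p - (c(20, 0, 0) + s * c(0, 0, 30)))^2)), numeric(1))))
    expect_equal(cov$min_distance[i], d_or, tolerance = 0.01)
  }
})

test_that("expected contacts are spaced from the target outward", {
  t <- plan_trajectory("LA", c(0, 0, 50), c(0, 0, 0))
  one <- expected_contacts(t, 1)
  expect_equal(nrow(one), 1L)
  expect_equal(as.numeric(one[1, c("x", "y", "z")]), c(0, 0, 0))
  ec <- expected_contacts(t, 10, 3.5)
  expect_equal(ec$name, paste0("LA", 1:10))
  span <- sqrt(sum((as.numeric(ec[10, c("x", "y", "z")]) -
                      as.numeric(ec[1, c("x", "y", "z")]))^2))
  expect_equal(span, 31.5, tolerance = 1e-9)
  expect_equal(as.numeric(ec[1, c("x", "y", "z")]), c(0, 0, 0))
  short <- plan_trajectory("S", c(0, 0, 30), c(0, 0, 0))
  expect_error(expected_contacts(short, 10, 3.5), "exceeds")
})

test_that("clearance and coverage are rigid-equivariant", {
  spec <- phantom_spec(seed = 43)
  vm <- make_vessel_mask(spec)
  t <- plan_trajectory("T", c(-40, 20, 10), c(0, 0, 0))
  targets <- point_set(c("a", "b"), c(5, -12), c(5, 8), c(5, -3))
  sr0 <- vessel_clearance(t, vm$mask)
  cov0 <- target_coverage(trajectory_plan(t), targets, 6)
  tr <- rigid_from_params(c(5, -3, 8, 10, -15, 20))
  vm_t <- vm$mask
  vm_t$affine <- tr$matrix %*% vm$mask$affine
  ee <- apply_transform(tr, mmii:::traj_entry(t, 1))[1, ]
  tt <- apply_transform(tr, mmii:::traj_target(t, 1))[1, ]
  t_t <- plan_trajectory("T", ee, tt)
  p_t <- apply_transform(tr, ps_coords(targets))
  targets_t <- point_set(targets$name, p_t[, 1], p_t[, 2], p_t[, 3])
  sr1 <- vessel_clearance(t_t, vm_t)
  cov1 <- target_coverage(trajectory_plan(t_t), targets_t, 6)
  expect_equal(sr1$min_vessel_distance, sr0$min_vessel_distance,
               tolerance = 1e-6)
  expect_equal(sr1$entry_zone_distance, sr0$entry_zone_distance,
               tolerance = 1e-6)
  expect_equal(cov1$min_distance, cov0$min_distance, tolerance = 1e-6)
  expect_identical(cov1$covered, cov0$covered)
})
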