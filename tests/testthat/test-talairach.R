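axis_frame <- function() {
  build_frame(ac = c(0, 0, 0), pc = c(0, -23, 0), ms = c(0, 0, 40),
              bounds = c(anterior = 70, posterior = 80, superior = 70,
                         inferior = 45, left = 65, right = 65))
}

test_that("an axis-aligned frame reproduces the world axes and VCA/VCP", {
  fr <- axis_frame()
  expect_equal(fr$axes, cbind(x = c(1, 0, 0), y = c(0, 1, 0),
                              z = c(0, 0, 1)))
  expect_equal(fr$acpc_dist, 23)
  gp <- grid_planes(fr)
  expect_true(0 %in% gp$sagittal)      # VCA
  expect_true(-23 %in% gp$sagittal)    # VCP
})

test_that("degenerate or inconsistent frame inputs are rejected", {
  expect_error(build_frame(c(0, 0, 0), c(0, 0, 0), c(0, 0, 40),
                           c(anterior = 1, posterior = 30, superior = 1,
                             inferior = 1, left = 1, right = 1)),
               "distinct")
  expect_error(build_frame(c(0, 0, 0), c(0, -23, 0), c(0, -50, 0),
                           c(anterior = 70, posterior = 80, superior = 70,
                             inferior = 45, left = 65, right = 65)),
               "collinear")
  expect_error(build_frame(c(0, 0, 0), c(0, -23, 0), c(0, 0, 40),
                           c(anterior = 70, posterior = 10, superior = 70,
                             inferior = 45, left = 65, right = 65)),
               "posterior")
  expect_error(build_frame(c(0, 0, 0), c(0, -23, 0), c(0, 0, 40),
                           c(anterior = -1, posterior = 80, superior = 70,
                             inferior = 45, left = 65, right = 65)),
               "positive")
})

test_that("the AC lands in sector E, level 8, column a", {
  cell <- grid_cell(c(0, 0, 0), axis_frame())
  expect_equal(cell$sector, "E")
  expect_equal(cell$level, 8L)
  expect_equal(cell$column, "a")
  expect_false(cell$out_of_grid)
})

test_that("proportional positions map to the documented sectors", {
  fr <- axis_frame()
  # 10% of the way from VCA toward the anterior bound: first band, D
  expect_equal(grid_cell(c(0, 7, 0), fr)$sector, "D")
  # most anterior band
  expect_equal(grid_cell(c(0, 69, 0), fr)$sector, "A")
  # between VCA and VCP
  expect_equal(grid_cell(c(0, -12, 0), fr)$sector, "E")
  # just posterior of VCP: F; most posterior: I
  expect_equal(grid_cell(c(0, -24, 0), fr)$sector, "F")
  expect_equal(grid_cell(c(0, -79, 0), fr)$sector, "I")
  # above the superior bound: flagged, not an error
  cell <- grid_cell(c(0, 0, 80), fr)
  expect_true(cell$out_of_grid)
  expect_true(is.na(cell$sector))
})

test_that("grid planes are evenly spaced with the documented counts", {
  fr <- axis_frame()
  gp <- grid_planes(fr)
  sup <- gp$levels[gp$levels >= 0]
  inf <- gp$levels[gp$levels <= 0]
  expect_length(sup, 9L)   # 8 bands above the AC-PC plane
  expect_length(inf, 5L)   # 4 bands below
  expect_lt(max(abs(diff(sup) - 70 / 8)), 1e-9)
  expect_lt(max(abs(diff(inf) - 45 / 4)), 1e-9)
  ant <- gp$sagittal[gp$sagittal >= 0]
  post <- gp$sagittal[gp$sagittal <= -23]
  expect_length(ant, 5L)   # 4 sectors anterior of VCA
  expect_length(post, 5L)  # 4 sectors posterior of VCP
  expect_lt(max(abs(diff(ant) - 70 / 4)), 1e-9)
  expect_lt(max(abs(diff(post) - (80 - 23) / 4)), 1e-9)
  right <- gp$columns[gp$columns >= 0]
  expect_length(right, 5L) # 4 columns per hemisphere
  expect_lt(max(abs(diff(right) - 65 / 4)), 1e-9)
})

test_that("grid cells are equivariant under rigid motion of all inputs", {
  fr <- axis_frame()
  set.seed(31)
  pts <- cbind(runif(40, -60, 60), runif(40, -75, 65), runif(40, -40, 65))
  base_cells <- grid_cell(pts, fr)
  for (i in 1:5) {
    t <- rigid_from_params(c(runif(3, -20, 20), runif(3, -40, 40)))
    fr_t <- build_frame(apply_transform(t, fr$ac)[1, ],
                        apply_transform(t, fr$pc)[1, ],
                        apply_transform(t, fr$ms)[1, ], fr$bounds)
    cells_t <- grid_cell(apply_transform(t, pts), fr_t)
    expect_identical(cells_t, base_cells)
  }
})

test_that("every in-box point gets exactly one cell and labels tile", {
  fr <- axis_frame()
  set.seed(32)
  pts <- cbind(runif(500, -64, 64), runif(500, -79, 69),
               runif(500, -44, 69))
  cells <- grid_cell(pts, fr)
  expect_false(any(cells$out_of_grid))
  expect_false(any(is.na(cells$sector)))
  expect_true(all(cells$level %in% 1:12))
  expect_true(all(cells$sector %in% c(LETTERS[1:4], "E", "F", "G", "H",
                                      "I")))
  expect_true(all(cells$column %in% letters[1:4]))
  # brute-force interval arithmetic oracle for the level bands
  lev_oracle <- ifelse(pts[, 3] >= 0,
                       9L - pmax(1L, ceiling(pts[, 3] / (70 / 8))),
                       8L + pmax(1L, ceiling(-pts[, 3] / (45 / 4))))
  expect_equal(cells$level, as.integer(lev_oracle))
})

test_that("moving anterior never moves the sector label posterior", {
  fr <- axis_frame()
  order_key <- c(I = 1, H = 2, G = 3, F = 4, E = 5, D = 6, C = 7, B = 8,
                 A = 9)
  ys <- seq(-79, 69, by = 0.7)
  sec <- grid_cell(cbind(0, ys, 0), fr)$sector
  expect_true(all(diff(order_key[sec]) >= 0))
})

test_that("frames serialize to JSON and back", {
  fr <- axis_frame()
  f <- tempfile(fileext = ".json")
  write_frame(fr, f)
  r <- read_frame(f)
  expect_equal(r$ac, fr$ac)
  expect_equal(r$bounds, fr$bounds)
  expect_equal(r$axes, fr$axes)
})

test_that("grid overlays burn into the base volume", {
  t1 <- make_t1_phantom(phantom_spec(seed = 33))
  fr <- build_frame(t1$truth$ac, t1$truth$pc, t1$truth$ms, t1$truth$bounds)
  b <- burn_grid(t1$volume, fr)
  expect_gt(sum(b$data > max(t1$volume$data)), 0)
})
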