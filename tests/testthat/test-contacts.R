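test_that("phantom CT contacts are segmented and named exactly", {
  spec <- phantom_spec(seed = 51)
  ct <- make_implant_ct(spec)
  cand <- segment_contact_candidates(ct$volume,
                                     threshold = ct$truth$threshold,
                                     expected_spacing = ct$truth$spacing)
  expect_equal(nrow(cand), 24L)
  cs <- assign_and_name(cand, spec$implant_plan)
  expect_equal(nrow(cs$contacts), 24L)
  expect_equal(nrow(cs$unassigned), 0L)
  truth <- ct$truth$contacts
  expect_setequal(cs$contacts$name, truth$name)
  m <- merge(cs$contacts, truth, by = "name", suffixes = c("", ".t"))
  err <- sqrt((m$x - m$x.t)^2 + (m$y - m$y.t)^2 + (m$z - m$z.t)^2)
  vox <- voxel_spacing(ct$volume)[1]
  expect_lt(mean(err) / vox, 0.5)
  # indices consecutive from 1 and projections increasing from the target
  for (el in unique(cs$contacts$electrode)) {
    rows <- cs$contacts[cs$contacts$electrode == el, ]
    expect_equal(rows$index, seq_len(nrow(rows)))
    tr <- spec$implant_plan[spec$implant_plan$name == el, ]
    u <- -trajectory_direction(tr)
    proj <- as.matrix(rows[, c("x", "y", "z")]) %*% u
    expect_true(all(diff(proj) > 0))
  }
})

test_that("a CT with nothing above threshold yields no candidates", {
  ct <- image_volume(array(50, c(20, 20, 20)), modality = "ct")
  expect_equal(nrow(segment_contact_candidates(ct, threshold = 100)), 0L)
})

test_that("merged components split at local intensity maxima", {
  # two contacts close enough that their blobs fuse above threshold
  v <- image_volume(array(0, c(30, 30, 30)), modality = "ct")
  w <- mmii:::volume_world_grid(v)
  c1 <- c(12, 15, 15); c2 <- c(15, 15, 15)   # 3 mm apart
  v$data <- array(1000 * exp(-rowSums(sweep(w, 2, c1)^2) / (2 * 0.9^2)) +
                  1000 * exp(-rowSums(sweep(w, 2, c2)^2) / (2 * 0.9^2)),
                  dim(v$data))
  lab <- mmii:::label_components(v$data > 300)
  expect_equal(max(lab), 1L)   # genuinely merged at this threshold
  cand <- segment_contact_candidates(v, threshold = 300,
                                     expected_spacing = 3.5)
  expect_equal(nrow(cand), 2L)
  d <- sqrt(sum((as.numeric(cand[1, c("x", "y", "z")]) -
                   as.numeric(cand[2, c("x", "y", "z")]))^2))
  expect_equal(d, 3, tolerance = 1)
})

test_that("candidates far from every trajectory are left unassigned", {
  plan <- trajectory_plan(plan_trajectory("LA", c(-40, 0, 0), c(0, 0, 0)))
  cand <- point_set(c("near", "far"), c(-20, -20), c(1, 15), c(0, 0),
                    value = c(10, 10))
  cs <- assign_and_name(cand, plan, tol = 4)
  expect_equal(cs$contacts$name, "LA1")
  expect_equal(cs$unassigned$name, "far")
  expect_error(assign_and_name(cand, trajectory_plan()), "empty")
})

test_that("assignment matches a brute-force nearest-segment search", {
  spec <- phantom_spec(seed = 52)
  ct <- make_implant_ct(spec)
  cand <- segment_contact_candidates(ct$volume,
                                     threshold = ct$truth$threshold)
  cs <- assign_and_name(cand, spec$implant_plan)
  plan <- spec$implant_plan
  for (i in seq_len(nrow(cand))) {
    p <- as.numeric(cand[i, c("x", "y", "z")])
    d <- vapply(seq_len(nrow(plan)), function(r) {
      a <- mmii:::traj_entry(plan, r); b <- mmii:::traj_target(plan, r)
      u <- b - a
      tt <- min(1, max(0, sum((p - a) * u) / sum(u^2)))
      sqrt(sum((p - (a + tt * u))^2))
    }, numeric(1))
    best <- plan$name[which.min(d)]
    row <- cs$contacts[cs$contacts$x == p[1] & cs$contacts$y == p[2], ]
    expect_equal(row$electrode[1], best)
  }
})

test_that("naming is invariant to candidate input order", {
  spec <- phantom_spec(seed = 53)
  ct <- make_implant_ct(spec)
  cand <- segment_contact_candidates(ct$volume,
                                     threshold = ct$truth$threshold)
  cs1 <- assign_and_name(cand, spec$implant_plan)
  set.seed(7)
  perm <- sample(nrow(cand))
  shuffled <- point_set(cand$name[perm], cand$x[perm], cand$y[perm],
                        cand$z[perm], value = cand$value[perm])
  cs2 <- assign_and_name(shuffled, spec$implant_plan)
  expect_equal(cs1$contacts[, c("electrode", "index", "name", "x", "y",
                                "z")],
               cs2$contacts[, c("electrode", "index", "name", "x", "y",
                                "z")])
})

test_that("contact sets serialize as TSV and JSON", {
  spec <- phantom_spec(seed = 54)
  ct <- make_implant_ct(spec)
  cand <- segment_contact_candidates(ct$volume,
                                     threshold = ct$truth$threshold)
  cs <- assign_and_name(cand, spec$implant_plan)
  ft <- tempfile(fileext = ".tsv")
  write_contact_set(cs, ft)
  tab <- utils::read.delim(ft)
  expect_equal(nrow(tab), nrow(cs$contacts))
  expect_true(all(c("electrode", "index", "name", "x", "y", "z") %in%
                    names(tab)))
  ps <- contacts_as_pointset(cs)
  expect_s3_class(ps, "point_set")
  expect_equal(nrow(ps), nrow(cs$contacts))
})
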