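# Geometric head phantoms with ground truth. The generators emulate the
# acquisitions the integration workflow consumes — a T1-like head, an
# ictal/interictal perfusion pair, a post-implant CT with bright contacts, a
# vessel mask — using nested ellipsoids, tubes and simple noise models
# (Gaussian for MRI/CT, Poisson for perfusion counts). Geometry, contrast and
# noise are what the downstream operators depend on; anatomical realism is
# deliberately out of scope.

#' Phantom specification
#'
#' Defines the geometry, landmarks, lesion, implant and vessel layout of a
#' synthetic head, with every derived dataset deterministic under `seed`.
#'
#' @param dims voxel counts per axis (>= 32), default `c(64, 64, 64)`.
#' @param voxel_size isotropic voxel size in mm, default 2 (perfusion-like);
#'   the implant CT is generated at `ct_voxel_size` on the same field of
#'   view.
#' @param ct_voxel_size voxel size of the implant CT in mm, default 1.
#' @param seed RNG seed.
#' @param acpc_dist AC-PC distance in mm (must lie in [20, 28], default 23).
#' @param blob_specs list of perfusion lesions, each
#'   `list(center = mm, radius = mm, delta = fractional change)`; default one
#'   +15\% sphere of radius 8 mm.
#' @param implant_plan a `trajectory_plan` with `n_contacts` and `spacing`
#'   columns; default 3 electrodes x 8 contacts at 3.5 mm.
#' @param vessel_spec `list(n_tubes, radius, tortuosity)`; default 3 tubes of
#'   radius 2 mm.
#' @param noise_sd Gaussian noise SD for T1/CT intensities.
#' @return a `phantom_spec` list (geometry, landmarks and truth inputs).
#' @export
phantom_spec <- function(dims = c(64L, 64L, 64L), voxel_size = 2,
                         ct_voxel_size = 1, seed = 1L, acpc_dist = 23,
                         blob_specs = NULL, implant_plan = NULL,
                         vessel_spec = list(n_tubes = 3L, radius = 2,
                                            tortuosity = 0.3),
                         noise_sd = 2) {
  dims <- rep_len(as.integer(dims), 3L)
  if (any(dims < 32L)) stop("dims must be >= 32 per axis", call. = FALSE)
  if (voxel_size <= 0 || ct_voxel_size <= 0)
    stop("voxel sizes must be > 0", call. = FALSE)
  if (acpc_dist < 20 || acpc_dist > 28)
    stop("AC-PC distance must lie in [20, 28] mm", call. = FALSE)
  fov <- dims * voxel_size
  # distinct semi-axes: a head with equal lateral and vertical extent is
  # nearly rotation-symmetric and under-determines registration
  head_semi <- c(0.42, 0.47, 0.37) * fov
  brain_semi <- 0.82 * head_semi
  ac <- c(0, acpc_dist / 2, 0)
  pc <- c(0, -acpc_dist / 2, 0)
  ms <- c(0, acpc_dist / 2, 0.8 * brain_semi[3])
  if (is.null(blob_specs))
    blob_specs <- list(list(center = c(0.55 * brain_semi[1],
                                       0.2 * brain_semi[2],
                                       0.2 * brain_semi[3]),
                            radius = 8, delta = 0.15))
  if (is.null(implant_plan)) {
    bx <- brain_semi[1]; by <- brain_semi[2]; bz <- brain_semi[3]
    implant_plan <- trajectory_plan(
      plan_trajectory("LA", c(-1.12 * bx, 0.45 * by, 0.2 * bz),
                      c(-0.15 * bx, 0.45 * by, 0.2 * bz)),
      plan_trajectory("LP", c(-1.12 * bx, -0.35 * by, 0.35 * bz),
                      c(-0.2 * bx, -0.35 * by, 0.35 * bz)),
      plan_trajectory("RB", c(1.12 * bx, 0.1 * by, -0.15 * bz),
                      c(0.18 * bx, 0.1 * by, -0.15 * bz)))
    implant_plan$n_contacts <- 8L
    implant_plan$spacing <- 3.5
  }
  structure(list(dims = dims, voxel_size = voxel_size,
                 ct_voxel_size = ct_voxel_size, seed = as.integer(seed),
                 ac = ac, pc = pc, ms = ms, acpc_dist = acpc_dist,
                 head_semi = head_semi, brain_semi = brain_semi,
                 blob_specs = blob_specs, implant_plan = implant_plan,
                 vessel_spec = vessel_spec, noise_sd = noise_sd),
            class = "phantom_spec")
}

# centred affine: world origin at the FOV centre
phantom_affine <- function(dims, voxel_size) {
  A <- diag(c(rep(voxel_size, 3), 1))
  A[1:3, 4] <- -(dims - 1) / 2 * voxel_size
  A
}

# squared normalized ellipsoid radius on the grid defined by axis coords
ellipsoid_u2 <- function(xs, ys, zs, center, semi) {
  x2 <- ((xs - center[1]) / semi[1])^2
  y2 <- ((ys - center[2]) / semi[2])^2
  z2 <- ((zs - center[3]) / semi[3])^2
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  array(rep(x2, times = ny * nz), c(nx, ny, nz)) +
    array(rep(rep(y2, each = nx), times = nz), c(nx, ny, nz)) +
    array(rep(z2, each = nx * ny), c(nx, ny, nz))
}

axis_coords <- function(dims, voxel_size)
  lapply(1:3, function(ax) (seq_len(dims[ax]) - 1 - (dims[ax] - 1) / 2) *
           voxel_size)

#' Generate a T1-like head phantom
#'
#' Ellipsoidal head with scalp, skull shell, CSF gap, gray/white brain bands
#' and ventricles, plus Gaussian noise. AC, PC and MS landmark truth and the
#' Talairach bounding box of the brain ellipsoid are recorded.
#'
#' @param spec a [phantom_spec()].
#' @return `list(volume = image_volume, truth = list(ac, pc, ms, bounds,
#'   brain_semi, head_semi, brain_volume_ml))`.
#' @export
make_t1_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  ax <- axis_coords(spec$dims, spec$voxel_size)
  uh <- ellipsoid_u2(ax[[1]], ax[[2]], ax[[3]], c(0, 0, 0), spec$head_semi)
  ub <- ellipsoid_u2(ax[[1]], ax[[2]], ax[[3]], c(0, 0, 0), spec$brain_semi)
  img <- array(0, spec$dims)
  img[uh <= 1] <- 55                                   # scalp
  img[uh <= 0.96 & uh > 0.88] <- 20                    # skull shell
  img[uh <= 0.88] <- 30                                # CSF gap
  img[ub <= 1] <- 70                                   # gray band
  img[ub <= 0.72] <- 100                               # white core
  for (side in c(-1, 1)) {   # lateral ventricles, mildly asymmetric
    uv <- ellipsoid_u2(ax[[1]], ax[[2]], ax[[3]],
                       c(side * 0.18 * spec$brain_semi[1],
                         side * 0.05 * spec$brain_semi[2],
                         0.1 * spec$brain_semi[3]),
                       c(0.14, 0.4, 0.18) * (1 + 0.08 * side) *
                         spec$brain_semi)
    img[uv <= 1] <- 25
  }
  img <- with_seed(spec$seed, img + stats::rnorm(length(img), 0,
                                                 spec$noise_sd))
  img[img < 0] <- 0
  vol <- image_volume(array(img, spec$dims),
                      phantom_affine(spec$dims, spec$voxel_size),
                      modality = "t1", frame_id = "base")
  bounds <- c(anterior = spec$brain_semi[2] - spec$ac[2],
              posterior = spec$brain_semi[2] + spec$pc[2] + spec$acpc_dist,
              superior = spec$brain_semi[3],
              inferior = spec$brain_semi[3],
              left = spec$brain_semi[1], right = spec$brain_semi[1])
  truth <- list(ac = spec$ac, pc = spec$pc, ms = spec$ms,
                bounds = as.list(bounds),
                brain_semi = spec$brain_semi, head_semi = spec$head_semi,
                brain_volume_ml = 4 / 3 * pi * prod(spec$brain_semi) / 1000)
  list(volume = vol, truth = truth)
}

#' Generate an ictal/interictal perfusion pair
#'
#' Interictal perfusion is smoothed brain-proportional activity with Poisson
#' counting noise; the ictal volume applies each lesion blob's fractional
#' perfusion change multiplicatively before an independent Poisson draw.
#'
#' @param spec a [phantom_spec()].
#' @return `list(ictal, interictal, mask, truth)`; `truth$blobs` holds the
#'   lesion centres/radii/deltas.
#' @export
make_perfusion_pair <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  ax <- axis_coords(spec$dims, spec$voxel_size)
  ub <- ellipsoid_u2(ax[[1]], ax[[2]], ax[[3]], c(0, 0, 0), spec$brain_semi)
  brain <- ub <= 1
  for (bl in spec$blob_specs) {
    margin <- spec$brain_semi - bl$radius
    if (any(margin <= 0) || sum((bl$center / margin)^2) > 1)
      stop("perfusion blob extends outside the brain", call. = FALSE)
  }
  lambda <- gaussian_smooth(100 * brain, rep(1, 3))
  lambda_ictal <- lambda
  for (bl in spec$blob_specs) {
    cu2 <- ellipsoid_u2(ax[[1]], ax[[2]], ax[[3]], bl$center,
                        rep(bl$radius, 3))
    lambda_ictal[cu2 <= 1] <- lambda_ictal[cu2 <= 1] * (1 + bl$delta)
  }
  n <- length(lambda)
  vols <- with_seed(spec$seed, {
    inter <- stats::rpois(n, lambda)
    ict <- stats::rpois(n, lambda_ictal)
    list(inter = inter, ict = ict)
  })
  A <- phantom_affine(spec$dims, spec$voxel_size)
  list(ictal = image_volume(array(vols$ict, spec$dims), A, "spect", "base"),
       interictal = image_volume(array(vols$inter, spec$dims), A, "spect",
                                 "base"),
       mask = image_volume(array(as.numeric(brain), spec$dims), A, "mask",
                           "base"),
       truth = list(blobs = spec$blob_specs))
}

#' Generate a post-implant CT phantom
#'
#' CT-like background (bright skull shell, mid-intensity brain) with
#' quasi-spherical hyperintense contacts rendered as Gaussian blobs at the
#' expected contact positions of the implant plan, displaced by sub-voxel
#' jitter (sigma 0.2 voxel). The truth contact set lists the exact jittered
#' centres with their names.
#'
#' @param spec a [phantom_spec()].
#' @param jitter_sd jitter SD in voxels (default 0.2).
#' @param contact_sigma Gaussian radius of a rendered contact in voxels
#'   (default 0.9, emulating the bloomed footprint of a sub-millimetre
#'   contact on a 1 mm CT).
#' @return `list(volume, truth)`; `truth$contacts` is the ground-truth
#'   contact table (`electrode`, `index`, `name`, `x`, `y`, `z`),
#'   `truth$threshold` a recommended segmentation threshold (midway between
#'   skull and brain intensity on one side and the contact peak on the
#'   other).
#' @export
make_implant_ct <- function(spec = phantom_spec(), jitter_sd = 0.2,
                            contact_sigma = 0.9) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- as.integer(round(spec$dims * spec$voxel_size / spec$ct_voxel_size))
  vs <- spec$ct_voxel_size
  ax <- axis_coords(dims, vs)
  uh <- ellipsoid_u2(ax[[1]], ax[[2]], ax[[3]], c(0, 0, 0), spec$head_semi)
  img <- array(0, dims)
  img[uh <= 1] <- 40                                   # soft tissue
  img[uh <= 0.96 & uh > 0.88] <- 800                   # skull
  img[uh <= 0.88] <- 50                                # brain
  plan <- as_trajectory_plan(spec$implant_plan)
  contact_peak <- 3000
  sigma_mm <- contact_sigma * vs
  truth_rows <- list()
  centers <- with_seed(spec$seed + 1L, {
    lapply(seq_len(nrow(plan)), function(r) {
      ec <- expected_contacts(plan[r, ], plan$n_contacts[r], plan$spacing[r])
      jit <- matrix(stats::rnorm(3 * nrow(ec), 0, jitter_sd * vs),
                    ncol = 3)
      ps_coords(ec) + jit
    })
  })
  A <- phantom_affine(dims, vs)
  vol <- image_volume(img, A, "ct", "base")
  for (r in seq_len(nrow(plan))) {
    cen <- centers[[r]]
    for (i in seq_len(nrow(cen))) {
      idx <- voxels_within_sphere(vol, cen[i, ], 3 * sigma_mm)
      if (!length(idx)) next
      d <- dim(vol$data)
      lin <- idx - 1L
      ijk <- cbind(lin %% d[1], (lin %/% d[1]) %% d[2],
                   lin %/% (d[1] * d[2]))
      w <- voxel_to_world(vol, ijk)
      dist2 <- rowSums(sweep(w, 2, cen[i, ])^2)
      vol$data[idx] <- vol$data[idx] +
        contact_peak * exp(-dist2 / (2 * sigma_mm^2))
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        electrode = plan$name[r], index = i,
        name = paste0(plan$name[r], i),
        x = cen[i, 1], y = cen[i, 2], z = cen[i, 3],
        stringsAsFactors = FALSE)
    }
  }
  vol$data <- with_seed(spec$seed + 2L,
    vol$data + array(stats::rnorm(length(vol$data), 0, spec$noise_sd), dims))
  vol$data[vol$data < 0] <- 0
  truth <- list(contacts = do.call(rbind, truth_rows),
                threshold = 1000,
                spacing = plan$spacing[1])
  list(volume = vol, truth = truth)
}

#' Generate a vessel mask with known centerlines
#'
#' Random smooth tubes inside the brain (or user-specified straight tubes),
#' returned as a binary mask plus the exact centerline polylines.
#'
#' @param spec a [phantom_spec()]. `spec$vessel_spec` may contain `tubes`, a
#'   list of n x 3 polyline matrices (world mm), to bypass random generation.
#' @param n_points polyline vertices per random tube.
#' @return `list(mask = image_volume, centerlines = point_set)` with one
#'   group per tube.
#' @export
make_vessel_mask <- function(spec = phantom_spec(), n_points = 15L) {
  stopifnot(inherits(spec, "phantom_spec"))
  vs <- spec$vessel_spec
  if (vs$radius < spec$voxel_size)
    stop("vessel radius must be at least one voxel", call. = FALSE)
  A <- phantom_affine(spec$dims, spec$voxel_size)
  base <- image_volume(array(0, spec$dims), A, "cta", "base")
  tubes <- vs$tubes
  if (is.null(tubes)) {
    tubes <- with_seed(spec$seed + 3L, {
      lapply(seq_len(vs$n_tubes), function(i) {
        a <- stats::runif(3, -0.6, 0.6) * spec$brain_semi
        b <- stats::runif(3, -0.6, 0.6) * spec$brain_semi
        tt <- seq(0, 1, length.out = n_points)
        line <- outer(1 - tt, a) + outer(tt, b)
        wig <- vs$tortuosity * sqrt(sum((b - a)^2)) / 4
        for (ax in 1:3) {
          ph <- stats::runif(1, 0, 2 * pi)
          line[, ax] <- line[, ax] + wig * sin(2 * pi * tt + ph) *
            sin(pi * tt)
        }
        line
      })
    })
  }
  mask <- array(FALSE, spec$dims)
  cl_names <- character(); cl_xyz <- NULL; cl_group <- character()
  for (i in seq_along(tubes)) {
    tube <- rbind3(tubes[[i]])
    for (s in seq_len(nrow(tube) - 1))
      mask <- mask | capsule_mask(base, tube[s, ], tube[s + 1, ], vs$radius)
    cl_names <- c(cl_names, paste0("V", i, "_", seq_len(nrow(tube))))
    cl_group <- c(cl_group, rep(paste0("V", i), nrow(tube)))
    cl_xyz <- rbind(cl_xyz, tube)
  }
  list(mask = image_volume(array(as.numeric(mask), spec$dims), A, "mask",
                           "base"),
       centerlines = point_set(cl_names, cl_xyz[, 1], cl_xyz[, 2],
                               cl_xyz[, 3], group = cl_group))
}

#' Write a complete phantom case to disk
#'
#' Generates the T1, perfusion pair, implant CT and vessel mask for one
#' phantom specification and writes them (NIfTI) together with the implant
#' plan (`plan.json`) and truth record (`truth.json`) — a self-contained
#' case directory for the pipeline.
#'
#' @param spec a [phantom_spec()].
#' @param dir output directory (created if needed).
#' @return invisibly, the truth list.
#' @export
write_phantom_case <- function(spec = phantom_spec(), dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  t1 <- make_t1_phantom(spec)
  perf <- make_perfusion_pair(spec)
  ct <- make_implant_ct(spec)
  ves <- make_vessel_mask(spec)
  write_volume(t1$volume, file.path(dir, "t1.nii.gz"))
  write_volume(perf$ictal, file.path(dir, "ictal.nii.gz"))
  write_volume(perf$interictal, file.path(dir, "interictal.nii.gz"))
  write_volume(perf$mask, file.path(dir, "brain_mask.nii.gz"))
  write_volume(ct$volume, file.path(dir, "ct.nii.gz"))
  write_volume(ves$mask, file.path(dir, "vessels.nii.gz"))
  plan <- as.data.frame(spec$implant_plan)
  jsonlite::write_json(plan, file.path(dir, "plan.json"), auto_unbox = TRUE,
                       digits = NA)
  truth <- list(t1 = t1$truth, perfusion = perf$truth, ct = ct$truth,
                seed = spec$seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(truth)
}
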