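#' Case configuration for the integration pipeline
#'
#' Collects the inputs and parameters of one presurgical case: the base T1,
#' optional modality volumes, the AC/PC/MS landmarks and brain bounding box,
#' the trajectory plan, resection pass markers, and stage parameters. Inputs
#' may be file paths (NIfTI / DICOM directory / TSV / JSON) or in-memory
#' objects.
#'
#' @param base_t1 base T1 volume (path or `image_volume`). Required.
#' @param out_dir output directory. Required.
#' @param pet,ictal_spect,interictal_spect,post_ct,vessels,postop_mri
#'   optional modality inputs (path or `image_volume`).
#' @param brain_mask optional brain mask; derived from the T1 if absent.
#' @param registered character vector naming inputs already in the base
#'   frame (registration skipped; identity transform recorded).
#' @param ac,pc,ms optional landmark points (world mm).
#' @param bounds optional named Talairach bounds (see [build_frame()]).
#' @param plan optional trajectory plan (path or `trajectory_plan`).
#' @param markers optional resection pass markers (path or `point_set`).
#' @param z_threshold SISCOM cluster threshold (default 1.5).
#' @param min_cluster_voxels minimum SISCOM cluster size (default 5).
#' @param clearance vessel clearance in mm (default 3).
#' @param coverage_radius target-coverage radius in mm (default 5).
#' @param contact_tol contact assignment tolerance in mm (default 4).
#' @param ct_threshold absolute CT contact threshold; `NULL` uses the
#'   99.9th-percentile default.
#' @param contact_spacing nominal contact spacing in mm (default 3.5).
#' @param brush_radius resection brush radius in mm (default 2).
#' @param mask_erosion erosion (voxels) of the brain mask used for the
#'   SISCOM statistics when the SPECT pair went through registration;
#'   suppresses brain-edge subtraction artifacts (default 1).
#' @param seed RNG seed for any stochastic step.
#' @return a `case_config` list.
#' @export
case_config <- function(base_t1, out_dir, pet = NULL, ictal_spect = NULL,
                        interictal_spect = NULL, post_ct = NULL,
                        vessels = NULL, postop_mri = NULL, brain_mask = NULL,
                        registered = character(), ac = NULL, pc = NULL,
                        ms = NULL, bounds = NULL, plan = NULL,
                        markers = NULL, z_threshold = 1.5,
                        min_cluster_voxels = 5L, clearance = 3,
                        coverage_radius = 5, contact_tol = 4,
                        ct_threshold = NULL, contact_spacing = 3.5,
                        brush_radius = 2, mask_erosion = 1L, seed = 1L) {
  if (missing(base_t1) || is.null(base_t1))
    stop("config error: base T1 volume is required", call. = FALSE)
  if (missing(out_dir) || is.null(out_dir))
    stop("config error: output directory is required", call. = FALSE)
  if (z_threshold <= 0 || clearance <= 0 || coverage_radius <= 0 ||
      contact_tol <= 0 || brush_radius <= 0)
    stop("config error: thresholds must be > 0", call. = FALSE)
  structure(list(base_t1 = base_t1, out_dir = out_dir, pet = pet,
                 ictal_spect = ictal_spect,
                 interictal_spect = interictal_spect, post_ct = post_ct,
                 vessels = vessels, postop_mri = postop_mri,
                 brain_mask = brain_mask, registered = registered,
                 ac = ac, pc = pc, ms = ms, bounds = bounds, plan = plan,
                 markers = markers, z_threshold = z_threshold,
                 min_cluster_voxels = min_cluster_voxels,
                 clearance = clearance, coverage_radius = coverage_radius,
                 contact_tol = contact_tol, ct_threshold = ct_threshold,
                 contact_spacing = contact_spacing,
                 brush_radius = brush_radius,
                 mask_erosion = as.integer(mask_erosion),
                 seed = as.integer(seed)),
            class = "case_config")
}

#' Read a case configuration from YAML
#'
#' Scalars map directly onto [case_config()] arguments; volume and plan
#' entries are paths resolved relative to the YAML file's directory.
#'
#' @param path YAML file.
#' @return a `case_config`.
#' @export
read_case_config <- function(path) {
  y <- yaml::read_yaml(path)
  root <- dirname(normalizePath(path))
  rel <- function(p) if (is.null(p)) NULL else
    (if (file.exists(p) || dir.exists(p)) p else file.path(root, p))
  args <- y
  for (f in c("base_t1", "pet", "ictal_spect", "interictal_spect",
              "post_ct", "vessels", "postop_mri", "brain_mask", "plan",
              "markers"))
    args[[f]] <- rel(y[[f]])
  for (f in c("ac", "pc", "ms"))
    if (!is.null(y[[f]])) args[[f]] <- as.numeric(y[[f]])
  if (!is.null(y$bounds)) args$bounds <- unlist(y$bounds)
  do.call(case_config, args)
}

load_input <- function(x, modality = NULL) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "image_volume")) return(x)
  read_volume(x, modality = modality)
}

load_plan_input <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.character(x)) read_plan(x) else as_trajectory_plan(x)
}

load_pointset_input <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.character(x)) read_pointset(x) else x
}

#' Run a full integration case
#'
#' Orchestrates the whole workflow from one configuration: registers every
#' present modality to the base T1 (recording its transform), computes the
#' SISCOM z-map and clusters when both SPECT volumes are present, builds the
#' Talairach frame when landmarks are given, checks trajectory safety and
#' coverage, segments and names electrode contacts from the post-implant CT,
#' evaluates the resection proposal, and writes every artifact plus a
#' manifest, a timestamped text log, and a machine-readable event stream.
#' Stage failures are recorded and independent stages still run. The
#' orchestration adds no computation of its own: each output equals the
#' corresponding module call on the registered inputs.
#'
#' @param cfg a [case_config()].
#' @return a `case_bundle` list: registered volumes, transforms, `siscom`
#'   (z-map + clusters), `frame`, `safety`, `coverage`, `contacts`,
#'   `resection` (+ containment), `manifest` (data frame), `errors` (named
#'   list of stage errors), `log` (character).
#' @export
run_case <- function(cfg) {
  stopifnot(inherits(cfg, "case_config"))
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  log_lines <- character()
  events <- list()
  errors <- list()
  manifest <- list()
  say <- function(stage, msg) {
    line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    stage, msg)
    log_lines <<- c(log_lines, line)
    events[[length(events) + 1L]] <<- list(stage = stage, message = msg)
    message(line)
  }
  record <- function(file, stage, inputs, params = list()) {
    manifest[[length(manifest) + 1L]] <<- list(
      file = basename(file), stage = stage,
      inputs = paste(inputs, collapse = ","),
      parameters = if (length(params))
        paste(names(params), unlist(params), sep = "=", collapse = ",")
      else "",
      md5 = unname(tools::md5sum(file)))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      errors[[stage]] <<- conditionMessage(e)
      say(stage, paste("STAGE ERROR:", conditionMessage(e)))
      NULL
    })
  }

  base <- load_input(cfg$base_t1, "t1")
  if (is.null(base)) stop("fatal config error: base T1 missing",
                          call. = FALSE)
  base$frame_id <- "base"
  say("init", sprintf("base volume %s", paste(dim(base$data),
                                              collapse = "x")))
  mask_vol <- run_stage("mask", {
    m <- if (is.null(cfg$brain_mask)) brain_mask(base)
         else load_input(cfg$brain_mask, "mask")
    f <- file.path(cfg$out_dir, "brain_mask.nii")
    write_volume(m, f)
    record(f, "mask", "base_t1")
    m
  })

  # --- registration ---------------------------------------------------
  reg_names <- c("pet", "ictal_spect", "interictal_spect", "post_ct",
                 "vessels", "postop_mri")
  reg_modality <- c(pet = "pet", ictal_spect = "spect",
                    interictal_spect = "spect", post_ct = "ct",
                    vessels = "cta", postop_mri = "t1")
  registered <- list()
  transforms <- list()
  native <- list()
  for (nm in reg_names) {
    if (is.null(cfg[[nm]])) {
      say("register", paste("no", nm, "input; skipped"))
      next
    }
    res <- run_stage("register", {
      vol <- load_input(cfg[[nm]], reg_modality[[nm]])
      interp <- if (nm == "vessels") "nearest" else "linear"
      if (nm %in% cfg$registered) {
        tr <- rigid_transform()
        say("register", paste(nm, "declared in base frame; identity",
                              "transform recorded"))
      } else {
        reg_mask <- if (nm == "postop_mri" && !is.null(mask_vol)) {
          # exclude the zero-intensity resection cavity from the metric
          mv <- mask_vol$data > 0.5 & base$data > 0
          image_volume(array(as.numeric(mv), dim(mv)), base$affine, "mask",
                       "base")
        }
        rr <- register_rigid(vol, base, mask = reg_mask)
        say("register", sprintf("%s: MI %.3f -> %.3f bits (%d evals)", nm,
                                rr$metric_before, rr$metric_after,
                                rr$iterations))
        tr <- rr$transform
      }
      out <- resample(vol, tr, base, interp)
      fv <- file.path(cfg$out_dir, paste0(nm, "_reg.nii"))
      ft <- file.path(cfg$out_dir, paste0(nm, "_transform.json"))
      write_volume(out, fv)
      write_transform(tr, ft)
      record(fv, "register", c(nm, "base_t1"), list(interp = interp))
      record(ft, "register", nm)
      list(vol = out, transform = tr, native = vol)
    })
    if (!is.null(res)) {
      registered[[nm]] <- res$vol
      transforms[[nm]] <- res$transform
      native[[nm]] <- res$native
    }
  }

  # --- SISCOM ---------------------------------------------------------
  # The subtraction is computed in the interictal SPECT's own space (ictal
  # registered SPECT-to-SPECT), and the z-map is then carried to the base
  # frame with the interictal volume's transform — the derived map always
  # travels with its carrier, never re-registered.
  siscom <- NULL
  if (!is.null(registered$ictal_spect) &&
      !is.null(registered$interictal_spect) && !is.null(mask_vol)) {
    siscom <- run_stage("siscom", {
      both_in_base <- all(c("ictal_spect", "interictal_spect") %in%
                            cfg$registered)
      if (both_in_base) {
        zm <- compute_siscom(registered$ictal_spect,
                             registered$interictal_spect, mask_vol,
                             threshold = cfg$z_threshold)
      } else {
        inter <- native$interictal_spect
        t_inter <- transforms$interictal_spect
        erode_vox <- cfg$mask_erosion
        t_i2i <- if ("ictal_spect" %in% cfg$registered)
          invert_transform(t_inter)  # ictal world is base world
        else {
          rr <- register_rigid(native$ictal_spect, inter)
          say("siscom", sprintf("ictal-to-interictal MI %.3f -> %.3f bits",
                                rr$metric_before, rr$metric_after))
          rr$transform
        }
        ict_i <- resample(native$ictal_spect, t_i2i, inter)
        mask_i <- resample(mask_vol, invert_transform(t_inter), inter,
                           "nearest")
        if (erode_vox > 0) {
          # registration leaves sub-voxel misalignment whose subtraction
          # artifacts sit on the brain edge; eroding the statistics mask
          # keeps the rim out of the z-map
          mask_i$data <- array(
            as.numeric(morph_ball(mask_i$data > 0.5, rep(erode_vox, 3),
                                  "erode")),
            dim(mask_i$data))
        }
        zm_i <- compute_siscom(ict_i, inter, mask_i,
                               threshold = cfg$z_threshold)
        zb <- transfer_map(t_inter, as_volume(zm_i), base)
        zdat <- zb$data
        zdat[!(mask_vol$data > 0.5)] <- 0
        zm <- structure(list(z = zdat, affine = base$affine,
                             mask = mask_vol$data > 0.5,
                             threshold = cfg$z_threshold),
                        class = "zscore_map")
        # cluster statistics are computed in the carrier space where the
        # z-map was estimated (interpolating z onto the base grid can split
        # clusters at the threshold); cluster coordinates are then mapped
        # through the carrier transform, which is exact for points
        cl_i <- threshold_clusters(zm_i, cfg$z_threshold,
                                   cfg$min_cluster_voxels)
        if (nrow(cl_i)) {
          cen <- apply_transform(t_inter, as.matrix(
            cl_i[, c("centroid_x", "centroid_y", "centroid_z")]))
          pk <- apply_transform(t_inter, as.matrix(
            cl_i[, c("peak_x", "peak_y", "peak_z_mm")]))
          cl_i[, c("centroid_x", "centroid_y", "centroid_z")] <- cen
          cl_i[, c("peak_x", "peak_y", "peak_z_mm")] <- pk
        }
      }
      cl <- if (both_in_base)
        threshold_clusters(zm, cfg$z_threshold, cfg$min_cluster_voxels)
      else cl_i
      fz <- file.path(cfg$out_dir, "siscom_z.nii")
      fc <- file.path(cfg$out_dir, "siscom_clusters.tsv")
      write_volume(as_volume(zm), fz)
      write_cluster_table(cl, fc)
      record(fz, "siscom", c("ictal_spect", "interictal_spect"),
             list(z = cfg$z_threshold))
      record(fc, "siscom", "siscom_z",
             list(z = cfg$z_threshold, min_voxels = cfg$min_cluster_voxels))
      say("siscom", sprintf("%d cluster(s) at z >= %.2f", nrow(cl),
                            cfg$z_threshold))
      list(zmap = zm, clusters = cl)
    })
  } else say("siscom", "SPECT pair incomplete; skipped")

  # --- Talairach frame ------------------------------------------------
  frame <- NULL
  if (!is.null(cfg$ac) && !is.null(cfg$pc) && !is.null(cfg$ms) &&
      !is.null(cfg$bounds)) {
    frame <- run_stage("talairach", {
      fr <- build_frame(cfg$ac, cfg$pc, cfg$ms, cfg$bounds)
      ff <- file.path(cfg$out_dir, "talairach_frame.json")
      write_frame(fr, ff)
      record(ff, "talairach", "landmarks")
      say("talairach", sprintf("frame built, AC-PC %.1f mm", fr$acpc_dist))
      fr
    })
  } else say("talairach", "landmarks incomplete; skipped")

  # --- trajectories ---------------------------------------------------
  plan <- run_stage("plan", load_plan_input(cfg$plan))
  safety <- NULL
  coverage <- NULL
  if (!is.null(plan) && nrow(plan)) {
    if (!is.null(registered$vessels)) {
      safety <- run_stage("trajectories", {
        st <- plan_safety(plan, registered$vessels, cfg$clearance)
        fs <- file.path(cfg$out_dir, "safety.tsv")
        utils::write.table(st, fs, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        record(fs, "trajectories", c("plan", "vessels"),
               list(clearance = cfg$clearance))
        say("trajectories", sprintf("%d/%d trajectories pass %.1f mm",
                                    sum(st$pass), nrow(st), cfg$clearance))
        st
      })
    }
    if (!is.null(siscom) && nrow(siscom$clusters)) {
      coverage <- run_stage("trajectories", {
        tg <- point_set(paste0("siscom_peak", siscom$clusters$rank),
                        siscom$clusters$peak_x, siscom$clusters$peak_y,
                        siscom$clusters$peak_z_mm)
        cv <- target_coverage(plan, tg, cfg$coverage_radius)
        fc <- file.path(cfg$out_dir, "coverage.tsv")
        utils::write.table(cv, fc, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        record(fc, "trajectories", c("plan", "siscom_clusters"),
               list(radius = cfg$coverage_radius))
        cv
      })
    }
    run_stage("trajectories", {
      burned <- burn_lines(base, plan)
      fb <- file.path(cfg$out_dir, "trajectories_burned.nii")
      write_volume(burned, fb)
      record(fb, "trajectories", c("plan", "base_t1"))
      NULL
    })
    if (!is.null(frame)) {
      run_stage("trajectories", {
        ends <- point_set(
          c(paste0(plan$name, "_entry"), paste0(plan$name, "_target")),
          c(plan$entry_x, plan$target_x), c(plan$entry_y, plan$target_y),
          c(plan$entry_z, plan$target_z))
        cells <- grid_cell(ends, frame)
        fg <- file.path(cfg$out_dir, "plan_grid_cells.tsv")
        utils::write.table(cells, fg, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        record(fg, "trajectories", c("plan", "talairach_frame"))
        NULL
      })
    }
  } else say("trajectories", "no plan; skipped")

  # --- contacts -------------------------------------------------------
  # Candidates are segmented on the native-resolution CT and their centres
  # mapped through the CT-to-base transform; resampling the CT onto a
  # coarser base grid first would throw away sub-voxel contact localization.
  contacts <- NULL
  if (!is.null(registered$post_ct) && !is.null(plan) && nrow(plan)) {
    contacts <- run_stage("contacts", {
      cand <- segment_contact_candidates(
        native$post_ct, threshold = cfg$ct_threshold,
        expected_spacing = cfg$contact_spacing)
      if (nrow(cand)) {
        xyz <- apply_transform(transforms$post_ct, ps_coords(cand))
        cand <- point_set(cand$name, xyz[, 1], xyz[, 2], xyz[, 3],
                          group = cand$group, value = cand$value)
      }
      cs <- assign_and_name(cand, plan, tol = cfg$contact_tol)
      ft <- file.path(cfg$out_dir, "contacts.tsv")
      fj <- file.path(cfg$out_dir, "contacts.json")
      write_contact_set(cs, ft)
      write_contact_set(cs, fj)
      record(ft, "contacts", c("post_ct", "plan"),
             list(tol = cfg$contact_tol))
      record(fj, "contacts", c("post_ct", "plan"))
      say("contacts", sprintf("%d contacts named, %d unassigned",
                              nrow(cs$contacts), nrow(cs$unassigned)))
      cs
    })
  } else say("contacts", "post-implant CT or plan missing; skipped")

  # --- resection ------------------------------------------------------
  resection <- NULL
  markers <- run_stage("resection", load_pointset_input(cfg$markers))
  if (!is.null(markers) && nrow(markers)) {
    resection <- run_stage("resection", {
      rm_ <- markers_to_mask(markers, cfg$brush_radius, base)
      mesh <- mask_to_voxel_mesh(rm_)
      burned <- export_burned_mask(base, rm_)
      fm <- file.path(cfg$out_dir, "resection_mask.nii")
      fo <- file.path(cfg$out_dir, "resection_mesh.obj")
      fb <- file.path(cfg$out_dir, "resection_burned.nii")
      write_volume(image_volume(rm_$mask, rm_$affine, "mask", "base"), fm)
      write_mesh_obj(mesh, fo)
      write_volume(burned, fb)
      record(fm, "resection", "markers",
             list(brush = cfg$brush_radius))
      record(fo, "resection", "resection_mask")
      record(fb, "resection", c("resection_mask", "base_t1"))
      containment <- NULL
      if (!is.null(contacts) && nrow(contacts$contacts)) {
        containment <- mask_contains(rm_, contacts_as_pointset(contacts))
        fc <- file.path(cfg$out_dir, "containment.tsv")
        utils::write.table(containment, fc, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        record(fc, "resection", c("resection_mask", "contacts"))
        say("resection", sprintf("%.0f%% of contacts inside the proposal",
                                 100 * attr(containment,
                                            "fraction_inside")))
      }
      list(mask = rm_, mesh = mesh, containment = containment)
    })
  } else say("resection", "no pass markers; skipped")

  # --- manifest and logs ----------------------------------------------
  manifest_df <- if (length(manifest))
    do.call(rbind, lapply(manifest, as.data.frame)) else
    data.frame(file = character(), stage = character(),
               inputs = character(), parameters = character(),
               md5 = character())
  fmf <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest_df, fmf, auto_unbox = TRUE, digits = NA)
  writeLines(log_lines, file.path(cfg$out_dir, "log.txt"))
  jsonlite::write_json(events, file.path(cfg$out_dir, "events.json"),
                       auto_unbox = TRUE)
  structure(list(base = base, mask = mask_vol, registered = registered,
                 transforms = transforms, siscom = siscom, frame = frame,
                 plan = plan, safety = safety, coverage = coverage,
                 contacts = contacts, resection = resection,
                 manifest = manifest_df, errors = errors, log = log_lines),
            class = "case_bundle")
}

#' @export
print.case_bundle <- function(x, ...) {
  cat(sprintf("<case_bundle> %d artifacts, %d stage error(s)\n",
              nrow(x$manifest), length(x$errors)))
  invisible(x)
}
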