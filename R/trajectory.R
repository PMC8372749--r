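#' Plan a straight-line SEEG trajectory
#'
#' A trajectory is the straight line connecting a scalp entry point to an
#' intracerebral target point, one per electrode.
#'
#' @param name electrode label (nonempty, unique within a plan).
#' @param entry,target world mm points; must be distinct.
#' @return a one-row `data.frame` of class `trajectory_plan` with columns
#'   `name`, `entry_x/y/z`, `target_x/y/z`, `length` (mm).
#' @export
plan_trajectory <- function(name, entry, target) {
  entry <- as.numeric(entry); target <- as.numeric(target)
  stopifnot(length(entry) == 3, length(target) == 3)
  if (!nzchar(name)) stop("trajectory name must be nonempty", call. = FALSE)
  len <- sqrt(sum((entry - target)^2))
  if (len == 0)
    stop("entry and target points coincide for trajectory ", name,
         call. = FALSE)
  out <- data.frame(name = as.character(name),
                    entry_x = entry[1], entry_y = entry[2], entry_z = entry[3],
                    target_x = target[1], target_y = target[2],
                    target_z = target[3], length = len,
                    stringsAsFactors = FALSE)
  class(out) <- c("trajectory_plan", "data.frame")
  out
}

#' Combine trajectories into a plan
#' @param ... `trajectory_plan` rows (or data frames of them).
#' @return a `trajectory_plan` data frame; names must be unique.
#' @export
trajectory_plan <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  if (is.null(out)) out <- plan_trajectory("x", c(0, 0, 0), c(1, 0, 0))[0, ]
  dup <- unique(out$name[duplicated(out$name)])
  if (length(dup))
    stop("duplicate trajectory names: ", paste(dup, collapse = ", "),
         call. = FALSE)
  class(out) <- c("trajectory_plan", "data.frame")
  out
}

as_trajectory_plan <- function(x) {
  if (inherits(x, "trajectory_plan")) return(x)
  if (is.data.frame(x)) return(trajectory_plan(x))
  do.call(trajectory_plan, x)
}

traj_entry <- function(plan, r)
  as.numeric(plan[r, c("entry_x", "entry_y", "entry_z")])
traj_target <- function(plan, r)
  as.numeric(plan[r, c("target_x", "target_y", "target_z")])

#' Unit direction of a trajectory (target minus entry)
#' @param t a one-row `trajectory_plan`.
#' @return unit length-3 vector pointing entry to target.
#' @export
trajectory_direction <- function(t) {
  u <- traj_target(t, 1) - traj_entry(t, 1)
  u / sqrt(sum(u^2))
}

#' Read / write a trajectory plan
#'
#' JSON (array of records) or CSV with columns `name, entry_x..target_z`
#' (optionally `n_contacts`, `spacing`).
#' @param path file path (`.json` or `.csv`).
#' @param plan a `trajectory_plan` (write only).
#' @return `read_plan` returns a `trajectory_plan` (extra columns preserved);
#'   `write_plan` returns `path` invisibly.
#' @export
read_plan <- function(path) {
  df <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path) else utils::read.csv(path)
  need <- c("name", "entry_x", "entry_y", "entry_z",
            "target_x", "target_y", "target_z")
  if (!all(need %in% names(df)))
    stop("plan file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  rows <- lapply(seq_len(nrow(df)), function(r)
    plan_trajectory(df$name[r],
                    as.numeric(df[r, c("entry_x", "entry_y", "entry_z")]),
                    as.numeric(df[r, c("target_x", "target_y", "target_z")])))
  out <- do.call(trajectory_plan, rows)
  for (extra in setdiff(names(df), names(out)))
    out[[extra]] <- df[[extra]]
  out
}

#' @rdname read_plan
#' @export
write_plan <- function(plan, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.data.frame(plan), path, auto_unbox = TRUE,
                         digits = NA)
  } else {
    utils::write.csv(as.data.frame(plan), path, row.names = FALSE)
  }
  invisible(path)
}

#' Vascular clearance of a trajectory
#'
#' Minimum distance from the trajectory segment to any vessel voxel centre of
#' a binary vessel mask (CTA/MRA segmentation in the base frame), with the
#' entry zone — the first 15 mm from the scalp entry — reported separately,
#' since vessel avoidance matters most there.
#'
#' @param t a one-row `trajectory_plan`.
#' @param vessels binary vessel-mask `image_volume`.
#' @param clearance pass/fail clearance in mm (default 3).
#' @param entry_zone length of the entry zone in mm (default 15).
#' @return a one-row `data.frame`: `name`, `min_vessel_distance` (mm),
#'   `closest_x/y/z` (closest point on the trajectory), `entry_zone_distance`
#'   (mm, minimum over the first `entry_zone` mm), `pass`. Distances are
#'   `Inf` (and `pass = TRUE`) for an empty mask.
#' @export
vessel_clearance <- function(t, vessels, clearance = 3, entry_zone = 15) {
  stopifnot(inherits(vessels, "image_volume"))
  a <- traj_entry(t, 1); b <- traj_target(t, 1)
  idx <- which(vessels$data > 0.5)
  if (!length(idx)) {
    return(data.frame(name = t$name[1], min_vessel_distance = Inf,
                      closest_x = NA_real_, closest_y = NA_real_,
                      closest_z = NA_real_, entry_zone_distance = Inf,
                      pass = TRUE, stringsAsFactors = FALSE))
  }
  d <- dim(vessels$data)
  lin <- idx - 1L
  ijk <- cbind(lin %% d[1], (lin %/% d[1]) %% d[2], lin %/% (d[1] * d[2]))
  w <- voxel_to_world(vessels, ijk)
  full <- point_segment_distance(w, a, b)
  i_min <- which.min(full$dist)
  len <- sqrt(sum((b - a)^2))
  closest <- a + full$t[i_min] * (b - a)
  ez_end <- a + min(1, entry_zone / len) * (b - a)
  ez <- point_segment_distance(w, a, ez_end)
  data.frame(name = t$name[1],
             min_vessel_distance = full$dist[i_min],
             closest_x = closest[1], closest_y = closest[2],
             closest_z = closest[3],
             entry_zone_distance = min(ez$dist),
             pass = full$dist[i_min] >= clearance,
             stringsAsFactors = FALSE)
}

#' Safety report for a whole plan
#' @param plan a `trajectory_plan`.
#' @inheritParams vessel_clearance
#' @return row-bound [vessel_clearance()] results, one row per trajectory.
#' @export
plan_safety <- function(plan, vessels, clearance = 3, entry_zone = 15) {
  plan <- as_trajectory_plan(plan)
  do.call(rbind, lapply(seq_len(nrow(plan)), function(r)
    vessel_clearance(plan[r, ], vessels, clearance, entry_zone)))
}

#' Coverage of localization targets by a trajectory plan
#'
#' For each target point (MEG dipole cluster centre, SISCOM cluster peak,
#' hypometabolic focus, ...) reports which trajectories pass within `radius`
#' mm and the minimal point-to-segment distance, flagging uncovered targets.
#'
#' @param plan a `trajectory_plan`.
#' @param targets a `point_set` of localization targets (world mm).
#' @param radius coverage radius in mm (> 0).
#' @return a `data.frame`: `target`, `covered`, `n_covering`,
#'   `closest_trajectory`, `min_distance` (mm), `covering` (comma-separated
#'   trajectory names within radius).
#' @export
target_coverage <- function(plan, targets, radius = 5) {
  stopifnot(radius > 0)
  plan <- as_trajectory_plan(plan)
  if (!nrow(targets))
    return(data.frame(target = character(), covered = logical(),
                      n_covering = integer(), closest_trajectory = character(),
                      min_distance = numeric(), covering = character(),
                      stringsAsFactors = FALSE))
  p <- ps_coords(targets)
  dists <- vapply(seq_len(nrow(plan)), function(r)
    point_segment_distance(p, traj_entry(plan, r), traj_target(plan, r))$dist,
    numeric(nrow(targets)))
  dists <- matrix(dists, nrow = nrow(targets))
  i_min <- apply(dists, 1, which.min)
  min_d <- dists[cbind(seq_len(nrow(targets)), i_min)]
  covering <- apply(dists, 1, function(row)
    paste(plan$name[row <= radius], collapse = ","))
  data.frame(target = targets$name,
             covered = min_d <= radius,
             n_covering = rowSums(dists <= radius),
             closest_trajectory = plan$name[i_min],
             min_distance = min_d,
             covering = covering,
             stringsAsFactors = FALSE)
}

#' Expected contact positions along a trajectory
#'
#' Contacts are numbered from the target (deepest, index 1) outward toward
#' the entry, at regular centre-to-centre spacing.
#'
#' @param t a one-row `trajectory_plan`.
#' @param n number of contacts (>= 1).
#' @param spacing centre-to-centre spacing in mm (> 0).
#' @return a `point_set` named `<electrode>1..<electrode>n`, group = the
#'   electrode name.
#' @export
expected_contacts <- function(t, n, spacing = 3.5) {
  stopifnot(n >= 1, spacing > 0)
  len <- t$length[1]
  if ((n - 1) * spacing > len)
    stop("contact span ", (n - 1) * spacing,
         " mm exceeds trajectory length ", round(len, 2), " mm for ",
         t$name[1], call. = FALSE)
  u <- -trajectory_direction(t)           # target -> entry
  b <- traj_target(t, 1)
  pts <- t(vapply(seq_len(n) - 1L, function(i) b + i * spacing * u,
                  numeric(3)))
  point_set(paste0(t$name[1], seq_len(n)), pts[, 1], pts[, 2], pts[, 3],
            group = t$name[1])
}
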