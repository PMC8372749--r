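#' Burn settings for high-intensity annotations
#'
#' Controls how points (e.g. MEG dipole locations) and trajectory lines are
#' printed into a volume as high-intensity features, bright enough to survive
#' export and be re-segmented downstream.
#'
#' @param marker_radius sphere radius for point markers, mm.
#' @param marker_intensity burned intensity as a factor of the volume's global
#'   maximum; must exceed 1 so burned voxels are strictly brighter than
#'   anatomy.
#' @param line_radius tube radius for trajectory lines, mm.
#' @return an object of class `burn_settings`.
#' @export
burn_settings <- function(marker_radius = 2, marker_intensity = 1.2,
                          line_radius = 1) {
  if (marker_radius <= 0 || line_radius <= 0)
    stop("burn radii must be > 0", call. = FALSE)
  if (marker_intensity <= 1)
    stop("marker_intensity must be > 1", call. = FALSE)
  structure(list(marker_radius = marker_radius,
                 marker_intensity = marker_intensity,
                 line_radius = line_radius),
            class = "burn_settings")
}

# linear array indices of voxels within `radius` mm of world point `p`
voxels_within_sphere <- function(vol, p, radius) {
  d <- dim(vol$data)
  sp <- voxel_spacing(vol)
  c0 <- world_to_voxel(vol, p)[1, ]
  rv <- ceiling(radius / sp)
  lo <- pmax(0, floor(c0) - rv)
  hi <- pmin(d - 1, ceiling(c0) + rv)
  if (any(lo > hi)) return(integer())
  ijk <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2],
                               k = lo[3]:hi[3]))
  w <- voxel_to_world(vol, ijk)
  keep <- rowSums(sweep(w, 2, p)^2) <= radius^2
  ijk <- ijk[keep, , drop = FALSE]
  1L + ijk[, 1] + d[1] * (ijk[, 2] + d[2] * ijk[, 3])
}

#' Burn points into a volume as high-intensity spheres
#'
#' Prints each point of a point set as a sphere of `marker_radius` whose
#' intensity is `marker_intensity` times the volume's global maximum — the
#' scriptable equivalent of printing dipole locations on top of the MRI.
#' Points outside the field of view are skipped with a warning.
#'
#' @param vol an `image_volume`.
#' @param pts a `point_set` in the volume's world coordinates (mm).
#' @param s a [burn_settings()] object.
#' @return the burned `image_volume`; attribute `"skipped"` lists the names of
#'   any out-of-field points.
#' @export
burn_points <- function(vol, pts, s = burn_settings()) {
  stopifnot(inherits(vol, "image_volume"))
  out <- vol
  if (!nrow(pts)) {
    attr(out, "skipped") <- character()
    return(out)
  }
  burn_val <- s$marker_intensity * max(vol$data)
  inside <- in_fov(vol, ps_coords(pts))
  skipped <- pts$name[!inside]
  for (nm in skipped)
    warning("point outside field of view, skipped: ", nm, call. = FALSE)
  for (r in which(inside)) {
    idx <- voxels_within_sphere(vol, as.numeric(pts[r, c("x", "y", "z")]),
                                s$marker_radius)
    out$data[idx] <- burn_val
  }
  attr(out, "skipped") <- skipped
  out
}

#' Burn trajectory lines into a volume
#'
#' Sets every voxel within `line_radius` of an entry-target segment to
#' `marker_intensity` times the global maximum, producing the high-intensity
#' line export used to hand planned electrodes to neuronavigation systems.
#'
#' @param vol an `image_volume`.
#' @param trajectories a trajectory plan (data frame from [plan_trajectory()]
#'   rows, or a list of them).
#' @param s a [burn_settings()] object.
#' @return the burned `image_volume`.
#' @export
burn_lines <- function(vol, trajectories, s = burn_settings()) {
  stopifnot(inherits(vol, "image_volume"))
  plan <- as_trajectory_plan(trajectories)
  out <- vol
  if (!nrow(plan)) return(out)
  burn_val <- s$marker_intensity * max(vol$data)
  d <- dim(vol$data)
  sp <- voxel_spacing(vol)
  for (r in seq_len(nrow(plan))) {
    a <- as.numeric(plan[r, c("entry_x", "entry_y", "entry_z")])
    b <- as.numeric(plan[r, c("target_x", "target_y", "target_z")])
    if (!all(in_fov(vol, rbind(a, b))))
      warning("trajectory endpoint outside field of view: ", plan$name[r],
              call. = FALSE)
    va <- world_to_voxel(vol, a)[1, ]
    vb <- world_to_voxel(vol, b)[1, ]
    rv <- ceiling(s$line_radius / sp)
    lo <- pmax(0, floor(pmin(va, vb)) - rv)
    hi <- pmin(d - 1, ceiling(pmax(va, vb)) + rv)
    if (any(lo > hi)) next
    ijk <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2],
                                 k = lo[3]:hi[3]))
    w <- voxel_to_world(vol, ijk)
    dist <- point_segment_distance(w, a, b)$dist
    keep <- dist <= s$line_radius
    idx <- 1L + ijk[keep, 1] + d[1] * (ijk[keep, 2] + d[2] * ijk[keep, 3])
    out$data[idx] <- burn_val
  }
  out
}

#' Segment bright points from a volume
#'
#' Finds 26-connected components of voxels above `threshold` and reports one
#' point per component at the component's centre of maximal intensity
#' (intensity-weighted centroid of its top-20% voxels, shared with electrode
#' contact segmentation). This is the inverse of [burn_points()]: it recovers
#' "localize point" lists from volumes carrying printed high-intensity
#' markers.
#'
#' @param vol an `image_volume`.
#' @param threshold absolute intensity; voxels strictly above it are kept.
#' @param prefix name prefix for the returned points (named `<prefix>1`,
#'   `<prefix>2`, ... in decreasing peak intensity).
#' @return a `point_set` in world mm; `value` holds each component's peak
#'   intensity.
#' @export
extract_bright_points <- function(vol, threshold, prefix = "P") {
  stopifnot(is.finite(threshold))
  mask <- vol$data > threshold
  if (!any(mask)) return(point_set())
  lab <- label_components(mask)
  n <- max(lab)
  centers <- matrix(0, n, 3)
  peaks <- numeric(n)
  for (comp in seq_len(n)) {
    idx <- which(lab == comp)
    centers[comp, ] <- component_center(vol, idx)
    peaks[comp] <- max(vol$data[idx])
  }
  ord <- order(peaks, decreasing = TRUE)
  point_set(paste0(prefix, seq_len(n)),
            centers[ord, 1], centers[ord, 2], centers[ord, 3],
            value = peaks[ord])
}

# centre of maximal intensity of a set of voxels (linear indices):
# intensity-weighted centroid of the top-20% intensity voxels
component_center <- function(vol, idx) {
  vals <- vol$data[idx]
  cutoff <- stats::quantile(vals, 0.8, names = FALSE, type = 7)
  top <- idx[vals >= cutoff]
  wts <- vol$data[top]
  d <- dim(vol$data)
  lin <- top - 1L
  ijk <- cbind(lin %% d[1],
               (lin %/% d[1]) %% d[2],
               lin %/% (d[1] * d[2]))
  w <- voxel_to_world(vol, ijk)
  if (sum(wts) <= 0) wts <- rep(1, length(top))
  colSums(w * wts) / sum(wts)
}
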