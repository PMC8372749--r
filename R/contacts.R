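#' Segment electrode-contact candidates from a post-implant CT
#'
#' Thresholds the co-registered post-implant CT, labels 26-connected
#' components, splits components that merge several contacts at their 3D
#' local intensity maxima (minimum peak separation 0.7 x the expected
#' contact spacing), and reports each candidate at its centre of maximal
#' intensity — the intensity-weighted centroid of the component's top-20%
#' intensity voxels, which is robust to CT blooming.
#'
#' @param ct post-implant CT `image_volume`, already resampled to the base
#'   frame.
#' @param threshold absolute intensity threshold, or `NULL` to use
#'   `percentile`.
#' @param percentile intensity percentile defining the threshold when
#'   `threshold` is `NULL` (default 99.9).
#' @param expected_spacing nominal contact spacing in mm used by the merge
#'   splitter (default 3.5).
#' @param min_voxels discard components smaller than this (default 1).
#' @return a `point_set` of candidates (named `C1`, `C2`, ... in decreasing
#'   peak intensity; `value` = peak intensity).
#' @export
segment_contact_candidates <- function(ct, threshold = NULL,
                                       percentile = 99.9,
                                       expected_spacing = 3.5,
                                       min_voxels = 1L) {
  stopifnot(inherits(ct, "image_volume"))
  if (is.null(threshold))
    threshold <- stats::quantile(ct$data, percentile / 100, names = FALSE)
  mask <- ct$data > threshold
  if (!any(mask)) return(point_set())
  lab <- label_components(mask)
  maxima <- array(cpp_local_maxima(as.numeric(ct$data),
                                   as.integer(dim(ct$data)),
                                   as.logical(mask)),
                  dim(ct$data))
  # peaks are distinct when separated by >= 0.7 x the nominal spacing; the
  # comparison gets half a voxel diagonal of slack because discrete maxima
  # are snapped to voxel centres and overlapping tails bias refined
  # positions toward each other
  min_sep <- max(0, 0.7 * expected_spacing -
                   sqrt(sum(voxel_spacing(ct)^2)) / 2)
  centers <- list()
  peaks <- numeric()
  d <- dim(ct$data)
  for (comp in seq_len(max(lab))) {
    idx <- which(lab == comp)
    if (length(idx) < min_voxels) next
    lin <- idx - 1L
    ijk <- cbind(lin %% d[1], (lin %/% d[1]) %% d[2], lin %/% (d[1] * d[2]))
    w <- voxel_to_world(ct, ijk)
    vals <- ct$data[idx]
    # candidate peaks: local maxima of the component, refined to sub-voxel
    # positions (grid snapping can pull two true peaks below the separation
    # limit), then greedily accepted in decreasing intensity subject to the
    # minimum separation
    pk <- which(maxima[idx])
    if (!length(pk)) pk <- which.max(vals)
    pk <- pk[order(vals[pk], decreasing = TRUE)]
    pk_pos <- t(vapply(pk, function(q)
      refine_peak(ct, ijk[q, ]), numeric(3)))
    accepted <- integer()
    for (s in seq_along(pk)) {
      q <- pk[s]
      if (!length(accepted) ||
          min(sqrt(rowSums(sweep(
            pk_pos[match(accepted, pk), , drop = FALSE], 2,
            pk_pos[s, ])^2))) >= min_sep)
        accepted <- c(accepted, q)
    }
    if (length(accepted) == 1L) {
      centers[[length(centers) + 1L]] <- component_center(ct, idx)
      peaks <- c(peaks, max(vals))
    } else {
      # assign each component voxel to its nearest accepted peak, then take
      # each sub-component's centre of maximal intensity
      dmat <- vapply(accepted, function(q)
        rowSums(sweep(w, 2, w[q, ])^2), numeric(length(idx)))
      nearest <- max.col(-matrix(dmat, nrow = length(idx)))
      for (s in seq_along(accepted)) {
        sub <- idx[nearest == s]
        centers[[length(centers) + 1L]] <- component_center(ct, sub)
        peaks <- c(peaks, max(ct$data[sub]))
      }
    }
  }
  if (!length(centers)) return(point_set())
  cen <- do.call(rbind, centers)
  ord <- order(peaks, decreasing = TRUE)
  point_set(paste0("C", seq_along(ord)),
            cen[ord, 1], cen[ord, 2], cen[ord, 3], value = peaks[ord])
}

# sub-voxel refinement of a local maximum: intensity-weighted centroid of
# its 3x3x3 neighbourhood, in world mm
refine_peak <- function(vol, ijk0) {
  d <- dim(vol$data)
  lo <- pmax(0, ijk0 - 1)
  hi <- pmin(d - 1, ijk0 + 1)
  nb <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2],
                              k = lo[3]:hi[3]))
  wts <- vol$data[nb + 1]
  wts <- pmax(wts - min(wts), 0)
  if (sum(wts) <= 0) wts <- rep(1, nrow(nb))
  w <- voxel_to_world(vol, nb)
  colSums(w * wts) / sum(wts)
}

#' Assign candidates to trajectories and name the contacts
#'
#' Each candidate is assigned to the planned trajectory minimizing its
#' point-to-segment distance, provided that distance is at most `tol` mm;
#' otherwise it is listed unassigned. Per electrode, contacts are ordered by
#' their projection onto the trajectory from the target (deepest) outward and
#' named `<electrode><index>` with index 1 deepest. Ties in projection are
#' broken by distance to the axis, then lexicographically by coordinates, so
#' the result is deterministic and independent of candidate order.
#'
#' @param candidates a `point_set` from [segment_contact_candidates()].
#' @param plan a `trajectory_plan` (nonempty).
#' @param tol assignment tolerance in mm (default 4).
#' @return a `contact_set`: `contacts` (data frame `electrode`, `index`,
#'   `name`, `x`, `y`, `z`, `distance_to_axis`, `peak_intensity`) and
#'   `unassigned` (`point_set`).
#' @export
assign_and_name <- function(candidates, plan, tol = 4) {
  plan <- as_trajectory_plan(plan)
  if (!nrow(plan)) stop("trajectory plan is empty", call. = FALSE)
  stopifnot(tol > 0)
  empty <- data.frame(electrode = character(), index = integer(),
                      name = character(), x = numeric(), y = numeric(),
                      z = numeric(), distance_to_axis = numeric(),
                      peak_intensity = numeric(), stringsAsFactors = FALSE)
  if (!nrow(candidates))
    return(structure(list(contacts = empty, unassigned = point_set()),
                     class = "contact_set"))
  p <- ps_coords(candidates)
  dists <- vapply(seq_len(nrow(plan)), function(r)
    point_segment_distance(p, traj_entry(plan, r), traj_target(plan, r))$dist,
    numeric(nrow(candidates)))
  dists <- matrix(dists, nrow = nrow(candidates))
  best <- apply(dists, 1, which.min)
  best_d <- dists[cbind(seq_len(nrow(candidates)), best)]
  assigned <- best_d <= tol
  rows <- list()
  for (r in seq_len(nrow(plan))) {
    sel <- which(assigned & best == r)
    if (!length(sel)) next
    b <- traj_target(plan, r)
    u <- -trajectory_direction(plan[r, ])   # target -> entry
    proj <- as.numeric(sweep(p[sel, , drop = FALSE], 2, b) %*% u)
    ord <- order(proj, best_d[sel], p[sel, 1], p[sel, 2], p[sel, 3])
    sel <- sel[ord]
    rows[[length(rows) + 1L]] <- data.frame(
      electrode = plan$name[r], index = seq_along(sel),
      name = paste0(plan$name[r], seq_along(sel)),
      x = p[sel, 1], y = p[sel, 2], z = p[sel, 3],
      distance_to_axis = best_d[sel],
      peak_intensity = candidates$value[sel],
      stringsAsFactors = FALSE)
  }
  contacts <- if (length(rows)) do.call(rbind, rows) else empty
  rownames(contacts) <- NULL
  un <- candidates[!assigned, , drop = FALSE]
  un <- point_set(un$name, un$x, un$y, un$z, group = un$group,
                  value = un$value)
  structure(list(contacts = contacts, unassigned = un),
            class = "contact_set")
}

#' @export
print.contact_set <- function(x, ...) {
  cat(sprintf("<contact_set> %d contacts on %d electrodes, %d unassigned\n",
              nrow(x$contacts), length(unique(x$contacts$electrode)),
              nrow(x$unassigned)))
  invisible(x)
}

#' Write a contact set as TSV or JSON
#' @param cs a `contact_set`.
#' @param path output path (`.json` for JSON, else TSV).
#' @return `path`, invisibly.
#' @export
write_contact_set <- function(cs, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(contacts = cs$contacts,
                              unassigned = as.data.frame(cs$unassigned)),
                         path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    utils::write.table(cs$contacts, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Convert a contact set to a point set
#' @param cs a `contact_set`.
#' @return a `point_set` (group = electrode, value = peak intensity).
#' @export
contacts_as_pointset <- function(cs) {
  cc <- cs$contacts
  point_set(cc$name, cc$x, cc$y, cc$z, group = cc$electrode,
            value = cc$peak_intensity)
}
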