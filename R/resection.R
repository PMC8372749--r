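#' Voxelize resection pass markers into a binary mask
#'
#' The scriptable counterpart of drawing a proposed resection on orthogonal
#' MRI views: each marker contributes a sphere of `brush_radius`, consecutive
#' markers within the same `group` (one group per stroke) are connected by
#' swept-sphere capsules, and the union is closed morphologically (ball
#' radius `brush_radius / 2`) to fill gaps between strokes.
#'
#' @param markers a `point_set`; `group` is the stroke id, point order within
#'   a group is the drawing order.
#' @param brush_radius brush radius in mm (> 0), default 2.
#' @param base base `image_volume` defining the grid.
#' @param closing apply the morphological closing (default TRUE).
#' @return a `resection_mask`: `mask` (binary array on the base grid),
#'   `affine`, `brush_radius`, `markers`.
#' @export
markers_to_mask <- function(markers, brush_radius = 2, base,
                            closing = TRUE) {
  stopifnot(inherits(base, "image_volume"), brush_radius > 0)
  d <- dim(base$data)
  mask <- array(FALSE, d)
  if (nrow(markers)) {
    if (!all(in_fov(base, ps_coords(markers))))
      warning("some pass markers lie outside the field of view",
              call. = FALSE)
    for (g in unique(markers$group)) {
      pts <- ps_coords(markers[markers$group == g, , drop = FALSE])
      for (i in seq_len(nrow(pts))) {
        idx <- voxels_within_sphere(base, pts[i, ], brush_radius)
        mask[idx] <- TRUE
      }
      if (nrow(pts) > 1) {
        for (i in seq_len(nrow(pts) - 1))
          mask <- mask | capsule_mask(base, pts[i, ], pts[i + 1, ],
                                      brush_radius)
      }
    }
    if (closing)
      mask <- close_mask(mask, brush_radius / 2, voxel_spacing(base))
  }
  structure(list(mask = array(as.integer(mask), d), affine = base$affine,
                 brush_radius = brush_radius, markers = markers),
            class = "resection_mask")
}

# voxels within `radius` of segment [a, b]
capsule_mask <- function(vol, a, b, radius) {
  d <- dim(vol$data)
  sp <- voxel_spacing(vol)
  va <- world_to_voxel(vol, a)[1, ]
  vb <- world_to_voxel(vol, b)[1, ]
  rv <- ceiling(radius / sp)
  lo <- pmax(0, floor(pmin(va, vb)) - rv)
  hi <- pmin(d - 1, ceiling(pmax(va, vb)) + rv)
  out <- array(FALSE, d)
  if (any(lo > hi)) return(out)
  ijk <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2],
                               k = lo[3]:hi[3]))
  w <- voxel_to_world(vol, ijk)
  keep <- point_segment_distance(w, a, b)$dist <= radius
  idx <- 1L + ijk[keep, 1] + d[1] * (ijk[keep, 2] + d[2] * ijk[keep, 3])
  out[idx] <- TRUE
  out
}

#' @export
print.resection_mask <- function(x, ...) {
  sp <- sqrt(colSums(x$affine[1:3, 1:3]^2))
  cat(sprintf("<resection_mask> %d voxels (%.1f ml), brush %.1f mm\n",
              sum(x$mask), sum(x$mask) * prod(sp) / 1000, x$brush_radius))
  invisible(x)
}

#' Voxel-mesh surface of a resection mask
#'
#' Emits the exposed faces of the mask's boundary voxels as quads in world
#' mm — a literal voxel mesh, not a smoothed isosurface. For a solid
#' (hole-free) mask the mesh is closed: every edge is shared by exactly two
#' faces.
#'
#' @param m a `resection_mask`.
#' @return a list: `vertices` (n x 3 world mm, deduplicated) and `faces`
#'   (m x 4 vertex indices, one row per quad).
#' @export
mask_to_voxel_mesh <- function(m) {
  mask <- m$mask > 0
  d <- dim(mask)
  vol <- image_volume(m$mask, m$affine, "mask")
  # pad lookup: neighbour occupancy with out-of-bounds = empty
  occ <- function(i, j, k) {
    ok <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
    res <- logical(length(i))
    res[ok] <- mask[cbind(i[ok], j[ok], k[ok])]
    res
  }
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx))
    return(list(vertices = matrix(numeric(), 0, 3),
                faces = matrix(integer(), 0, 4)))
  # unit-cube corner offsets (0-based voxel corner coordinates ijk +/- 0.5)
  face_defs <- list(
    list(dir = c(-1, 0, 0), corners = rbind(c(-1,-1,-1), c(-1, 1,-1),
                                            c(-1, 1, 1), c(-1,-1, 1))),
    list(dir = c( 1, 0, 0), corners = rbind(c( 1,-1,-1), c( 1,-1, 1),
                                            c( 1, 1, 1), c( 1, 1,-1))),
    list(dir = c(0, -1, 0), corners = rbind(c(-1,-1,-1), c(-1,-1, 1),
                                            c( 1,-1, 1), c( 1,-1,-1))),
    list(dir = c(0,  1, 0), corners = rbind(c(-1, 1,-1), c( 1, 1,-1),
                                            c( 1, 1, 1), c(-1, 1, 1))),
    list(dir = c(0, 0, -1), corners = rbind(c(-1,-1,-1), c( 1,-1,-1),
                                            c( 1, 1,-1), c(-1, 1,-1))),
    list(dir = c(0, 0,  1), corners = rbind(c(-1,-1, 1), c(-1, 1, 1),
                                            c( 1, 1, 1), c( 1,-1, 1))))
  corner_keys <- character()
  corner_ijk <- list()
  faces <- list()
  key_env <- new.env(parent = emptyenv())
  get_vertex <- function(cijk) {
    key <- paste(cijk, collapse = "_")
    id <- key_env[[key]]
    if (is.null(id)) {
      id <- length(corner_ijk) + 1L
      corner_ijk[[id]] <<- cijk
      key_env[[key]] <- id
    }
    id
  }
  for (f in face_defs) {
    nb <- occ(idx[, 1] + f$dir[1], idx[, 2] + f$dir[2], idx[, 3] + f$dir[3])
    exposed <- which(!nb)
    for (e in exposed) {
      center2 <- 2 * (idx[e, ] - 1L)           # doubled 0-based center
      quad <- vapply(1:4, function(ci)
        get_vertex(center2 + f$corners[ci, ]), integer(1))
      faces[[length(faces) + 1L]] <- quad
    }
  }
  verts_ijk2 <- do.call(rbind, corner_ijk)
  verts <- voxel_to_world(vol, verts_ijk2 / 2)
  list(vertices = verts, faces = do.call(rbind, faces))
}

#' Write a voxel mesh as Wavefront OBJ (quads)
#' @param mesh a mesh list from [mask_to_voxel_mesh()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mesh_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(mesh$vertices))
    writeLines(sprintf("v %.6f %.6f %.6f", mesh$vertices[, 1],
                       mesh$vertices[, 2], mesh$vertices[, 3]), con)
  if (nrow(mesh$faces))
    writeLines(sprintf("f %d %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                       mesh$faces[, 3], mesh$faces[, 4]), con)
  invisible(path)
}

#' Test containment of points in a resection mask
#'
#' Each point is labeled inside/outside by looking up the voxel containing
#' it; out-of-field points are labeled outside with a warning. The summary
#' fraction (e.g. of ictal-onset contacts inside the proposal) is returned as
#' an attribute.
#'
#' @param m a `resection_mask`.
#' @param ps a `point_set` (e.g. from [contacts_as_pointset()]).
#' @return a `data.frame` `name, x, y, z, inside`; attribute
#'   `"fraction_inside"`.
#' @export
mask_contains <- function(m, ps) {
  vol <- image_volume(m$mask, m$affine, "mask")
  n <- nrow(ps)
  inside <- logical(n)
  if (n) {
    v <- round(world_to_voxel(vol, ps_coords(ps)))
    d <- dim(vol$data)
    ok <- v[, 1] >= 0 & v[, 1] <= d[1] - 1 &
          v[, 2] >= 0 & v[, 2] <= d[2] - 1 &
          v[, 3] >= 0 & v[, 3] <= d[3] - 1
    if (any(!ok))
      warning(sum(!ok), " point(s) outside the field of view, labeled ",
              "outside", call. = FALSE)
    iok <- which(ok)
    inside[iok] <- vol$data[cbind(v[iok, 1] + 1, v[iok, 2] + 1,
                                  v[iok, 3] + 1)] > 0
  }
  out <- data.frame(name = ps$name, x = ps$x, y = ps$y, z = ps$z,
                    inside = inside, stringsAsFactors = FALSE)
  attr(out, "fraction_inside") <- if (n) mean(inside) else NA_real_
  out
}

#' Burn a resection mask into the base volume
#'
#' Sets masked voxels to `marker_intensity` times the global maximum — the
#' high-intensity export handed to neuronavigation — leaving all other
#' voxels unchanged.
#'
#' @param base base `image_volume`.
#' @param m a `resection_mask` on the base grid.
#' @param s a [burn_settings()] object (only `marker_intensity` is used).
#' @return the burned `image_volume`, writable as NIfTI or DICOM via
#'   [write_volume()].
#' @export
export_burned_mask <- function(base, m, s = burn_settings()) {
  if (!identical(dim(base$data), dim(m$mask)) ||
      max(abs(base$affine - m$affine)) > 1e-6)
    stop("resection mask is not aligned with the base grid", call. = FALSE)
  out <- base
  out$data[m$mask > 0] <- s$marker_intensity * max(base$data)
  out
}
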