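#' @useDynLib mmii, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

MODALITIES <- c("t1", "t2", "flair", "pet", "spect", "ct", "cta", "map",
                "fmri", "mask", "other")

#' Create an image volume
#'
#' The universal carrier for every modality in the integration workflow: a 3D
#' scalar array together with a 4x4 affine mapping 0-based voxel indices to
#' world coordinates in RAS+ millimetres.
#'
#' @param data 3D numeric array of intensities (units depend on modality).
#' @param affine 4x4 voxel-index-to-world-mm matrix (NIfTI convention,
#'   0-based indices). Default: identity (1 mm isotropic at the origin).
#' @param modality one of `"t1"`, `"t2"`, `"flair"`, `"pet"`, `"spect"`,
#'   `"ct"`, `"cta"`, `"map"`, `"fmri"`, `"mask"`, `"other"`.
#' @param frame_id label of the coordinate frame the volume lives in
#'   (`"base"` once registered to the base T1).
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, affine = diag(4), modality = "other",
                         frame_id = "native") {
  data <- as.array(data)
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 3L)
    stop("volume data must be a 3D array", call. = FALSE)
  if (any(dim(data) < 1L))
    stop("volume dimensions must all be >= 1", call. = FALSE)
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("affine must be a 4x4 matrix", call. = FALSE)
  if (abs(det(affine)) < 1e-12)
    stop("affine must be invertible", call. = FALSE)
  sp <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(sp <= 0))
    stop("all voxel spacings must be > 0", call. = FALSE)
  modality <- match.arg(modality, MODALITIES)
  structure(list(data = data, affine = affine, modality = modality,
                 frame_id = frame_id),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  sp <- voxel_spacing(x)
  cat(sprintf("<image_volume> %s [%s], %d x %d x %d voxels, spacing %s mm\n",
              x$modality, x$frame_id, d[1], d[2], d[3],
              paste(signif(sp, 4), collapse = " x ")))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' Voxel spacing of a volume in mm
#' @param vol an `image_volume`.
#' @return numeric length-3 vector of spacings along the three voxel axes.
#' @export
voxel_spacing <- function(vol) sqrt(colSums(vol$affine[1:3, 1:3]^2))

#' Convert 0-based voxel indices to world mm
#' @param vol an `image_volume`.
#' @param ijk n x 3 matrix (or length-3 vector) of 0-based voxel indices.
#' @return n x 3 matrix of world coordinates (mm).
#' @export
voxel_to_world <- function(vol, ijk) {
  ijk <- rbind3(ijk)
  p <- vol$affine %*% rbind(t(ijk), 1)
  t(p[1:3, , drop = FALSE])
}

#' Convert world mm to (continuous, 0-based) voxel indices
#' @param vol an `image_volume`.
#' @param xyz n x 3 matrix (or length-3 vector) of world coordinates (mm).
#' @return n x 3 matrix of continuous 0-based voxel indices.
#' @export
world_to_voxel <- function(vol, xyz) {
  xyz <- rbind3(xyz)
  p <- solve(vol$affine) %*% rbind(t(xyz), 1)
  t(p[1:3, , drop = FALSE])
}

rbind3 <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3)
  as.matrix(x)
}

# world coordinates (mm) of every voxel centre, n x 3, voxel order = array order
volume_world_grid <- function(vol) {
  d <- dim(vol$data)
  ijk <- cbind(
    rep(seq_len(d[1]) - 1, times = d[2] * d[3]),
    rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3]),
    rep(seq_len(d[3]) - 1, each = d[1] * d[2]))
  voxel_to_world(vol, ijk)
}

# TRUE for world points whose nearest voxel lies inside the array
in_fov <- function(vol, xyz) {
  v <- round(world_to_voxel(vol, xyz))
  d <- dim(vol$data)
  v[, 1] >= 0 & v[, 1] <= d[1] - 1 &
  v[, 2] >= 0 & v[, 2] <= d[2] - 1 &
  v[, 3] >= 0 & v[, 3] <= d[3] - 1
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$affine - b$affine)) < tol
}

#' Create a rigid world-to-world transform
#'
#' @param matrix 4x4 homogeneous matrix mapping world mm to world mm. The 3x3
#'   rotation block must be orthonormal with determinant +1.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(matrix = diag(4)) {
  m <- as.matrix(matrix)
  if (!all(dim(m) == c(4L, 4L)))
    stop("transform must be a 4x4 matrix", call. = FALSE)
  R <- m[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > 1e-6)
    stop("rotation block is not orthonormal", call. = FALSE)
  if (abs(det(R) - 1) > 1e-6)
    stop("rotation block must have determinant +1 (no reflection)",
         call. = FALSE)
  if (any(abs(m[4, ] - c(0, 0, 0, 1)) > 1e-9))
    stop("last row of a homogeneous transform must be (0,0,0,1)",
         call. = FALSE)
  structure(list(matrix = m), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  print(round(x$matrix, 6))
  invisible(x)
}

#' Invert a rigid transform
#' @param t a `rigid_transform`.
#' @return the inverse `rigid_transform`.
#' @export
invert_transform <- function(t) rigid_transform(solve(t$matrix))

#' Compose rigid transforms
#'
#' `compose_transforms(a, b)` applies `b` first, then `a`.
#' @param a,b `rigid_transform` objects.
#' @return the composed `rigid_transform`.
#' @export
compose_transforms <- function(a, b) rigid_transform(a$matrix %*% b$matrix)

#' Apply a rigid transform to points
#' @param t a `rigid_transform`.
#' @param xyz n x 3 matrix (or length-3 vector) of world mm points.
#' @return n x 3 matrix of transformed points.
#' @export
apply_transform <- function(t, xyz) {
  xyz <- rbind3(xyz)
  p <- t$matrix %*% rbind(t(xyz), 1)
  t(p[1:3, , drop = FALSE])
}

#' Read or write a transform as plain text / JSON
#'
#' Plain text holds the 4x4 matrix one row per line; JSON holds it under
#' `"matrix"` (row-major list of rows).
#' @param path file path; `.json` selects JSON, anything else plain text.
#' @param t a `rigid_transform` (write only).
#' @return `read_transform` returns a `rigid_transform`; `write_transform`
#'   returns `path` invisibly.
#' @export
read_transform <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    m <- do.call(rbind, jsonlite::fromJSON(path, simplifyMatrix = FALSE)$matrix)
    mode(m) <- "numeric"
  } else {
    m <- as.matrix(utils::read.table(path))
    dimnames(m) <- NULL
  }
  rigid_transform(m)
}

#' @rdname read_transform
#' @export
write_transform <- function(t, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(matrix = apply(t$matrix, 1, as.list)), path,
                         auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(format(t$matrix, digits = 17), path,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
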