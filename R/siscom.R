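#' Global mean normalization of a perfusion volume
#'
#' Scales a perfusion SPECT volume so its mean within the brain mask is
#' exactly 100, removing global count differences between the ictal and
#' interictal acquisitions before subtraction.
#'
#' @param vol perfusion `image_volume`.
#' @param mask binary brain-mask `image_volume` (or logical/0-1 array) on the
#'   same grid.
#' @return the normalized `image_volume` (mask mean = 100).
#' @export
normalize_perfusion <- function(vol, mask) {
  m <- mask_array(mask, vol)
  mu <- mean(vol$data[m])
  if (!is.finite(mu) || mu <= 0)
    stop("mask mean must be > 0 for perfusion normalization", call. = FALSE)
  out <- vol
  out$data <- vol$data * (100 / mu)
  out
}

mask_array <- function(mask, reference) {
  mv <- if (inherits(mask, "image_volume")) {
    if (!same_grid(mask, reference))
      stop("mask is not on the same grid as the volume", call. = FALSE)
    mask$data
  } else mask
  if (!identical(dim(mv), dim(reference$data)))
    stop("mask dimensions do not match the volume", call. = FALSE)
  m <- mv > 0.5
  if (!any(m)) stop("mask is empty", call. = FALSE)
  m
}

#' Compute a SISCOM z-score map
#'
#' Subtraction ictal SPECT co-registered to MRI: both perfusion volumes
#' (already resampled to the base grid) are mean-100 normalized within the
#' brain mask, subtracted (ictal minus interictal), and the difference is
#' z-scored against its own mean and standard deviation within the mask.
#' Outside the mask z is 0.
#'
#' @param ictal,interictal perfusion `image_volume`s on the base grid.
#' @param mask binary brain mask (`image_volume` or array) on the same grid.
#' @param fwhm optional Gaussian pre-smoothing FWHM in mm applied to both
#'   inputs (default 0 = off).
#' @param threshold default display/cluster threshold stored with the map
#'   (z-score; 1.5 and 2 are the conventional review values).
#' @return a `zscore_map`: fields `z` (3D array), `affine`, `mask`,
#'   `threshold`.
#' @export
compute_siscom <- function(ictal, interictal, mask, fwhm = 0,
                           threshold = 1.5) {
  if (!same_grid(ictal, interictal))
    stop("ictal and interictal volumes must share the base grid",
         call. = FALSE)
  m <- mask_array(mask, ictal)
  if (fwhm > 0) {
    sig <- fwhm / (2 * sqrt(2 * log(2))) / voxel_spacing(ictal)
    ictal$data <- gaussian_smooth(ictal$data, sig)
    interictal$data <- gaussian_smooth(interictal$data, sig)
  }
  d <- normalize_perfusion(ictal, m)$data -
       normalize_perfusion(interictal, m)$data
  dv <- d[m]
  s <- stats::sd(dv)
  if (!is.finite(s) || s == 0)
    stop("degenerate input: subtraction image has zero variance in the mask",
         call. = FALSE)
  z <- array(0, dim(d))
  z[m] <- (dv - mean(dv)) / s
  structure(list(z = z, affine = ictal$affine, mask = m,
                 threshold = threshold),
            class = "zscore_map")
}

#' @export
print.zscore_map <- function(x, ...) {
  cat(sprintf("<zscore_map> %s voxels, %d in mask, z range [%.2f, %.2f]\n",
              paste(dim(x$z), collapse = " x "), sum(x$mask),
              min(x$z[x$mask]), max(x$z[x$mask])))
  invisible(x)
}

#' Threshold a z-score map into clusters
#'
#' 26-connected components of voxels with z >= `z_thresh`, discarding
#' components smaller than `min_voxels`, sorted by peak z descending.
#'
#' @param zm a `zscore_map` from [compute_siscom()].
#' @param z_thresh z threshold (> 0); 1.5 and 2 are the conventional review
#'   values.
#' @param min_voxels minimum cluster size in voxels (default 5).
#' @return a `data.frame` with one row per cluster: `rank`, `voxel_count`,
#'   `centroid_x/y/z` (world mm, unweighted voxel centroid), `peak_z`,
#'   `peak_x/y/z` (world mm location of the maximum z).
#' @export
threshold_clusters <- function(zm, z_thresh = zm$threshold, min_voxels = 5L) {
  stopifnot(inherits(zm, "zscore_map"), z_thresh > 0)
  vol <- image_volume(zm$z, zm$affine, "map")
  supra <- zm$z >= z_thresh
  empty <- data.frame(rank = integer(), voxel_count = integer(),
                      centroid_x = numeric(), centroid_y = numeric(),
                      centroid_z = numeric(), peak_z = numeric(),
                      peak_x = numeric(), peak_y = numeric(),
                      peak_z_mm = numeric())
  names(empty)[7:9] <- c("peak_x", "peak_y", "peak_z_mm")
  if (!any(supra)) return(empty)
  lab <- label_components(supra)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_voxels)
  if (!length(keep)) return(empty)
  rows <- lapply(keep, function(comp) {
    idx <- which(lab == comp)
    dd <- dim(zm$z)
    lin <- idx - 1L
    ijk <- cbind(lin %% dd[1], (lin %/% dd[1]) %% dd[2],
                 lin %/% (dd[1] * dd[2]))
    w <- voxel_to_world(vol, ijk)
    cen <- colMeans(w)
    pk <- which.max(zm$z[idx])
    data.frame(voxel_count = length(idx),
               centroid_x = cen[1], centroid_y = cen[2], centroid_z = cen[3],
               peak_z = zm$z[idx[pk]],
               peak_x = w[pk, 1], peak_y = w[pk, 2], peak_z_mm = w[pk, 3])
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$peak_z, decreasing = TRUE), , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Write a cluster table as TSV
#' @param clusters data frame from [threshold_clusters()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(clusters, path) {
  utils::write.table(clusters, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Convert a z-score map to an image volume
#' @param zm a `zscore_map`.
#' @return an `image_volume` with `modality = "map"`.
#' @export
as_volume <- function(zm) {
  stopifnot(inherits(zm, "zscore_map"))
  image_volume(zm$z, zm$affine, "map", "base")
}
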