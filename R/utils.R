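# Shared low-level helpers: components, smoothing, masks, geometry.

# integer label array of 26- (default) or 6-connected components of a mask
label_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  lab <- cpp_label_components(as.logical(mask), as.integer(d),
                              as.integer(connectivity))
  array(lab, d)
}

# offsets (m x 3 integer) of a ball structuring element, radius in voxels
ball_offsets <- function(radius_vox) {
  r <- ceiling(radius_vox)
  if (any(r < 0)) stop("radius must be >= 0")
  g <- expand.grid(i = -r[1]:r[1], j = -r[2]:r[2], k = -r[3]:r[3])
  keep <- (g$i / max(radius_vox[1], 1e-9))^2 +
          (g$j / max(radius_vox[2], 1e-9))^2 +
          (g$k / max(radius_vox[3], 1e-9))^2 <= 1 + 1e-9
  as.matrix(g[keep, , drop = FALSE])
}

morph_ball <- function(mask, radius_vox, op = c("dilate", "erode")) {
  op <- match.arg(op)
  offs <- ball_offsets(rep_len(radius_vox, 3L))
  out <- cpp_morph(as.logical(mask), as.integer(dim(mask)),
                   matrix(as.integer(offs), ncol = 3),
                   if (op == "dilate") 0L else 1L)
  array(out, dim(mask))
}

# morphological closing with a ball of `radius_mm`
close_mask <- function(mask, radius_mm, spacing) {
  rv <- radius_mm / spacing
  if (all(rv < 0.5)) return(mask)
  morph_ball(morph_ball(mask, rv, "dilate"), rv, "erode")
}

# fill interior holes: background 6-components not touching the array border
fill_holes <- function(mask) {
  bg <- label_components(!mask, connectivity = 6L)
  d <- dim(mask)
  border <- unique(c(bg[c(1, d[1]), , ], bg[, c(1, d[2]), ], bg[, , c(1, d[3])]))
  border <- border[border > 0]
  mask | (bg > 0 & !(bg %in% border))
}

# Otsu threshold of a numeric array (maximizes between-class variance)
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  h <- tabulate(pmin(nbins, 1L + floor((x - r[1]) / diff(r) * nbins)), nbins)
  p <- h / sum(h)
  mids <- r[1] + (seq_len(nbins) - 0.5) / nbins * diff(r)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

# separable Gaussian smoothing; sigma in voxels per axis (0 = skip axis)
gaussian_smooth <- function(x, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3L)
  d <- dim(x)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    kern <- exp(-((-r:r)^2) / (2 * s^2))
    kern <- kern / sum(kern)
    x <- convolve_axis(x, kern, ax)
  }
  array(x, d)
}

# 1D convolution along one axis with edge replication, via matrix products
convolve_axis <- function(x, kern, axis) {
  d <- dim(x)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  xp <- aperm(x, perm)
  dp <- dim(xp)
  m <- matrix(xp, nrow = dp[1])
  r <- (length(kern) - 1L) / 2L
  pad_top <- m[rep(1L, r), , drop = FALSE]
  pad_bot <- m[rep(nrow(m), r), , drop = FALSE]
  mp <- rbind(pad_top, m, pad_bot)
  out <- matrix(0, nrow = dp[1], ncol = ncol(m))
  for (t in seq_along(kern))
    out <- out + kern[t] * mp[t:(t + dp[1] - 1L), , drop = FALSE]
  res <- array(out, dp)
  aperm(res, order(perm))
}

#' Derive a brain mask from a base anatomical volume
#'
#' Otsu intensity threshold, then the largest 26-connected component, then
#' interior hole filling. Used as the default mask wherever one is not
#' supplied (SISCOM, registration of post-operative scans).
#'
#' @param vol an `image_volume` (typically the base T1).
#' @return an `image_volume` with `modality = "mask"` and binary data.
#' @export
brain_mask <- function(vol) {
  thr <- otsu_threshold(vol$data)
  m <- vol$data > thr
  lab <- label_components(m)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    m <- lab == which.max(sizes)
  }
  m <- fill_holes(m)
  image_volume(array(as.numeric(m), dim(m)), vol$affine,
               modality = "mask", frame_id = vol$frame_id)
}

# minimum distance from each point (n x 3) to segment [a, b]; also returns the
# parameter t in [0,1] of the closest point on the segment
point_segment_distance <- function(p, a, b) {
  p <- rbind3(p)
  u <- b - a
  len2 <- sum(u^2)
  if (len2 == 0) {
    dvec <- sweep(p, 2, a)
    return(list(dist = sqrt(rowSums(dvec^2)), t = rep(0, nrow(p))))
  }
  tt <- pmin(1, pmax(0, (sweep(p, 2, a) %*% u) / len2))
  closest <- outer(as.numeric(tt), u) + matrix(a, nrow(p), 3, byrow = TRUE)
  list(dist = sqrt(rowSums((p - closest)^2)), t = as.numeric(tt))
}

# run body with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, body) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(body)
}
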