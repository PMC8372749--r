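#' Mutual information between two volumes on a common grid
#'
#' MI = H(a) + H(b) - H(a,b) in bits, computed from a joint histogram with
#' `bins`^2 cells. Intensities are winsorized at the 0.5 / 99.5 percentiles
#' before binning for robustness against CT metal and MRI bias extremes.
#'
#' @param a,b `image_volume`s sampled on the same grid (resample first).
#' @param bins number of histogram bins per image (>= 2), default 32.
#' @param mask optional logical array / binary volume restricting the voxels
#'   entering the histogram.
#' @return mutual information in bits (>= 0 within numerical tolerance).
#' @export
mutual_information <- function(a, b, bins = 32L, mask = NULL) {
  if (bins < 2) stop("bins must be >= 2", call. = FALSE)
  av <- if (inherits(a, "image_volume")) a$data else a
  bv <- if (inherits(b, "image_volume")) b$data else b
  if (!identical(dim(av), dim(bv)))
    stop("volumes must share a grid; resample first", call. = FALSE)
  if (!is.null(mask)) {
    mv <- if (inherits(mask, "image_volume")) mask$data else mask
    keep <- as.logical(mv)
    av <- av[keep]; bv <- bv[keep]
  }
  mi_binned(bin_indices(av, bins), bin_indices(bv, bins), bins)
}

binned_entropies <- function(ai, bi, bins) {
  joint <- tabulate((ai - 1L) * bins + bi, nbins = bins * bins)
  p <- joint / sum(joint)
  pm <- matrix(p, bins, bins, byrow = TRUE)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  c(hx = ent(rowSums(pm)), hy = ent(colSums(pm)), hxy = ent(p))
}

# MI in bits from pre-binned intensity vectors
mi_binned <- function(ai, bi, bins) {
  h <- binned_entropies(ai, bi, bins)
  h[["hx"]] + h[["hy"]] - h[["hxy"]]
}

# normalized MI (Studholme): overlap-invariant, used as the internal
# registration objective so that zero padding cannot be rewarded
nmi_binned <- function(ai, bi, bins) {
  h <- binned_entropies(ai, bi, bins)
  if (h[["hxy"]] <= 0) return(1)
  (h[["hx"]] + h[["hy"]]) / h[["hxy"]]
}

bin_indices <- function(x, bins) {
  lim <- stats::quantile(x, c(0.005, 0.995), names = FALSE, type = 7)
  x <- pmin(pmax(x, lim[1]), lim[2])
  if (lim[2] <= lim[1]) return(rep(1L, length(x)))
  pmin(bins, 1L + as.integer(floor((x - lim[1]) / (lim[2] - lim[1]) * bins)))
}

# 6 rigid parameters (tx,ty,tz mm; rx,ry,rz degrees) -> world-to-world 4x4,
# rotating about `center` (world mm)
params_to_matrix <- function(p, center = c(0, 0, 0)) {
  th <- p[4:6] * pi / 180
  cx <- cos(th[1]); sx <- sin(th[1])
  cy <- cos(th[2]); sy <- sin(th[2])
  cz <- cos(th[3]); sz <- sin(th[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  R <- Rz %*% Ry %*% Rx
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- center - R %*% center + p[1:3]
  m
}

fov_center <- function(vol) {
  d <- dim(vol$data)
  voxel_to_world(vol, (d - 1) / 2)[1, ]
}

# smooth + subsample a volume by an integer factor (pyramid level)
downsample_volume <- function(vol, factor) {
  if (factor <= 1) return(vol)
  sm <- gaussian_smooth(vol$data, rep(factor / 2, 3))
  d <- dim(vol$data)
  idx <- lapply(d, function(n) seq(1L, n, by = factor))
  data <- sm[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  A <- vol$affine
  A[1:3, 1:3] <- A[1:3, 1:3] * factor
  image_volume(data, A, vol$modality, vol$frame_id)
}

#' Resample a volume through a rigid transform onto a reference grid
#'
#' For each reference voxel the moving volume is sampled at the location the
#' inverse transform maps it to. Out-of-field voxels are 0. Use nearest
#' interpolation for masks and label maps.
#'
#' @param vol moving `image_volume`.
#' @param t `rigid_transform` mapping `vol`'s world to the reference world.
#' @param reference `image_volume` defining the output grid.
#' @param interp `"linear"` (default) or `"nearest"`.
#' @return an `image_volume` on the reference grid (reference `frame_id`).
#' @export
resample <- function(vol, t = rigid_transform(), reference = vol,
                     interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  map <- solve(vol$affine) %*% solve(t$matrix) %*% reference$affine
  d_out <- dim(reference$data)
  out <- cpp_resample(as.numeric(vol$data), as.integer(dim(vol$data)),
                      as.integer(d_out), map,
                      if (interp == "nearest") 1L else 0L)
  image_volume(array(out, d_out), reference$affine, vol$modality,
               reference$frame_id)
}

#' Transfer a derived statistical map through a carrier volume's transform
#'
#' Derived maps (fMRI activation, SISCOM z-scores, morphometric z-maps) are
#' voxel-aligned with the anatomical carrier volume they were computed on.
#' After the carrier has been registered to the base volume, the very same
#' transformation matrix is applied to the maps — never re-estimated — so the
#' maps land exactly where the carrier does.
#'
#' @param carrier_transform `rigid_transform` estimated for the carrier.
#' @param derived derived-map `image_volume`, on the carrier's grid.
#' @param reference base `image_volume` defining the output grid.
#' @param carrier optional carrier `image_volume`; when supplied, the
#'   derived map's grid is checked against it.
#' @param interp interpolation, as in [resample()].
#' @return the derived map resampled onto the base grid.
#' @export
transfer_map <- function(carrier_transform, derived, reference,
                         carrier = NULL, interp = c("linear", "nearest")) {
  if (!is.null(carrier) && !same_grid(derived, carrier))
    stop("derived map is not on the carrier volume's grid", call. = FALSE)
  resample(derived, carrier_transform, reference, match.arg(interp))
}

#' Rigid registration by mutual-information maximization
#'
#' Six-parameter (3 translations + 3 rotations) registration of a moving
#' volume to a fixed volume, maximizing mutual information over a
#' multi-resolution pyramid (coarse-to-fine, Nelder-Mead at each level).
#' Optionally initialized by aligning intensity centroids. Deterministic for
#' fixed inputs and options.
#'
#' @param moving,fixed `image_volume`s with overlapping fields of view.
#' @param bins histogram bins for the MI metric.
#' @param levels integer subsampling factors, coarse to fine.
#' @param max_iter Nelder-Mead iteration budget per level.
#' @param init_com start from intensity-centroid alignment (default TRUE).
#' @param mask optional fixed-space mask (`image_volume` or logical array)
#'   restricting the metric, e.g. to exclude a resection cavity.
#' @param smooth_sigma Gaussian smoothing (voxels, at each pyramid level)
#'   applied to both images before the metric; regularizes the MI surface
#'   against acquisition noise (default 0.8).
#' @param tol relative convergence tolerance passed to the optimizer.
#' @return a `registration_result`: `transform` (moving world to fixed
#'   world), `metric_before` / `metric_after` (bits, on the finest level),
#'   `iterations`, `converged`.
#' @export
register_rigid <- function(moving, fixed, bins = 32L, levels = c(4L, 2L, 1L),
                           max_iter = 300L, init_com = TRUE, mask = NULL,
                           smooth_sigma = 0.8, tol = 1e-9) {
  center <- fov_center(fixed)
  p <- rep(0, 6)
  if (init_com) {
    com_m <- intensity_centroid(moving)
    com_f <- intensity_centroid(fixed)
    if (!all(is.finite(com_m)) || !all(is.finite(com_f)))
      stop("cannot initialize registration: no overlapping signal",
           call. = FALSE)
    p[1:3] <- com_f - com_m
  }
  iterations <- 0L
  converged <- TRUE
  for (li in seq_along(levels)) {
    lv <- levels[li]
    fx <- downsample_volume(fixed, lv)
    mv <- downsample_volume(moving, lv)
    if (smooth_sigma > 0) {
      fx$data <- gaussian_smooth(fx$data, rep(smooth_sigma, 3))
      mv$data <- gaussian_smooth(mv$data, rep(smooth_sigma, 3))
    }
    msk <- if (!is.null(mask))
      resample(as_mask_volume(mask, fixed), rigid_transform(), fx,
               "nearest")$data > 0.5
    # precompute fixed-image bins and moving winsorization limits once per
    # level; only the moving image is re-binned inside the objective
    fxv <- if (is.null(msk)) as.numeric(fx$data) else fx$data[msk]
    fb <- bin_indices(fxv, bins)
    lim_m <- stats::quantile(mv$data, c(0.005, 0.995), names = FALSE,
                             type = 7)
    objective <- function(q) {
      t <- rigid_transform(params_to_matrix(q, center))
      res <- resample(mv, t, fx)$data
      rv <- if (is.null(msk)) as.numeric(res) else res[msk]
      rv <- pmin(pmax(rv, lim_m[1]), lim_m[2])
      mb <- if (lim_m[2] > lim_m[1])
        pmin(bins, 1L + as.integer((rv - lim_m[1]) /
                                     (lim_m[2] - lim_m[1]) * bins))
      else rep(1L, length(rv))
      -nmi_binned(fb, mb, bins)
    }
    if (li == 1L) {
      # multi-start over coarse rotation seeds: MI is multimodal in the
      # rotations, and the coarsest level is cheap to probe
      starts <- list(p)
      for (ax in 4:6) for (dg in c(-8, 8)) {
        q <- p; q[ax] <- q[ax] + dg
        starts[[length(starts) + 1L]] <- q
      }
      vals <- vapply(starts, objective, numeric(1))
      iterations <- iterations + length(starts)
      p <- starts[[which.min(vals)]]
    }
    scale <- c(rep(max(voxel_spacing(fx)) / 2, 3), rep(1, 3))
    for (round in 1:2) {  # NM restart escapes collapsed simplices
      opt <- stats::optim(p, objective, method = "Nelder-Mead",
                          control = list(maxit = max_iter, reltol = tol,
                                         parscale = scale))
      p <- opt$par
      iterations <- iterations + opt$counts[1]
    }
    if (li == length(levels)) {
      # final polish with a small simplex tightens the sub-voxel residual
      opt <- stats::optim(p, objective, method = "Nelder-Mead",
                          control = list(maxit = max_iter, reltol = tol,
                                         parscale = scale / 5))
      p <- opt$par
      iterations <- iterations + opt$counts[1]
    }
    if (lv == levels[length(levels)] && opt$convergence != 0)
      converged <- FALSE
  }
  transform <- rigid_transform(params_to_matrix(p, center))
  msk_full <- if (!is.null(mask)) as_mask_volume(mask, fixed)$data > 0.5
  metric_before <- mutual_information(
    fixed, resample(moving, rigid_transform(), fixed), bins = bins,
    mask = msk_full)
  metric_after <- mutual_information(
    fixed, resample(moving, transform, fixed), bins = bins, mask = msk_full)
  if (metric_after < metric_before) {
    # optimization must never leave the alignment worse than where it started
    transform <- rigid_transform()
    metric_after <- metric_before
    converged <- FALSE
  }
  structure(list(transform = transform, metric_before = metric_before,
                 metric_after = metric_after, iterations = iterations,
                 converged = converged, parameters = p),
            class = "registration_result")
}

as_mask_volume <- function(mask, reference) {
  if (inherits(mask, "image_volume")) return(mask)
  image_volume(array(as.numeric(mask), dim(mask)), reference$affine,
               "mask", reference$frame_id)
}

intensity_centroid <- function(vol) {
  w <- volume_world_grid(vol)
  v <- pmax(as.numeric(vol$data), 0)
  colSums(w * v) / sum(v)
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf(
    "<registration_result> MI %.4f -> %.4f bits, %d evaluations%s\n",
    x$metric_before, x$metric_after, x$iterations,
    if (x$converged) "" else " (NOT converged)"))
  print(x$transform)
  invisible(x)
}
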