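# Shared helpers for the suite: error metrics for rigid transforms, brute
# force oracles, and small synthetic volumes.

# maximum point displacement (mm) between two rigid transforms over a 50 mm
# lever arm, and the rotation/translation decomposition errors
transform_error <- function(est, truth) {
  e <- est$matrix %*% solve(truth$matrix)
  R <- e[1:3, 1:3]
  ang <- acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
  pts <- rbind(c(0, 0, 0), c(50, 0, 0), c(0, 50, 0), c(0, 0, 50))
  tp <- t(R %*% t(pts)) + matrix(e[1:3, 4], 4, 3, byrow = TRUE)
  list(rotation_deg = ang,
       translation_mm = sqrt(sum(e[1:3, 4]^2)),
       max_displacement_mm = max(sqrt(rowSums((tp - pts)^2))))
}

rigid_from_params <- function(p, center = c(0, 0, 0))
  rigid_transform(mmii:::params_to_matrix(p, center = center))

# independent flood-fill connected components (26-neighbourhood), pure R
oracle_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nxt <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (lab[start] > 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      lin <- v - 1L
      i <- lin %% d[1]; j <- (lin %/% d[1]) %% d[2]; k <- lin %/% (d[1] * d[2])
      for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
        if (di == 0 && dj == 0 && dk == 0) next
        ii <- i + di; jj <- j + dj; kk <- k + dk
        if (ii < 0 || jj < 0 || kk < 0 ||
            ii >= d[1] || jj >= d[2] || kk >= d[3]) next
        w <- 1L + ii + d[1] * (jj + d[2] * kk)
        if (mask[w] && lab[w] == 0L) {
          lab[w] <- nxt
          queue <- c(queue, w)
        }
      }
    }
  }
  lab
}

# brute-force min distance from every TRUE voxel of a mask volume to a segment
oracle_min_segment_distance <- function(vol, a, b) {
  idx <- which(vol$data > 0.5)
  best <- Inf
  d <- dim(vol$data)
  u <- b - a
  len2 <- sum(u^2)
  for (v in idx) {
    lin <- v - 1L
    ijk <- c(lin %% d[1], (lin %/% d[1]) %% d[2], lin %/% (d[1] * d[2]))
    p <- as.numeric(voxel_to_world(vol, ijk))
    tt <- min(1, max(0, sum((p - a) * u) / len2))
    best <- min(best, sqrt(sum((p - (a + tt * u))^2)))
  }
  best
}

small_volume <- function(dims = c(16, 16, 16), spacing = 1, seed = 1) {
  set.seed(seed)
  image_volume(array(stats::runif(prod(dims)), dims),
               diag(c(rep(spacing, 3), 1)))
}
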