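#' Build a Talairach proportional-grid frame
#'
#' Constructs the AC-PC-based reference frame: origin at the anterior
#' commissure (AC), y-axis along PC-to-AC pointing anterior, z-axis in the
#' AC-PC-midsagittal plane pointing superior, x-axis completing a
#' right-handed triad pointing lateral-right. The VCA and VCP planes are
#' perpendicular to the AC-PC line through AC and PC. The brain bounding box
#' is given as positive distances (mm) from the frame's reference planes.
#'
#' @param ac,pc,ms world-mm points: anterior commissure, posterior
#'   commissure, and a midsagittal point superior to the AC-PC line.
#' @param bounds named numeric vector with elements `anterior` (AC to
#'   anterior bound), `posterior` (AC to posterior bound, must exceed the
#'   AC-PC distance), `superior` / `inferior` (AC-PC plane to superior /
#'   inferior bound), `left` / `right` (midsagittal plane to lateral bound),
#'   all positive mm.
#' @return a `talairach_frame`: `ac`, `pc`, `ms`, `axes` (3x3, columns x/y/z),
#'   `acpc_dist`, `bounds`.
#' @export
build_frame <- function(ac, pc, ms, bounds) {
  ac <- as.numeric(ac); pc <- as.numeric(pc); ms <- as.numeric(ms)
  stopifnot(length(ac) == 3, length(pc) == 3, length(ms) == 3)
  d <- sqrt(sum((ac - pc)^2))
  if (d <= 0) stop("AC and PC must be distinct", call. = FALSE)
  y <- (ac - pc) / d
  v <- ms - ac
  z <- v - sum(v * y) * y
  nz <- sqrt(sum(z^2))
  if (nz < 1e-9)
    stop("MS is collinear with the AC-PC line; cannot define the midsagittal ",
         "plane", call. = FALSE)
  z <- z / nz
  x <- c(y[2] * z[3] - y[3] * z[2],
         y[3] * z[1] - y[1] * z[3],
         y[1] * z[2] - y[2] * z[1])
  need <- c("anterior", "posterior", "superior", "inferior", "left", "right")
  if (!all(need %in% names(bounds)))
    stop("bounds must name: ", paste(need, collapse = ", "), call. = FALSE)
  b <- as.numeric(bounds[need])
  names(b) <- need
  if (any(!is.finite(b)) || any(b <= 0))
    stop("all bounds must be positive distances in mm", call. = FALSE)
  if (b["posterior"] <= d)
    stop("posterior bound must lie posterior to the VCP plane (> AC-PC ",
         "distance ", round(d, 2), " mm)", call. = FALSE)
  structure(list(ac = ac, pc = pc, ms = ms,
                 axes = cbind(x = x, y = y, z = z),
                 acpc_dist = d, bounds = b),
            class = "talairach_frame")
}

#' @export
print.talairach_frame <- function(x, ...) {
  cat(sprintf("<talairach_frame> AC-PC %.1f mm; bounds A%+.0f P%+.0f S%+.0f I%+.0f L%+.0f R%+.0f mm\n",
              x$acpc_dist, x$bounds["anterior"], -x$bounds["posterior"],
              x$bounds["superior"], -x$bounds["inferior"],
              -x$bounds["left"], x$bounds["right"]))
  invisible(x)
}

# local frame coordinates (lateral-right, anterior, superior) of world points
frame_coords <- function(frame, p) {
  p <- rbind3(p)
  sweep(p, 2, frame$ac) %*% frame$axes
}

SECTOR_ANTERIOR <- c("D", "C", "B", "A")   # index 1 abuts VCA
SECTOR_POSTERIOR <- c("F", "G", "H", "I")  # index 1 abuts VCP
COLUMN_LETTERS <- c("a", "b", "c", "d")    # mesial to lateral

# half-open band index: values in (0, extent] -> 1..n, inclusive at the edge
# closer to the reference plane (ceiling convention); 0 -> 0
prop_band <- function(v, extent, n) {
  idx <- as.integer(ceiling(v / (extent / n) - 1e-9))
  idx[v <= 0] <- pmax(0L, idx[v <= 0])
  idx
}

#' Assign Talairach grid cells to points
#'
#' Labels each point with its proportional-grid cell: sagittal sector
#' (A..D anterior of VCA, E between VCA and VCP, F..I posterior of VCP, with
#' A most anterior and I most posterior), level (1..8 above the AC-PC plane,
#' 1 topmost; 9..12 below), coronal column (a mesial .. d lateral within the
#' point's hemisphere), and hemisphere. Band edges are half-open, inclusive
#' at the edge nearer the AC-PC plane / VCA, so AC itself is sector E, level
#' 8, column a. Points outside the bounding box are flagged `out_of_grid`
#' with `NA` labels.
#'
#' @param p n x 3 matrix (or length-3 vector, or `point_set`) of world mm
#'   points.
#' @param frame a `talairach_frame` from [build_frame()].
#' @return a `data.frame`: `sector`, `level`, `column`, `hemisphere`,
#'   `out_of_grid` (plus `name` if `p` was a `point_set`).
#' @export
grid_cell <- function(p, frame) {
  stopifnot(inherits(frame, "talairach_frame"))
  nm <- NULL
  if (inherits(p, "point_set") || is.data.frame(p)) {
    nm <- p$name
    p <- ps_coords(p)
  }
  u <- frame_coords(frame, p)
  n <- nrow(u)
  b <- frame$bounds
  d <- frame$acpc_dist
  sector <- character(n); level <- integer(n)
  column <- character(n); hemi <- character(n)
  oog <- logical(n)
  ux <- u[, 1]; uy <- u[, 2]; uz <- u[, 3]
  oog <- uy > b["anterior"] + 1e-9 | uy < -(b["posterior"]) - 1e-9 |
         uz > b["superior"] + 1e-9 | uz < -(b["inferior"]) - 1e-9 |
         ux > b["right"] + 1e-9 | ux < -(b["left"]) - 1e-9
  # sagittal sector
  ant <- uy > 0 & !oog
  post <- uy < -d & !oog
  mid <- !ant & !post & !oog
  sector[mid] <- "E"
  sector[ant] <- SECTOR_ANTERIOR[pmin(4L, pmax(1L,
    prop_band(uy[ant], b["anterior"], 4L)))]
  sector[post] <- SECTOR_POSTERIOR[pmin(4L, pmax(1L,
    prop_band(-uy[post] - d, b["posterior"] - d, 4L)))]
  # level: 8 bands above the AC-PC plane (level 8 abuts the plane, inclusive),
  # 4 below (level 9 abuts the plane)
  up <- uz >= 0 & !oog
  lo <- uz < 0 & !oog
  level[up] <- 9L - pmin(8L, pmax(1L, prop_band(uz[up], b["superior"], 8L)))
  level[up & uz == 0] <- 8L
  level[lo] <- 8L + pmin(4L, pmax(1L, prop_band(-uz[lo], b["inferior"], 4L)))
  # hemisphere and coronal column
  hemi[!oog] <- ifelse(ux[!oog] < 0, "left", "right")
  lat_extent <- ifelse(hemi == "left", b["left"], b["right"])
  inb <- !oog
  column[inb] <- COLUMN_LETTERS[pmin(4L, pmax(1L,
    prop_band(abs(ux[inb]), lat_extent[inb], 4L)))]
  column[inb & abs(ux) < 1e-12] <- "a"
  sector[oog] <- NA_character_
  level[oog] <- NA_integer_
  column[oog] <- NA_character_
  hemi[oog] <- NA_character_
  out <- data.frame(sector = sector, level = level, column = column,
                    hemisphere = hemi, out_of_grid = oog,
                    stringsAsFactors = FALSE)
  if (!is.null(nm)) out <- cbind(name = nm, out)
  out
}

#' Dividing planes of the proportional grid
#'
#' Returns, per axis, the positions of the grid's dividing planes in frame
#' coordinates (mm from AC along the frame axes): the sagittal planes
#' (posterior bound, VCP, VCA, anterior bound, with the even subdivisions —
#' 4 anterior sectors, 4 posterior sectors), the axial level planes (8 even
#' bands above the AC-PC plane, 4 below), and the coronal column planes
#' (4 even columns per hemisphere).
#'
#' @param frame a `talairach_frame`.
#' @return a list with sorted numeric vectors `sagittal` (y), `levels` (z)
#'   and `columns` (x).
#' @export
grid_planes <- function(frame) {
  b <- frame$bounds
  d <- frame$acpc_dist
  list(
    sagittal = c(seq(-b["posterior"], -d, length.out = 5L),
                 seq(0, b["anterior"], length.out = 5L)),
    levels = sort(c(seq(-b["inferior"], 0, length.out = 5L),
                    seq(0, b["superior"], length.out = 9L)[-1])),
    columns = sort(c(seq(-b["left"], 0, length.out = 5L),
                     seq(0, b["right"], length.out = 5L)[-1])))
}

#' Serialize / read a Talairach frame as JSON
#' @param frame a `talairach_frame` (write only).
#' @param path file path.
#' @return `read_frame` returns a `talairach_frame`; `write_frame` returns
#'   `path` invisibly.
#' @export
write_frame <- function(frame, path) {
  jsonlite::write_json(list(ac = frame$ac, pc = frame$pc, ms = frame$ms,
                            bounds = as.list(frame$bounds)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_frame
#' @export
read_frame <- function(path) {
  j <- jsonlite::fromJSON(path)
  build_frame(j$ac, j$pc, j$ms, unlist(j$bounds))
}

#' Burn the grid planes into a volume as an overlay
#'
#' Marks voxels lying within half a voxel of any grid plane (within the
#' bounding box) at `marker_intensity` times the global max, so the grid can
#' be exported alongside the anatomy.
#'
#' @param vol base `image_volume`.
#' @param frame a `talairach_frame`.
#' @param s a [burn_settings()] object (only `marker_intensity` is used).
#' @return the burned `image_volume`.
#' @export
burn_grid <- function(vol, frame, s = burn_settings()) {
  planes <- grid_planes(frame)
  w <- volume_world_grid(vol)
  u <- frame_coords(frame, w)
  b <- frame$bounds
  half <- max(voxel_spacing(vol)) / 2
  inbox <- u[, 2] <= b["anterior"] & u[, 2] >= -b["posterior"] &
           u[, 3] <= b["superior"] & u[, 3] >= -b["inferior"] &
           u[, 1] <= b["right"] & u[, 1] >= -b["left"]
  near <- function(vals, planes)
    Reduce(`|`, lapply(planes, function(pp) abs(vals - pp) <= half))
  hit <- inbox & (near(u[, 2], planes$sagittal) |
                  near(u[, 3], planes$levels) |
                  near(u[, 1], planes$columns))
  out <- vol
  out$data[hit] <- s$marker_intensity * max(vol$data)
  out
}
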