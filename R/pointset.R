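#' Create a named point set
#'
#' Point sets carry every kind of "localize point" in the workflow: MEG dipole
#' locations, segmented electrode contacts, resection pass markers. Points are
#' named, live in world mm (base frame once registered), and may carry a group
#' label and a scalar value.
#'
#' @param name character vector of point names (unique within the set).
#' @param x,y,z world coordinates in mm.
#' @param group optional group label per point (e.g. dipole cluster id,
#'   pass-marker stroke id). Default `""`.
#' @param value optional scalar per point (e.g. dipole strength). Default `NA`.
#' @return A `data.frame` of class `point_set` with columns
#'   `name, x, y, z, group, value`.
#' @export
point_set <- function(name = character(), x = numeric(), y = numeric(),
                      z = numeric(), group = "", value = NA_real_) {
  n <- length(name)
  ps <- data.frame(name = as.character(name),
                   x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                   group = rep_len(as.character(group), n),
                   value = rep_len(as.numeric(value), n),
                   stringsAsFactors = FALSE)
  validate_point_set(ps)
}

validate_point_set <- function(ps) {
  dup <- unique(ps$name[duplicated(ps$name)])
  if (length(dup))
    stop("duplicate point names: ", paste(dup, collapse = ", "),
         call. = FALSE)
  if (nrow(ps) && !all(is.finite(as.matrix(ps[, c("x", "y", "z")]))))
    stop("point coordinates must be finite", call. = FALSE)
  class(ps) <- c("point_set", "data.frame")
  ps
}

ps_coords <- function(ps) as.matrix(ps[, c("x", "y", "z"), drop = FALSE])

#' Read / write point sets
#'
#' Tab-separated columns `name, x, y, z[, group, value]` (with header), or an
#' equivalent JSON array of records (`.json` extension). The unique-name
#' invariant is enforced on read.
#'
#' @param path file path.
#' @param ps a `point_set` (write only).
#' @return `read_pointset` returns a `point_set`; `write_pointset` returns
#'   `path` invisibly.
#' @export
read_pointset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
    if (length(df) == 0) df <- data.frame(name = character())
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = c(name = "character"))
  }
  if (!all(c("name", "x", "y", "z") %in% names(df)))
    stop("point-set file must have columns name, x, y, z: ", path,
         call. = FALSE)
  point_set(df$name, df$x, df$y, df$z,
            group = if (is.null(df$group)) "" else df$group,
            value = if (is.null(df$value)) NA_real_ else df$value)
}

#' @rdname read_pointset
#' @export
write_pointset <- function(ps, path) {
  ps <- validate_point_set(as.data.frame(ps))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.data.frame(ps), path, auto_unbox = TRUE,
                         digits = NA, na = "null")
  } else {
    utils::write.table(as.data.frame(ps), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
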