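# Minimal single-series DICOM I/O (Explicit VR Little Endian, monochrome,
# 16-bit). Covers what the integration workflow needs: geometry
# (ImagePositionPatient / ImageOrientationPatient / PixelSpacing), rescale,
# and pixel data — enough for lossless round trips and for handing burned
# volumes to DICOM-consuming neuronavigation systems. DICOM patient
# coordinates are LPS; volumes are converted to/from the package's RAS+ world.

DICOM_LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# process-unique series UIDs without touching the global RNG
.uid_counter <- new.env(parent = emptyenv())
next_uid_suffix <- function() {
  n <- (.uid_counter$n %||% 0L) + 1L
  .uid_counter$n <- n
  paste0(Sys.getpid(), ".", n)
}

dcm_pad <- function(s, nul = FALSE) {
  b <- charToRaw(s)
  if (length(b) %% 2 == 1) b <- c(b, if (nul) as.raw(0) else charToRaw(" "))
  b
}

dcm_elem <- function(group, elem, vr, bytes) {
  hdr <- writeBin(as.integer(c(group, elem)), raw(), size = 2,
                  endian = "little")
  if (vr %in% DICOM_LONG_VRS) {
    c(hdr, charToRaw(vr), as.raw(c(0, 0)),
      writeBin(as.integer(length(bytes)), raw(), size = 4, endian = "little"),
      bytes)
  } else {
    c(hdr, charToRaw(vr),
      writeBin(as.integer(length(bytes)), raw(), size = 2, endian = "little"),
      bytes)
  }
}

dcm_str_elem <- function(group, elem, vr, value)
  dcm_elem(group, elem, vr, dcm_pad(value, nul = vr == "UI"))

dcm_us_elem <- function(group, elem, value)
  dcm_elem(group, elem, "US", writeBin(as.integer(value), raw(), size = 2,
                                       endian = "little"))

dcm_ds <- function(x) paste(sprintf("%.10g", x), collapse = "\\")

modality_to_dicom <- function(m)
  switch(m, ct = "CT", cta = "CT", pet = "PT", spect = "NM", mask = "OT",
         t1 = , t2 = , flair = , fmri = , map = "MR", "OT")

dicom_to_modality <- function(m)
  switch(m, CT = "ct", PT = "pet", NM = "spect", "other")

write_dicom_series <- function(vol, path) {
  d <- dim(vol$data)
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE))
    stop("cannot create directory: ", path, call. = FALSE)
  A <- vol$affine
  lps <- diag(c(-1, -1, 1))
  col_dir <- A[1:3, 1] / sqrt(sum(A[1:3, 1]^2))   # along increasing column idx
  row_dir <- A[1:3, 2] / sqrt(sum(A[1:3, 2]^2))   # along increasing row idx
  iop <- c(lps %*% col_dir, lps %*% row_dir)
  pix_spacing <- c(sqrt(sum(A[1:3, 2]^2)), sqrt(sum(A[1:3, 1]^2)))
  smin <- min(vol$data); smax <- max(vol$data)
  slope <- if (smax > smin) (smax - smin) / 65535 else 1
  intercept <- smin
  stored <- array(as.integer(round((vol$data - intercept) / slope)), d)
  series_uid <- paste0("1.2.826.0.1.3680043.9.7435.", next_uid_suffix())
  study_uid <- paste0(series_uid, ".0")
  for (k in seq_len(d[3])) {
    ipp <- lps %*% voxel_to_world(vol, c(0, 0, k - 1))[1, ]
    body <- c(
      dcm_str_elem(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.7"),
      dcm_str_elem(0x0008, 0x0018, "UI", paste0(series_uid, ".", k)),
      dcm_str_elem(0x0008, 0x0060, "CS", modality_to_dicom(vol$modality)),
      dcm_str_elem(0x0020, 0x000D, "UI", study_uid),
      dcm_str_elem(0x0020, 0x000E, "UI", series_uid),
      dcm_str_elem(0x0020, 0x0013, "IS", as.character(k)),
      dcm_str_elem(0x0020, 0x0032, "DS", dcm_ds(ipp)),
      dcm_str_elem(0x0020, 0x0037, "DS", dcm_ds(iop)),
      dcm_us_elem(0x0028, 0x0002, 1L),
      dcm_str_elem(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dcm_us_elem(0x0028, 0x0010, d[2]),   # Rows
      dcm_us_elem(0x0028, 0x0011, d[1]),   # Columns
      dcm_str_elem(0x0028, 0x0030, "DS", dcm_ds(pix_spacing)),
      dcm_us_elem(0x0028, 0x0100, 16L),
      dcm_us_elem(0x0028, 0x0101, 16L),
      dcm_us_elem(0x0028, 0x0102, 15L),
      dcm_us_elem(0x0028, 0x0103, 0L),
      dcm_str_elem(0x0028, 0x1052, "DS", dcm_ds(intercept)),
      dcm_str_elem(0x0028, 0x1053, "DS", dcm_ds(slope)),
      dcm_elem(0x7FE0, 0x0010, "OW",
               writeBin(as.vector(stored[, , k]), raw(), size = 2,
                        endian = "little")))
    meta <- c(
      dcm_str_elem(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"))
    meta <- c(dcm_elem(0x0002, 0x0000, "UL",
                       writeBin(as.integer(length(meta)), raw(), size = 4,
                                endian = "little")),
              meta)
    con <- file(file.path(path, sprintf("slice_%04d.dcm", k)), "wb")
    writeBin(raw(128), con)
    writeBin(charToRaw("DICM"), con)
    writeBin(c(meta, body), con)
    close(con)
  }
  invisible(path)
}

# parse one DICOM file into a named list of raw element values
parse_dicom_file <- function(file) {
  raw <- readBin(file, raw(), n = file.size(file))
  if (length(raw) < 132 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM file: ", file, call. = FALSE)
  pos <- 133L
  out <- list()
  n <- length(raw)
  while (pos + 7L <= n) {
    group <- readBin(raw[pos:(pos + 1)], integer(), size = 2, signed = FALSE,
                     endian = "little")
    elem <- readBin(raw[(pos + 2):(pos + 3)], integer(), size = 2,
                    signed = FALSE, endian = "little")
    vr <- rawToChar(raw[(pos + 4):(pos + 5)])
    if (vr %in% DICOM_LONG_VRS) {
      len <- readBin(raw[(pos + 8):(pos + 11)], integer(), size = 4,
                     endian = "little")
      pos <- pos + 12L
    } else {
      len <- readBin(raw[(pos + 6):(pos + 7)], integer(), size = 2,
                     signed = FALSE, endian = "little")
      pos <- pos + 8L
    }
    if (len < 0 || pos + len - 1L > n)
      stop("malformed DICOM element in ", file, call. = FALSE)
    key <- sprintf("%04X%04X", group, elem)
    out[[key]] <- list(vr = vr,
                       value = if (len > 0) raw[pos:(pos + len - 1L)] else raw(0))
    pos <- pos + len
  }
  out
}

dcm_string <- function(el) {
  if (is.null(el)) return(NULL)
  v <- el$value
  while (length(v) && (v[length(v)] == as.raw(0) || v[length(v)] == as.raw(32)))
    v <- v[-length(v)]
  rawToChar(v)
}

dcm_numbers <- function(el)
  as.numeric(strsplit(dcm_string(el), "\\", fixed = TRUE)[[1]])

dcm_uint16 <- function(el)
  readBin(el$value, integer(), n = length(el$value) %/% 2L, size = 2,
          signed = FALSE, endian = "little")

read_dicom_series <- function(path, modality = NULL) {
  files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (!length(files))
    stop("no files in DICOM directory: ", path, call. = FALSE)
  slices <- lapply(files, function(f) {
    el <- parse_dicom_file(f)
    for (tag in c("00200032", "00200037", "00280010", "00280011",
                  "00280030", "7FE00010"))
      if (is.null(el[[tag]]))
        stop("missing required DICOM tag (", tag, ") in ", f, call. = FALSE)
    el
  })
  series_uids <- vapply(slices, function(el) dcm_string(el[["0020000E"]]) %||% "",
                        "")
  if (length(unique(series_uids)) > 1)
    stop("mixed DICOM series in ", path, ": first offending file ",
         files[which(series_uids != series_uids[1])[1]], call. = FALSE)
  rows <- dcm_uint16(slices[[1]][["00280010"]])
  cols <- dcm_uint16(slices[[1]][["00280011"]])
  for (i in seq_along(slices))
    if (dcm_uint16(slices[[i]][["00280010"]]) != rows ||
        dcm_uint16(slices[[i]][["00280011"]]) != cols)
      stop("inconsistent slice dimensions in ", files[i], call. = FALSE)
  iop <- dcm_numbers(slices[[1]][["00200037"]])
  normal <- c(iop[2] * iop[6] - iop[3] * iop[5],
              iop[3] * iop[4] - iop[1] * iop[6],
              iop[1] * iop[5] - iop[2] * iop[4])
  ipps <- t(vapply(slices, function(el) dcm_numbers(el[["00200032"]]),
                   numeric(3)))
  proj <- as.numeric(ipps %*% normal)
  if (length(proj) > 1 && min(diff(sort(proj))) < 1e-6)
    stop("duplicate slice positions in DICOM series ", path, call. = FALSE)
  ord <- order(proj)
  slices <- slices[ord]
  ipps <- ipps[ord, , drop = FALSE]
  pix_spacing <- dcm_numbers(slices[[1]][["00280030"]])
  n_slices <- length(slices)
  lps <- diag(c(-1, -1, 1))
  col_dir_ras <- as.numeric(lps %*% iop[1:3])
  row_dir_ras <- as.numeric(lps %*% iop[4:6])
  origin_ras <- as.numeric(lps %*% ipps[1, ])
  slice_step <- if (n_slices > 1) {
    as.numeric(lps %*% (ipps[n_slices, ] - ipps[1, ])) / (n_slices - 1)
  } else {
    thick <- if (!is.null(slices[[1]][["00180050"]]))
      dcm_numbers(slices[[1]][["00180050"]]) else 1
    as.numeric(lps %*% normal) * thick
  }
  A <- diag(4)
  A[1:3, 1] <- col_dir_ras * pix_spacing[2]
  A[1:3, 2] <- row_dir_ras * pix_spacing[1]
  A[1:3, 3] <- slice_step
  A[1:3, 4] <- origin_ras
  data <- array(0, c(cols, rows, n_slices))
  for (k in seq_len(n_slices)) {
    el <- slices[[k]]
    pix <- dcm_uint16(el[["7FE00010"]])
    if (length(pix) != cols * rows)
      stop("pixel data size mismatch in DICOM series ", path, call. = FALSE)
    slope <- if (!is.null(el[["00281053"]])) dcm_numbers(el[["00281053"]]) else 1
    inter <- if (!is.null(el[["00281052"]])) dcm_numbers(el[["00281052"]]) else 0
    data[, , k] <- pix * slope + inter
  }
  dcm_mod <- dcm_string(slices[[1]][["00080060"]])
  image_volume(data, A,
               modality = modality %||%
                 (if (is.null(dcm_mod)) "other" else dicom_to_modality(dcm_mod)))
}
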