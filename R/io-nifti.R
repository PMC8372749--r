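#' Read a volume from NIfTI-1 or a DICOM series directory
#'
#' A path ending in `.nii`/`.nii.gz` is read as NIfTI-1; a directory is read
#' as a single-series DICOM stack (slices assembled in spatial order along the
#' slice normal). The voxel-to-world affine follows the NIfTI convention:
#' 0-based voxel indices to RAS+ millimetres.
#'
#' @param path NIfTI file or DICOM series directory.
#' @param modality modality tag override; if `NULL`, inferred from DICOM
#'   metadata where possible, else `"other"`.
#' @return an `image_volume`.
#' @export
read_volume <- function(path, modality = NULL) {
  if (dir.exists(path)) return(read_dicom_series(path, modality = modality))
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (!grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE))
    stop("not a recognised volume format (expected .nii/.nii.gz or a DICOM ",
         "directory): ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop("failed to read NIfTI file ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  data <- array(as.numeric(img), dim(img)[1:3])
  image_volume(data, aff, modality = modality %||% "other")
}

#' Write a volume as NIfTI-1 or a DICOM series
#'
#' @param vol an `image_volume`.
#' @param path output file (`nifti`) or directory (`dicom_series`).
#' @param format `"nifti"` or `"dicom_series"`; default inferred from `path`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = NULL) {
  stopifnot(inherits(vol, "image_volume"))
  if (is.null(format))
    format <- if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE))
      "nifti" else "dicom_series"
  format <- match.arg(format, c("nifti", "dicom_series"))
  if (format == "dicom_series") return(write_dicom_series(vol, path))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- voxel_spacing(vol)
  RNifti::`sform<-`(img, structure(vol$affine, code = 2L)) -> img
  RNifti::`qform<-`(img, structure(vol$affine, code = 2L)) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
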