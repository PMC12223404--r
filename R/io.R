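#' Read and write image volumes as NIfTI-1
#'
#' Thin wrappers around RNifti preserving voxel spacing via the NIfTI
#' pixdim. Label maps are stored as two integer NIfTI files (tissue and
#' sector); dynamic series as one 4D NIfTI plus a JSON sidecar carrying
#' timestamps (minutes) and window tags.
#'
#' @param volume An [image_volume()].
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `read_image_volume` returns an [image_volume()];
#'   writers return their path invisibly.
#' @name nifti-io
NULL

#' @rdname nifti-io
#' @export
write_image_volume <- function(volume, path) {
  stopifnot(inherits(volume, "image_volume"))
  im <- RNifti::asNifti(volume$data)
  RNifti::pixdim(im) <- volume$voxel_mm
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' @rdname nifti-io
#' @export
read_image_volume <- function(path) {
  im <- RNifti::readNifti(path)
  image_volume(array(as.numeric(im), dim(im)), RNifti::pixdim(im)[1:3])
}

#' @rdname nifti-io
#' @param labels A [label_map()].
#' @param prefix Path prefix; writes `<prefix>_tissue.nii.gz` and
#'   `<prefix>_sector.nii.gz`.
#' @export
write_label_map <- function(labels, prefix) {
  stopifnot(inherits(labels, "label_map"))
  for (part in c("tissue", "sector")) {
    im <- RNifti::asNifti(labels[[part]])
    RNifti::pixdim(im) <- labels$voxel_mm
    RNifti::writeNifti(im, paste0(prefix, "_", part, ".nii.gz"),
                       datatype = "int16")
  }
  invisible(prefix)
}

#' @rdname nifti-io
#' @export
read_label_map <- function(prefix) {
  rd <- function(part) {
    im <- RNifti::readNifti(paste0(prefix, "_", part, ".nii.gz"))
    list(data = array(as.integer(im), dim(im)),
         voxel = RNifti::pixdim(im)[1:3])
  }
  tis <- rd("tissue"); sec <- rd("sector")
  label_map(tis$data, sec$data, tis$voxel)
}

#' @rdname nifti-io
#' @param series A [dynamic_series()].
#' @export
write_dynamic_series <- function(series, path) {
  stopifnot(inherits(series, "dynamic_series"))
  im <- RNifti::asNifti(series$data)
  RNifti::pixdim(im) <- c(series$voxel_mm, 1)
  RNifti::writeNifti(im, path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(t_min = series$t_min, window = series$window),
                       sidecar, digits = NA)
  invisible(path)
}

#' @rdname nifti-io
#' @export
read_dynamic_series <- function(path) {
  im <- RNifti::readNifti(path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  dynamic_series(array(as.numeric(im), dim(im)), meta$t_min, meta$window,
                 RNifti::pixdim(im)[1:3])
}
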