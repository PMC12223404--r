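#' LV cavity volume from a label map
#'
#' Slice-summation (Simpson) volume: cavity voxel count times voxel
#' volume, in microlitres.
#'
#' @param labels A [label_map()].
#' @return Volume in microlitres, with attribute `empty = TRUE` (and a
#'   warning) when no cavity voxels are present.
#' @export
cavity_volume <- function(labels) {
  stopifnot(inherits(labels, "label_map"))
  n <- sum(labels$tissue == tissue_codes[["cavity"]])
  if (n == 0) {
    warning("label map contains no cavity voxels")
    return(structure(0, empty = TRUE))
  }
  n * voxel_volume_ul(labels$voxel_mm)
}

#' Ejection fraction from per-frame cavity volumes
#'
#' End-diastole is the frame of maximal cavity volume, end-systole the
#' minimal (ties broken by the earliest frame);
#' `EF = 100 * (EDV - ESV) / EDV`.
#'
#' @param volumes_ul Numeric vector of per-frame cavity volumes, uL
#'   (>= 2 frames).
#' @return An object of class `volumetrics_result`: `edv_ul`, `esv_ul`,
#'   `ef_pct` (`NA` and flagged `degenerate` when EDV = 0), `frame_ed`,
#'   `frame_es`.
#' @export
ejection_fraction <- function(volumes_ul) {
  stopifnot(length(volumes_ul) >= 2, all(volumes_ul >= 0))
  frame_ed <- which.max(volumes_ul)
  frame_es <- which.min(volumes_ul)
  edv <- volumes_ul[frame_ed]; esv <- volumes_ul[frame_es]
  ef <- if (edv > 0) 100 * (edv - esv) / edv else NA_real_
  structure(list(edv_ul = edv, esv_ul = esv, ef_pct = ef,
                 frame_ed = frame_ed, frame_es = frame_es,
                 degenerate = edv == 0),
            class = "volumetrics_result")
}

#' @export
print.volumetrics_result <- function(x, ...) {
  cat(sprintf(
    "<volumetrics> EDV %.1f uL (frame %d), ESV %.1f uL (frame %d), EF %.2f%%\n",
    x$edv_ul, x$frame_ed, x$esv_ul, x$frame_es, x$ef_pct))
  invisible(x)
}

#' Segmental wall thickness on a short-axis slice
#'
#' Casts `n_segments * rays_per_segment` radial rays from the cavity
#' centroid and measures, per ray, the distance between the endocardial
#' (first myocardial) and epicardial (last myocardial) boundary crossing.
#' Segment thickness is the mean over its rays. Segments are numbered
#' counterclockwise from the anterior-septal junction (135 degrees); with
#' the default 4 segments they are septal, inferior, lateral, anterior in
#' order. Rays that meet no myocardium are excluded; more than 25%
#' excluded rays aborts with an error (open annulus).
#'
#' @param labels A [label_map()].
#' @param slice_index Slice to analyse (typically mid-ventricular).
#' @param n_segments Number of angular segments (4 or 6).
#' @param rays_per_segment Rays per segment (default 16).
#' @return Data frame with columns `segment_id`, `segment_name`
#'   (4-segment case only), `wt_mm`, `n_rays`.
#' @export
wall_thickness <- function(labels, slice_index, n_segments = 4L,
                           rays_per_segment = 16L) {
  stopifnot(inherits(labels, "label_map"),
            slice_index >= 1, slice_index <= dim(labels$tissue)[3],
            n_segments >= 1, rays_per_segment >= 1)
  tissue <- labels$tissue[, , slice_index]
  vx <- labels$voxel_mm
  cav <- tissue == tissue_codes[["cavity"]]
  if (!any(cav))
    stop("no endocardial boundary: slice ", slice_index, " has no cavity")
  idx <- which(cav, arr.ind = TRUE)
  cx <- mean((idx[, 1] - 0.5) * vx[1])
  cy <- mean((idx[, 2] - 0.5) * vx[2])
  dims <- dim(tissue)
  nray <- n_segments * rays_per_segment
  ## rays offset half a step so none sits exactly on a segment boundary
  theta <- (135 + (seq_len(nray) - 0.5) * 360 / nray) %% 360
  dr <- min(vx[1:2]) / 5
  rmax <- sqrt(max(cx, dims[1] * vx[1] - cx)^2 +
               max(cy, dims[2] * vx[2] - cy)^2)
  r <- seq(dr / 2, rmax, by = dr)
  thick <- rep(NA_real_, nray)
  for (j in seq_len(nray)) {
    px <- cx + r * cos(theta[j] * pi / 180)
    py <- cy + r * sin(theta[j] * pi / 180)
    i1 <- floor(px / vx[1]) + 1L
    i2 <- floor(py / vx[2]) + 1L
    ok <- i1 >= 1 & i1 <= dims[1] & i2 >= 1 & i2 <= dims[2]
    tv <- rep(tissue_codes[["background"]], length(r))
    tv[ok] <- tissue[cbind(i1[ok], i2[ok])]
    hit <- which(tv == tissue_codes[["myocardium"]])
    if (length(hit) == 0) next
    thick[j] <- r[max(hit)] - r[min(hit)] + dr
  }
  excluded <- sum(is.na(thick))
  if (excluded > 0.25 * nray)
    stop("open annulus: ", excluded, " of ", nray,
         " rays found no myocardium")
  seg <- rep(seq_len(n_segments), each = rays_per_segment)
  wt <- vapply(seq_len(n_segments),
               function(s) mean(thick[seg == s], na.rm = TRUE), numeric(1))
  nr <- vapply(seq_len(n_segments),
               function(s) sum(!is.na(thick[seg == s])), integer(1))
  out <- data.frame(segment_id = seq_len(n_segments), wt_mm = wt,
                    n_rays = nr)
  if (n_segments == 4L)
    out$segment_name <- c("septal", "inferior", "lateral", "anterior")
  out
}

#' Segmental fractional wall thickening
#'
#' `fWT = 100 * (WT_ES - WT_ED) / WT_ED` per segment, from matched ED and
#' ES thickness profiles (same segmentation).
#'
#' @param wt_ed,wt_es Data frames from [wall_thickness()] at end-diastole
#'   and end-systole.
#' @return `wt_ed` augmented with columns `wt_ed_mm`, `wt_es_mm` and
#'   `fwt_pct` (`NA` and flagged where `wt_ed = 0`).
#' @export
fractional_wall_thickening <- function(wt_ed, wt_es) {
  if (nrow(wt_ed) != nrow(wt_es) ||
      !all(wt_ed$segment_id == wt_es$segment_id))
    stop("ED and ES profiles must share the same segments")
  out <- wt_ed[setdiff(names(wt_ed), c("wt_mm", "n_rays"))]
  out$wt_ed_mm <- wt_ed$wt_mm
  out$wt_es_mm <- wt_es$wt_mm
  out$fwt_pct <- ifelse(wt_ed$wt_mm > 0,
                        100 * (wt_es$wt_mm - wt_ed$wt_mm) / wt_ed$wt_mm,
                        NA_real_)
  out
}
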