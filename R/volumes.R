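#' @importFrom stats coef confint cor lm lm.fit median pt rnorm runif sd
#'   t.test var
#' @importFrom utils head tail
NULL

#' Tissue and sector label codes
#'
#' Integer codes used throughout: tissue volumes code background = 0,
#' LV cavity = 1, myocardium = 2. Sector volumes code the four 90-degree
#' angular quadrants of the myocardium, with the lateral wall centred on
#' 0 degrees (the LAD territory in the short-axis phantom) and the septum
#' on 180 degrees.
#'
#' @format Named integer vectors.
#' @name label-codes
#' @export
tissue_codes <- c(background = 0L, cavity = 1L, myocardium = 2L)

#' @rdname label-codes
#' @export
sector_codes <- c(septal = 1L, anterior = 2L, lateral = 3L, inferior = 4L)

## angular centres (degrees) of the four sectors, lateral on +x
sector_centers <- c(septal = 180, anterior = 90, lateral = 0, inferior = 270)

#' Image volume container
#'
#' A 3D scalar intensity grid with in-plane voxel spacing and slice
#' thickness in mm. Volumes are stored as plain numeric arrays; 1 mm^3
#' equals 1 microlitre, so voxel counts convert directly to volumes.
#'
#' @param data Numeric 3D array (nx, ny, nz).
#' @param voxel_mm Numeric length-3: in-plane spacings and slice thickness.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, voxel_mm) {
  data <- as.array(data)
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
  stopifnot(length(dim(data)) == 3L, length(voxel_mm) == 3L, all(voxel_mm > 0))
  structure(list(data = data, voxel_mm = as.numeric(voxel_mm)),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %d x %d x %d, voxel %.4g x %.4g x %.4g mm\n",
              d[1], d[2], d[3], x$voxel_mm[1], x$voxel_mm[2], x$voxel_mm[3]))
  invisible(x)
}

#' Label map container
#'
#' Integer tissue labels (background/cavity/myocardium, see
#' [tissue_codes]) plus an auxiliary sector volume assigning each
#' myocardial voxel to one of the four angular quadrants
#' (see [sector_codes]; 0 outside the myocardium).
#'
#' @param tissue Integer 3D array of tissue codes.
#' @param sector Integer 3D array of sector codes (0 outside myocardium).
#' @param voxel_mm Numeric length-3 voxel spacing, mm.
#' @return An object of class `label_map`.
#' @export
label_map <- function(tissue, sector, voxel_mm) {
  tissue <- as.array(tissue); sector <- as.array(sector)
  stopifnot(identical(dim(tissue), dim(sector)),
            length(dim(tissue)) == 3L, length(voxel_mm) == 3L)
  myo <- tissue == tissue_codes[["myocardium"]]
  if (any(myo & sector == 0L))
    stop("every myocardial voxel must carry a sector code")
  if (any(!myo & sector != 0L))
    stop("sector codes are defined on myocardium only")
  structure(list(tissue = tissue, sector = sector,
                 voxel_mm = as.numeric(voxel_mm)),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  d <- dim(x$tissue)
  cat(sprintf("<label_map> %d x %d x %d: %d cavity, %d myocardium voxels\n",
              d[1], d[2], d[3],
              sum(x$tissue == 1L), sum(x$tissue == 2L)))
  invisible(x)
}

#' Dynamic image series container
#'
#' An ordered stack of image volumes on a shared grid, each frame carrying
#' an acquisition timestamp (minutes) and a window tag (`"ischemia"` for
#' frames at or before the occlusion release, `"reperfusion"` after).
#'
#' @param data Numeric 4D array (nx, ny, nz, n_frames).
#' @param t_min Numeric vector of frame timestamps, minutes, strictly
#'   increasing.
#' @param window Character vector of per-frame tags
#'   (`"ischemia"`/`"reperfusion"`).
#' @param voxel_mm Numeric length-3 voxel spacing, mm.
#' @return An object of class `dynamic_series`.
#' @export
dynamic_series <- function(data, t_min, window, voxel_mm) {
  data <- as.array(data)
  stopifnot(length(dim(data)) == 4L,
            dim(data)[4] == length(t_min),
            length(window) == length(t_min),
            all(diff(t_min) > 0),
            all(window %in% c("ischemia", "reperfusion")))
  structure(list(data = data, t_min = as.numeric(t_min),
                 window = as.character(window),
                 voxel_mm = as.numeric(voxel_mm)),
            class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<dynamic_series> %d frames (%s), %.1f-%.1f min, grid %d x %d x %d\n",
    d[4], paste(table(x$window)[unique(x$window)], unique(x$window),
                collapse = " + "),
    min(x$t_min), max(x$t_min), d[1], d[2], d[3]))
  invisible(x)
}

n_frames <- function(series) dim(series$data)[4]

## voxel volume in microlitres (1 mm^3 = 1 uL)
voxel_volume_ul <- function(voxel_mm) prod(voxel_mm)

## In-plane voxel-centre coordinates relative to `center` (mm).
## Voxel i covers [(i-1)*dx, i*dx); its centre sits at (i-0.5)*dx
## (half-voxel centre convention). Returns matrices over one slice.
plane_coords <- function(dims, voxel_mm, center = NULL) {
  x <- (seq_len(dims[1]) - 0.5) * voxel_mm[1]
  y <- (seq_len(dims[2]) - 0.5) * voxel_mm[2]
  if (is.null(center))
    center <- c(dims[1] * voxel_mm[1], dims[2] * voxel_mm[2]) / 2
  xm <- matrix(x - center[1], dims[1], dims[2])
  ym <- matrix(y - center[2], dims[1], dims[2], byrow = TRUE)
  list(x = xm, y = ym,
       rho = sqrt(xm^2 + ym^2),
       theta = (atan2(ym, xm) * 180 / pi) %% 360,
       center = center)
}

## TRUE where angle theta (deg) lies in the half-open interval
## [lo, hi) walked counterclockwise; interval may wrap through 360.
angle_in_interval <- function(theta_deg, interval) {
  width <- (interval[2] - interval[1]) %% 360
  if (width == 0) return(rep(FALSE, length(theta_deg)))
  ((theta_deg - interval[1]) %% 360) < width
}

## quadrant sector code for an angle in degrees
sector_of_angle <- function(theta_deg) {
  th <- theta_deg %% 360
  out <- integer(length(th))
  out[th >= 315 | th < 45] <- sector_codes[["lateral"]]
  out[th >= 45 & th < 135] <- sector_codes[["anterior"]]
  out[th >= 135 & th < 225] <- sector_codes[["septal"]]
  out[th >= 225 & th < 315] <- sector_codes[["inferior"]]
  out
}

## resolve a sector/tissue name or code to a logical mask
resolve_roi_mask <- function(labels, roi_code) {
  if (is.character(roi_code)) {
    if (roi_code %in% names(sector_codes))
      return(labels$sector == sector_codes[[roi_code]])
    if (roi_code %in% names(tissue_codes))
      return(labels$tissue == tissue_codes[[roi_code]])
    stop("unknown ROI code: ", roi_code)
  }
  labels$sector == as.integer(roi_code)
}
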