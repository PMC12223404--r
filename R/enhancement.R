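#' Septal reference statistics
#'
#' Sample mean and SD (n - 1 denominator) of signal intensity over the
#' septal myocardium, the remote reference territory for enhancement
#' thresholding.
#'
#' @param volume An [image_volume()] (or bare 3D array).
#' @param labels A [label_map()] on the same grid.
#' @return List of class `reference_stats`: `mean`, `sd`, `n`,
#'   `roi_code = "septal"`.
#' @export
septal_reference <- function(volume, labels) {
  data <- if (inherits(volume, "image_volume")) volume$data else as.array(volume)
  stopifnot(inherits(labels, "label_map"),
            identical(dim(data), dim(labels$tissue)))
  m <- labels$sector == sector_codes[["septal"]]
  n <- sum(m)
  if (n < 2) stop("septal reference ROI needs >= 2 voxels (have ", n, ")")
  structure(list(mean = mean(data[m]), sd = sd(data[m]), n = n,
                 roi_code = "septal"),
            class = "reference_stats")
}

#' @export
print.reference_stats <- function(x, ...) {
  cat(sprintf("<reference_stats> %s ROI: mean %.2f, sd %.2f (n = %d)\n",
              x$roi_code, x$mean, x$sd, x$n))
  invisible(x)
}

#' Threshold-based enhancement fraction
#'
#' Fraction of LV myocardium beyond a reference-derived intensity
#' threshold. Polarity `"above"` (the LGE area-at-risk convention) counts
#' voxels strictly greater than `mean + k * sd`; polarity `"below"` (the
#' MEMRI hypo-enhancement convention at the end of occlusion) counts
#' voxels strictly less than `mean - k * sd`. Ties at the threshold are
#' excluded, making the count deterministic and measure-zero under noise.
#'
#' @param volume An [image_volume()] or bare 3D array.
#' @param labels A [label_map()] on the same grid.
#' @param ref A [septal_reference()] result (or any list with `mean`, `sd`).
#' @param k Threshold multiplier (>= 0); 2 is the conventional choice.
#' @param polarity `"above"` or `"below"`.
#' @return An object of class `enhancement_result`: `fraction_pct_lv`,
#'   `threshold_value`, `polarity`, `n_voxels`, `n_lv_voxels`.
#' @export
threshold_fraction <- function(volume, labels, ref, k = 2,
                               polarity = c("above", "below")) {
  polarity <- match.arg(polarity)
  if (k < 0) stop("k must be >= 0")
  data <- if (inherits(volume, "image_volume")) volume$data else as.array(volume)
  stopifnot(inherits(labels, "label_map"),
            identical(dim(data), dim(labels$tissue)))
  myo <- labels$tissue == tissue_codes[["myocardium"]]
  if (!any(myo)) stop("label map contains no myocardium")
  vals <- data[myo]
  thr <- if (polarity == "above") ref$mean + k * ref$sd else ref$mean - k * ref$sd
  n_hit <- if (polarity == "above") sum(vals > thr) else sum(vals < thr)
  structure(list(fraction_pct_lv = 100 * n_hit / length(vals),
                 threshold_value = thr, polarity = polarity,
                 k = k, n_voxels = n_hit, n_lv_voxels = length(vals)),
            class = "enhancement_result")
}

#' @export
print.enhancement_result <- function(x, ...) {
  cat(sprintf(
    "<enhancement_result> %.2f %%LV %s threshold %.2f (k = %g)\n",
    x$fraction_pct_lv, x$polarity, x$threshold_value, x$k))
  invisible(x)
}
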