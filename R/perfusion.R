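#' Split a dynamic series at the occlusion release
#'
#' Frames acquired at or before `t_occlusion` form the ischemia window,
#' later frames the reperfusion window. Splitting (rather than motion
#' correction) isolates the small rigid repositioning that can occur when
#' the occlusion is released.
#'
#' @param series A [dynamic_series()].
#' @param t_occlusion Occlusion release time, minutes; must fall strictly
#'   inside the acquisition span so both windows are non-empty.
#' @return List with elements `ischemia` and `reperfusion`, each a
#'   [dynamic_series()].
#' @export
split_windows <- function(series, t_occlusion = 30) {
  stopifnot(inherits(series, "dynamic_series"))
  isch <- series$t_min <= t_occlusion
  if (!any(isch) || all(isch))
    stop("t_occlusion = ", t_occlusion,
         " min leaves an empty window (acquisition spans ",
         min(series$t_min), "-", max(series$t_min), " min)")
  take <- function(keep, tag)
    dynamic_series(series$data[, , , keep, drop = FALSE],
                   series$t_min[keep], rep(tag, sum(keep)),
                   series$voxel_mm)
  list(ischemia = take(isch, "ischemia"),
       reperfusion = take(!isch, "reperfusion"))
}

#' Region-of-interest signal time-course
#'
#' Mean signal intensity over an ROI at each frame of a dynamic series.
#'
#' @param series A [dynamic_series()].
#' @param labels A [label_map()] on the same grid.
#' @param roi_code Sector name (`"septal"`, `"lateral"`, `"anterior"`,
#'   `"inferior"`), tissue name (`"myocardium"`, `"cavity"`), or an
#'   integer sector code.
#' @return A data frame of class `roi_timecourse` with columns `t_min`,
#'   `si`, `window`, and attributes `roi_code`, `n_voxels`.
#' @export
extract_roi_timecourse <- function(series, labels, roi_code) {
  stopifnot(inherits(series, "dynamic_series"), inherits(labels, "label_map"))
  mask <- resolve_roi_mask(labels, roi_code)
  if (!any(mask)) stop("ROI '", roi_code, "' is empty on this label map")
  idx <- which(mask)
  nf <- n_frames(series)
  si <- vapply(seq_len(nf),
               function(f) mean(series$data[, , , f][idx]), numeric(1))
  out <- data.frame(t_min = series$t_min, si = si, window = series$window)
  attr(out, "roi_code") <- roi_code
  attr(out, "n_voxels") <- length(idx)
  class(out) <- c("roi_timecourse", "data.frame")
  out
}

#' Windowed linear regression of an ROI time-course
#'
#' Ordinary least squares of signal intensity on time restricted to one
#' analysis window, with a two-sided t-test of zero slope. A perfectly
#' constant trace (zero slope, zero residual) is reported as
#' non-significant (`p = 1`); a perfect non-flat line as `p = 0`.
#'
#' @param tc A time-course from [extract_roi_timecourse()], or any data
#'   frame with columns `t_min`, `si`, `window`.
#' @param window `"ischemia"` or `"reperfusion"`.
#' @return List with `slope` (intensity/min), `intercept`, `p_nonzero_slope`,
#'   `n` and `window`.
#' @export
fit_window_slope <- function(tc, window = c("ischemia", "reperfusion")) {
  window <- match.arg(window)
  keep <- tc$window == window
  t <- tc$t_min[keep]; s <- tc$si[keep]
  n <- length(t)
  if (n < 3) stop("need >= 3 frames in the ", window,
                  " window for a slope test (have ", n, ")")
  tc_ <- t - mean(t)
  sxx <- sum(tc_^2)
  slope <- sum(tc_ * (s - mean(s))) / sxx
  intercept <- mean(s) - slope * mean(t)
  resid <- s - (intercept + slope * t)
  sse <- sum(resid^2)
  if (sse <= .Machine$double.eps * sum(s^2)) {
    p <- if (abs(slope) <= .Machine$double.eps * max(abs(s), 1)) 1 else 0
  } else {
    se <- sqrt(sse / (n - 2) / sxx)
    p <- 2 * pt(-abs(slope / se), df = n - 2)
  }
  list(slope = slope, intercept = intercept, p_nonzero_slope = p,
       n = n, window = window)
}

#' Per-pixel signal-intensity slope map
#'
#' Maps the contrast-uptake rate of every myocardial voxel over the
#' ischemia window. The default `"endpoint"` mode divides the difference
#' between the final and initial signal intensities of the window by the
#' elapsed time; `"ols"` mode fits an ordinary least-squares line through
#' all window frames, which is more noise-robust and identical to the
#' endpoint estimate when trajectories are exactly linear in time.
#'
#' @param series A [dynamic_series()] (only its ischemia-tagged frames are
#'   used; pass the full series or the output of [split_windows()]).
#' @param labels A [label_map()] on the same grid.
#' @param mode `"endpoint"` or `"ols"`.
#' @return An object of class `slope_map`: `slope` array (intensity/min,
#'   `NA` outside the myocardium), `mode`, `window_min`, `n_frames_used`.
#' @export
pixel_slope_map <- function(series, labels, mode = c("endpoint", "ols")) {
  mode <- match.arg(mode)
  stopifnot(inherits(series, "dynamic_series"), inherits(labels, "label_map"))
  keep <- series$window == "ischemia"
  if (sum(keep) < 2)
    stop("ischemia window must contain >= 2 frames")
  t <- series$t_min[keep]
  if (max(t) == min(t)) stop("degenerate window: t_end equals t_start")
  myo <- labels$tissue == tissue_codes[["myocardium"]]
  idx <- which(myo)
  S <- vapply(which(keep), function(f) series$data[, , , f][idx],
              numeric(length(idx)))
  slope_v <- if (mode == "endpoint") {
    (S[, ncol(S)] - S[, 1]) / (max(t) - min(t))
  } else {
    tc_ <- t - mean(t)
    as.vector(S %*% tc_) / sum(tc_^2)
  }
  slope <- array(NA_real_, dim(labels$tissue))
  slope[idx] <- slope_v
  structure(list(slope = slope, mode = mode,
                 window_min = range(t), n_frames_used = length(t),
                 voxel_mm = series$voxel_mm),
            class = "slope_map")
}

#' @export
print.slope_map <- function(x, ...) {
  cat(sprintf(
    "<slope_map> mode %s over %.0f-%.0f min (%d frames), %d voxels\n",
    x$mode, x$window_min[1], x$window_min[2], x$n_frames_used,
    sum(!is.na(x$slope))))
  invisible(x)
}

#' Perfusion deficit from a slope map
#'
#' The slope-criterion deficit: myocardial voxels whose uptake slope is
#' nonpositive (slope <= 0 — a literal zero counts as deficit) expressed
#' as a percentage of all LV myocardium voxels.
#'
#' @param smap A [pixel_slope_map()] result.
#' @param labels The [label_map()] defining the LV myocardium.
#' @return An object of class `deficit_result`: `deficit_pct_lv`,
#'   `method = "slope"`, `n_deficit_voxels`, `n_lv_voxels`.
#' @export
deficit_from_slopes <- function(smap, labels) {
  stopifnot(inherits(smap, "slope_map"), inherits(labels, "label_map"))
  myo <- labels$tissue == tissue_codes[["myocardium"]]
  if (!any(myo)) stop("label map contains no myocardium")
  sl <- smap$slope[myo]
  if (anyNA(sl)) stop("slope undefined on some myocardial voxels")
  n_def <- sum(sl <= 0)
  structure(list(deficit_pct_lv = 100 * n_def / sum(myo),
                 method = "slope",
                 n_deficit_voxels = n_def, n_lv_voxels = sum(myo)),
            class = "deficit_result")
}

#' @export
print.deficit_result <- function(x, ...) {
  cat(sprintf("<deficit_result> %s method: %.2f %%LV (%d / %d voxels)\n",
              x$method, x$deficit_pct_lv, x$n_deficit_voxels,
              x$n_lv_voxels))
  invisible(x)
}
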