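#' Spoiled gradient-echo steady-state signal
#'
#' The SPGR/FLASH closed form
#' `S = M0 * sin(a) * (1 - E1) / (1 - E1 * cos(a))` with
#' `E1 = exp(-TR / T1)`. Vectorised over any argument.
#'
#' @param alpha_deg Flip angle, degrees, in \[0, 90\].
#' @param m0 Equilibrium signal scale.
#' @param t1_ms Longitudinal relaxation time, ms (> 0).
#' @param tr_ms Repetition time, ms (> 0).
#' @return Signal intensity (same units as `m0`).
#' @export
spgr_signal <- function(alpha_deg, m0, t1_ms, tr_ms) {
  if (any(t1_ms <= 0)) stop("t1_ms must be positive")
  if (any(tr_ms <= 0)) stop("tr_ms must be positive")
  if (any(alpha_deg < 0 | alpha_deg > 90))
    stop("alpha_deg must lie in [0, 90]")
  a <- alpha_deg * pi / 180
  e1 <- exp(-tr_ms / t1_ms)
  m0 * sin(a) * (1 - e1) / (1 - e1 * cos(a))
}

#' Variable-flip-angle stack container
#'
#' A set of co-registered SPGR volumes acquired at increasing flip angles
#' with shared TR, plus a logical fitting mask.
#'
#' @param volumes List of [image_volume()] objects, one per flip angle.
#' @param flip_angles_deg Strictly increasing flip angles, degrees; at
#'   least two distinct angles.
#' @param tr_ms Repetition time, ms.
#' @param te_ms Echo time, ms (metadata only).
#' @param mask Logical array on the shared grid (default: everywhere).
#' @return An object of class `vfa_stack`.
#' @export
vfa_stack <- function(volumes, flip_angles_deg, tr_ms, te_ms = NA_real_,
                      mask = NULL) {
  stopifnot(length(volumes) == length(flip_angles_deg),
            length(flip_angles_deg) >= 2, tr_ms > 0,
            all(diff(flip_angles_deg) > 0))
  dims <- dim(volumes[[1]]$data)
  for (v in volumes) stopifnot(identical(dim(v$data), dims))
  if (is.null(mask)) mask <- array(TRUE, dims)
  stopifnot(identical(dim(mask), dims))
  structure(list(volumes = volumes,
                 flip_angles_deg = as.numeric(flip_angles_deg),
                 tr_ms = tr_ms, te_ms = te_ms, mask = mask,
                 voxel_mm = volumes[[1]]$voxel_mm),
            class = "vfa_stack")
}

#' @export
print.vfa_stack <- function(x, ...) {
  cat(sprintf("<vfa_stack> %d flip angles (%s deg), TR %.2f ms, %d voxels in mask\n",
              length(x$flip_angles_deg),
              paste(x$flip_angles_deg, collapse = ", "),
              x$tr_ms, sum(x$mask)))
  invisible(x)
}

## signals inside the mask as an (n_voxel x n_angle) matrix
stack_signal_matrix <- function(stack) {
  idx <- which(stack$mask)
  vapply(stack$volumes, function(v) v$data[idx], numeric(length(idx)))
}

t1_map_result <- function(stack, t1, m0, fit_ok, method) {
  dims <- dim(stack$mask)
  mk <- function(vals) {
    a <- array(NA_real_, dims); a[which(stack$mask)] <- vals; a
  }
  ok <- array(FALSE, dims); ok[which(stack$mask)] <- fit_ok
  structure(list(t1_ms = mk(t1), m0 = mk(m0), fit_ok = ok,
                 method = method, voxel_mm = stack$voxel_mm),
            class = "t1_map")
}

#' @export
print.t1_map <- function(x, ...) {
  ok <- x$fit_ok
  cat(sprintf("<t1_map> method %s: %d voxels fitted, median T1 %.0f ms\n",
              x$method, sum(ok), median(x$t1_ms[ok])))
  invisible(x)
}

#' Linear variable-flip-angle T1 fit
#'
#' Per-voxel linearisation of the SPGR closed form: regressing
#' `y = S / sin(a)` on `x = S / tan(a)` gives slope `E1 = exp(-TR/T1)` and
#' intercept `M0 * (1 - E1)`, so `T1 = -TR / log(slope)`. Voxels whose
#' fitted slope falls outside (0, 1) — all-zero input, model-inconsistent
#' signals — are flagged `fit_ok = FALSE` rather than clamped, so failure
#' stays visible in the map.
#'
#' @param stack A [vfa_stack()].
#' @return An object of class `t1_map` with per-voxel `t1_ms`, `m0` and
#'   `fit_ok` arrays (`NA`/`FALSE` outside the mask).
#' @export
fit_t1_linear <- function(stack) {
  stopifnot(inherits(stack, "vfa_stack"))
  S <- stack_signal_matrix(stack)
  a <- stack$flip_angles_deg * pi / 180
  nA <- length(a)
  X <- sweep(S, 2, tan(a), "/")
  Y <- sweep(S, 2, sin(a), "/")
  sx <- rowSums(X); sy <- rowSums(Y)
  sxx <- rowSums(X^2); sxy <- rowSums(X * Y)
  denom <- nA * sxx - sx^2
  slope <- (nA * sxy - sx * sy) / denom
  intercept <- (sy - slope * sx) / nA
  ok <- is.finite(slope) & slope > 0 & slope < 1
  t1 <- rep(NA_real_, nrow(S)); m0 <- rep(NA_real_, nrow(S))
  t1[ok] <- -stack$tr_ms / log(slope[ok])
  m0[ok] <- intercept[ok] / (1 - slope[ok])
  ok <- ok & is.finite(t1) & t1 > 0
  t1_map_result(stack, t1, m0, ok, "linear")
}

#' Nonlinear refinement of a T1 map
#'
#' Per-voxel Levenberg–Marquardt least squares directly on the SPGR closed
#' form, started from a linear fit. The residual never increases relative
#' to the initial values; T1 is constrained to \[100, 10000\] ms. Voxels
#' whose initial fit failed are left flagged and untouched.
#'
#' @param stack A [vfa_stack()].
#' @param init A `t1_map` providing starting values (default: the linear
#'   fit of `stack`).
#' @param max_iter Maximum LM iterations.
#' @param t1_bounds Lower/upper T1 bounds, ms.
#' @return A `t1_map` with `method = "nonlinear"`.
#' @export
fit_t1_nonlinear <- function(stack, init = fit_t1_linear(stack),
                             max_iter = 60L, t1_bounds = c(100, 10000)) {
  stopifnot(inherits(stack, "vfa_stack"), inherits(init, "t1_map"))
  idx <- which(stack$mask)
  S <- stack_signal_matrix(stack)
  a <- stack$flip_angles_deg * pi / 180
  tr <- stack$tr_ms
  ok0 <- init$fit_ok[idx]
  t1 <- pmin(pmax(init$t1_ms[idx], t1_bounds[1]), t1_bounds[2])
  m0 <- init$m0[idx]
  fit <- which(ok0 & is.finite(t1) & is.finite(m0) & m0 != 0)
  if (length(fit)) {
    Sf <- S[fit, , drop = FALSE]
    sina <- sin(a); cosa <- cos(a)
    model <- function(m0v, t1v) {
      e1 <- exp(-tr / t1v)
      num <- outer(1 - e1, sina)
      den <- 1 - outer(e1, cosa)
      m0v * num / den
    }
    sse_of <- function(m0v, t1v) rowSums((Sf - model(m0v, t1v))^2)
    m0f <- m0[fit]; t1f <- t1[fit]
    sse <- sse_of(m0f, t1f)
    lambda <- rep(1e-3, length(fit))
    for (it in seq_len(max_iter)) {
      e1 <- exp(-tr / t1f)
      den <- 1 - outer(e1, cosa)
      Sm <- m0f * outer(1 - e1, sina) / den
      R <- Sf - Sm
      g1 <- Sm / m0f                                   # dS/dM0
      dS_dE <- m0f * outer(rep(1, length(fit)), sina) *
        outer(rep(1, length(fit)), cosa - 1) / den^2
      g2 <- dS_dE * (e1 * tr / t1f^2)                  # dS/dT1
      A <- rowSums(g1^2); B <- rowSums(g1 * g2); C <- rowSums(g2^2)
      r1 <- rowSums(g1 * R); r2 <- rowSums(g2 * R)
      Ad <- A * (1 + lambda); Cd <- C * (1 + lambda)
      det <- Ad * Cd - B^2
      dm0 <- (Cd * r1 - B * r2) / det
      dt1 <- (Ad * r2 - B * r1) / det
      bad <- !is.finite(dm0) | !is.finite(dt1)
      dm0[bad] <- 0; dt1[bad] <- 0
      m0_new <- m0f + dm0
      t1_new <- pmin(pmax(t1f + dt1, t1_bounds[1]), t1_bounds[2])
      m0_new[m0_new == 0] <- .Machine$double.eps
      sse_new <- sse_of(m0_new, t1_new)
      better <- is.finite(sse_new) & sse_new <= sse
      m0f[better] <- m0_new[better]
      t1f[better] <- t1_new[better]
      sse[better] <- sse_new[better]
      lambda[better] <- pmax(lambda[better] / 3, 1e-12)
      lambda[!better] <- pmin(lambda[!better] * 4, 1e8)
      if (all(abs(dt1[better]) < 1e-9 * t1f[better])) break
    }
    m0[fit] <- m0f; t1[fit] <- t1f
  }
  out <- t1_map_result(stack, t1, m0, ok0, "nonlinear")
  out$t1_ms[!out$fit_ok] <- NA_real_
  out$m0[!out$fit_ok] <- NA_real_
  out
}

#' Multiplicative bias-field correction
#'
#' Estimates a smooth multiplicative shading field by fitting, per slice, a
#' 2D polynomial of total degree `order` to the log-intensity of voxels
#' inside the mask, then divides the volume by the exponentiated field.
#' The field is normalised to unit mean over the mask so the corrected
#' volume keeps its mean intensity. Non-positive intensities are excluded
#' from the fit; slices with no usable mask voxels keep a unit field.
#'
#' @param volume An [image_volume()] (or bare 3D array).
#' @param mask Logical array, or a [label_map()] whose myocardium defines
#'   the fit region.
#' @param order Polynomial total degree, 1-3.
#' @return List with `corrected` (an [image_volume()]) and `bias` (the
#'   estimated field as an [image_volume()], unit mean over the mask).
#' @export
correct_bias_field <- function(volume, mask, order = 2L) {
  if (!order %in% 1:3) stop("order must be 1, 2 or 3")
  voxel_mm <- if (inherits(volume, "image_volume")) volume$voxel_mm else
    c(1, 1, 1)
  data <- if (inherits(volume, "image_volume")) volume$data else as.array(volume)
  if (inherits(mask, "label_map"))
    mask <- mask$tissue == tissue_codes[["myocardium"]]
  stopifnot(identical(dim(mask), dim(data)))
  dims <- dim(data)
  xh <- seq(-1, 1, length.out = dims[1])
  yh <- seq(-1, 1, length.out = dims[2])
  xg <- matrix(xh, dims[1], dims[2])
  yg <- matrix(yh, dims[1], dims[2], byrow = TRUE)
  terms <- list()
  for (px in 0:order) for (py in 0:(order - px))
    terms[[length(terms) + 1L]] <- xg^px * yg^py
  Xfull <- vapply(terms, as.vector, numeric(length(xg)))
  field <- array(1, dims)
  any_fit <- FALSE
  for (k in seq_len(dims[3])) {
    sl <- data[, , k]
    m <- mask[, , k] & sl > 0
    if (sum(m) < ncol(Xfull) + 2L) next
    any_fit <- TRUE
    fit <- lm.fit(Xfull[as.vector(m), , drop = FALSE], log(sl[m]))
    f <- exp(Xfull %*% fit$coefficients)
    field[, , k] <- f / mean(f[as.vector(m)])
  }
  if (!any_fit) stop("no usable voxels in mask for bias estimation")
  list(corrected = image_volume(data / field, voxel_mm),
       bias = image_volume(field, voxel_mm))
}
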