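#' Synthetic left-ventricle phantom specification
#'
#' Defines the geometry, noise and artefact model of the digital short-axis
#' LV phantom used to validate every estimator in the package. The default
#' grid and field of view reproduce a typical high-resolution murine 3D
#' acquisition (matrix 120 x 110 x 10, FOV 28 x 25 x 8 mm^3). The LV is an
#' annulus per slice: cavity inside `r_endo`, myocardium between `r_endo`
#' and `r_epi`, interpolated between end-diastolic (ED) and end-systolic
#' (ES) radii for cine simulation.
#'
#' @param grid_shape Integer triple (nx, ny, nz).
#' @param voxel_mm Voxel spacing triple, mm (in-plane x, y, slice).
#' @param center In-plane centre of the annulus, mm; `NULL` = grid centre.
#' @param r_endo_ed,r_epi_ed End-diastolic endocardial/epicardial radii, mm.
#' @param r_endo_es,r_epi_es End-systolic radii, mm.
#' @param ischemic_sector Angular interval `c(lo, hi)` in degrees (lateral
#'   wall centred on 0) occupied by the ischemic territory, or `NULL` for
#'   none. The interval is walked counterclockwise and may wrap through 360.
#' @param ischemic_slices Integer slice indices carrying the ischemic
#'   sector; `NULL` = all slices.
#' @param impaired_sector Angular interval whose wall motion is impaired in
#'   cine simulation (typically the ischemic sector), or `NULL`.
#' @param impairment_severity Fraction of local contraction lost in the
#'   impaired sector: 0 = normal motion, 1 = akinetic.
#' @param noise_sigma Additive Gaussian noise SD, intensity units.
#' @param bias_amplitude Fractional peak of the multiplicative in-plane
#'   bias field `1 + A * x * y` (x, y normalised to \[-1, 1\] over the FOV).
#' @param shift_mm In-plane rigid shift `c(dx, dy)` (mm) applied to frames
#'   after the occlusion release, rounded to whole voxels.
#' @param seed Integer RNG seed; identical spec + seed gives bit-identical
#'   output.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(120L, 110L, 10L),
                         voxel_mm = c(28 / 120, 25 / 110, 8 / 10),
                         center = NULL,
                         r_endo_ed = 1.5, r_epi_ed = 2.5,
                         r_endo_es = 0.8, r_epi_es = 2.154,
                         ischemic_sector = NULL,
                         ischemic_slices = NULL,
                         impaired_sector = NULL,
                         impairment_severity = 0.6,
                         noise_sigma = 2.5,
                         bias_amplitude = 0.1,
                         shift_mm = c(0, 0),
                         seed = 1L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1),
            length(voxel_mm) == 3L, all(voxel_mm > 0),
            r_endo_ed >= 0, r_endo_es >= 0,
            r_endo_ed < r_epi_ed, r_endo_es < r_epi_es,
            noise_sigma >= 0, bias_amplitude >= 0,
            impairment_severity >= 0, impairment_severity <= 1,
            length(shift_mm) == 2L)
  if (!is.null(ischemic_sector)) {
    w <- (ischemic_sector[2] - ischemic_sector[1]) %% 360
    if (w <= 0) stop("ischemic sector width must lie in (0, 360) degrees")
  }
  ## centre the annulus on the voxel centre nearest the grid centre: on
  ## even grids the exact grid centre is a voxel corner, and the 4-fold
  ## lattice symmetry there maximises rasterisation error for small radii
  if (is.null(center))
    center <- (ceiling(grid_shape[1:2] / 2) - 0.5) * voxel_mm[1:2]
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_mm = as.numeric(voxel_mm), center = center,
                 r_endo_ed = r_endo_ed, r_epi_ed = r_epi_ed,
                 r_endo_es = r_endo_es, r_epi_es = r_epi_es,
                 ischemic_sector = ischemic_sector,
                 ischemic_slices = ischemic_slices,
                 impaired_sector = impaired_sector,
                 impairment_severity = impairment_severity,
                 noise_sigma = noise_sigma,
                 bias_amplitude = bias_amplitude,
                 shift_mm = as.numeric(shift_mm),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Manganese uptake kinetics
#'
#' Kinetic parameters of the dynamic contrast model. Perfused myocardium
#' follows a saturating mono-exponential wash-in,
#' `SI(t) = s0 * (1 + u_max * (1 - exp(-t / tau_up)))`; ischemic tissue
#' follows a linear non-increase `SI(t) = s0 * (1 - d_rate * min(t,
#' t_occlusion))`. The defaults span a 66-min acquisition of 11 frames
#' covering 30 min of occlusion followed by 36 min of reperfusion; frame
#' timestamps are the midpoints of 11 equal 6-min intervals.
#'
#' @param s0 Baseline intensity, a.u.
#' @param u_max Fractional plateau enhancement of perfused tissue.
#' @param tau_up Uptake time constant, minutes (> 0).
#' @param d_rate Fractional decline per minute in ischemic tissue (>= 0).
#' @param t_occlusion Occlusion release time, minutes.
#' @param t_total Total acquisition span, minutes.
#' @param n_frames Number of frames (>= 2).
#' @return An object of class `uptake_kinetics`.
#' @export
uptake_kinetics <- function(s0 = 100, u_max = 1, tau_up = 15,
                            d_rate = 0.005, t_occlusion = 30,
                            t_total = 66, n_frames = 11L) {
  stopifnot(tau_up > 0, d_rate >= 0, s0 > 0,
            t_occlusion > 0, t_total > t_occlusion)
  if (n_frames < 2) stop("n_frames must be >= 2: no slope is estimable")
  structure(list(s0 = s0, u_max = u_max, tau_up = tau_up, d_rate = d_rate,
                 t_occlusion = t_occlusion, t_total = t_total,
                 n_frames = as.integer(n_frames)),
            class = "uptake_kinetics")
}

## closed-form signal trajectories
si_perfused <- function(t, kin)
  kin$s0 * (1 + kin$u_max * (1 - exp(-t / kin$tau_up)))
si_ischemic <- function(t, kin)
  kin$s0 * (1 - kin$d_rate * pmin(t, kin$t_occlusion))

kinetics_timestamps <- function(kin)
  (seq_len(kin$n_frames) - 0.5) * kin$t_total / kin$n_frames

phase_radii <- function(spec, phase) {
  phase <- match.arg(phase, c("ED", "ES"))
  if (phase == "ED") c(spec$r_endo_ed, spec$r_epi_ed)
  else c(spec$r_endo_es, spec$r_epi_es)
}

## Annulus label map for given radii; optionally different radii inside an
## impaired angular sector. Radii must fit inside the FOV.
build_annulus <- function(spec, r_endo, r_epi,
                          r_endo_imp = NULL, r_epi_imp = NULL,
                          impaired_sector = NULL) {
  dims <- spec$grid_shape
  pc <- plane_coords(dims, spec$voxel_mm, spec$center)
  fov <- dims[1:2] * spec$voxel_mm[1:2]
  margin <- min(pc$center, fov - pc$center)
  if (max(r_epi, r_epi_imp %||% 0) > margin)
    stop("geometry error: epicardial radius ", max(r_epi, r_epi_imp %||% 0),
         " mm exceeds the in-plane FOV margin ", signif(margin, 4), " mm")
  re <- matrix(r_endo, dims[1], dims[2])
  rp <- matrix(r_epi, dims[1], dims[2])
  if (!is.null(impaired_sector)) {
    imp <- angle_in_interval(pc$theta, impaired_sector)
    re[imp] <- r_endo_imp
    rp[imp] <- r_epi_imp
  }
  cavity <- pc$rho < re
  myo <- pc$rho >= re & pc$rho <= rp
  tissue_slice <- array(tissue_codes[["background"]], dims[1:2])
  tissue_slice[cavity] <- tissue_codes[["cavity"]]
  tissue_slice[myo] <- tissue_codes[["myocardium"]]
  sector_slice <- array(0L, dims[1:2])
  sector_slice[myo] <- sector_of_angle(pc$theta[myo])
  tissue <- array(rep(tissue_slice, dims[3]), dims)
  sector <- array(rep(sector_slice, dims[3]), dims)
  label_map(tissue, sector, spec$voxel_mm)
}

#' Build the LV annulus label map
#'
#' Rasterises the phantom's annulus at the requested cardiac phase:
#' voxels with in-plane centre distance `rho < r_endo` are cavity,
#' `r_endo <= rho <= r_epi` myocardium. Myocardial voxels carry one of
#' four 90-degree sector codes (septal centred at 180 degrees, lateral at
#' 0; see [sector_codes]).
#'
#' @param spec A [phantom_spec()].
#' @param phase `"ED"` (end-diastole) or `"ES"` (end-systole).
#' @return A [label_map()].
#' @export
make_lv_labelmap <- function(spec, phase = c("ED", "ES")) {
  r <- phase_radii(spec, match.arg(phase))
  build_annulus(spec, r[1], r[2])
}

## logical ischemic-territory mask on the myocardium of `labels`
ischemic_mask_for <- function(spec, labels) {
  mask <- array(FALSE, dim(labels$tissue))
  if (is.null(spec$ischemic_sector)) return(mask)
  pc <- plane_coords(spec$grid_shape, spec$voxel_mm, spec$center)
  in_sector <- angle_in_interval(pc$theta, spec$ischemic_sector)
  slices <- spec$ischemic_slices %||% seq_len(spec$grid_shape[3])
  for (k in slices)
    mask[, , k] <- in_sector
  mask & labels$tissue == tissue_codes[["myocardium"]]
}

## multiplicative in-plane bias field, unit value at the FOV centre:
## 1 + A * xhat * yhat with xhat, yhat in [-1, 1]
bias_field_slice <- function(spec) {
  dims <- spec$grid_shape
  fov <- dims[1:2] * spec$voxel_mm[1:2]
  xh <- ((seq_len(dims[1]) - 0.5) * spec$voxel_mm[1] - fov[1] / 2) / (fov[1] / 2)
  yh <- ((seq_len(dims[2]) - 0.5) * spec$voxel_mm[2] - fov[2] / 2) / (fov[2] / 2)
  1 + spec$bias_amplitude * outer(xh, yh)
}

apply_bias <- function(vol_data, spec) {
  if (spec$bias_amplitude == 0) return(vol_data)
  field <- bias_field_slice(spec)
  sweep_dims <- dim(vol_data)
  vol_data * array(rep(field, sweep_dims[3]), sweep_dims)
}

## whole-voxel in-plane translation; vacated voxels take `fill`
shift_volume <- function(vol_data, shift_vox, fill = 0) {
  if (all(shift_vox == 0)) return(vol_data)
  d <- dim(vol_data)
  out <- array(fill, d)
  sx <- shift_vox[1]; sy <- shift_vox[2]
  xs <- seq_len(d[1]) - sx; ys <- seq_len(d[2]) - sy
  okx <- xs >= 1 & xs <= d[1]; oky <- ys >= 1 & ys <= d[2]
  out[which(okx), which(oky), ] <- vol_data[xs[okx], ys[oky], , drop = FALSE]
  out
}

#' Simulate a dynamic MEMRI acquisition
#'
#' Generates the 11-frame (by default) dynamic series of a remote-occlusion
#' experiment: perfused myocardium brightens along the saturating wash-in
#' curve, voxels in the ischemic sector follow a flat-to-declining linear
#' trajectory frozen after the occlusion release, cavity and background sit
#' at constant baselines (`s0` and `0.05 * s0`). A multiplicative bias
#' field, an optional whole-voxel rigid shift of post-occlusion frames, and
#' additive zero-mean Gaussian noise are applied last, in that order.
#'
#' @param spec A [phantom_spec()].
#' @param kin An [uptake_kinetics()].
#' @return A list with elements `series` (a [dynamic_series()]), `labels`
#'   (the ED [label_map()] used as the fixed acquisition geometry), and
#'   `truth` (ground truth: `ischemic_mask`, `deficit_fraction_true` as
#'   percent of LV myocardium voxels, timestamps and window tags).
#' @export
simulate_memri_dynamics <- function(spec, kin) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(kin, "uptake_kinetics"))
  labels <- make_lv_labelmap(spec, "ED")
  isch <- ischemic_mask_for(spec, labels)
  myo <- labels$tissue == tissue_codes[["myocardium"]]
  cav <- labels$tissue == tissue_codes[["cavity"]]
  t <- kinetics_timestamps(kin)
  window <- ifelse(t <= kin$t_occlusion, "ischemia", "reperfusion")
  dims <- spec$grid_shape
  data <- array(0, c(dims, kin$n_frames))
  shift_vox <- round(spec$shift_mm / spec$voxel_mm[1:2])
  for (f in seq_along(t)) {
    frame <- array(0.05 * kin$s0, dims)
    frame[cav] <- kin$s0
    frame[myo] <- si_perfused(t[f], kin)
    frame[isch] <- si_ischemic(t[f], kin)
    frame <- apply_bias(frame, spec)
    if (t[f] > kin$t_occlusion)
      frame <- shift_volume(frame, shift_vox, fill = 0.05 * kin$s0)
    data[, , , f] <- frame
  }
  if (spec$noise_sigma > 0) {
    set.seed(spec$seed)
    data <- data + array(rnorm(length(data), sd = spec$noise_sigma), dim(data))
  }
  truth <- list(ischemic_mask = isch,
                deficit_fraction_true = 100 * sum(isch) / sum(myo),
                t_min = t, window = window)
  list(series = dynamic_series(data, t, window, spec$voxel_mm),
       labels = labels, truth = truth)
}

#' True T1 and M0 volumes for the phantom
#'
#' Convenience ground-truth maps for VFA simulation: uniform myocardial T1
#' (default 1490 ms, a typical native murine value at 7 T), blood-pool T1
#' in the cavity, zero equilibrium signal outside the heart.
#'
#' @param spec A [phantom_spec()].
#' @param t1_myo_ms,t1_blood_ms True T1 values, ms.
#' @param m0 Equilibrium signal scale in tissue.
#' @return List with `t1` and `m0` arrays plus the ED `labels`.
#' @export
phantom_t1_truth <- function(spec, t1_myo_ms = 1490, t1_blood_ms = 2200,
                             m0 = 1000) {
  labels <- make_lv_labelmap(spec, "ED")
  t1 <- array(t1_myo_ms, spec$grid_shape)
  t1[labels$tissue == tissue_codes[["cavity"]]] <- t1_blood_ms
  m0v <- array(0, spec$grid_shape)
  m0v[labels$tissue != tissue_codes[["background"]]] <- m0
  list(t1 = t1, m0 = m0v, labels = labels)
}

#' Simulate a variable-flip-angle SPGR stack
#'
#' Evaluates the spoiled-gradient-echo steady-state closed form
#' ([spgr_signal()]) voxelwise at each requested flip angle, then applies
#' the phantom's bias field and Gaussian noise if enabled.
#'
#' @param spec A [phantom_spec()] (supplies grid, bias, noise, seed).
#' @param t1_map Numeric array of true T1 (ms) on the grid, or scalar.
#' @param m0 Numeric array (or scalar) of equilibrium signal.
#' @param flip_angles_deg Flip angles in degrees, strictly increasing,
#'   each in (0, 90].
#' @param tr_ms Repetition time, ms.
#' @param mask Logical array restricting downstream fitting (default: the
#'   phantom myocardium).
#' @param noise_sigma,bias_amplitude Override the spec's values (defaults:
#'   take them from `spec`).
#' @return A [vfa_stack()] whose volumes hold the simulated signals.
#' @export
simulate_vfa_stack <- function(spec, t1_map, m0,
                               flip_angles_deg = c(2, 5, 8, 11, 14),
                               tr_ms = 11.1, mask = NULL,
                               noise_sigma = spec$noise_sigma,
                               bias_amplitude = spec$bias_amplitude) {
  stopifnot(inherits(spec, "phantom_spec"), tr_ms > 0)
  if (any(flip_angles_deg <= 0 | flip_angles_deg > 90))
    stop("flip angles must lie in (0, 90] degrees")
  dims <- spec$grid_shape
  if (length(t1_map) == 1L) t1_map <- array(t1_map, dims)
  if (length(m0) == 1L) m0 <- array(m0, dims)
  if (is.null(mask))
    mask <- make_lv_labelmap(spec, "ED")$tissue == tissue_codes[["myocardium"]]
  if (any(t1_map[mask] <= 0))
    stop("non-positive T1 inside the fitting mask")
  spec2 <- spec; spec2$bias_amplitude <- bias_amplitude
  if (noise_sigma > 0) set.seed(spec$seed)
  vols <- lapply(flip_angles_deg, function(a) {
    v <- spgr_signal(a, m0, t1_map, tr_ms)
    v <- apply_bias(v, spec2)
    if (noise_sigma > 0)
      v <- v + array(rnorm(length(v), sd = noise_sigma), dims)
    image_volume(v, spec$voxel_mm)
  })
  vfa_stack(vols, flip_angles_deg, tr_ms, te_ms = 2.3, mask = mask)
}

#' Simulate a late-enhancement volume
#'
#' A single post-contrast T1-weighted volume: myocardium at a uniform
#' baseline with an enhanced angular sector multiplied by
#' `enhancement_factor`, bright blood pool, dim background. Optionally a
#' scar sub-sector (strictly inside the enhanced sector in the intended
#' use) is recorded in the ground truth for overestimation analyses.
#'
#' @param spec A [phantom_spec()].
#' @param enhanced_sector_deg Angular interval of the enhanced territory,
#'   or `NULL` for none.
#' @param enhancement_factor Multiplicative enhancement (> 1).
#' @param scar_sector_deg Optional angular interval of the true scar.
#' @param baseline Myocardial baseline intensity.
#' @return List with `volume` (an [image_volume()]), `labels`, and `truth`
#'   (`enhanced_fraction_true` and `scar_fraction_true`, percent of LV
#'   myocardium voxels).
#' @export
simulate_lge_volume <- function(spec, enhanced_sector_deg,
                                enhancement_factor = 2,
                                scar_sector_deg = NULL,
                                baseline = 100) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (enhancement_factor <= 1) stop("enhancement_factor must exceed 1")
  labels <- make_lv_labelmap(spec, "ED")
  myo <- labels$tissue == tissue_codes[["myocardium"]]
  pc <- plane_coords(spec$grid_shape, spec$voxel_mm, spec$center)
  sector_mask <- function(interval) {
    if (is.null(interval)) return(array(FALSE, dim(myo)))
    ins <- angle_in_interval(pc$theta, interval)
    array(rep(ins, spec$grid_shape[3]), dim(myo)) & myo
  }
  enh <- sector_mask(enhanced_sector_deg)
  scar <- sector_mask(scar_sector_deg)
  data <- array(0.05 * baseline, spec$grid_shape)
  data[labels$tissue == tissue_codes[["cavity"]]] <- 1.5 * baseline
  data[myo] <- baseline
  data[enh] <- baseline * enhancement_factor
  data <- apply_bias(data, spec)
  if (spec$noise_sigma > 0) {
    set.seed(spec$seed + 1L)
    data <- data + array(rnorm(length(data), sd = spec$noise_sigma), dim(data))
  }
  truth <- list(enhanced_mask = enh,
                enhanced_fraction_true = 100 * sum(enh) / sum(myo),
                scar_mask = scar,
                scar_fraction_true = 100 * sum(scar) / sum(myo))
  list(volume = image_volume(data, spec$voxel_mm), labels = labels,
       truth = truth)
}

#' Simulate a cine label-map sequence
#'
#' Interpolates endo- and epicardial radii sinusoidally between the ED and
#' ES geometries over `n_frames` cardiac frames (frame 1 is ED). If the
#' spec defines an impaired sector, radii there interpolate only partially
#' towards ES: the local ES endocardial radius is
#' `r_es + severity * (r_ed - r_es)` (severity 1 = akinetic), and likewise
#' for the epicardium, reproducing regional hypokinesia with preserved
#' remote contraction. True cavity volumes are computed analytically as
#' sector-weighted disc areas times the stack length.
#'
#' @param spec A [phantom_spec()].
#' @param n_frames Number of cardiac frames (>= 2); 20 matches a typical
#'   retrospectively gated reconstruction.
#' @return List with `frames` (list of [label_map()]), and `truth`
#'   (`cavity_volume_true_ul` per frame, `edv_true_ul`, `esv_true_ul`,
#'   `ef_true_pct`, `phase_weight`).
#' @export
simulate_cine <- function(spec, n_frames = 20L) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (n_frames < 2) stop("n_frames must be >= 2")
  w <- (1 + cos(2 * pi * (seq_len(n_frames) - 1) / n_frames)) / 2  # 1=ED
  sev <- spec$impairment_severity
  interp <- function(ed, es, wf) es + (ed - es) * wf
  height <- spec$grid_shape[3] * spec$voxel_mm[3]
  frames <- vector("list", n_frames)
  vol_true <- numeric(n_frames)
  imp_frac <- if (is.null(spec$impaired_sector)) 0 else
    ((spec$impaired_sector[2] - spec$impaired_sector[1]) %% 360) / 360
  for (f in seq_len(n_frames)) {
    r_en <- interp(spec$r_endo_ed, spec$r_endo_es, w[f])
    r_ep <- interp(spec$r_epi_ed, spec$r_epi_es, w[f])
    ## impaired sector: contraction scaled back towards ED by `sev`
    w_imp <- w[f] + sev * (1 - w[f])
    r_en_i <- interp(spec$r_endo_ed, spec$r_endo_es, w_imp)
    r_ep_i <- interp(spec$r_epi_ed, spec$r_epi_es, w_imp)
    frames[[f]] <- build_annulus(spec, r_en, r_ep,
                                 r_endo_imp = r_en_i, r_epi_imp = r_ep_i,
                                 impaired_sector = spec$impaired_sector)
    vol_true[f] <- height * pi *
      ((1 - imp_frac) * r_en^2 + imp_frac * r_en_i^2)
  }
  edv <- max(vol_true); esv <- min(vol_true)
  list(frames = frames,
       truth = list(cavity_volume_true_ul = vol_true,
                    edv_true_ul = edv, esv_true_ul = esv,
                    ef_true_pct = 100 * (edv - esv) / edv,
                    phase_weight = w))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
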