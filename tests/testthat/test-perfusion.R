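abind_frames <- function(win) {
  d <- dim(win$ischemia$data)
  out <- array(0, c(d[1:3], d[4] + dim(win$reperfusion$data)[4]))
  out[, , , seq_len(d[4])] <- win$ischemia$data
  out[, , , -seq_len(d[4])] <- win$reperfusion$data
  out
}

test_that("window split partitions the series at the occlusion release", {
  kin <- uptake_kinetics()
  mem <- simulate_memri_dynamics(small_spec(), kin)
  win <- split_windows(mem$series, 30)
  expect_true(all(win$ischemia$t_min <= 30))
  expect_true(all(win$reperfusion$t_min > 30))
  # concatenation restores the input frame set
  expect_equal(c(win$ischemia$t_min, win$reperfusion$t_min),
               mem$series$t_min)
  expect_identical(abind_frames(win), mem$series$data)
  expect_error(split_windows(mem$series, 100), "empty window")
  expect_error(split_windows(mem$series, 1), "empty window")
})

test_that("ROI time-courses are means over the ROI", {
  kin <- uptake_kinetics()
  spec <- small_spec(ischemic_sector = c(-45, 45))
  mem <- simulate_memri_dynamics(spec, kin)

  # noise-free septal (fully perfused) ROI equals the generator kinetics
  tc <- extract_roi_timecourse(mem$series, mem$labels, "septal")
  expect_equal(tc$si,
               oracle_si_perfused(tc$t_min, kin$s0, kin$u_max, kin$tau_up),
               tolerance = 1e-12)

  # single-voxel ROI reproduces that voxel's trajectory
  v <- which(mem$labels$tissue == 2L, arr.ind = TRUE)[1, ]
  tissue <- array(0L, dim(mem$labels$tissue)); sector <- array(0L, dim(tissue))
  tissue[v[1], v[2], v[3]] <- 2L
  sector[v[1], v[2], v[3]] <- sector_codes[["lateral"]]
  one <- label_map(tissue, sector, mem$labels$voxel_mm)
  tc1 <- extract_roi_timecourse(mem$series, one, "lateral")
  expect_equal(tc1$si,
               sapply(seq_along(tc1$t_min),
                      function(f) mem$series$data[v[1], v[2], v[3], f]))
  expect_error(extract_roi_timecourse(mem$series, one, "septal"), "empty")
})

test_that("windowed slope regression matches the closed-form OLS", {
  # hand-computed worked set
  tc <- data.frame(t_min = c(0, 6, 12), si = c(10, 11, 13),
                   window = "ischemia")
  fit <- fit_window_slope(tc, "ischemia")
  tb <- mean(c(0, 6, 12)); sb <- mean(c(10, 11, 13))
  slope_hand <- sum((c(0, 6, 12) - tb) * (c(10, 11, 13) - sb)) /
    sum((c(0, 6, 12) - tb)^2)
  expect_equal(fit$slope, slope_hand)
  expect_equal(fit$intercept, sb - slope_hand * tb)

  # perfect line: slope exact, p below any threshold
  tc2 <- data.frame(t_min = 0:5, si = 100 + 2 * (0:5), window = "ischemia")
  fit2 <- fit_window_slope(tc2, "ischemia")
  expect_equal(fit2$slope, 2)
  expect_lt(fit2$p_nonzero_slope, 1e-12)

  # exactly constant trace: zero slope, non-significant by convention
  tc3 <- data.frame(t_min = 0:5, si = rep(7, 6), window = "ischemia")
  fit3 <- fit_window_slope(tc3, "ischemia")
  expect_equal(fit3$slope, 0)
  expect_equal(fit3$p_nonzero_slope, 1)

  expect_error(fit_window_slope(tc[1:2, ], "ischemia"), ">= 3 frames")
})

test_that("pixel slope map: endpoint formula, OLS oracle, linear identity", {
  kin <- uptake_kinetics()
  spec <- small_spec(ischemic_sector = c(-54, 54))
  mem <- simulate_memri_dynamics(spec, kin)
  smap <- pixel_slope_map(mem$series, mem$labels, mode = "endpoint")

  # generator oracle: perfused endpoint slope from the closed form
  t_isch <- mem$series$t_min[mem$series$window == "ischemia"]
  t0 <- min(t_isch); t1 <- max(t_isch)
  perf <- which(mem$labels$tissue == 2L & !mem$truth$ischemic_mask)
  expected <- (oracle_si_perfused(t1, kin$s0, kin$u_max, kin$tau_up) -
               oracle_si_perfused(t0, kin$s0, kin$u_max, kin$tau_up)) /
    (t1 - t0)
  expect_equal(unique(round(smap$slope[perf], 12)), round(expected, 12))

  # identical frames give zero slope everywhere
  flat <- mem$series
  for (f in seq_len(dim(flat$data)[4])) flat$data[, , , f] <- flat$data[, , , 1]
  smap0 <- pixel_slope_map(flat, mem$labels)
  expect_true(all(smap0$slope[!is.na(smap0$slope)] == 0))

  # OLS mode equals an independent per-voxel lm() on a random series
  set.seed(5)
  dims <- c(10, 10, 2); nf <- 5
  data <- array(rnorm(prod(dims) * nf), c(dims, nf))
  t <- sort(runif(nf, 0, 30))
  ser <- dynamic_series(data, t, rep("ischemia", nf), c(1, 1, 1))
  lab <- all_myo_labels(dims)
  sm <- pixel_slope_map(ser, lab, mode = "ols")
  brute <- apply(matrix(data, prod(dims), nf), 1,
                 function(s) unname(coef(lm(s ~ t))[2]))
  expect_equal(as.vector(sm$slope), brute, tolerance = 1e-10)

  # endpoint and OLS agree exactly on exactly-linear trajectories
  lin_data <- array(0, c(dims, nf))
  base <- array(rnorm(prod(dims)), dims)
  rate <- array(rnorm(prod(dims)), dims)
  for (f in seq_len(nf)) lin_data[, , , f] <- base + rate * t[f]
  lser <- dynamic_series(lin_data, t, rep("ischemia", nf), c(1, 1, 1))
  expect_equal(pixel_slope_map(lser, lab, "endpoint")$slope,
               pixel_slope_map(lser, lab, "ols")$slope, tolerance = 1e-10)
})

test_that("slope-criterion deficit recovers the generated ischemic burden", {
  kin <- uptake_kinetics()
  for (frac in c(10, 30)) {
    w <- 3.6 * frac
    spec <- small_spec(ischemic_sector = c(-w / 2, w / 2))
    mem <- simulate_memri_dynamics(spec, kin)
    smap <- pixel_slope_map(mem$series, mem$labels)
    res <- deficit_from_slopes(smap, mem$labels)
    expect_equal(res$deficit_pct_lv, mem$truth$deficit_fraction_true)
    expect_equal(res$deficit_pct_lv,
                 100 * res$n_deficit_voxels / res$n_lv_voxels)
  }

  # nonpositive includes zero: flat trajectories count as deficit
  dims <- c(6, 6, 1); t <- c(0, 10, 20)
  lab <- all_myo_labels(dims)
  flat <- dynamic_series(array(5, c(dims, 3)), t, rep("ischemia", 3),
                         c(1, 1, 1))
  expect_equal(deficit_from_slopes(pixel_slope_map(flat, lab),
                                   lab)$deficit_pct_lv, 100)
  rising <- flat
  for (f in 1:3) rising$data[, , , f] <- t[f]
  expect_equal(deficit_from_slopes(pixel_slope_map(rising, lab),
                                   lab)$deficit_pct_lv, 0)
})

test_that("adding a uniform positive trend never increases the deficit", {
  kin <- uptake_kinetics(d_rate = 0.002)
  spec <- small_spec(ischemic_sector = c(-60, 60), noise_sigma = 1.5)
  mem <- simulate_memri_dynamics(spec, kin)
  base <- deficit_from_slopes(pixel_slope_map(mem$series, mem$labels),
                              mem$labels)$deficit_pct_lv
  for (c_trend in c(0.05, 0.3, 1)) {
    ser <- mem$series
    for (f in seq_len(dim(ser$data)[4]))
      ser$data[, , , f] <- ser$data[, , , f] + c_trend * ser$t_min[f]
    shifted <- deficit_from_slopes(pixel_slope_map(ser, mem$labels),
                                   mem$labels)$deficit_pct_lv
    expect_lte(shifted, base)
  }
})
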