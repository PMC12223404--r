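test_that("annulus label map matches analytic geometry", {
  # degenerate endocardial radius: solid myocardial disc, no cavity
  spec0 <- small_spec(r_endo_ed = 0, r_epi_ed = 2.5)
  lm0 <- make_lv_labelmap(spec0, "ED")
  expect_equal(sum(lm0$tissue == tissue_codes[["cavity"]]), 0)
  expect_gt(sum(lm0$tissue == tissue_codes[["myocardium"]]), 0)

  # analytic cylinder volume at the full-resolution voxel size
  spec <- phantom_spec(noise_sigma = 0, bias_amplitude = 0)
  lab <- make_lv_labelmap(spec, "ED")
  vol <- sum(lab$tissue == tissue_codes[["cavity"]]) * prod(spec$voxel_mm)
  expect_lt(abs(vol - pi * 1.5^2 * 8) / (pi * 1.5^2 * 8), 0.03)

  # sector codes partition the myocardium
  myo <- lab$tissue == tissue_codes[["myocardium"]]
  expect_true(all(lab$sector[myo] %in% sector_codes))
  expect_true(all(lab$sector[!myo] == 0L))

  # radii exceeding the FOV are rejected
  expect_error(make_lv_labelmap(small_spec(r_epi_ed = 50), "ED"),
               "geometry")
})

test_that("dynamic MEMRI simulation follows the stated kinetics", {
  kin <- uptake_kinetics()
  spec <- small_spec(ischemic_sector = c(-45, 45))
  mem <- simulate_memri_dynamics(spec, kin)
  t <- mem$series$t_min

  # frame midpoints of 11 equal 6-min intervals, tagged at 30 min
  expect_equal(t, seq(3, 63, by = 6))
  expect_equal(mem$series$window, ifelse(t <= 30, "ischemia", "reperfusion"))

  # noise-free perfused voxel equals the closed form at every frame
  perf <- which(mem$labels$tissue == 2L & !mem$truth$ischemic_mask)[1]
  si <- sapply(seq_along(t), function(f) mem$series$data[, , , f][perf])
  expect_equal(si, oracle_si_perfused(t, kin$s0, kin$u_max, kin$tau_up),
               tolerance = 1e-12)

  # ischemic voxel: linear decline frozen after occlusion release
  isc <- which(mem$truth$ischemic_mask)[1]
  si_i <- sapply(seq_along(t), function(f) mem$series$data[, , , f][isc])
  expect_equal(si_i, oracle_si_ischemic(t, kin$s0, kin$d_rate, 30),
               tolerance = 1e-12)

  # d_rate = 0: ischemic trajectory exactly flat through occlusion
  kin0 <- uptake_kinetics(d_rate = 0)
  mem0 <- simulate_memri_dynamics(spec, kin0)
  si0 <- sapply(which(t <= 30), function(f) mem0$series$data[, , , f][isc])
  expect_equal(diff(si0), rep(0, sum(t <= 30) - 1))

  # monotone uptake of perfused tissue
  expect_true(all(diff(si) >= 0))

  # truth consistency
  expect_equal(mem$truth$deficit_fraction_true,
               100 * sum(mem$truth$ischemic_mask) /
                 sum(mem$labels$tissue == 2L))
})

test_that("simulation is deterministic under a fixed seed", {
  kin <- uptake_kinetics()
  spec <- small_spec(ischemic_sector = c(-40, 40), noise_sigma = 2,
                     bias_amplitude = 0.1, seed = 42L)
  a <- simulate_memri_dynamics(spec, kin)
  b <- simulate_memri_dynamics(spec, kin)
  expect_identical(a$series$data, b$series$data)
  sa <- simulate_vfa_stack(spec, 1490, 1000)
  sb <- simulate_vfa_stack(spec, 1490, 1000)
  expect_identical(sa$volumes[[3]]$data, sb$volumes[[3]]$data)
})

test_that("n_frames below 2 is rejected", {
  expect_error(uptake_kinetics(n_frames = 1), "n_frames")
})

test_that("VFA stack simulation equals the scalar closed form", {
  spec <- small_spec()
  tt <- phantom_t1_truth(spec, t1_myo_ms = 1490, m0 = 1000)
  st <- simulate_vfa_stack(spec, tt$t1, tt$m0, noise_sigma = 0,
                           bias_amplitude = 0)
  myo <- st$mask
  for (j in seq_along(st$flip_angles_deg)) {
    expected <- spgr_signal(st$flip_angles_deg[j], 1000, 1490, st$tr_ms)
    expect_equal(unique(st$volumes[[j]]$data[myo]), expected,
                 tolerance = 1e-12)
  }
  expect_error(simulate_vfa_stack(spec, tt$t1, tt$m0,
                                  flip_angles_deg = c(0, 5)),
               "flip angles")
  bad_t1 <- tt$t1; bad_t1[which(myo)[1]] <- -5
  expect_error(simulate_vfa_stack(spec, bad_t1, tt$m0), "non-positive T1")
})

test_that("LGE phantom records its enhanced fraction exactly", {
  spec <- small_spec()
  # designed enhanced fraction 34 %LV: sector width 3.6 * 34 degrees
  w <- 3.6 * 34
  lge <- simulate_lge_volume(spec, c(-w / 2, w / 2), enhancement_factor = 2)
  myo <- lge$labels$tissue == 2L
  quantum <- 100 / sum(myo)
  # voxel-count oracle on the sector mask
  expect_equal(lge$truth$enhanced_fraction_true,
               100 * sum(lge$truth$enhanced_mask) / sum(myo))
  expect_lt(abs(lge$truth$enhanced_fraction_true - 34), 1 + quantum)

  # lateral-confined enhancement never touches the septum
  lat <- simulate_lge_volume(spec, c(-44, 44), enhancement_factor = 1.01)
  sect <- lat$labels$sector[lat$truth$enhanced_mask]
  expect_false(any(sect == sector_codes[["septal"]]))

  # near-unity factor, zero noise: septal mean + 2SD (SD = 0) recovers
  # the enhanced sector exactly
  ref <- septal_reference(lat$volume, lat$labels)
  expect_equal(ref$sd, 0)
  res <- threshold_fraction(lat$volume, lat$labels, ref, k = 2)
  expect_equal(res$fraction_pct_lv, lat$truth$enhanced_fraction_true)

  expect_error(simulate_lge_volume(spec, c(-30, 30), enhancement_factor = 1),
               "exceed 1")
})

test_that("cine interpolation hits the ED/ES endpoints and orders volumes", {
  spec <- small_spec()
  two <- simulate_cine(spec, 2)
  expect_identical(two$frames[[1]]$tissue,
                   make_lv_labelmap(spec, "ED")$tissue)
  expect_identical(two$frames[[2]]$tissue,
                   make_lv_labelmap(spec, "ES")$tissue)

  cine <- simulate_cine(spec, 20)
  vols <- cine$truth$cavity_volume_true_ul
  expect_equal(which.max(vols), 1L)
  expect_true(all(vols[1] >= vols))
  expect_equal(cine$truth$ef_true_pct,
               100 * (max(vols) - min(vols)) / max(vols))
  expect_error(simulate_cine(spec, 1), "n_frames")
})
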