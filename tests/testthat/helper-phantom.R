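# Small, fast phantom used throughout the unit tests; the acceptance
# tests use the full default matrix/FOV instead.
small_spec <- function(...) {
  args <- list(...)
  defaults <- list(grid_shape = c(60L, 56L, 4L),
                   voxel_mm = c(0.25, 0.25, 0.8),
                   noise_sigma = 0, bias_amplitude = 0)
  do.call(phantom_spec, utils::modifyList(defaults, args))
}

# a label map whose myocardium is every voxel of the given dims
# (sector: lateral), used for voxelwise regression oracles
all_myo_labels <- function(dims, voxel_mm = c(1, 1, 1)) {
  tissue <- array(2L, dims)
  sector <- array(sector_codes[["lateral"]], dims)
  label_map(tissue, sector, voxel_mm)
}

# closed-form uptake trajectories, written independently of the package
# internals, for generator-oracle comparisons
oracle_si_perfused <- function(t, s0, u_max, tau) s0 * (1 + u_max * (1 - exp(-t / tau)))
oracle_si_ischemic <- function(t, s0, d_rate, t_occ) s0 * (1 - d_rate * pmin(t, t_occ))
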