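# Shared synthetic scenarios built from package generators.

flowering_params <- function(seed, n_days = 150) {
  stage_params("flowering_fruit_setting", n_days = n_days,
               mean_dar = 83.67, mean_vpd = 0.48, mean_ta = 21.27,
               mean_w = 0.10, seed = seed)
}

picking_params <- function(seed, n_days = 150) {
  stage_params("picking", n_days = n_days, mean_dar = 99.21,
               mean_vpd = 0.84, mean_ta = 26.23, mean_w = 0.17,
               seed = seed)
}

# Daily LAI rising logistically through the flowering stage. The segmented
# model's flowering branch applies from unit LAI up to the plateau, so the
# trajectory is floored at 1 (the crop enters flowering near unit LAI).
flowering_lai <- function(n_days, lai_max = 2.64) {
  traj <- generate_lai_trajectory(
    lai_params(lai_max = lai_max, midpoint_day = 0.25 * n_days, rate = 0.15,
               measurement_days = seq_len(n_days)))$lai_true
  pmax(traj, 1)
}

# Flowering-stage dataset generated from the published coefficients.
flowering_scenario <- function(seed, n_days = 150, noise_sd = 0.05) {
  micro <- generate_microclimate(flowering_params(seed, n_days))
  lai <- flowering_lai(n_days)
  tm <- generate_transpiration(micro, lai, published_coefficients("flowering"),
                               noise_sd = noise_sd, seed = seed + 1000)
  cbind(micro, lai = lai, tm = tm$tm)
}
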