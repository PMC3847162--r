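# Shared fixture builders. Everything is generated in code, seeded.

# tracks for a population with given CV / non-grower fraction
make_fixture_tracks <- function(n = 300, cv = 0.3, frac_nongrower = 0,
                                noise_cv = 0.05, n_frames = 25, seed = 1,
                                mean_rate = log(2) / 8.4) {
  cfg <- generator_config(seed = seed, n_cells = n, mean_rate = mean_rate,
                          cv = cv, frac_nongrower = frac_nongrower,
                          noise_cv = noise_cv, n_frames = n_frames)
  rates <- gen_growth_rates(cfg)
  list(config = cfg, rates = rates,
       tracks = gen_colony_trajectories(rates, cfg))
}

# run fits + exclusions on a track table
fit_pipeline <- function(tracks, ...) {
  apply_exclusions(fit_colonies(tracks, ...), tracks)
}

# rasterized-disk pixel count: independent oracle for the image renderer
disk_pixel_count <- function(radius, cx, cy, shape = c(64, 64)) {
  cols <- matrix(rep(seq_len(shape[2]), each = shape[1]), nrow = shape[1])
  rows <- matrix(rep(seq_len(shape[1]), times = shape[2]), nrow = shape[1])
  sum((cols - cx)^2 + (rows - cy)^2 <= radius^2)
}
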