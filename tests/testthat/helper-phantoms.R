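# shared fixtures, built in code at test time

small_maize_spec <- function(n_bundles = 12, speck_count = 0, rotation = 20,
                             noise_sd = 6) {
  phantom_spec(plant_type = "pith-filled",
               outer_semi_axes = c(150, 130),
               inner_semi_axes = c(115, 95),
               rotation = rotation,
               n_bundles = n_bundles,
               bundle_radius_range = c(6, 8),
               bundle_min_separation = 21,
               speck_count = speck_count,
               noise_sd = noise_sd,
               px_per_mm = 50)
}

small_hollow_spec <- function(rotation = 0, noise_sd = 6, speck_count = 0,
                              outer = c(140, 120), inner = c(100, 80)) {
  phantom_spec(plant_type = "hollow",
               outer_semi_axes = outer, inner_semi_axes = inner,
               rotation = rotation, n_bundles = 0,
               speck_count = speck_count, noise_sd = noise_sd,
               px_per_mm = 50)
}

default_config <- function(spec, ...) {
  pipeline_config(plant_type = spec$plant_type, px_per_mm = spec$px_per_mm, ...)
}

# circular disk mask for constructing masks directly
disk_mask <- function(side, center, radius) {
  x <- matrix(0:(side - 1), side, side, byrow = TRUE) - center[1]
  y <- matrix(0:(side - 1), side, side) - center[2]
  x * x + y * y <= radius^2
}

# population-variance brute-force Otsu (independent oracle)
otsu_brute_force <- function(vals) {
  pvar <- function(x) mean((x - mean(x))^2)
  best <- Inf; bt <- NA_integer_
  for (t in 0:254) {
    lo <- vals[vals <= t]; hi <- vals[vals > t]
    if (length(lo) == 0 || length(hi) == 0) next
    w <- (length(lo) * pvar(lo) + length(hi) * pvar(hi)) / length(vals)
    if (w < best) { best <- w; bt <- t }
  }
  bt
}
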