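# Shared fixtures: parameterized synthetic scenes and small utilities.

iou <- function(a, b) sum(a & b) / sum(a | b)

`%||%` <- function(a, b) if (is.null(a)) b else a

# battery of scenes varying shape, rotation, colour jitter and noise;
# every scene keeps the leaf green-dominant (the acquisition assumption)
scene_battery <- function(n = 20) {
  lapply(seq_len(n), function(i) {
    shape <- list(
      type = c("ellipse", "superellipse", "rectangle")[1 + i %% 3],
      center_px = c(240 + 10 * ((i %% 5) - 2), 240 - 8 * ((i %% 3) - 1)),
      semi_axes_px = c(90 + 6 * (i %% 7), 40 + 4 * (i %% 5)),
      rotation_deg = 17 * i,
      exponent = 2 + (i %% 3))
    scene_spec(
      leaf_shape = shape,
      leaf_color_mean = c(50 + 2 * (i %% 6), 135 + 3 * (i %% 8),
                          60 + 2 * (i %% 5)),
      leaf_color_sd = c(4, 5 + (i %% 4), 4),
      noise_sd = 1 + (i %% 3),
      seed = 1000L + i)
  })
}

# interior-hole audit: every background pixel must reach the border
# through background (4-connectivity)
has_interior_holes <- function(mask) {
  bg <- matrix(as.integer(mask == 0), nrow(mask), ncol(mask))
  lab <- as.matrix(EBImage::bwlabel(bg))
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  any(!unique(lab[lab > 0]) %in% border)
}

# quick simulated train/test pair for model tests
sim_pair <- function(n_train, n_test, stage = "growing", noise = 0.2,
                     seed = 5L) {
  list(train = simulate_dataset(sim_spec(n_train, stage,
                                         noise_sd_gkg = noise, seed = seed)),
       test = simulate_dataset(sim_spec(n_test, stage,
                                        noise_sd_gkg = noise,
                                        seed = seed + 1L)))
}
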