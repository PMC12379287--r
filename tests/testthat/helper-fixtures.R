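# Small fixtures shared across test files. Everything is generated in code;
# sizes are kept small so the whole suite runs in seconds per file.

# A compact in vivo-style configuration for simulation tests.
small_config <- function(rows = 40, cols = 48, spacing = 0.2) {
  cfg <- build_schedule("L22-14v in vivo")
  cfg$image_rows <- as.integer(rows)
  cfg$image_cols <- as.integer(cols)
  cfg$axial_spacing <- spacing
  cfg$lateral_spacing <- spacing
  cfg
}

# Uniform-background scene with an optional single gas-vesicle pixel.
point_scene <- function(cfg, amplitude = 0,
                        at = pmin(c(20, 24),
                                  c(cfg$image_rows, cfg$image_cols)),
                        speckle_scale = 0, noise_sd = 0, seed = 1,
                        motion_events = list(),
                        profile = NULL) {
  mode <- if (cfg$mode == "burst_invitro") "burst_invitro" else "burst_star"
  if (is.null(profile)) {
    profile <- default_collapse_profile(mode, cfg$n_high_frames)
  }
  gv <- matrix(0, cfg$image_rows, cfg$image_cols)
  if (amplitude > 0) gv[at[1], at[2]] <- amplitude
  scene_truth(
    gv_map = gv,
    background_map = matrix(1, cfg$image_rows, cfg$image_cols),
    collapse_profile = profile, mode = mode,
    motion_events = motion_events,
    speckle_scale = speckle_scale, noise_sd = noise_sd, seed = seed
  )
}

# A random (valid) frame stack for oracle-equivalence tests.
random_stack <- function(cfg, seed) {
  set.seed(seed)
  n <- cfg$n_low_frames + cfg$n_high_frames
  frames <- array(stats::runif(n * cfg$image_rows * cfg$image_cols),
                  dim = c(n, cfg$image_rows, cfg$image_cols))
  frame_stack(frames, frame_voltages(cfg), cfg)
}

# recon_image wrapper for hand-built matrices (assembly tests).
fake_recon <- function(pixels, kind = "burst_star", spacing = 0.2,
                       excluded = FALSE) {
  structure(
    list(pixels = pixels, kind = kind, frames_used = c(2L, 3L),
         excluded = excluded, reason = if (excluded) "test" else NULL,
         spacing = c(spacing, spacing)),
    class = "recon_image"
  )
}
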