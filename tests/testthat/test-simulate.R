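test_that("a static gas-vesicle-free noiseless scene yields identical frames", {
  cfg <- small_config()
  st <- simulate_acquisition(cfg, point_scene(cfg, speckle_scale = 1))
  idx <- collapsing_frames(st)
  for (f in idx[-1]) {
    expect_equal(st$frames[f, , ], st$frames[idx[1], , ])
  }
  expect_equal(max(abs(burst_star(st)$pixels)), 0)
  expect_equal(max(abs(burst_invitro(st)$pixels)), 0)
})

test_that("single gv pixel without speckle/noise matches the closed form", {
  cfg <- small_config()
  a <- 2.5
  prof <- default_collapse_profile(n_frames = cfg$n_high_frames)
  st <- simulate_acquisition(cfg, point_scene(cfg, amplitude = a))
  idx <- collapsing_frames(st)
  # collapsing frame 2 minus 1 at the gv pixel = a * (c2 - c1)
  expect_equal(st$frames[idx[2], 20, 24] - st$frames[idx[1], 20, 24],
               a * (prof[2] - prof[1]), tolerance = 1e-12)
  # low-voltage frame carries the pre-collapse visibility c_low
  expect_equal(st$frames[1, 20, 24], 1 + a * 0.1 * prof[1], tolerance = 1e-12)
})

test_that("simulation is a pure function of parameters and seed", {
  cfg <- small_config(rows = 24, cols = 24)
  sc <- point_scene(cfg, amplitude = 1, speckle_scale = 1, noise_sd = 0.1,
                    seed = 42)
  s1 <- simulate_acquisition(cfg, sc)
  s2 <- simulate_acquisition(cfg, sc)
  expect_identical(s1$frames, s2$frames)
  sc2 <- point_scene(cfg, amplitude = 1, speckle_scale = 1, noise_sd = 0.1,
                     seed = 43)
  s3 <- simulate_acquisition(cfg, sc2)
  expect_false(identical(s1$frames, s3$frames))
  # simulation does not disturb the caller's RNG stream
  set.seed(7); before <- rnorm(1)
  set.seed(7); invisible(simulate_acquisition(cfg, sc)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("speckle is unit-mean, right-skewed, and shared across frames", {
  cfg <- small_config(rows = 64, cols = 64)
  sc <- point_scene(cfg, speckle_scale = 1, seed = 5)
  st <- simulate_acquisition(cfg, sc)
  f1 <- st$frames[1, , ]
  expect_equal(mean(f1), 1, tolerance = 0.05)
  skew <- mean((f1 - mean(f1))^3) / stats::sd(f1)^3
  expect_gt(skew, 0.5)
  idx <- collapsing_frames(st)
  expect_equal(st$frames[idx[1], , ], f1)   # same realization on every frame
})

test_that("collapse-profile invariants hold and drive frame-mean ordering", {
  p_star <- default_collapse_profile("burst_star", 7)
  expect_gt(p_star[2], p_star[1])
  expect_lte(p_star[7], p_star[1])
  p_vitro <- default_collapse_profile("burst_invitro", 46)
  expect_gt(p_vitro[1], p_vitro[46])
  expect_error(
    scene_truth(matrix(1, 4, 4), matrix(1, 4, 4),
                collapse_profile = c(1, 0.5, 0.2), mode = "burst_star"),
    "rise"
  )

  cfg <- small_config()
  st <- simulate_acquisition(cfg, point_scene(cfg, amplitude = 3))
  idx <- collapsing_frames(st)
  gv_px <- which(st$truth$gv_map > 0)
  expect_gt(mean(st$frames[idx[2], , ][gv_px]),
            mean(st$frames[idx[1], , ][gv_px]))
})

test_that("motion events warp the frame, decorrelate speckle, and set flags", {
  cfg <- small_config()
  ev <- motion_event(2, displacement = c(0.6, 0.4), decorrelation = 1)
  sc <- point_scene(cfg, speckle_scale = 1, noise_sd = 0,
                    motion_events = list(ev), seed = 3)
  st <- simulate_acquisition(cfg, sc)
  moved <- cfg$n_low_frames + 2L
  expect_true(st$motion_flags[moved])
  expect_equal(sum(st$motion_flags), 1L)
  idx <- collapsing_frames(st)
  cor_moved <- stats::cor(as.vector(st$frames[idx[1], , ]),
                          as.vector(st$frames[moved, , ]))
  expect_lt(cor_moved, 0.5)
  expect_error(motion_event(1, decorrelation = 1.2), "decorrelation")
})

test_that("a planned scan yields one stack per position sampling its cell", {
  cfg <- small_config(rows = 30, spacing = 0.2)
  plan <- plan_in_vivo_scan(3, 9.6, 5, 0.5)
  truth <- blank_scan_truth(plan, cfg, noise_sd = 0)
  # inclusion at station 4, lateral world 15 mm -> middle stage cell (step
  # width 9.6 mm = 48 px; cell 2 spans 9.6-19.2 mm)
  truth <- place_inclusion(truth, 4, 3, 15, 0.8, 2, 0.2, 0.2)
  scans <- simulate_scan(plan, truth, cfg, seed = 1)
  expect_length(scans$stacks, 15)
  sums <- vapply(scans$stacks, function(st) {
    sum(abs(burst_star(st)$pixels))
  }, numeric(1))
  hot <- which(sums > 1e-9)
  pos <- scans$positions[hot, ]
  expect_true(all(pos$longitudinal_index == 4))
  expect_true(all(pos$lateral_index == 2))
  expect_error(simulate_scan(plan_in_vivo_scan(2, 9.6, 5, 0.5), truth, cfg),
               "extent")
})

test_that("full-size plan simulates 240 stacks", {
  cfg <- small_config(rows = 12, cols = 12, spacing = 0.2)
  plan <- plan_in_vivo_scan(3, 9.6, 80, 0.5)
  truth <- blank_scan_truth(plan, cfg, speckle_scale = 0, noise_sd = 0)
  scans <- simulate_scan(plan, truth, cfg, seed = 1)
  expect_length(scans$stacks, 240)
})

test_that("dose-response simulator honours the Hill model and its seed", {
  # half-max identity: noiseless value at K is (y0 + ymax) / 2 for any n
  for (n in c(0.7, 1, 2.4)) {
    expect_equal(hill_response(50, 2, 80, 50, n), 41)
  }
  expect_equal(hill_response(0, 2, 80, 50, 1.5), 2)
  tab0 <- simulate_dose_response(y0 = 3, noise_cv = 0, seed = 1)
  expect_equal(mean(tab0$response[tab0$concentration == 0]), 3)
  t1 <- simulate_dose_response(seed = 5)
  t2 <- simulate_dose_response(seed = 5)
  expect_identical(t1, t2)
  expect_error(simulate_dose_response(y0 = 5, ymax = 2), "ymax")
  expect_error(simulate_dose_response(half_max_conc = -1), "half_max_conc")
})

test_that("patch-plate simulator plants measurable effects and rejects overlap", {
  effects <- c(parent_0 = 5, parent_1 = 60, null = 0)
  plate <- simulate_patch_plate(effects, noise_sd = 0, seed = 2)
  m <- measure_plate(plate)
  # background subtraction removes the gradient: corrected ~ true effect
  expect_equal(m$corrected, unname(effects), tolerance = 0.05)
  # zero-effect patch on (gradient) background -> corrected ~ 0
  expect_lt(abs(m$corrected[m$strain_id == "null"]), 0.05)
  expect_error(simulate_patch_plate(1:5, spacing_px = 10), "overlap")
})

test_that("flow simulator produces the requested mixture", {
  ev0 <- simulate_flow_sample(2000, frac_positive = 0, seed = 1)
  expect_equal(gate_and_summarize(ev0)$gfp_positive_fraction, 0,
               tolerance = 0.01)
  ev <- simulate_flow_sample(20000, frac_positive = 0.5, seed = 2)
  frac <- gate_and_summarize(ev)$gfp_positive_fraction
  # binomial 99.9% CI half-width at n = 20000 is ~0.012
  expect_lt(abs(frac - 0.5), 0.015)
  expect_identical(simulate_flow_sample(100, seed = 3),
                   simulate_flow_sample(100, seed = 3))
})
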