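test_that("stitching at full image width concatenates blocks bit-identically", {
  set.seed(1)
  imgs <- lapply(1:3, function(i) fake_recon(matrix(runif(40 * 48), 40, 48)))
  plane <- stitch_transverse(imgs, lateral_step_mm = 9.6,
                             lateral_spacing = 0.2)
  expect_equal(dim(plane), c(40, 144))
  expect_identical(plane[, 1:48], imgs[[1]]$pixels)
  expect_identical(plane[, 49:96], imgs[[2]]$pixels)
  expect_identical(plane[, 97:144], imgs[[3]]$pixels)
})

test_that("a point in the middle acquisition lands at its stage offset", {
  blank <- matrix(0, 40, 48)
  mid <- blank; mid[10, 7] <- 5
  imgs <- list(fake_recon(blank), fake_recon(mid), fake_recon(blank))
  plane <- stitch_transverse(imgs, 9.6, 0.2)
  expect_equal(which(plane == 5, arr.ind = TRUE)[1, ],
               c(row = 10, col = 48 + 7))
})

test_that("crop policy keeps the central step-width block", {
  # image wider than the stage step: 60 px vs 48-px step
  wide <- matrix(rep(1:60, each = 40), 40, 60)
  plane <- stitch_transverse(list(fake_recon(wide)), 9.6, 0.2,
                             policy = "crop")
  expect_equal(dim(plane), c(40, 48))
  expect_equal(plane[1, ], 7:54)   # centred crop
  # narrower image: zero-padded, centred
  narrow <- matrix(1, 40, 40)
  plane2 <- stitch_transverse(list(fake_recon(narrow)), 9.6, 0.2)
  expect_equal(dim(plane2), c(40, 48))
  expect_equal(sum(plane2 == 0), 40 * 8)
  expect_error(stitch_transverse(list(fake_recon(matrix(0, 40, 48)),
                                      fake_recon(matrix(0, 30, 48))), 9.6),
               "axial")
})

test_that("motion-excluded blocks are zeroed in BURST* but kept in B-mode", {
  px <- matrix(1, 40, 48)
  excl_star <- fake_recon(px, "burst_star", excluded = TRUE)
  ok_star <- fake_recon(px, "burst_star")
  plane <- stitch_transverse(list(ok_star, excl_star), 9.6, 0.2)
  expect_equal(sum(plane[, 1:48]), 40 * 48)
  expect_equal(sum(plane[, 49:96]), 0)
  excl_bmode <- fake_recon(px, "bmode", excluded = TRUE)
  plane_b <- stitch_transverse(list(excl_bmode), 9.6, 0.2)
  expect_equal(sum(plane_b), 40 * 48)   # anatomy retained
})

simulated_volume <- function(seed = 1, noise_sd = 0, dilate = 2,
                             motion_table = NULL) {
  cfg <- small_config(rows = 50, spacing = 0.2)
  plan <- plan_in_vivo_scan(3, 9.6, 6, 0.5)
  truth <- blank_scan_truth(plan, cfg, noise_sd = noise_sd)
  truth <- place_inclusion(truth, 3, 5, 14, 0.2, 2, 0.2, 0.2)
  scans <- simulate_scan(plan, truth, cfg, seed = seed,
                         motion_table = motion_table)
  recons <- reconstruct_scan(scans)
  list(truth = truth, recons = recons,
       vol = build_volume(recons, roi_from_truth(truth, dilate)))
}

test_that("masking zeroes BURST* outside ROIs and records exclusions", {
  sv <- simulated_volume()
  vol <- sv$vol
  expect_s3_class(vol, "gv_volume")
  expect_equal(dim(vol$burst_star), c(6, 50, 144))
  expect_true(all(vol$burst_star[!vol$mask] == 0))
  # inclusion inside the mask: masked total equals unmasked reconstruction
  unmasked <- sum(vapply(sv$recons$burst_star,
                         function(im) sum(im$pixels), numeric(1)))
  expect_equal(total_signal(vol), unmasked, tolerance = 1e-12)
  # all-zero ROI set -> zero total
  empty_rois <- roi_set(lapply(1:6, function(j) matrix(FALSE, 50, 144)))
  vol0 <- build_volume(sv$recons, empty_rois)
  expect_equal(total_signal(vol0), 0)
})

test_that("enlarging a mask never decreases the noise-free total signal", {
  sv <- simulated_volume()
  small <- total_signal(build_volume(sv$recons, roi_from_truth(sv$truth, 0)))
  big <- total_signal(build_volume(sv$recons, roi_from_truth(sv$truth, 4)))
  expect_gte(big, small)
})

test_that("missing plane masks warn (or reject in strict mode)", {
  sv <- simulated_volume()
  short_rois <- roi_set(lapply(1:3, function(j) matrix(TRUE, 50, 144)))
  w <- testthat::capture_warnings(build_volume(sv$recons, short_rois))
  expect_length(w, 3)   # one warning per uncovered station
  expect_match(w, "no ROI mask", all = TRUE)
  expect_error(build_volume(sv$recons, short_rois, strict = TRUE),
               "no ROI mask")
})

test_that("breathing exclusions zero the BURST* channel voxelwise", {
  mt <- tibble::tibble(lateral_index = 2L, longitudinal_index = 3L,
                       frame_index = 2L, displacement_axial_mm = 0.6,
                       displacement_lateral_mm = 0.4, decorrelation = 1)
  sv <- simulated_volume(noise_sd = 0.05, motion_table = mt)
  expect_true(any(sv$recons$screening$excluded))
  vol <- sv$vol
  # the inclusion sits in the excluded acquisition's cell -> zeroed
  expect_true(all(vol$burst_star[3, , 49:96] == 0))
  expect_true(all(vol$exclusion_map[3, , 49:96]))
  # B-mode keeps anatomy there
  expect_gt(sum(vol$bmode[3, , 49:96]), 0)
})

test_that("geometry round-trip: the inclusion localizes at its true voxel", {
  sv <- simulated_volume()
  vol <- sv$vol
  peak <- which(vol$burst_star == max(vol$burst_star), arr.ind = TRUE)[1, ]
  # truth: station 3, depth 5 mm -> row 25, world lateral 14 mm -> col 70
  expect_equal(unname(peak[1]), 3)
  expect_lte(abs(peak[2] - 25), 1)
  expect_lte(abs(peak[3] - 70), 1)
})

test_that("ex vivo assembly carries signed landmark-relative coordinates", {
  cfg <- small_config(rows = 70, cols = 48)
  plan <- plan_in_vivo_scan(1, 9.6, 12, 1)
  truth <- blank_scan_truth(plan, cfg, noise_sd = 0)
  truth <- place_inclusion(truth, 9, 6, 4.8, 1, 2, 0.2, 0.2)
  scans <- simulate_scan(plan, truth, cfg, seed = 2)
  ser <- assemble_ex_vivo(scans$stacks, step_mm = 1, landmark_station = 5)
  expect_equal(ser$length_mm[1], -4)   # station 1 is 4 mm proximal
  expect_equal(ser$length_mm[12], 7)
  prof <- ex_vivo_profile(ser, depth_range = c(4, 12))
  expect_equal(prof$length_mm[which.max(prof$burst_star)], 4)  # station 9
  expect_error(assemble_ex_vivo(list(), landmark_station = 1), "empty")
  expect_error(assemble_ex_vivo(scans$stacks, landmark_station = 5,
                                stations = c(1, 3, 2, seq(4, 12))),
               "increasing")
})
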