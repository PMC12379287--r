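test_that("SBR is the ratio of ROI means with its degenerate cases flagged", {
  img <- matrix(2, 10, 10)
  img[1:5, ] <- 10
  sample_roi <- matrix(FALSE, 10, 10); sample_roi[1:5, ] <- TRUE
  bg_roi <- matrix(FALSE, 10, 10); bg_roi[6:10, ] <- TRUE
  expect_equal(sbr(img, sample_roi, bg_roi), 5)
  expect_equal(sbr(img, bg_roi, bg_roi), 1)          # ROI against itself
  expect_equal(to_db(sbr(img, bg_roi, bg_roi)), 0)   # ... is 0 dB
  neg <- matrix(-1, 10, 10)
  expect_warning(out <- sbr(neg, sample_roi, bg_roi), "not positive")
  expect_true(is.na(out))
  expect_error(sbr(img, matrix(FALSE, 10, 10), bg_roi), "nonempty")
})

test_that("SBR increases with gas-vesicle amplitude on noise-free phantoms", {
  cfg <- build_schedule("L22-14v in vitro")
  cfg$image_rows <- 30L; cfg$image_cols <- 30L
  well <- matrix(FALSE, 30, 30); well[10:20, 10:20] <- TRUE
  bg <- matrix(FALSE, 30, 30); bg[1:5, ] <- TRUE
  prof <- default_collapse_profile("burst_invitro", cfg$n_high_frames)
  vals <- vapply(c(0.5, 1, 2, 4), function(a) {
    gv <- matrix(0, 30, 30); gv[well] <- a
    sc <- scene_truth(gv, matrix(1, 30, 30), collapse_profile = prof,
                      mode = "burst_invitro", speckle_scale = 0, seed = 1)
    img <- burst_invitro(simulate_acquisition(cfg, sc))
    # difference image has ~0 background; quantify against the B-mode bg
    mean(img$pixels[well]) / 1
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("dB conversion matches 20*log10 and is additive over products", {
  expect_equal(to_db(1), 0)
  expect_equal(to_db(10), 20)
  x <- c(0.3, 2.7, 91.2)
  expect_equal(to_db(x), 20 * log10(x), tolerance = 1e-12)
  expect_equal(to_db(3 * 7), to_db(3) + to_db(7), tolerance = 1e-12)
  expect_warning(out <- to_db(c(1, 0, -2)), "nonpositive")
  expect_equal(out, c(0, NA, NA))
})

test_that("display constants table is exact", {
  expect_equal(display_params("burst", "L22-14v")[c("A", "B")],
               list(A = 3, B = 1))
  expect_equal(display_params("burst", "L22-14vX")[c("A", "B")],
               list(A = 2, B = 0.5))
  expect_equal(display_params("xam", "L22-14v")[c("A", "B")],
               list(A = 2, B = 0.5))
  expect_equal(display_params("xam", "L22-14vX")[c("A", "B")],
               list(A = 2, B = 0.4))
})

test_that("display normalization shares limits and is scale invariant", {
  set.seed(4)
  imgs <- list(matrix(runif(100, 1, 3), 10, 10),
               matrix(runif(100, 2, 8), 10, 10))
  bg <- matrix(FALSE, 10, 10); bg[9:10, ] <- TRUE
  p <- display_params("burst", "L22-14v")
  out <- normalize_display(imgs, bg, p)
  # limits computed once from the pooled set
  expect_equal(out$limits_db[1], 20 * log10(3))
  expect_equal(out$limits_db[2],
               20 * log10(1 * max(unlist(out$normalized))))
  # applying a common gain leaves the display output identical
  out2 <- normalize_display(lapply(imgs, function(m) 17 * m), bg, p)
  expect_equal(out2$images, out$images, tolerance = 1e-12)
  expect_equal(out2$limits_db, out$limits_db, tolerance = 1e-12)
  # an image equal to its background everywhere normalizes to 1, floored at A
  flat <- matrix(5, 10, 10)
  out3 <- normalize_display(list(flat), bg, p)
  expect_true(all(out3$normalized[[1]] == 1))
  expect_true(all(out3$images[[1]] == 20 * log10(3)))
})

test_that("depth windows are half-open with boundaries rounded down", {
  cfg <- small_config(rows = 60, spacing = 0.2)
  plan <- plan_in_vivo_scan(1, 9.6, 1, 0.5)
  truth <- blank_scan_truth(plan, cfg, speckle_scale = 0, noise_sd = 0)
  # impulse inside the 4-8 mm B-mode window and inside the ROI
  truth <- place_inclusion(truth, 1, 5, 4.8, 0.15, 3, 0.2, 0.2)
  # second impulse below the B-mode window (9 mm) but inside the ROI
  truth <- place_inclusion(truth, 1, 9, 2.4, 0.15, 3, 0.2, 0.2)
  scans <- simulate_scan(plan, truth, cfg, seed = 1)
  vol <- build_volume(suppressWarnings(reconstruct_scan(scans)),
                      roi_from_truth(truth, 1))
  maps <- integrate_2d(vol, bmode_depth_range = c(4, 8))
  col_shallow <- 24; col_deep <- 12
  base <- maps$bmode_2d[1, col_shallow + 10]
  expect_gt(maps$bmode_2d[1, col_shallow], base)  # in-window impulse adds
  expect_equal(maps$bmode_2d[1, col_deep], base)  # out-of-window does not
  expect_gt(maps$burst_2d[1, col_shallow], 0)     # BURST* spans full ROI
  expect_gt(maps$burst_2d[1, col_deep], 0)
  expect_error(integrate_2d(vol, c(4, 30)), "outside")
})

test_that("Fubini: the 2-D integrated BURST* map sums to the 3-D total", {
  cfg <- small_config(rows = 50, spacing = 0.2)
  plan <- plan_in_vivo_scan(2, 9.6, 4, 0.5)
  truth <- blank_scan_truth(plan, cfg, noise_sd = 0.05)
  truth <- place_inclusion(truth, 2, 5, 6, 1, 2, 0.2, 0.2)
  scans <- simulate_scan(plan, truth, cfg, seed = 6)
  vol <- build_volume(reconstruct_scan(scans), roi_from_truth(truth, 2))
  maps <- integrate_2d(vol)
  expect_equal(sum(maps$burst_2d), total_signal(vol), tolerance = 1e-12)
})

test_that("total signal is additive, signed by default, and scale linear", {
  cfg <- small_config(rows = 50, spacing = 0.2)
  plan <- plan_in_vivo_scan(2, 9.6, 4, 0.5)
  base <- blank_scan_truth(plan, cfg, speckle_scale = 0, noise_sd = 0)
  one <- place_inclusion(base, 1, 5, 4, 0.5, 2, 0.2, 0.2)
  two <- place_inclusion(base, 3, 6, 12, 0.5, 1, 0.2, 0.2)
  both <- place_inclusion(one, 3, 6, 12, 0.5, 1, 0.2, 0.2)
  tot <- function(tr) {
    scans <- simulate_scan(plan, tr, cfg, seed = 2)
    total_signal(build_volume(suppressWarnings(reconstruct_scan(scans)),
                              roi_from_truth(tr, 1)))
  }
  t1 <- tot(one); t2 <- tot(two); t12 <- tot(both)
  expect_equal(t12, t1 + t2, tolerance = 1e-10)
  expect_equal(total_signal(build_volume(
    suppressWarnings(reconstruct_scan(simulate_scan(plan, base, cfg,
                                                    seed = 2))),
    roi_set(lapply(1:4, function(j) matrix(FALSE, 50, 96))))), 0)
  # clip-at-zero variant never decreases the signed total
  scans <- simulate_scan(plan,
                         blank_scan_truth(plan, cfg, noise_sd = 0.1),
                         cfg, seed = 3)
  vol <- build_volume(reconstruct_scan(scans),
                      roi_set(lapply(1:4, function(j) matrix(TRUE, 50, 96))))
  expect_gte(total_signal(vol, clip_negative = TRUE), total_signal(vol))
})

test_that("total signal separates gv amplitudes monotonically", {
  cfg <- small_config(rows = 40, spacing = 0.2)
  plan <- plan_in_vivo_scan(1, 9.6, 2, 0.5)
  tots <- vapply(c(0, 1, 2, 4), function(a) {
    tr <- blank_scan_truth(plan, cfg, speckle_scale = 0, noise_sd = 0)
    if (a > 0) tr <- place_inclusion(tr, 1, 4, 4, 0.6, a, 0.2, 0.2)
    scans <- simulate_scan(plan, tr, cfg, seed = 4)
    rois <- roi_set(lapply(1:2, function(j) matrix(TRUE, 40, 48)))
    total_signal(build_volume(suppressWarnings(reconstruct_scan(scans)),
                              rois))
  }, numeric(1))
  expect_true(all(diff(tots) > 0))
})

test_that("overlay thresholding hides subthreshold pixels", {
  set.seed(9)
  burst <- matrix(rnorm(400), 20, 20)
  bm <- matrix(runif(400, 1, 2), 20, 20)
  ov <- overlay(burst, bm, threshold = max(burst) + 1)
  expect_false(any(ov$show))                       # pure B-mode output
  ov0 <- overlay(burst, bm, threshold = 0)
  expect_equal(ov0$show, burst > 0)                # all positive pixels shown
  ovq <- overlay(burst, bm, q = 0.975)
  expect_lte(mean(ovq$show), 1 - 0.975 + 1e-9)     # order-statistics bound
  expect_error(overlay(burst, bm[1:10, ]), "shape")
})

test_that("ex vivo profiles are linear in amplitude and zero for empty scenes", {
  cfg <- small_config(rows = 70, cols = 48)
  plan <- plan_in_vivo_scan(1, 9.6, 8, 1)
  mk <- function(a) {
    tr <- blank_scan_truth(plan, cfg, speckle_scale = 0, noise_sd = 0)
    if (a > 0) tr <- place_inclusion(tr, 5, 6, 4.8, 0.8, a, 0.2, 0.2)
    scans <- simulate_scan(plan, tr, cfg, seed = 5)
    ex_vivo_profile(assemble_ex_vivo(scans$stacks, 1, landmark_station = 2))
  }
  p0 <- mk(0); p1 <- mk(1); p2 <- mk(2)
  expect_true(all(p0$burst_star == 0))
  expect_equal(p2$burst_star, 2 * p1$burst_star, tolerance = 1e-12)
  expect_equal(p1$length_mm, (1:8) - 2)
})
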