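# Synthetic acquisition model.
#
# One acquisition is a stack of beamformed envelope frames. Pixel intensity of
# frame f at pixel p:
#
#   I_f(p) = background(p) * S(p) + gv(p) * c_f + eps_f(p)
#
# where S is ONE multiplicative, unit-mean, right-skewed speckle realization
# shared by all frames of a static scene (collapse differencing relies on
# frame-to-frame speckle correlation), c_f is the gas-vesicle visibility of
# frame f (a small pre-collapse value c_low on low-voltage frames, the
# collapse profile c_1..c_K on collapsing frames), and eps is independent
# zero-mean Gaussian noise with sd noise_sd / sqrt(accumulations). Frames with
# a motion event are translated and their speckle partially decorrelated.

.restore_rng <- function() {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  function() {
    if (has) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }
}

# Run expr under a fixed seed without disturbing the caller's RNG stream.
.with_seed <- function(seed, expr) {
  restore <- .restore_rng()
  on.exit(restore())
  set.seed(as.integer(seed))
  expr
}

#' Default gas-vesicle collapse profile
#'
#' Per-collapsing-frame visibility multipliers of the gas-vesicle signal.
#' For the in-vivo/ex-vivo (`burst_star`) convention the signal rises from the
#' first to the second collapsing frame, then decays: the 7-frame default is
#' `c(0.6, 1, 0.5, 0.25, 0.1, 0.05, 0)`; other lengths keep the 0.6 -> 1 rise
#' and halve from there. For the in-vitro (`burst_invitro`) convention the
#' first collapsing frame is brightest and the signal decays exponentially to
#' near zero by the last frame.
#'
#' @param mode `"burst_star"` or `"burst_invitro"`.
#' @param n_frames Number of collapsing frames (>= 2; >= 3 for burst_star).
#' @return Numeric vector of length `n_frames`.
#' @export
default_collapse_profile <- function(mode = c("burst_star", "burst_invitro"),
                                     n_frames = 7) {
  mode <- match.arg(mode)
  n_frames <- as.integer(n_frames)
  if (mode == "burst_star") {
    stopifnot("burst_star profile needs >= 3 collapsing frames" = n_frames >= 3)
    if (n_frames == 7) return(c(0.6, 1, 0.5, 0.25, 0.1, 0.05, 0))
    c(0.6, 1, 0.5 ^ seq_len(n_frames - 2))
  } else {
    stopifnot(n_frames >= 2)
    exp(-5 * (seq_len(n_frames) - 1) / (n_frames - 1))
  }
}

#' Ground truth for one simulated acquisition
#'
#' @param gv_map Matrix (axial x lateral) of gas-vesicle contrast amplitude,
#'   arbitrary linear units, nonnegative.
#' @param background_map Matrix of tissue echogenicity, same shape,
#'   nonnegative.
#' @param collapse_profile Per-collapsing-frame visibility multipliers; must
#'   rise from frame 1 to frame 2 then end at or below frame 1 for the
#'   burst_star conventions, or start highest and end lowest for
#'   burst_invitro. Checked against `mode`.
#' @param mode Reconstruction convention the profile is meant for.
#' @param c_low Pre-collapse gas-vesicle visibility on low-voltage frames
#'   (default a tenth of the first collapsing-frame value).
#' @param motion_events List of [motion_event()]s.
#' @param speckle_scale Speckle contrast in `[0, 1]`; 0 disables speckle.
#' @param noise_sd Additive noise standard deviation, linear units.
#' @param seed Integer seed driving every random draw for this scene.
#' @return A `scene_truth` object.
#' @export
scene_truth <- function(gv_map, background_map,
                        collapse_profile = default_collapse_profile(),
                        mode = c("burst_star", "burst_invitro"),
                        c_low = 0.1 * collapse_profile[1],
                        motion_events = list(),
                        speckle_scale = 1,
                        noise_sd = 0,
                        seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(
    "gv_map and background_map must be matrices of the same shape" =
      is.matrix(gv_map) && is.matrix(background_map) &&
      all(dim(gv_map) == dim(background_map)),
    "amplitudes must be nonnegative" =
      all(gv_map >= 0) && all(background_map >= 0),
    "collapse_profile must be nonnegative" = all(collapse_profile >= 0),
    "speckle_scale must be in [0, 1]" =
      speckle_scale >= 0 && speckle_scale <= 1,
    "noise_sd must be nonnegative" = noise_sd >= 0
  )
  K <- length(collapse_profile)
  stopifnot("collapse_profile needs >= 2 frames" = K >= 2)
  if (mode == "burst_star") {
    stopifnot(
      "burst_star profile must rise from frame 1 to frame 2" =
        collapse_profile[2] > collapse_profile[1],
      "burst_star profile must end at or below its first value" =
        collapse_profile[K] <= collapse_profile[1]
    )
  } else {
    stopifnot(
      "burst_invitro profile must start above its final value" =
        collapse_profile[1] > collapse_profile[K]
    )
  }
  for (ev in motion_events) {
    stopifnot(inherits(ev, "motion_event"),
              ev$frame_index >= 1, ev$frame_index <= K)
  }
  structure(
    list(
      gv_map = gv_map, background_map = background_map,
      collapse_profile = collapse_profile, mode = mode, c_low = c_low,
      motion_events = motion_events, speckle_scale = speckle_scale,
      noise_sd = noise_sd, seed = as.integer(seed)
    ),
    class = "scene_truth"
  )
}

#' A breathing-motion event on one collapsing frame
#'
#' @param frame_index Index into the collapsing frames (1 = first collapsing
#'   frame).
#' @param displacement Length-2 numeric, (axial mm, lateral mm) rigid
#'   translation of the scene during the frame.
#' @param decorrelation Fraction in `[0, 1]` of the speckle field replaced by
#'   a fresh realization (1 = fully decorrelated).
#' @return A `motion_event` object.
#' @export
motion_event <- function(frame_index, displacement = c(0, 0),
                         decorrelation = 1) {
  stopifnot(frame_index >= 1, length(displacement) == 2,
            "decorrelation must be in [0, 1]" =
              decorrelation >= 0 && decorrelation <= 1)
  structure(
    list(frame_index = as.integer(frame_index),
         displacement = as.numeric(displacement),
         decorrelation = decorrelation),
    class = "motion_event"
  )
}

# Unit-mean right-skewed speckle: squared magnitude of a smoothed complex
# Gaussian field (fully developed speckle is exponential; smoothing sets the
# lateral/axial correlation length in pixels).
.speckle_field <- function(rows, cols, corr_px = 2) {
  pad <- ceiling(3 * corr_px)
  re <- matrix(stats::rnorm((rows + 2 * pad) * (cols + 2 * pad)),
               rows + 2 * pad, cols + 2 * pad)
  im <- matrix(stats::rnorm((rows + 2 * pad) * (cols + 2 * pad)),
               rows + 2 * pad, cols + 2 * pad)
  k <- stats::dnorm(seq(-pad, pad), sd = corr_px)
  k <- k / sqrt(sum(k^2))
  blur <- function(m) {
    m <- apply(m, 2, function(col) stats::convolve(col, k, type = "open")[
      (pad + 1):(pad + length(col))])
    t(apply(t(m), 2, function(row) stats::convolve(row, k, type = "open")[
      (pad + 1):(pad + length(row))]))
  }
  z2 <- blur(re)^2 + blur(im)^2
  s <- z2[(pad + 1):(pad + rows), (pad + 1):(pad + cols), drop = FALSE]
  s / mean(s)
}

# Nearest-pixel rigid translation with zero padding outside the field of view.
.translate <- function(m, d_rows, d_cols) {
  out <- matrix(0, nrow(m), ncol(m))
  src_r <- seq_len(nrow(m)) - d_rows
  src_c <- seq_len(ncol(m)) - d_cols
  ok_r <- src_r >= 1 & src_r <= nrow(m)
  ok_c <- src_c >= 1 & src_c <= ncol(m)
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c], drop = FALSE]
  out
}

#' Multi-frame acquisition stack
#'
#' Container for one acquisition position: a `[frame, axial, lateral]` array
#' of nonnegative envelope intensities, the per-frame voltages, the
#' configuration, per-frame motion flags (ground truth when simulated) and an
#' optional stage position.
#'
#' @param frames 3-D array `[frame, axial, lateral]`, nonnegative.
#' @param voltages Per-frame voltages; length must match the frame count and
#'   the configuration's schedule.
#' @param config The [acquisition_config()].
#' @param motion_flags Per-frame logical; defaults to all `FALSE`.
#' @param position Optional stage position (named vector or list).
#' @param truth Optional [scene_truth()] used to simulate the stack.
#' @return A `frame_stack` object.
#' @export
frame_stack <- function(frames, voltages, config, motion_flags = NULL,
                        position = NULL, truth = NULL) {
  stopifnot(
    inherits(config, "acquisition_config"),
    is.array(frames), length(dim(frames)) == 3,
    "frame count must equal n_low_frames + n_high_frames" =
      dim(frames)[1] == config$n_low_frames + config$n_high_frames,
    "one voltage per frame required" = length(voltages) == dim(frames)[1],
    "envelope intensities must be nonnegative" = all(frames >= 0)
  )
  if (is.null(motion_flags)) motion_flags <- rep(FALSE, dim(frames)[1])
  stopifnot(length(motion_flags) == dim(frames)[1])
  structure(
    list(frames = frames, voltages = as.numeric(voltages), config = config,
         motion_flags = as.logical(motion_flags), position = position,
         truth = truth),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<frame_stack> %d frames of %d x %d px (%s, %s)%s\n",
    d[1], d[2], d[3], x$config$transducer_id, x$config$mode,
    if (any(x$motion_flags)) sprintf(", motion on frame(s) %s",
                                     paste(which(x$motion_flags),
                                           collapse = ", ")) else ""
  ))
  invisible(x)
}

#' Indices of the collapsing (high-voltage) frames of a stack
#'
#' @param stack A [frame_stack()].
#' @return Integer vector of frame indices.
#' @export
collapsing_frames <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  seq(stack$config$n_low_frames + 1L,
      stack$config$n_low_frames + stack$config$n_high_frames)
}

#' Simulate one acquisition from a ground-truth scene
#'
#' Applies the signal model described above: one speckle realization shared
#' across frames, per-frame gas-vesicle visibility from the collapse profile
#' (`c_low` on low-voltage frames), independent zero-mean noise with standard
#' deviation `noise_sd / sqrt(accumulations)`, and rigid translation plus
#' partial speckle decorrelation on motion-event frames (whose motion flags
#' are set in the output as ground truth for detector tests; the
#' reconstruction functions never read them). Identical `(config, scene)`
#' including the scene seed give bitwise-identical stacks.
#'
#' @param config An [acquisition_config()]; its `collapse profile` length must
#'   equal the scene's and its image extent must match the scene maps.
#' @param scene A [scene_truth()].
#' @param position Optional stage position forwarded to the stack.
#' @return A [frame_stack()] with `truth = scene`.
#' @export
simulate_acquisition <- function(config, scene, position = NULL) {
  stopifnot(inherits(config, "acquisition_config"),
            inherits(scene, "scene_truth"))
  rows <- nrow(scene$gv_map); cols <- ncol(scene$gv_map)
  if (rows != config$image_rows || cols != config$image_cols) {
    stop("scene maps (", rows, " x ", cols,
         ") do not match the configured image shape (",
         config$image_rows, " x ", config$image_cols, ")", call. = FALSE)
  }
  if (length(scene$collapse_profile) != config$n_high_frames) {
    stop("collapse profile length (", length(scene$collapse_profile),
         ") must equal n_high_frames (", config$n_high_frames, ")",
         call. = FALSE)
  }
  n_frames <- config$n_low_frames + config$n_high_frames
  eff_sd <- scene$noise_sd / sqrt(config$accumulations)

  .with_seed(scene$seed, {
    speckle <- if (scene$speckle_scale > 0) {
      1 + scene$speckle_scale * (.speckle_field(rows, cols) - 1)
    } else {
      matrix(1, rows, cols)
    }
    motion_by_frame <- vector("list", n_frames)
    for (ev in scene$motion_events) {
      motion_by_frame[[config$n_low_frames + ev$frame_index]] <- ev
    }
    frames <- array(0, dim = c(n_frames, rows, cols))
    flags <- rep(FALSE, n_frames)
    for (f in seq_len(n_frames)) {
      coef <- if (f <= config$n_low_frames) {
        scene$c_low
      } else {
        scene$collapse_profile[f - config$n_low_frames]
      }
      bg <- scene$background_map
      gv <- scene$gv_map
      spk <- speckle
      ev <- motion_by_frame[[f]]
      if (!is.null(ev)) {
        flags[f] <- TRUE
        d_rows <- round(ev$displacement[1] / config$axial_spacing)
        d_cols <- round(ev$displacement[2] / config$lateral_spacing)
        bg <- .translate(bg, d_rows, d_cols)
        gv <- .translate(gv, d_rows, d_cols)
        spk <- .translate(spk, d_rows, d_cols)
        if (ev$decorrelation > 0 && scene$speckle_scale > 0) {
          fresh <- 1 + scene$speckle_scale * (.speckle_field(rows, cols) - 1)
          spk <- (1 - ev$decorrelation) * spk + ev$decorrelation * fresh
        }
      }
      img <- bg * spk + gv * coef
      if (eff_sd > 0) img <- img + matrix(stats::rnorm(rows * cols, 0, eff_sd),
                                          rows, cols)
      frames[f, , ] <- pmax(img, 0)
    }
    frame_stack(frames, frame_voltages(config), config,
                motion_flags = flags, position = position, truth = scene)
  })
}

#' Ground truth for a whole stage scan
#'
#' Holds 3-D gas-vesicle and background fields covering the planned scan
#' extent: `[longitudinal station, axial pixel, stitched lateral pixel]`.
#' Each acquisition samples the lateral span of its stage cell at its
#' longitudinal station.
#'
#' @param gv,background 3-D arrays of identical shape (nonnegative).
#' @param collapse_profile,mode,c_low,speckle_scale,noise_sd Passed to each
#'   per-position [scene_truth()].
#' @return A `scan_truth` object.
#' @export
scan_truth <- function(gv, background,
                       collapse_profile = default_collapse_profile(),
                       mode = "burst_star",
                       c_low = 0.1 * collapse_profile[1],
                       speckle_scale = 1, noise_sd = 0) {
  stopifnot(is.array(gv), length(dim(gv)) == 3,
            all(dim(gv) == dim(background)),
            all(gv >= 0), all(background >= 0))
  structure(
    list(gv = gv, background = background,
         collapse_profile = collapse_profile, mode = mode, c_low = c_low,
         speckle_scale = speckle_scale, noise_sd = noise_sd),
    class = "scan_truth"
  )
}

#' Blank scan truth of the planned extent
#'
#' Convenience constructor: uniform background, zero gas-vesicle field, sized
#' so that each acquisition of `plan` under `config` samples its own stage
#' cell exactly.
#'
#' @param plan A [plan_in_vivo_scan()] result.
#' @param config An [acquisition_config()].
#' @param background_level Uniform tissue echogenicity.
#' @inheritParams scan_truth
#' @return A `scan_truth`.
#' @export
blank_scan_truth <- function(plan, config, background_level = 1,
                             collapse_profile = default_collapse_profile(
                               n_frames = config$n_high_frames),
                             speckle_scale = 1, noise_sd = 0) {
  step_px <- round(plan$lateral_step_mm / config$lateral_spacing)
  dims <- c(plan$longitudinal_steps, config$image_rows,
            plan$lateral_steps * step_px)
  scan_truth(
    gv = array(0, dims),
    background = array(background_level, dims),
    collapse_profile = collapse_profile,
    speckle_scale = speckle_scale, noise_sd = noise_sd
  )
}

#' Plant a spherical-ish inclusion in a scan truth
#'
#' Adds gas-vesicle amplitude in a disc of radius `radius_mm` (in the imaging
#' plane) at the given longitudinal station(s).
#'
#' @param truth A [scan_truth()].
#' @param longitudinal_index Station index (may be a range of stations).
#' @param axial_mm,lateral_mm Centre of the disc: depth below the transducer
#'   face and stitched lateral world coordinate, mm.
#' @param radius_mm In-plane radius, mm.
#' @param amplitude Gas-vesicle contrast amplitude to add.
#' @param axial_spacing,lateral_spacing Pixel pitch (mm/px) used to convert
#'   world coordinates to voxels.
#' @return The modified `scan_truth`.
#' @export
place_inclusion <- function(truth, longitudinal_index, axial_mm, lateral_mm,
                            radius_mm, amplitude,
                            axial_spacing = 0.1, lateral_spacing = 0.1) {
  stopifnot(inherits(truth, "scan_truth"), amplitude >= 0)
  dims <- dim(truth$gv)
  ax_px <- (seq_len(dims[2]) - 0.5) * axial_spacing
  lat_px <- (seq_len(dims[3]) - 0.5) * lateral_spacing
  disc <- outer(ax_px, lat_px, function(a, l)
    (a - axial_mm)^2 + (l - lateral_mm)^2 <= radius_mm^2)
  for (j in longitudinal_index) {
    stopifnot(j >= 1, j <= dims[1])
    truth$gv[j, , ][disc] <- truth$gv[j, , ][disc] + amplitude
  }
  truth
}

#' Simulate every acquisition of a planned stage scan
#'
#' One [simulate_acquisition()] per planned position, each sampling the slab
#' of `truth` under its stage cell, with a per-position child seed derived
#' from `seed` (seed + acquisition ordinal). Motion events can be injected at
#' named positions via `motion_table`.
#'
#' @param plan A [plan_in_vivo_scan()] result.
#' @param truth A [scan_truth()] covering the planned extent.
#' @param config An [acquisition_config()]; its lateral image width is set to
#'   the stage step width so the truth partitions exactly among positions.
#' @param seed Integer master seed.
#' @param motion_table Optional tibble/data.frame with columns
#'   `lateral_index`, `longitudinal_index`, `frame_index` (collapsing-frame
#'   ordinal), `displacement_axial_mm`, `displacement_lateral_mm`,
#'   `decorrelation`.
#' @return A `scan_set`: the plan, config, and one stack per position.
#' @export
simulate_scan <- function(plan, truth, config, seed = 1L,
                          motion_table = NULL) {
  stopifnot(inherits(plan, "scan_plan"), inherits(truth, "scan_truth"),
            inherits(config, "acquisition_config"))
  step_px <- round(plan$lateral_step_mm / config$lateral_spacing)
  dims <- dim(truth$gv)
  if (dims[1] != plan$longitudinal_steps ||
      dims[2] != config$image_rows ||
      dims[3] != plan$lateral_steps * step_px) {
    stop("scan truth extent ", paste(dims, collapse = " x "),
         " does not cover the planned ", plan$longitudinal_steps, " x ",
         config$image_rows, " x ", plan$lateral_steps * step_px,
         " (stations x axial px x stitched lateral px)", call. = FALSE)
  }
  cfg <- config
  cfg$image_cols <- as.integer(step_px)
  pos <- positions(plan)
  stacks <- vector("list", nrow(pos))
  for (i in seq_len(nrow(pos))) {
    li <- pos$lateral_index[i]; lj <- pos$longitudinal_index[i]
    cols <- ((li - 1) * step_px + 1):(li * step_px)
    events <- list()
    if (!is.null(motion_table)) {
      sel <- motion_table$lateral_index == li &
        motion_table$longitudinal_index == lj
      events <- purrr::pmap(
        motion_table[sel, , drop = FALSE],
        function(frame_index, displacement_axial_mm, displacement_lateral_mm,
                 decorrelation, ...) {
          motion_event(frame_index,
                       c(displacement_axial_mm, displacement_lateral_mm),
                       decorrelation)
        })
    }
    scene <- scene_truth(
      gv_map = matrix(truth$gv[lj, , cols], dims[2], step_px),
      background_map = matrix(truth$background[lj, , cols], dims[2], step_px),
      collapse_profile = truth$collapse_profile,
      mode = if (truth$mode == "burst_invitro") "burst_invitro"
             else "burst_star",
      c_low = truth$c_low,
      motion_events = events,
      speckle_scale = truth$speckle_scale,
      noise_sd = truth$noise_sd,
      seed = as.integer(seed) + i
    )
    stacks[[i]] <- simulate_acquisition(
      cfg, scene, position = list(lateral_index = li, longitudinal_index = lj))
  }
  structure(
    list(plan = plan, config = cfg, positions = pos, stacks = stacks,
         seed = as.integer(seed)),
    class = "scan_set"
  )
}

#' @export
print.scan_set <- function(x, ...) {
  cat(sprintf("<scan_set> %d acquisitions (%d x %d grid), seed %d\n",
              length(x$stacks), x$plan$lateral_steps,
              x$plan$longitudinal_steps, x$seed))
  invisible(x)
}
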