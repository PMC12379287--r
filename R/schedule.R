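#' Acquisition configuration for a collapse-based pulse sequence
#'
#' Bundles the frame schedule (how many low-voltage pre-collapse frames, how
#' many high-voltage collapsing frames, at which voltages), the transmit
#' parameters and the pixel geometry of one acquisition. Collapsing frames are
#' the frames acquired at the high (collapse) voltage; every reconstruction in
#' this package operates on them.
#'
#' @param transducer_id `"L22-14v"` or `"L22-14vX"`.
#' @param mode One of `"burst_invitro"`, `"burst_star_invivo"`,
#'   `"burst_star_exvivo"`. Selects the reconstruction convention downstream.
#' @param n_low_frames,n_high_frames Frame counts; at least one low frame and
#'   at least two collapsing frames (differencing needs two).
#' @param low_voltage,high_voltage Transmit voltages in volts;
#'   `high_voltage` must exceed `low_voltage`.
#' @param frequency Transmit frequency, MHz.
#' @param focus_depth Transmit focus, mm.
#' @param n_half_cycles Transmit waveform half-cycles.
#' @param accumulations Frame averaging count (modeled downstream as reduced
#'   noise, not explicit sub-frames).
#' @param beams_per_transmit Simultaneously transmitted focused beams.
#' @param axial_spacing,lateral_spacing Pixel pitch, mm/pixel.
#' @param image_rows,image_cols Simulated image extent in pixels.
#' @return An object of class `acquisition_config`.
#' @seealso [build_schedule()] for the named presets.
#' @export
acquisition_config <- function(transducer_id,
                               mode,
                               n_low_frames,
                               n_high_frames,
                               low_voltage,
                               high_voltage,
                               frequency = 18,
                               focus_depth = 6,
                               n_half_cycles = 3,
                               accumulations = 1,
                               beams_per_transmit = 1,
                               axial_spacing = 0.1,
                               lateral_spacing = 0.1,
                               image_rows = 128,
                               image_cols = 96) {
  transducer_id <- match.arg(transducer_id, c("L22-14v", "L22-14vX"))
  mode <- match.arg(mode, c("burst_invitro", "burst_star_invivo",
                            "burst_star_exvivo"))
  stopifnot(
    "n_low_frames must be >= 1" = n_low_frames >= 1,
    "n_high_frames must be >= 2 (differencing needs two collapsing frames)" =
      n_high_frames >= 2,
    "high_voltage must exceed low_voltage" = high_voltage > low_voltage,
    "pixel spacings must be positive" =
      axial_spacing > 0 && lateral_spacing > 0,
    "image extent must be positive" = image_rows >= 1 && image_cols >= 1,
    "accumulations must be >= 1" = accumulations >= 1,
    "beams_per_transmit must be >= 1" = beams_per_transmit >= 1
  )
  structure(
    list(
      transducer_id = transducer_id,
      mode = mode,
      n_low_frames = as.integer(n_low_frames),
      n_high_frames = as.integer(n_high_frames),
      low_voltage = low_voltage,
      high_voltage = high_voltage,
      frequency = frequency,
      focus_depth = focus_depth,
      n_half_cycles = as.integer(n_half_cycles),
      accumulations = as.integer(accumulations),
      beams_per_transmit = as.integer(beams_per_transmit),
      axial_spacing = axial_spacing,
      lateral_spacing = lateral_spacing,
      image_rows = as.integer(image_rows),
      image_cols = as.integer(image_cols)
    ),
    class = "acquisition_config"
  )
}

#' @export
print.acquisition_config <- function(x, ...) {
  cat(sprintf(
    "<acquisition_config> %s, %s\n  %d frame(s) at %.1f V + %d collapsing frame(s) at %.1f V\n  %.1f MHz, focus %.1f mm, %d half-cycles, %d accumulation(s), %d beam(s)/transmit\n  %d x %d px at %.3f x %.3f mm/px (axial x lateral)\n",
    x$transducer_id, x$mode, x$n_low_frames, x$low_voltage,
    x$n_high_frames, x$high_voltage, x$frequency, x$focus_depth,
    x$n_half_cycles, x$accumulations, x$beams_per_transmit,
    x$image_rows, x$image_cols, x$axial_spacing, x$lateral_spacing
  ))
  invisible(x)
}

#' Per-frame voltage schedule of a configuration
#'
#' @param config An [acquisition_config()].
#' @return Numeric vector, one voltage per frame, low frames first.
#' @export
frame_voltages <- function(config) {
  stopifnot(inherits(config, "acquisition_config"))
  c(rep(config$low_voltage, config$n_low_frames),
    rep(config$high_voltage, config$n_high_frames))
}

# Named schedules as used on the two transducers. In vitro, the L22-14v runs
# 10 frames at 1.6 V then 46 collapsing frames at 25 V; the L22-14vX runs one
# 1.6 V frame then 7 collapsing frames at 20 V with 3-beam multiplexing. In
# vivo both transducers run 1 + 7 frames (collapse at 25 V / 20 V). The ex
# vivo gut scan reuses the in vivo L22-14v schedule at an 8 mm focus.
.named_schedules <- function() {
  list(
    "L22-14v in vitro" = acquisition_config(
      "L22-14v", "burst_invitro",
      n_low_frames = 10, n_high_frames = 46,
      low_voltage = 1.6, high_voltage = 25,
      frequency = 18, focus_depth = 6, n_half_cycles = 3,
      accumulations = 50, beams_per_transmit = 1
    ),
    "L22-14vX in vitro" = acquisition_config(
      "L22-14vX", "burst_invitro",
      n_low_frames = 1, n_high_frames = 7,
      low_voltage = 1.6, high_voltage = 20,
      frequency = 18, focus_depth = 6, n_half_cycles = 3,
      accumulations = 50, beams_per_transmit = 3
    ),
    "L22-14v in vivo" = acquisition_config(
      "L22-14v", "burst_star_invivo",
      n_low_frames = 1, n_high_frames = 7,
      low_voltage = 1.6, high_voltage = 25,
      frequency = 18, focus_depth = 6, n_half_cycles = 3,
      beams_per_transmit = 3
    ),
    "L22-14vX in vivo" = acquisition_config(
      "L22-14vX", "burst_star_invivo",
      n_low_frames = 1, n_high_frames = 7,
      low_voltage = 1.6, high_voltage = 20,
      frequency = 18, focus_depth = 6, n_half_cycles = 2,
      beams_per_transmit = 3
    ),
    "L22-14v ex vivo" = acquisition_config(
      "L22-14v", "burst_star_exvivo",
      n_low_frames = 1, n_high_frames = 7,
      low_voltage = 1.6, high_voltage = 25,
      frequency = 18, focus_depth = 8, n_half_cycles = 3,
      beams_per_transmit = 3
    )
  )
}

#' Build one of the named acquisition schedules
#'
#' Returns the published frame schedule for a named transducer/context
#' combination: `"L22-14v in vitro"` (10 frames at 1.6 V, then 46 collapsing
#' frames at 25 V), `"L22-14vX in vitro"` (1 + 7 frames, collapse at 20 V),
#' `"L22-14v in vivo"` and `"L22-14vX in vivo"` (1 + 7 frames, collapse at
#' 25 V / 20 V, three beams per transmit), and `"L22-14v ex vivo"` (in vivo
#' schedule at 8 mm focus for the linearized-gut scan).
#'
#' @param config_name One of the names above.
#' @return An [acquisition_config()].
#' @examples
#' build_schedule("L22-14v in vitro")$n_high_frames  # 46
#' @export
build_schedule <- function(config_name) {
  schedules <- .named_schedules()
  if (!is.character(config_name) || length(config_name) != 1 ||
      !config_name %in% names(schedules)) {
    stop("unknown configuration name; known names: ",
         paste(sQuote(names(schedules)), collapse = ", "), call. = FALSE)
  }
  schedules[[config_name]]
}

#' Plan a rectangular in vivo stage scan
#'
#' Enumerates acquisition positions on a lateral-by-longitudinal stage grid in
#' row-major order (all lateral positions of the first longitudinal station,
#' then the next station), starting at the rib-cage landmark and moving toward
#' the tail. The whole-abdomen protocol uses three 9.6-mm lateral steps and
#' eighty 0.5-mm longitudinal steps, i.e. 240 acquisitions per animal.
#'
#' @param lateral_steps,longitudinal_steps Position counts (>= 1).
#' @param lateral_step_mm,longitudinal_step_mm Stage step sizes, mm (> 0).
#' @param start_landmark Anatomical starting landmark, recorded in the plan.
#' @return A `scan_plan` object; `positions(plan)` lists the grid.
#' @examples
#' plan <- plan_in_vivo_scan(3, 9.6, 80, 0.5)
#' nrow(positions(plan))  # 240
#' @export
plan_in_vivo_scan <- function(lateral_steps = 3, lateral_step_mm = 9.6,
                              longitudinal_steps = 80,
                              longitudinal_step_mm = 0.5,
                              start_landmark = "rib cage") {
  stopifnot(
    "step counts must be >= 1" = lateral_steps >= 1 && longitudinal_steps >= 1,
    "step sizes must be > 0" = lateral_step_mm > 0 && longitudinal_step_mm > 0
  )
  structure(
    list(
      lateral_steps = as.integer(lateral_steps),
      lateral_step_mm = lateral_step_mm,
      longitudinal_steps = as.integer(longitudinal_steps),
      longitudinal_step_mm = longitudinal_step_mm,
      start_landmark = start_landmark
    ),
    class = "scan_plan"
  )
}

#' Enumerate the positions of a scan plan
#'
#' @param plan A [plan_in_vivo_scan()] result.
#' @return A tibble with one row per acquisition position: integer grid
#'   indices (`lateral_index`, `longitudinal_index`, both 1-based) and stage
#'   coordinates in mm from the starting landmark, in acquisition (row-major)
#'   order.
#' @export
positions <- function(plan) {
  stopifnot(inherits(plan, "scan_plan"))
  grid <- expand.grid(
    lateral_index = seq_len(plan$lateral_steps),
    longitudinal_index = seq_len(plan$longitudinal_steps)
  )
  tibble::tibble(
    lateral_index = as.integer(grid$lateral_index),
    longitudinal_index = as.integer(grid$longitudinal_index),
    lateral_mm = (grid$lateral_index - 1) * plan$lateral_step_mm,
    longitudinal_mm = (grid$longitudinal_index - 1) * plan$longitudinal_step_mm
  )
}

#' @export
print.scan_plan <- function(x, ...) {
  cat(sprintf(
    "<scan_plan> %d x %d positions (%.1f mm lateral, %.1f mm longitudinal steps) from %s\n",
    x$lateral_steps, x$longitudinal_steps, x$lateral_step_mm,
    x$longitudinal_step_mm, x$start_landmark
  ))
  invisible(x)
}

#' Number of transmit events needed for one frame
#'
#' With multiplexed transmits, several focused beams are fired per transmit
#' event; the event count for a frame of `n_ray_lines` ray lines is
#' `ceiling(n_ray_lines / beams_per_transmit)`. Three simultaneous beams give
#' the three-fold frame-rate improvement of the fast B-mode schedule.
#'
#' @param n_ray_lines Ray lines per frame (>= 1).
#' @param beams_per_transmit Simultaneous beams per transmit event (>= 1).
#' @return Integer transmit-event count.
#' @examples
#' transmit_event_count(96, 3)  # 32
#' @export
transmit_event_count <- function(n_ray_lines, beams_per_transmit) {
  stopifnot(
    "n_ray_lines must be >= 1" = n_ray_lines >= 1,
    "beams_per_transmit must be >= 1" = beams_per_transmit >= 1
  )
  as.integer(ceiling(n_ray_lines / beams_per_transmit))
}
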