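# Supporting assays: fecal CFU and mutant fraction, flow-cytometry gating
# statistics, Freedman-Diaconis binning, and internal-standard-normalized
# thiosulfate quantification.

#' Colony-forming units per gram of feces
#'
#' `colonies / (plated_volume_ml * serial_dilution_factor *
#' homogenate_density)` from a drop-plate count. A zero count reports 0
#' CFU/g together with the limit of detection (the density one colony would
#' have represented).
#'
#' @param colonies Colony count (>= 0).
#' @param serial_dilution_factor Overall dilution of the plated material,
#'   e.g. `1e-4` (> 0).
#' @param plated_volume_ml Plated drop volume, mL (> 0).
#' @param homogenate_density_g_per_ml Feces per homogenate volume, g/mL
#'   (the standard homogenate is 100 mg/mL = 0.1 g/mL).
#' @return One-row tibble: `cfu_per_g`, `limit_of_detection` (CFU/g for one
#'   colony), `below_lod`.
#' @examples
#' cfu_per_gram(20, 1e-4, 0.01, 0.1)$cfu_per_g  # 2e8
#' @export
cfu_per_gram <- function(colonies, serial_dilution_factor, plated_volume_ml,
                         homogenate_density_g_per_ml = 0.1) {
  stopifnot(
    "colonies must be >= 0" = colonies >= 0,
    "dilution factor, volume and density must be > 0" =
      serial_dilution_factor > 0 && plated_volume_ml > 0 &&
      homogenate_density_g_per_ml > 0
  )
  grams <- plated_volume_ml * serial_dilution_factor *
    homogenate_density_g_per_ml
  tibble::tibble(
    cfu_per_g = colonies / grams,
    limit_of_detection = 1 / grams,
    below_lod = colonies == 0
  )
}

#' Fraction of mutant (non-expressing) colonies
#'
#' Colonies that fail to express the reporter genes on inducer plates,
#' divided by the total colony count on those plates.
#'
#' @param total_colonies Total colonies on the inducer plate (> 0).
#' @param non_expressing Colonies without reporter expression
#'   (0 <= `non_expressing` <= `total_colonies`).
#' @return Fraction in `[0, 1]`.
#' @export
mutant_fraction <- function(total_colonies, non_expressing) {
  stopifnot(
    "total colony count must be positive" = total_colonies > 0,
    "non-expressing count must lie in [0, total]" =
      non_expressing >= 0 && non_expressing <= total_colonies
  )
  non_expressing / total_colonies
}

#' Rectangular flow-cytometry gates
#'
#' @param fsc_range,ssc_range Length-2 numeric ranges (channel units) for
#'   the scatter gate; events inside both are kept.
#' @param mcherry_threshold Events must exceed this Y2 value.
#' @return A `flow_gates` list.
#' @export
flow_gates <- function(fsc_range = c(1e3, 1e6), ssc_range = c(1e3, 1e6),
                       mcherry_threshold = 500) {
  stopifnot(length(fsc_range) == 2, length(ssc_range) == 2,
            fsc_range[1] < fsc_range[2], ssc_range[1] < ssc_range[2])
  structure(list(fsc_range = fsc_range, ssc_range = ssc_range,
                 mcherry_threshold = mcherry_threshold),
            class = "flow_gates")
}

#' Gate a flow-cytometry event table and summarize GFP expression
#'
#' Gates on forward/side scatter and positive mCherry (Y2 above the
#' threshold), then reports: the gated event count, mean GFP fluorescence as
#' the geometric mean of B1 (nonpositive values floored to `epsilon` before
#' the log), and the GFP-positive fraction — events strictly above 1000 in
#' B1 divided by all gated events.
#'
#' @param events Data frame with columns `fsc_a`, `ssc_a`, `y2`, `b1`.
#' @param gates A [flow_gates()].
#' @param gfp_threshold B1 threshold for the positive fraction
#'   (strictly-greater rule; default 1000).
#' @param epsilon Floor applied to nonpositive B1 values before the
#'   geometric mean (default 1 channel unit).
#' @return One-row tibble: `n_gated`, `gfp_geometric_mean`,
#'   `gfp_positive_fraction`. All `NA` with a warning when no event passes
#'   the gates.
#' @export
gate_and_summarize <- function(events, gates = flow_gates(),
                               gfp_threshold = 1000, epsilon = 1) {
  stopifnot(inherits(gates, "flow_gates"),
            all(c("fsc_a", "ssc_a", "y2", "b1") %in% names(events)))
  keep <- events$fsc_a >= gates$fsc_range[1] &
    events$fsc_a <= gates$fsc_range[2] &
    events$ssc_a >= gates$ssc_range[1] &
    events$ssc_a <= gates$ssc_range[2] &
    events$y2 > gates$mcherry_threshold
  b1 <- events$b1[keep]
  if (length(b1) == 0) {
    warning("no events pass the gates; statistics undefined")
    return(tibble::tibble(n_gated = 0L, gfp_geometric_mean = NA_real_,
                          gfp_positive_fraction = NA_real_))
  }
  tibble::tibble(
    n_gated = length(b1),
    gfp_geometric_mean = exp(mean(log(pmax(b1, epsilon)))),
    gfp_positive_fraction = sum(b1 > gfp_threshold) / length(b1)
  )
}

#' Freedman-Diaconis histogram bins with a 100-bin floor
#'
#' Bin width `2 * IQR * n^(-1/3)`; the bin count is the data range divided
#' by that width, rounded up, and never less than 100. Degenerate data
#' (zero IQR or zero range) fall back to exactly 100 bins.
#'
#' @param values Numeric vector with at least 2 finite values.
#' @return List: `n_bins`, `width`, `edges` (length `n_bins + 1` spanning
#'   the data range).
#' @export
fd_bins <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2) {
    stop("at least 2 finite values are required", call. = FALSE)
  }
  iqr <- stats::IQR(values, type = 7)
  rng <- diff(range(values))
  width <- 2 * iqr * length(values)^(-1 / 3)
  n_bins <- if (width <= 0 || rng <= 0) 100L
            else max(100L, as.integer(ceiling(rng / width)))
  list(
    n_bins = n_bins,
    width = if (rng > 0) rng / n_bins else width,
    edges = if (rng > 0) seq(min(values), max(values), length.out = n_bins + 1)
            else min(values) + seq(-0.5, 0.5, length.out = n_bins + 1)
  )
}

#' Thiosulfate concentration from IC-MS peak areas
#'
#' The thiosulfate peak area of each injection is normalized by its
#' phosphate peak area (the shared PBS background serves as an internal
#' standard correcting injection-volume variation), a linear calibration is
#' fit through the external standards by least squares (intercept free), and
#' concentrations are inverse-predicted, multiplied by the sample dilution
#' factor, and averaged over technical replicates.
#'
#' @param records Data frame with columns `sample_id`,
#'   `thiosulfate_peak_area`, `phosphate_peak_area` (> 0), and
#'   `dilution_factor`; one row per technical replicate injection.
#' @param standards Data frame with columns `concentration` (uM) and
#'   `normalized_area` (or `thiosulfate_peak_area` + `phosphate_peak_area`),
#'   at least 3 standards spanning the sample range.
#' @return Tibble, one row per sample: `sample_id`, `concentration` (uM, in
#'   the original sample), `n_replicates`, `extrapolated` (`TRUE` when the
#'   mean normalized area falls outside the standard range).
#' @export
thiosulfate_conc <- function(records, standards) {
  stopifnot(
    all(c("sample_id", "thiosulfate_peak_area", "phosphate_peak_area",
          "dilution_factor") %in% names(records)),
    "phosphate areas must be positive" =
      all(records$phosphate_peak_area > 0),
    "peak areas must be nonnegative" =
      all(records$thiosulfate_peak_area >= 0)
  )
  if (!"normalized_area" %in% names(standards)) {
    stopifnot(all(c("thiosulfate_peak_area", "phosphate_peak_area") %in%
                    names(standards)))
    standards$normalized_area <- standards$thiosulfate_peak_area /
      standards$phosphate_peak_area
  }
  stopifnot("at least 3 standards are required" = nrow(standards) >= 3,
            "concentration" %in% names(standards))
  cal <- stats::lm(normalized_area ~ concentration, data = standards)
  slope <- stats::coef(cal)[["concentration"]]
  intercept <- stats::coef(cal)[["(Intercept)"]]
  if (slope == 0) stop("degenerate calibration (zero slope)", call. = FALSE)
  rng <- range(standards$normalized_area)

  records |>
    dplyr::mutate(
      normalized_area = .data$thiosulfate_peak_area /
        .data$phosphate_peak_area
    ) |>
    dplyr::group_by(.data$sample_id, .data$dilution_factor) |>
    dplyr::summarise(
      mean_area = mean(.data$normalized_area),
      n_replicates = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::transmute(
      sample_id = .data$sample_id,
      concentration = (.data$mean_area - intercept) / slope *
        .data$dilution_factor,
      n_replicates = .data$n_replicates,
      extrapolated = .data$mean_area < rng[1] | .data$mean_area > rng[2]
    )
}
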