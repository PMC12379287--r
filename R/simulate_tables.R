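# Tabular simulators: dose-response titrations, replica-plate patch images,
# and flow-cytometry event tables.

#' Hill dose-response model
#'
#' `y(c) = y0 + (ymax - y0) * c^n / (K^n + c^n)`, the four-parameter
#' sigmoid with baseline `y0`, saturating response `ymax`, half-maximal
#' concentration `K` (same units as `conc`) and Hill coefficient `n`.
#'
#' @param conc Concentrations (uM throughout this package).
#' @param y0,ymax,k,n Hill parameters.
#' @return Numeric vector of responses.
#' @export
hill_response <- function(conc, y0, ymax, k, n) {
  stopifnot(k > 0, n > 0)
  frac <- ifelse(conc > 0, conc^n / (k^n + conc^n), 0)
  y0 + (ymax - y0) * frac
}

#' Simulate a replicated dose-response titration
#'
#' Draws `n_reps` replicate responses per concentration from the Hill model
#' with multiplicative noise of coefficient of variation `noise_cv`, clipped
#' at zero. Defaults mirror a biosensor titration read out as
#' signal-to-background ratio over a thiosulfate dose range.
#'
#' @param y0 Baseline response at zero dose (>= 0).
#' @param ymax Saturating response (> y0).
#' @param half_max_conc Half-maximal concentration K, uM (> 0).
#' @param hill_n Hill coefficient (> 0).
#' @param conc Concentrations to titrate, uM.
#' @param n_reps Replicates per concentration.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param seed Integer seed.
#' @return Tibble with columns `concentration`, `replicate`, `response`.
#' @export
simulate_dose_response <- function(y0 = 1, ymax = 50, half_max_conc = 75,
                                   hill_n = 1.5,
                                   conc = c(0, 1, 3, 10, 30, 100, 300, 1000),
                                   n_reps = 4, noise_cv = 0.1, seed = 1L) {
  stopifnot(
    "y0 must be >= 0" = y0 >= 0,
    "ymax must exceed y0" = ymax > y0,
    "half_max_conc must be > 0" = half_max_conc > 0,
    "hill_n must be > 0" = hill_n > 0,
    "concentrations must be nonnegative" = all(conc >= 0),
    n_reps >= 1, noise_cv >= 0
  )
  mu <- hill_response(conc, y0, ymax, half_max_conc, hill_n)
  .with_seed(seed, {
    tab <- tidyr::expand_grid(concentration = conc,
                              replicate = seq_len(n_reps))
    tab$response <- pmax(
      0,
      rep(mu, each = n_reps) *
        (1 + stats::rnorm(nrow(tab), 0, noise_cv))
    )
    dplyr::arrange(tab, .data$concentration, .data$replicate)
  })
}

#' Simulate a replica-plate patch image with ROI table
#'
#' Lays out circular patches on a grid over a spatially varying background
#' (linear gradient plus optional noise); each patch adds its variant's
#' corrected-opacity effect to the local background. The returned ROI table
#' pairs every patch disc with an adjacent background annulus, ready for
#' [measure_patch()].
#'
#' @param variant_effects Named or unnamed numeric vector, one entry per
#'   patch: the true background-corrected patch intensity (same linear units
#'   as the anchors).
#' @param parent_anchors Length-2 vector `c(a0, a1)`: true corrected opacity
#'   of the parent strain at 0 mM and at 1 mM inducer (a1 > a0). Recorded in
#'   the output for anchored normalization downstream.
#' @param patch_radius_px Patch disc radius, pixels.
#' @param spacing_px Grid pitch between patch centres; must exceed twice the
#'   outer background-annulus radius so patches and their background ROIs do
#'   not overlap.
#' @param background_level Background intensity at the image origin.
#' @param background_gradient Length-2 `(per-row, per-col)` linear gradient of
#'   the background.
#' @param noise_sd Pixelwise Gaussian noise sd.
#' @param seed Integer seed.
#' @return List with `image` (matrix), `rois` (tibble: `strain_id`,
#'   `centre_row`, `centre_col`, `patch_radius`, `bg_inner`, `bg_outer`,
#'   `true_effect`), and `anchors` (the [opacity_anchors()]).
#' @export
simulate_patch_plate <- function(variant_effects,
                                 parent_anchors = c(5, 60),
                                 patch_radius_px = 6,
                                 spacing_px = 30,
                                 background_level = 40,
                                 background_gradient = c(0.02, 0.01),
                                 noise_sd = 0.5,
                                 seed = 1L) {
  stopifnot(
    length(parent_anchors) == 2,
    "anchor at 1 mM must exceed anchor at 0 mM" =
      parent_anchors[2] > parent_anchors[1],
    patch_radius_px >= 1
  )
  n <- length(variant_effects)
  bg_inner <- patch_radius_px + 2
  bg_outer <- patch_radius_px + 5
  if (spacing_px <= 2 * bg_outer) {
    stop("patches overlap: spacing_px must exceed twice the outer ",
         "background radius (", 2 * bg_outer, " px)", call. = FALSE)
  }
  n_cols <- ceiling(sqrt(n))
  n_rows <- ceiling(n / n_cols)
  rows_px <- n_rows * spacing_px
  cols_px <- n_cols * spacing_px
  centre <- tibble::tibble(
    strain_id = if (!is.null(names(variant_effects))) names(variant_effects)
                else sprintf("v%02d", seq_len(n)),
    centre_row = (((seq_len(n) - 1) %/% n_cols) + 0.5) * spacing_px,
    centre_col = (((seq_len(n) - 1) %% n_cols) + 0.5) * spacing_px,
    patch_radius = patch_radius_px,
    bg_inner = bg_inner,
    bg_outer = bg_outer,
    true_effect = as.numeric(variant_effects)
  )
  .with_seed(seed, {
    r <- matrix(seq_len(rows_px), rows_px, cols_px)
    cc <- matrix(rep(seq_len(cols_px), each = rows_px), rows_px, cols_px)
    img <- background_level + background_gradient[1] * r +
      background_gradient[2] * cc
    for (i in seq_len(n)) {
      disc <- (r - centre$centre_row[i])^2 + (cc - centre$centre_col[i])^2 <=
        patch_radius_px^2
      img[disc] <- img[disc] + centre$true_effect[i]
    }
    if (noise_sd > 0) {
      img <- img + matrix(stats::rnorm(rows_px * cols_px, 0, noise_sd),
                          rows_px, cols_px)
    }
    list(image = img, rois = centre,
         anchors = opacity_anchors(parent_anchors[1], parent_anchors[2]))
  })
}

#' Simulate a flow-cytometry event table
#'
#' Events carry forward/side scatter (log-normal around the gated bacterial
#' population), an mCherry channel (Y2) positive for `mcherry_frac` of
#' events, and a GFP channel (B1) drawn from a two-component log-normal
#' mixture ("unflipped" negative and "flipped" positive populations) with
#' positive-component weight `frac_positive`.
#'
#' @param n_events Number of events.
#' @param frac_positive Weight of the GFP-positive component, in `[0, 1]`.
#' @param neg_mean,pos_mean Median B1 value of the negative and positive
#'   components (channel units; `pos_mean` should sit above the downstream
#'   GFP-positive threshold of 1000).
#' @param spread Log-scale sd of each component.
#' @param mcherry_frac Fraction of events positive in Y2, in `[0, 1]`.
#' @param seed Integer seed.
#' @return Tibble with columns `fsc_a`, `ssc_a`, `y2`, `b1` and a logical
#'   `gfp_positive_truth` recording which component each event came from.
#' @export
simulate_flow_sample <- function(n_events = 10000, frac_positive = 0.5,
                                 neg_mean = 100, pos_mean = 20000,
                                 spread = 0.5, mcherry_frac = 0.95,
                                 seed = 1L) {
  stopifnot(
    "fractions must be in [0, 1]" =
      frac_positive >= 0 && frac_positive <= 1 &&
      mcherry_frac >= 0 && mcherry_frac <= 1,
    n_events >= 1, neg_mean > 0, pos_mean > neg_mean, spread > 0
  )
  .with_seed(seed, {
    pos <- stats::runif(n_events) < frac_positive
    b1 <- stats::rlnorm(n_events,
                        meanlog = ifelse(pos, log(pos_mean), log(neg_mean)),
                        sdlog = spread)
    mch <- stats::runif(n_events) < mcherry_frac
    tibble::tibble(
      fsc_a = stats::rlnorm(n_events, log(5e4), 0.3),
      ssc_a = stats::rlnorm(n_events, log(2e4), 0.3),
      y2 = stats::rlnorm(n_events, ifelse(mch, log(5000), log(50)), 0.4),
      b1 = b1,
      gfp_positive_truth = pos
    )
  })
}

#' Simulate a cell-density titration read out as SBR
#'
#' Log-linear signal growth above a detection knee, for exercising
#' [detection_limit()]: blank wells at SBR ~ 1, signal rising with density.
#'
#' @param densities Cells/mL tested (must include 0 for the blank).
#' @param knee_density Density at which signal first clearly exceeds blank.
#' @param slope_per_decade SBR gained per tenfold density above the knee.
#' @param n_reps Replicates per density.
#' @param noise_sd Additive SBR noise sd.
#' @param seed Integer seed.
#' @return Tibble with columns `density`, `replicate`, `sbr`.
#' @export
simulate_density_series <- function(densities = c(0, 1e3, 1e4, 1e5, 1e6,
                                                  1e7, 1e8, 1e9),
                                    knee_density = 1e5,
                                    slope_per_decade = 2,
                                    n_reps = 3, noise_sd = 0.05, seed = 1L) {
  stopifnot(0 %in% densities, knee_density > 0, n_reps >= 1)
  mu <- ifelse(densities >= knee_density & densities > 0,
               1 + slope_per_decade * (log10(densities / knee_density) + 1),
               1)
  .with_seed(seed, {
    tab <- tidyr::expand_grid(density = densities,
                              replicate = seq_len(n_reps))
    tab$sbr <- pmax(0, rep(mu, each = n_reps) +
                      stats::rnorm(nrow(tab), 0, noise_sd))
    dplyr::arrange(tab, .data$density, .data$replicate)
  })
}
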