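# Quantification: SBR, decibel conversion, shared display normalization,
# depth-integrated 2-D maps, thresholded overlays, total BURST* signal and
# ex vivo length profiles.

.as_pixels <- function(image) {
  if (inherits(image, "recon_image")) image$pixels else image
}

.as_mask <- function(roi, image) {
  if (is.logical(roi)) {
    stopifnot(all(dim(roi) == dim(image)))
    which(roi)
  } else {
    stopifnot(all(roi >= 1), all(roi <= length(image)))
    as.integer(roi)
  }
}

#' Signal-to-background ratio
#'
#' Mean pixel intensity of the sample ROI divided by the mean pixel intensity
#' of the background ROI.
#'
#' @param image Matrix or `recon_image`.
#' @param sample_roi,background_roi Logical masks of the image shape, or
#'   linear pixel indices. Both must be nonempty.
#' @return The ratio (dimensionless), or `NA` with a warning when the
#'   background mean is not positive (the ratio is then undefined).
#' @export
sbr <- function(image, sample_roi, background_roi) {
  px <- .as_pixels(image)
  s <- .as_mask(sample_roi, px)
  b <- .as_mask(background_roi, px)
  if (length(s) == 0 || length(b) == 0) {
    stop("sample and background ROIs must be nonempty", call. = FALSE)
  }
  bg <- mean(px[b])
  if (bg <= 0) {
    warning("background ROI mean is not positive; SBR undefined")
    return(NA_real_)
  }
  mean(px[s]) / bg
}

#' Convert a linear ratio to decibels
#'
#' `20 * log10(x)`, the amplitude-ratio convention used for SBR.
#'
#' @param x Positive ratio(s).
#' @return Value(s) in dB; nonpositive inputs give `NA` with a warning (a
#'   display floor is applied only in [normalize_display()]).
#' @export
to_db <- function(x) {
  out <- rep(NA_real_, length(x))
  ok <- is.finite(x) & x > 0
  if (any(!ok)) warning("nonpositive value(s): dB undefined, returning NA")
  out[ok] <- 20 * log10(x[ok])
  out
}

#' Display-normalization constants
#'
#' The colormap limits used when displaying a set of images together are
#' `(A, B * max / avg-background)` with constants fixed per imaging mode and
#' transducer: BURST with the L22-14v uses `A = 3, B = 1`; BURST with the
#' L22-14vX, `A = 2, B = 0.5`; xAM with the L22-14v, `A = 2, B = 0.5`; xAM
#' with the L22-14vX, `A = 2, B = 0.4`.
#'
#' @param mode `"burst"` or `"xam"`.
#' @param transducer_id `"L22-14v"` or `"L22-14vX"`.
#' @return A `display_params` list with elements `A`, `B`, `mode`,
#'   `transducer_id`.
#' @export
display_params <- function(mode = c("burst", "xam"),
                           transducer_id = c("L22-14v", "L22-14vX")) {
  mode <- match.arg(mode)
  transducer_id <- match.arg(transducer_id)
  tab <- list(
    "burst.L22-14v"  = c(A = 3, B = 1),
    "burst.L22-14vX" = c(A = 2, B = 0.5),
    "xam.L22-14v"    = c(A = 2, B = 0.5),
    "xam.L22-14vX"   = c(A = 2, B = 0.4)
  )
  ab <- tab[[paste(mode, transducer_id, sep = ".")]]
  structure(list(A = unname(ab["A"]), B = unname(ab["B"]), mode = mode,
                 transducer_id = transducer_id),
            class = "display_params")
}

#' Normalize a set of images for shared display
#'
#' Divides every image by the average background signal pooled over all
#' images being compared, fixes shared colormap limits — lower limit `A`,
#' upper limit `B` times the set-wide maximum normalized intensity — and
#' converts to dB, flooring values below the lower limit to it. The limits
#' are computed once for the whole compared set, never per image, so images
#' remain directly comparable; the whole construction is invariant to a
#' common linear intensity rescaling.
#'
#' @param images List of matrices or `recon_image`s.
#' @param backgrounds List of background ROIs (logical masks or index
#'   vectors), one per image, or a single ROI recycled to all images.
#' @param params A [display_params()].
#' @return List: `images` (dB matrices, floored at the lower limit),
#'   `normalized` (linear normalized images before flooring), `limits_db`
#'   (shared colormap limits in dB), `avg_background` (linear).
#' @export
normalize_display <- function(images, backgrounds, params = display_params()) {
  stopifnot(inherits(params, "display_params"), length(images) >= 1)
  px <- lapply(images, .as_pixels)
  if (!is.list(backgrounds)) backgrounds <- list(backgrounds)
  if (length(backgrounds) == 1) {
    backgrounds <- rep(backgrounds, length(px))
  }
  stopifnot(length(backgrounds) == length(px))
  bg_vals <- unlist(purrr::map2(px, backgrounds,
                                function(im, b) im[.as_mask(b, im)]))
  avg_bg <- mean(bg_vals)
  if (!is.finite(avg_bg) || avg_bg <= 0) {
    stop("average background must be positive", call. = FALSE)
  }
  norm <- lapply(px, function(im) im / avg_bg)
  upper <- params$B * max(vapply(norm, max, numeric(1)))
  lower <- params$A
  db <- lapply(norm, function(im) {
    im <- pmax(im, lower)   # floor at the lower colormap limit before dB
    matrix(20 * log10(im), nrow(im), ncol(im))
  })
  list(images = db,
       normalized = norm,
       limits_db = c(20 * log10(lower), 20 * log10(upper)),
       avg_background = avg_bg)
}

# Convert a half-open [lo, hi) depth window in mm to axial pixel rows;
# boundaries are rounded down to whole pixels.
.depth_rows <- function(lo_mm, hi_mm, axial_spacing, n_rows) {
  lo_px <- floor(lo_mm / axial_spacing)
  hi_px <- floor(hi_mm / axial_spacing)
  if (lo_px < 0 || hi_px > n_rows || hi_px <= lo_px) {
    stop("depth range [", lo_mm, ", ", hi_mm,
         ") mm falls outside the imaged depth", call. = FALSE)
  }
  (lo_px + 1L):hi_px
}

#' Depth-integrate a volume into 2-D maps
#'
#' The B-mode channel is summed over the fixed anatomical depth window
#' (default 4-8 mm below the transducer face); the BURST* channel is summed
#' over the full depth of the ROI (outside-ROI and motion-excluded voxels
#' are already zero). Depth windows are half-open `[lo, hi)` in mm.
#'
#' @param volume A [build_volume()] result.
#' @param bmode_depth_range Length-2 numeric, mm.
#' @return List of two matrices `[longitudinal, lateral]`: `bmode_2d`,
#'   `burst_2d`, plus `pixel_spacing` (mm, anisotropic).
#' @export
integrate_2d <- function(volume, bmode_depth_range = c(4, 8)) {
  stopifnot(inherits(volume, "gv_volume"), length(bmode_depth_range) == 2)
  ax <- volume$voxel_spacing[2]
  rows <- .depth_rows(bmode_depth_range[1], bmode_depth_range[2], ax,
                      dim(volume$bmode)[2])
  bmode_2d <- apply(volume$bmode[, rows, , drop = FALSE], c(1, 3), sum)
  keep <- volume$burst_star
  keep[!volume$mask | volume$exclusion_map] <- 0
  burst_2d <- apply(keep, c(1, 3), sum)
  list(bmode_2d = bmode_2d, burst_2d = burst_2d,
       pixel_spacing = volume$voxel_spacing[c(1, 3)])
}

#' Total BURST* signal of a masked volume
#'
#' Sum of every BURST* voxel inside the ROI and not excluded for breathing.
#' The sum is signed by default — negative difference values are included;
#' `clip_negative = TRUE` floors voxels at zero first (sensitivity-analysis
#' variant).
#'
#' @param volume A [build_volume()] result.
#' @param clip_negative Clip voxels below zero before summing.
#' @return Scalar total signal (linear intensity times voxel count units).
#' @export
total_signal <- function(volume, clip_negative = FALSE) {
  stopifnot(inherits(volume, "gv_volume"))
  v <- volume$burst_star[volume$mask & !volume$exclusion_map]
  if (clip_negative) v <- pmax(v, 0)
  sum(v)
}

#' Threshold a BURST* map over its B-mode anatomy
#'
#' Prepares the hot-over-gray composite: both channels in dB, BURST* pixels
#' at or below the threshold transparent. The default policy sets the
#' threshold at a percentile (default 97.5%) of the BURST* pixel
#' distribution, so on signal-free noise at most `1 - q` of pixels survive;
#' a fixed linear threshold may be given instead.
#'
#' @param burst_2d,bmode_2d Matrices of the same shape
#'   (see [integrate_2d()]).
#' @param threshold Fixed linear threshold; overrides the percentile policy.
#' @param q Percentile for the default policy, in (0, 1).
#' @return An `overlay_image`: `bmode_db`, `burst_db` (NA where hidden),
#'   `show` (logical), `threshold` used.
#' @export
overlay <- function(burst_2d, bmode_2d, threshold = NULL, q = 0.975) {
  if (!all(dim(burst_2d) == dim(bmode_2d))) {
    stop("burst and B-mode maps must have the same shape", call. = FALSE)
  }
  if (is.null(threshold)) {
    threshold <- stats::quantile(burst_2d, q, names = FALSE, type = 7)
  }
  show <- burst_2d > threshold
  burst_db <- matrix(NA_real_, nrow(burst_2d), ncol(burst_2d))
  pos <- show & burst_2d > 0
  burst_db[pos] <- 20 * log10(burst_2d[pos])
  bmode_db <- matrix(NA_real_, nrow(bmode_2d), ncol(bmode_2d))
  posb <- bmode_2d > 0
  bmode_db[posb] <- 20 * log10(bmode_2d[posb])
  structure(
    list(bmode_db = bmode_db, burst_db = burst_db, show = show,
         threshold = threshold),
    class = "overlay_image"
  )
}

#' Ex vivo length profile of integrated BURST* signal
#'
#' Per-station sum of BURST* pixel intensities over the stated depth band
#' (default 4-12 mm, half-open) and the full transducer width, keyed by the
#' signed length coordinate relative to the landmark.
#'
#' @param series An [assemble_ex_vivo()] result.
#' @param depth_range Length-2 numeric, mm.
#' @return Tibble with columns `length_mm`, `burst_star`, `bmode` (the
#'   B-mode channel is summed over the same band and width).
#' @export
ex_vivo_profile <- function(series, depth_range = c(4, 12)) {
  stopifnot(inherits(series, "ex_vivo_series"))
  ax <- series$burst_star[[1]]$spacing[1]
  n_rows <- nrow(series$burst_star[[1]]$pixels)
  rows <- .depth_rows(depth_range[1], depth_range[2], ax, n_rows)
  tibble::tibble(
    length_mm = series$length_mm,
    burst_star = vapply(series$burst_star,
                        function(im) sum(im$pixels[rows, ]), numeric(1)),
    bmode = vapply(series$bmode,
                   function(im) sum(im$pixels[rows, ]), numeric(1))
  )
}
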