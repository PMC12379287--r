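# Replica-plate patch quantification: background-corrected opacity, the
# anchored "relative patch opacity" statistic, and screening hit selection.

#' Parent-strain opacity anchors
#'
#' Corrected opacities of the parent strain at 0 mM and 1 mM inducer
#' (30 degrees C); relative patch opacity maps these to 0 and 1.
#'
#' @param a0 Corrected opacity of the parent at 0 mM.
#' @param a1 Corrected opacity of the parent at 1 mM; must exceed `a0`.
#' @return An `opacity_anchors` list.
#' @export
opacity_anchors <- function(a0, a1) {
  stopifnot("anchor at 1 mM must exceed anchor at 0 mM" = a1 > a0)
  structure(list(a0 = a0, a1 = a1), class = "opacity_anchors")
}

#' Build patch and adjacent-background ROI masks
#'
#' The patch ROI is a disc; the background ROI is the annulus directly
#' around it (inner/outer radii in pixels), which corrects for spatial
#' nonuniformity of the plate illumination.
#'
#' @param dim Image dimensions `c(rows, cols)`.
#' @param centre_row,centre_col Patch centre, pixels.
#' @param patch_radius Disc radius, pixels.
#' @param bg_inner,bg_outer Annulus radii, pixels (`bg_inner` >
#'   `patch_radius` keeps the ROIs disjoint).
#' @return List of two logical masks: `patch`, `background`.
#' @export
patch_masks <- function(dim, centre_row, centre_col, patch_radius,
                        bg_inner = patch_radius + 2,
                        bg_outer = patch_radius + 5) {
  stopifnot(bg_inner > patch_radius, bg_outer > bg_inner)
  r <- matrix(seq_len(dim[1]), dim[1], dim[2])
  cc <- matrix(rep(seq_len(dim[2]), each = dim[1]), dim[1], dim[2])
  d2 <- (r - centre_row)^2 + (cc - centre_col)^2
  list(patch = d2 <= patch_radius^2,
       background = d2 > bg_inner^2 & d2 <= bg_outer^2)
}

#' Measure one patch: background-corrected opacity
#'
#' Mean pixel intensity of the patch ROI minus the mean of the adjacent
#' background ROI. The corrected value may be negative and is recorded
#' as-is.
#'
#' @param image Intensity matrix (white-trans plate image, or a
#'   fluorescence image for GFP-mode patches — the arithmetic is identical).
#' @param patch_roi,background_roi Logical masks of the image shape, or
#'   linear pixel indices; must be nonempty, within the image, and disjoint.
#' @param strain_id,condition Optional labels carried into the result.
#' @return One-row tibble: `strain_id`, `condition`, `patch_mean`,
#'   `background_mean`, `corrected`.
#' @export
measure_patch <- function(image, patch_roi, background_roi,
                          strain_id = NA_character_,
                          condition = NA_character_) {
  px <- .as_pixels(image)
  p <- .as_mask(patch_roi, px)
  b <- .as_mask(background_roi, px)
  if (length(p) == 0 || length(b) == 0) {
    stop("patch and background ROIs must be nonempty", call. = FALSE)
  }
  if (length(intersect(p, b)) > 0) {
    stop("patch and background ROIs overlap", call. = FALSE)
  }
  tibble::tibble(
    strain_id = strain_id, condition = condition,
    patch_mean = mean(px[p]),
    background_mean = mean(px[b]),
    corrected = mean(px[p]) - mean(px[b])
  )
}

#' Relative patch opacity
#'
#' Anchored normalization of a corrected opacity: `(corrected - a0) /
#' (a1 - a0)`, so the parent strain at 0 mM maps to 0 and at 1 mM maps
#' to 1. Invariant to affine intensity rescaling applied to image and
#' anchors together.
#'
#' @param corrected Background-corrected opacity value(s), or a tibble from
#'   [measure_patch()] (its `corrected` column is used and the tibble is
#'   returned with a `relative_opacity` column).
#' @param anchors An [opacity_anchors()].
#' @return Numeric vector, or the input tibble augmented with
#'   `relative_opacity`.
#' @export
relative_opacity <- function(corrected, anchors) {
  stopifnot(inherits(anchors, "opacity_anchors"))
  if (is.data.frame(corrected)) {
    corrected$relative_opacity <-
      (corrected$corrected - anchors$a0) / (anchors$a1 - anchors$a0)
    return(corrected)
  }
  (corrected - anchors$a0) / (anchors$a1 - anchors$a0)
}

#' Select screening hits from paired 0/1 mM patch measurements
#'
#' A candidate is a hit when its corrected opacity at 1 mM inducer exceeds
#' its corrected opacity at 0 mM by the margin, expressed as a fraction of
#' the anchor span `a1 - a0` (default 0.25). Hits are ranked by relative
#' opacity at 1 mM, descending; ties break toward the lower 0 mM value.
#'
#' @param measurements Data frame with columns `strain_id`, `condition`
#'   (values `"0mM"` and `"1mM"`), `corrected`; every candidate must have
#'   both conditions.
#' @param anchors An [opacity_anchors()].
#' @param margin Required excess of 1 mM over 0 mM corrected opacity, as a
#'   fraction of `a1 - a0`.
#' @return Tibble of all candidates, ranked, with `corrected_0`,
#'   `corrected_1`, `relative_0`, `relative_1`, `hit`, and `rank` (`NA` for
#'   non-hits).
#' @export
select_hits <- function(measurements, anchors, margin = 0.25) {
  stopifnot(inherits(anchors, "opacity_anchors"),
            all(c("strain_id", "condition", "corrected") %in%
                  names(measurements)))
  wide <- measurements |>
    dplyr::select("strain_id", "condition", "corrected") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "corrected")
  if (!all(c("0mM", "1mM") %in% names(wide)) ||
      anyNA(wide[["0mM"]]) || anyNA(wide[["1mM"]])) {
    stop("every candidate needs measurements at both 0 mM and 1 mM",
         call. = FALSE)
  }
  span <- anchors$a1 - anchors$a0
  out <- tibble::tibble(
    strain_id = wide$strain_id,
    corrected_0 = wide[["0mM"]],
    corrected_1 = wide[["1mM"]],
    relative_0 = relative_opacity(wide[["0mM"]], anchors),
    relative_1 = relative_opacity(wide[["1mM"]], anchors),
    hit = wide[["1mM"]] > wide[["0mM"]] + margin * span
  ) |>
    dplyr::arrange(dplyr::desc(.data$relative_1), .data$relative_0)
  out$rank <- NA_integer_
  out$rank[out$hit] <- seq_len(sum(out$hit))
  out
}

#' Measure every patch of a simulated plate
#'
#' Convenience wrapper applying [measure_patch()] across the ROI table that
#' [simulate_patch_plate()] produces.
#'
#' @param plate A [simulate_patch_plate()] result.
#' @param condition Condition label for every measurement.
#' @return Tibble of per-patch measurements with `relative_opacity`.
#' @export
measure_plate <- function(plate, condition = NA_character_) {
  rows <- purrr::pmap(
    plate$rois,
    function(strain_id, centre_row, centre_col, patch_radius, bg_inner,
             bg_outer, ...) {
      m <- patch_masks(dim(plate$image), centre_row, centre_col,
                       patch_radius, bg_inner, bg_outer)
      measure_patch(plate$image, m$patch, m$background,
                    strain_id = strain_id, condition = condition)
    })
  relative_opacity(dplyr::bind_rows(rows), plate$anchors)
}
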