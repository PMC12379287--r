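# Stitching per-position reconstructions into transverse planes and 3-D
# volumes (in vivo) and into an ordered long-axis series (ex vivo).

#' Stitch the acquisitions of one transverse plane
#'
#' Concatenates the lateral (across-the-body) acquisitions of one
#' longitudinal station into a single plane image at the stage spacing. When
#' the image width differs from the stage step width the configured policy
#' applies: `"crop"` (default) keeps the central step-width block of each
#' image (zero-padding images narrower than the step), `"average"` lays
#' images at their stage offsets and averages where neighbours overlap.
#' BURST-channel blocks of acquisitions excluded for motion are zeroed;
#' B-mode blocks are always kept for anatomical context.
#'
#' @param images List of `recon_image`s of equal axial extent, ordered
#'   left-to-right across the body.
#' @param lateral_step_mm Stage step between acquisitions, mm.
#' @param lateral_spacing Lateral pixel pitch, mm/px (defaults to the first
#'   image's recorded spacing).
#' @param policy `"crop"` or `"average"`.
#' @return Matrix of the stitched plane (axial x stitched lateral).
#' @export
stitch_transverse <- function(images, lateral_step_mm,
                              lateral_spacing = images[[1]]$spacing[2],
                              policy = c("crop", "average")) {
  policy <- match.arg(policy)
  stopifnot(length(images) >= 1,
            all(vapply(images, inherits, logical(1), "recon_image")))
  rows <- vapply(images, function(im) nrow(im$pixels), integer(1))
  if (length(unique(rows)) != 1) {
    stop("images have mismatched axial sizes: ",
         paste(rows, collapse = ", "), call. = FALSE)
  }
  step_px <- round(lateral_step_mm / lateral_spacing)
  stopifnot(step_px >= 1)
  block <- function(im) {
    px <- im$pixels
    if (isTRUE(im$excluded) && im$kind != "bmode") px <- px * 0
    px
  }
  if (policy == "crop") {
    blocks <- lapply(images, function(im) {
      px <- block(im)
      w <- ncol(px)
      if (w == step_px) return(px)
      if (w > step_px) {
        off <- floor((w - step_px) / 2)
        return(px[, (off + 1):(off + step_px), drop = FALSE])
      }
      out <- matrix(0, nrow(px), step_px)
      off <- floor((step_px - w) / 2)
      out[, (off + 1):(off + w)] <- px
      out
    })
    do.call(cbind, blocks)
  } else {
    total <- step_px * length(images)
    acc <- matrix(0, rows[1], total)
    wt <- matrix(0, rows[1], total)
    for (i in seq_along(images)) {
      px <- block(images[[i]])
      w <- ncol(px)
      start <- (i - 1) * step_px + 1 + floor((step_px - w) / 2)
      cols <- start:(start + w - 1)
      keep <- cols >= 1 & cols <= total
      acc[, cols[keep]] <- acc[, cols[keep]] + px[, keep, drop = FALSE]
      wt[, cols[keep]] <- wt[, cols[keep]] + 1
    }
    out <- acc
    out[wt > 0] <- acc[wt > 0] / wt[wt > 0]
    out
  }
}

#' Per-plane GI-tract ROI masks
#'
#' @param masks List of logical matrices, one per longitudinal station, in
#'   stitched-plane pixel coordinates.
#' @return An `roi_set` object.
#' @export
roi_set <- function(masks) {
  stopifnot(length(masks) >= 1,
            all(vapply(masks, is.logical, logical(1))))
  structure(list(masks = masks), class = "roi_set")
}

#' Derive GI-tract ROI masks from scan ground truth
#'
#' Marks every gas-vesicle-positive voxel of the truth, optionally dilated —
#' used to build test ROIs that mimic hand-drawn masks enclosing the signal.
#'
#' @param truth A [scan_truth()].
#' @param dilate_px Dilation radius in pixels (square structuring element).
#' @return An [roi_set()] with one mask per longitudinal station.
#' @export
roi_from_truth <- function(truth, dilate_px = 0) {
  stopifnot(inherits(truth, "scan_truth"))
  masks <- lapply(seq_len(dim(truth$gv)[1]), function(j) {
    m <- truth$gv[j, , ] > 0
    if (dilate_px > 0) {
      out <- m
      for (dr in -dilate_px:dilate_px) {
        for (dc in -dilate_px:dilate_px) {
          out <- out | (.translate(m * 1, dr, dc) > 0)
        }
      }
      m <- out
    }
    m
  })
  roi_set(masks)
}

#' Assemble reconstructed acquisitions into a masked 3-D volume
#'
#' Stitches every plane, stacks planes into `[longitudinal, axial, lateral]`
#' arrays, and applies the GI masks and motion exclusions: BURST* voxels
#' outside a plane's mask, or belonging to an excluded acquisition, are set
#' to zero (the exclusion map records the latter); the B-mode array is kept
#' unmasked for anatomy. A station without a mask is treated as
#' all-background with a warning unless `strict = TRUE`.
#'
#' @param recons A [reconstruct_scan()] result.
#' @param rois An [roi_set()]; `masks[[j]]` applies to station `j`.
#' @param strict Reject (rather than warn about) missing plane masks.
#' @param policy Stitching policy, see [stitch_transverse()].
#' @return A `gv_volume`: `burst_star`, `bmode`, `mask`, `exclusion_map`
#'   (3-D arrays of equal shape) and `voxel_spacing` in mm
#'   `(longitudinal, axial, lateral)` — deliberately anisotropic.
#' @export
build_volume <- function(recons, rois, strict = FALSE,
                         policy = c("crop", "average")) {
  policy <- match.arg(policy)
  stopifnot(inherits(rois, "roi_set"))
  plan <- recons$plan
  n_long <- plan$longitudinal_steps
  n_lat <- plan$lateral_steps
  step_px <- round(plan$lateral_step_mm / recons$config$lateral_spacing)
  rows <- recons$config$image_rows
  total_lat <- n_lat * step_px

  burst <- array(0, c(n_long, rows, total_lat))
  bm <- array(0, c(n_long, rows, total_lat))
  mask <- array(FALSE, c(n_long, rows, total_lat))
  excl <- array(FALSE, c(n_long, rows, total_lat))

  for (j in seq_len(n_long)) {
    sel <- which(recons$positions$longitudinal_index == j)
    sel <- sel[order(recons$positions$lateral_index[sel])]
    stopifnot(length(sel) == n_lat)
    plane_b <- stitch_transverse(recons$burst_star[sel],
                                 plan$lateral_step_mm,
                                 recons$config$lateral_spacing, policy)
    plane_m <- stitch_transverse(recons$bmode[sel],
                                 plan$lateral_step_mm,
                                 recons$config$lateral_spacing, policy)
    burst[j, , ] <- plane_b
    bm[j, , ] <- plane_m
    for (k in seq_along(sel)) {
      if (isTRUE(recons$burst_star[[sel[k]]]$excluded)) {
        excl[j, , ((k - 1) * step_px + 1):(k * step_px)] <- TRUE
      }
    }
    m <- if (j <= length(rois$masks) && !is.null(rois$masks[[j]])) {
      rois$masks[[j]]
    } else if (strict) {
      stop("no ROI mask for longitudinal station ", j, call. = FALSE)
    } else {
      warning("no ROI mask for station ", j, "; treating as all-background")
      matrix(FALSE, rows, total_lat)
    }
    stopifnot(all(dim(m) == c(rows, total_lat)))
    mask[j, , ] <- m
  }
  burst[!mask | excl] <- 0
  structure(
    list(burst_star = burst, bmode = bm, mask = mask, exclusion_map = excl,
         voxel_spacing = c(plan$longitudinal_step_mm,
                           recons$config$axial_spacing,
                           recons$config$lateral_spacing)),
    class = "gv_volume"
  )
}

#' @export
print.gv_volume <- function(x, ...) {
  d <- dim(x$burst_star)
  cat(sprintf(
    "<gv_volume> %d x %d x %d voxels at %s mm (longitudinal x axial x lateral; anisotropic)\n  %d ROI voxel(s), %d excluded for motion\n",
    d[1], d[2], d[3],
    paste(signif(x$voxel_spacing, 3), collapse = " x "),
    sum(x$mask), sum(x$exclusion_map)
  ))
  invisible(x)
}

#' Assemble an ex vivo long-axis scan series
#'
#' Reconstructs BURST* and B-mode for each station of a linearized-gut scan
#' and attaches a signed length coordinate relative to a named landmark
#' (positive toward the rectum, negative proximal of the landmark).
#'
#' @param stacks List of [frame_stack()]s ordered by station (proximal to
#'   distal).
#' @param step_mm Stage step between stations, mm (the gut protocol uses
#'   1-mm steps).
#' @param landmark_station Station index of the anatomical landmark.
#' @param landmark Landmark name (default `"cecum"`).
#' @param stations Optional explicit station indices (must be strictly
#'   increasing); defaults to `seq_along(stacks)`.
#' @return An `ex_vivo_series`: per-station `burst_star` and `bmode` recon
#'   images plus `length_mm`, the signed coordinate of each station.
#' @export
assemble_ex_vivo <- function(stacks, step_mm = 1, landmark_station,
                             landmark = "cecum",
                             stations = seq_along(stacks)) {
  if (length(stacks) == 0) stop("empty station series", call. = FALSE)
  stopifnot(all(vapply(stacks, inherits, logical(1), "frame_stack")))
  if (any(diff(stations) <= 0)) {
    stop("stations must be strictly increasing (ordered proximal to distal)",
         call. = FALSE)
  }
  stopifnot(landmark_station >= min(stations),
            landmark_station <= max(stations))
  structure(
    list(
      burst_star = lapply(stacks, burst_star),
      bmode = lapply(stacks, bmode),
      length_mm = (stations - landmark_station) * step_mm,
      step_mm = step_mm, landmark = landmark,
      landmark_station = landmark_station
    ),
    class = "ex_vivo_series"
  )
}

#' @export
print.ex_vivo_series <- function(x, ...) {
  cat(sprintf(
    "<ex_vivo_series> %d stations, %.0f to %.0f mm relative to the %s\n",
    length(x$burst_star), min(x$length_mm), max(x$length_mm), x$landmark
  ))
  invisible(x)
}
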