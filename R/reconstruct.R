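# Collapse-differencing reconstructions. All three images are defined on the
# collapsing (high-voltage) frames of the stack:
#   BURST   (in vitro): first collapsing frame - last collapsing frame
#   BURST*  (in vivo) : second collapsing frame - first collapsing frame
#   B-mode            : first collapsing frame, unmodified
# Difference images are signed and never clipped before quantification.

.recon_image <- function(pixels, kind, frames_used, excluded = FALSE,
                         reason = NULL, spacing = c(NA_real_, NA_real_)) {
  structure(
    list(pixels = pixels, kind = kind, frames_used = frames_used,
         excluded = excluded, reason = reason, spacing = spacing),
    class = "recon_image"
  )
}

#' @export
print.recon_image <- function(x, ...) {
  cat(sprintf(
    "<recon_image> %s, %d x %d px, frames %s%s\n",
    x$kind, nrow(x$pixels), ncol(x$pixels),
    paste(x$frames_used, collapse = "-"),
    if (isTRUE(x$excluded)) paste0(" [EXCLUDED: ", x$reason, "]") else ""
  ))
  invisible(x)
}

.check_collapsing <- function(stack, need = 2) {
  stopifnot(inherits(stack, "frame_stack"))
  idx <- collapsing_frames(stack)
  if (length(idx) < need) {
    stop("stack has ", length(idx), " collapsing frame(s); ", need,
         " are required", call. = FALSE)
  }
  idx
}

#' In vitro BURST reconstruction (first minus last collapsing frame)
#'
#' Intact gas vesicles scatter strongly in the first collapsing frame and are
#' destroyed by the last, so the difference isolates collapse-sensitive
#' contrast from static tissue. The result is signed; negative pixels are
#' retained through quantification.
#'
#' @param stack A [frame_stack()] with at least two collapsing frames.
#' @return A `recon_image` of kind `"burst"`, with `frames_used` recording
#'   the (first, last) collapsing-frame indices.
#' @export
burst_invitro <- function(stack) {
  idx <- .check_collapsing(stack, 2)
  first <- idx[1]; last <- idx[length(idx)]
  .recon_image(
    stack$frames[first, , ] - stack$frames[last, , ],
    kind = "burst", frames_used = c(first, last),
    spacing = c(stack$config$axial_spacing, stack$config$lateral_spacing)
  )
}

#' BURST* reconstruction (second minus first collapsing frame)
#'
#' The gas-vesicle-specific signal rises from the first to the second
#' collapsing frame, so subtracting the first collapsing frame from the
#' second isolates it while using only two adjacent frames — which keeps the
#' image robust to slow tissue motion. Note the frame order is opposite to
#' [burst_invitro()].
#'
#' @inheritParams burst_invitro
#' @return A `recon_image` of kind `"burst_star"`.
#' @export
burst_star <- function(stack) {
  idx <- .check_collapsing(stack, 2)
  .recon_image(
    stack$frames[idx[2], , ] - stack$frames[idx[1], , ],
    kind = "burst_star", frames_used = c(idx[1], idx[2]),
    spacing = c(stack$config$axial_spacing, stack$config$lateral_spacing)
  )
}

#' B-mode image (first collapsing frame)
#'
#' @inheritParams burst_invitro
#' @return A `recon_image` of kind `"bmode"` equal to the first
#'   high-voltage frame, unmodified.
#' @export
bmode <- function(stack) {
  idx <- .check_collapsing(stack, 1)
  .recon_image(
    stack$frames[idx[1], , ], kind = "bmode", frames_used = idx[1],
    spacing = c(stack$config$axial_spacing, stack$config$lateral_spacing)
  )
}

#' Screen an acquisition for breathing motion
#'
#' Automated surrogate for manual breathing exclusion: the score is
#' `1 - Pearson correlation` between the two collapsing frames the active
#' reconstruction differences (frames 1 and 2 for `burst_star`, first and
#' last for `burst`), computed over a background band of image rows. The
#' acquisition is excluded when the score exceeds the threshold or when it is
#' on a user-supplied manual exclusion list — the manual list remains the
#' authoritative override.
#'
#' @param stack A [frame_stack()].
#' @param decorrelation_threshold Exclusion threshold on the score
#'   (default 0.5).
#' @param mode Which frame pair to compare: `"burst_star"` (frames 1, 2) or
#'   `"burst"` (first, last).
#' @param band Optional integer vector of image rows forming the background
#'   band; defaults to every row.
#' @param manual_exclude `TRUE` to force exclusion regardless of score (the
#'   caller matches acquisition identity against its own exclusion list).
#' @return A one-row tibble: `excluded`, `score`, `reason`.
#' @export
screen_motion <- function(stack, decorrelation_threshold = 0.5,
                          mode = c("burst_star", "burst"),
                          band = NULL, manual_exclude = FALSE) {
  mode <- match.arg(mode)
  idx <- .check_collapsing(stack, 2)
  pair <- if (mode == "burst_star") idx[1:2] else c(idx[1], idx[length(idx)])
  a <- stack$frames[pair[1], , ]
  b <- stack$frames[pair[2], , ]
  if (!is.null(band)) {
    stopifnot(all(band >= 1), all(band <= nrow(a)))
    a <- a[band, , drop = FALSE]
    b <- b[band, , drop = FALSE]
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant frame(s): inter-frame correlation undefined, score 0")
    score <- 0
  } else {
    score <- 1 - stats::cor(as.vector(a), as.vector(b))
  }
  excluded <- manual_exclude || score > decorrelation_threshold
  tibble::tibble(
    excluded = excluded,
    score = score,
    reason = dplyr::case_when(
      manual_exclude ~ "manual exclusion list",
      score > decorrelation_threshold ~
        sprintf("decorrelation score %.3f > %.3f", score,
                decorrelation_threshold),
      TRUE ~ NA_character_
    )
  )
}

#' Reconstruct and motion-screen every acquisition of a scan set
#'
#' @param scans A [simulate_scan()] result (or equivalently structured list).
#' @param decorrelation_threshold Passed to [screen_motion()].
#' @param manual_exclusions Optional tibble with `lateral_index` and
#'   `longitudinal_index` columns naming acquisitions to exclude outright.
#' @return A list with per-position `burst_star` and `bmode` recon images
#'   (the BURST* image of an excluded acquisition is flagged `excluded`) and
#'   a `screening` tibble (position, score, excluded, reason).
#' @export
reconstruct_scan <- function(scans, decorrelation_threshold = 0.5,
                             manual_exclusions = NULL) {
  stopifnot(inherits(scans, "scan_set"))
  n <- length(scans$stacks)
  burst <- vector("list", n)
  bm <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    st <- scans$stacks[[i]]
    manual <- FALSE
    if (!is.null(manual_exclusions)) {
      manual <- any(
        manual_exclusions$lateral_index == st$position$lateral_index &
        manual_exclusions$longitudinal_index == st$position$longitudinal_index)
    }
    scr <- screen_motion(st, decorrelation_threshold,
                         mode = "burst_star", manual_exclude = manual)
    img <- burst_star(st)
    if (scr$excluded) {
      img$excluded <- TRUE
      img$reason <- scr$reason
    }
    burst[[i]] <- img
    bm[[i]] <- bmode(st)
    rows[[i]] <- tibble::tibble(
      lateral_index = st$position$lateral_index,
      longitudinal_index = st$position$longitudinal_index,
      score = scr$score, excluded = scr$excluded, reason = scr$reason
    )
  }
  list(plan = scans$plan, config = scans$config, positions = scans$positions,
       burst_star = burst, bmode = bm,
       screening = dplyr::bind_rows(rows))
}
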