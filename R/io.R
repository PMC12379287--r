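# TIFF + JSON-sidecar I/O. Pixel data go into multi-page TIFF; everything
# else (config, voltages, position, seed, motion flags, spacing, the
# offset/scale that maps the stored [0,1] samples back to linear intensity)
# goes into a JSON sidecar next to it.

.write_array_tiff <- function(arr, tif_path, json_path, meta = list()) {
  lo <- min(arr); hi <- max(arr)
  scale <- if (hi > lo) hi - lo else 1
  pages <- if (length(dim(arr)) == 3) {
    lapply(seq_len(dim(arr)[1]), function(i) (arr[i, , ] - lo) / scale)
  } else {
    list((arr - lo) / scale)
  }
  tiff::writeTIFF(pages, tif_path, bits.per.sample = 32L)
  meta$intensity_offset <- lo
  meta$intensity_scale <- scale
  meta$dim <- dim(arr)
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(meta)
}

.read_array_tiff <- function(tif_path, json_path) {
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(tif_path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- meta$dim
  arr <- if (length(d) == 3) {
    out <- array(0, d)
    for (i in seq_along(pages)) out[i, , ] <- pages[[i]]
    out
  } else {
    pages[[1]]
  }
  list(array = arr * meta$intensity_scale + meta$intensity_offset,
       meta = meta)
}

#' Write a frame stack as multi-page TIFF plus JSON sidecar
#'
#' @param stack A [frame_stack()].
#' @param path_prefix Output path without extension; writes
#'   `<prefix>.tif` and `<prefix>.json`.
#' @return The prefix, invisibly.
#' @export
write_frame_stack <- function(stack, path_prefix) {
  stopifnot(inherits(stack, "frame_stack"))
  cfg <- unclass(stack$config)
  .write_array_tiff(
    stack$frames,
    paste0(path_prefix, ".tif"), paste0(path_prefix, ".json"),
    meta = list(
      type = "frame_stack",
      config = cfg,
      voltages = stack$voltages,
      motion_flags = stack$motion_flags,
      position = stack$position,
      seed = if (!is.null(stack$truth)) stack$truth$seed else NULL
    )
  )
  invisible(path_prefix)
}

#' Read a frame stack written by [write_frame_stack()]
#'
#' @param path_prefix Path prefix used when writing.
#' @return A [frame_stack()] (without ground truth; TIFF storage is 32-bit
#'   float, so intensities round-trip to single precision).
#' @export
read_frame_stack <- function(path_prefix) {
  r <- .read_array_tiff(paste0(path_prefix, ".tif"),
                        paste0(path_prefix, ".json"))
  cfg <- do.call(acquisition_config, r$meta$config[
    setdiff(names(r$meta$config), character())])
  frame_stack(pmax(r$array, 0), r$meta$voltages, cfg,
              motion_flags = r$meta$motion_flags,
              position = r$meta$position)
}

#' Write a 3-D volume as multi-page TIFF plus JSON sidecar
#'
#' One TIFF per channel (`<prefix>_burst.tif`, `<prefix>_bmode.tif`,
#' `<prefix>_mask.tif`); the sidecar records the anisotropic voxel spacing
#' and the motion-exclusion map.
#'
#' @param volume A [build_volume()] result.
#' @param path_prefix Output path prefix.
#' @return The prefix, invisibly.
#' @export
write_volume <- function(volume, path_prefix) {
  stopifnot(inherits(volume, "gv_volume"))
  .write_array_tiff(volume$burst_star, paste0(path_prefix, "_burst.tif"),
                    paste0(path_prefix, "_burst.json"),
                    meta = list(type = "volume_burst_star",
                                voxel_spacing = volume$voxel_spacing))
  .write_array_tiff(volume$bmode, paste0(path_prefix, "_bmode.tif"),
                    paste0(path_prefix, "_bmode.json"),
                    meta = list(type = "volume_bmode",
                                voxel_spacing = volume$voxel_spacing))
  .write_array_tiff(volume$mask * 1, paste0(path_prefix, "_mask.tif"),
                    paste0(path_prefix, "_mask.json"),
                    meta = list(type = "volume_mask",
                                voxel_spacing = volume$voxel_spacing,
                                excluded_voxels = sum(volume$exclusion_map)))
  invisible(path_prefix)
}

#' Read a volume written by [write_volume()]
#'
#' @param path_prefix Path prefix used when writing.
#' @return A `gv_volume` (exclusion map collapsed into the zeroed voxels;
#'   the stored mask is restored exactly).
#' @export
read_volume <- function(path_prefix) {
  b <- .read_array_tiff(paste0(path_prefix, "_burst.tif"),
                        paste0(path_prefix, "_burst.json"))
  m <- .read_array_tiff(paste0(path_prefix, "_bmode.tif"),
                        paste0(path_prefix, "_bmode.json"))
  k <- .read_array_tiff(paste0(path_prefix, "_mask.tif"),
                        paste0(path_prefix, "_mask.json"))
  structure(
    list(burst_star = b$array, bmode = m$array, mask = k$array > 0.5,
         exclusion_map = array(FALSE, dim(b$array)),
         voxel_spacing = b$meta$voxel_spacing),
    class = "gv_volume"
  )
}
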