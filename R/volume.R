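#' Multi-channel 3D image volume
#'
#' A `channel_volume` wraps a 4D intensity array ordered `(channel, z, y, x)`
#' together with channel names, physical voxel size and acquisition bit depth.
#' Intensities are arbitrary units (AU) in `[0, 2^bit_depth - 1]`. The z index
#' runs from the top of the stack (z = 1 at the animal pole for embryos
#' mounted animal-cap up).
#'
#' @param voxels Numeric 4D array `(channel, z, y, x)`, non-negative.
#' @param channel_names Character vector of unique channel labels, one per
#'   channel (e.g. `c("DAPI", "GFP", "EFFECTOR")`).
#' @param voxel_size_um Numeric length-3 vector of physical voxel edge lengths
#'   in micrometres, ordered `(z, y, x)`. The confocal stacks this mirrors use
#'   a 9 um z-interval and a few um laterally.
#' @param bit_depth Acquisition bit depth, 8 or 16.
#' @return An object of class `channel_volume`.
#' @export
channel_volume <- function(voxels, channel_names, voxel_size_um = c(9, 6, 6),
                           bit_depth = 16) {
  if (!is.array(voxels) || length(dim(voxels)) != 4L) {
    abort("`voxels` must be a 4D array ordered (channel, z, y, x).")
  }
  if (length(channel_names) != dim(voxels)[1L]) {
    abort(sprintf("%d channel names supplied for %d channels.",
                  length(channel_names), dim(voxels)[1L]))
  }
  if (anyDuplicated(channel_names)) abort("`channel_names` must be unique.")
  if (!bit_depth %in% c(8, 16)) abort("`bit_depth` must be 8 or 16.")
  if (length(voxel_size_um) != 3L || any(voxel_size_um <= 0)) {
    abort("`voxel_size_um` must be 3 positive lengths (z, y, x).")
  }
  rng <- range(voxels)
  if (rng[1L] < 0 || rng[2L] > 2^bit_depth - 1) {
    abort(sprintf("Intensities must lie in [0, %d] for bit depth %d.",
                  2^bit_depth - 1, bit_depth))
  }
  structure(
    list(voxels = voxels, channel_names = as.character(channel_names),
         voxel_size_um = as.numeric(voxel_size_um), bit_depth = as.integer(bit_depth)),
    class = "channel_volume"
  )
}

#' @exportS3Method base::print
print.channel_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<channel_volume> %d channel(s) [%s], %d x %d x %d (z,y,x), %d-bit\n",
              d[1L], paste(x$channel_names, collapse = ", "),
              d[2L], d[3L], d[4L], x$bit_depth))
  cat(sprintf("  voxel size (um): z=%g y=%g x=%g\n",
              x$voxel_size_um[1L], x$voxel_size_um[2L], x$voxel_size_um[3L]))
  invisible(x)
}

#' Extract one channel as a 3D array
#'
#' @param volume A [channel_volume()].
#' @param channel Channel name.
#' @return Numeric 3D array `(z, y, x)`.
#' @export
get_channel <- function(volume, channel) {
  stopifnot(inherits(volume, "channel_volume"))
  i <- match(channel, volume$channel_names)
  if (is.na(i)) {
    abort(sprintf("Channel '%s' not found; volume has: %s.",
                  channel, paste(volume$channel_names, collapse = ", ")))
  }
  d <- dim(volume$voxels)
  array(volume$voxels[i, , , ], dim = d[2:4])
}

#' Grid dimensions of a volume
#' @param volume A [channel_volume()].
#' @return Integer `(z, y, x)` dimensions.
#' @export
volume_dim <- function(volume) {
  stopifnot(inherits(volume, "channel_volume"))
  dim(volume$voxels)[2:4]
}

#' Write a multi-channel volume to disk
#'
#' Writes a plain multi-page TIFF with channel-major page order (all z slices
#' of channel 1, then channel 2, ...) plus a JSON sidecar (`<path>.json`)
#' recording channel names, voxel size, bit depth and grid shape. Integer
#' intensities round-trip losslessly at 8 and 16 bit.
#'
#' @param volume A [channel_volume()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "channel_volume"))
  d <- volume_dim(volume)
  maxval <- 2^volume$bit_depth - 1
  pages <- vector("list", dim(volume$voxels)[1L] * d[1L])
  k <- 0L
  for (ci in seq_len(dim(volume$voxels)[1L])) {
    for (zi in seq_len(d[1L])) {
      k <- k + 1L
      pages[[k]] <- matrix(volume$voxels[ci, zi, , ], d[2L], d[3L]) / maxval
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = volume$bit_depth,
                  compression = "LZW", reduce = FALSE)
  meta <- list(channel_names = volume$channel_names,
               voxel_size_um = volume$voxel_size_um,
               bit_depth = volume$bit_depth,
               dim_zyx = as.integer(d))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-channel volume
#'
#' Reads a multi-page TIFF written by [write_volume()] (JSON sidecar present)
#' or any plain multi-page TIFF with an explicit channel mapping. Pages are
#' assumed channel-major: `length(pages) = n_channels * n_z`.
#'
#' @param path TIFF path.
#' @param channel_names Optional channel name override; required when no
#'   sidecar metadata exists.
#' @param voxel_size_um Optional voxel size override `(z, y, x)` in um.
#' @param bit_depth Optional bit depth override (8 or 16).
#' @param require_channels Optional character vector; an error names any
#'   channel missing from the volume (guards against misconfigured datasets).
#' @return A [channel_volume()].
#' @export
read_volume <- function(path, channel_names = NULL, voxel_size_um = NULL,
                        bit_depth = NULL, require_channels = NULL) {
  if (!file.exists(path)) abort(sprintf("No such file: '%s'.", path))
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE) else NULL
  channel_names <- channel_names %||% meta$channel_names
  if (is.null(channel_names)) {
    abort("No channel metadata found; supply `channel_names` explicitly.")
  }
  voxel_size_um <- voxel_size_um %||% meta$voxel_size_um %||% c(9, 6, 6)
  bit_depth <- bit_depth %||% meta$bit_depth %||% 16
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nc <- length(channel_names)
  if (length(pages) %% nc != 0L) {
    abort(sprintf("%d TIFF pages are not divisible by %d channels.",
                  length(pages), nc))
  }
  nz <- length(pages) %/% nc
  dy <- nrow(pages[[1L]]); dx <- ncol(pages[[1L]])
  maxval <- 2^bit_depth - 1
  vox <- array(0, dim = c(nc, nz, dy, dx))
  k <- 0L
  for (ci in seq_len(nc)) {
    for (zi in seq_len(nz)) {
      k <- k + 1L
      vox[ci, zi, , ] <- round(pages[[k]] * maxval, 6)
    }
  }
  vol <- channel_volume(vox, channel_names, voxel_size_um, bit_depth)
  if (!is.null(require_channels)) {
    missing <- setdiff(require_channels, vol$channel_names)
    if (length(missing)) {
      abort(sprintf("Volume '%s' is missing required channel(s): %s.",
                    path, paste(missing, collapse = ", ")))
    }
  }
  vol
}

manifest_required_cols <- c("sample_id", "tool", "condition", "axis_value",
                            "bio_replicate")

#' Load and validate a sample manifest
#'
#' The manifest CSV drives dataset-level processing: one row per imaged sample
#' with columns `sample_id`, `tool` (FGF/BMP/Nodal/none), `condition`
#' (dark/455nm/495nm_plus), `axis_value` (time in min or irradiance in W/m2),
#' `bio_replicate`, and optionally `path` (TIFF location, relative to the
#' manifest), `technical_rep`, and `manual_flags` (semicolon-separated visual
#' QC exclusion reasons, e.g. `off_frame;second_embryo`).
#'
#' @param path Manifest CSV path.
#' @return A tibble of validated sample metadata; `manual_flags` is a
#'   list-column of character vectors.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: '%s'.", path))
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(manifest_required_cols, names(df))
  if (length(missing)) {
    abort(sprintf("Manifest is missing required column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(df$sample_id)) {
    dup <- unique(df$sample_id[duplicated(df$sample_id)])
    abort(sprintf("Duplicate sample_id in manifest: %s.",
                  paste(dup, collapse = ", ")))
  }
  ax <- suppressWarnings(as.numeric(df$axis_value))
  if (anyNA(ax)) {
    bad <- which(is.na(ax))
    abort(sprintf("Non-numeric axis_value in manifest row(s) %s (sample_id %s).",
                  paste(bad, collapse = ", "),
                  paste(df$sample_id[bad], collapse = ", ")))
  }
  if (any(ax < 0)) abort("axis_value must be non-negative.")
  df$axis_value <- ax
  if (!"manual_flags" %in% names(df)) df$manual_flags <- NA_character_
  df$manual_flags <- lapply(df$manual_flags, function(s) {
    if (is.na(s) || !nzchar(s)) character() else strsplit(s, ";", fixed = TRUE)[[1L]]
  })
  if ("technical_rep" %in% names(df)) {
    df$technical_rep <- suppressWarnings(as.integer(df$technical_rep))
  }
  tibble::as_tibble(df)
}
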