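#' Quality-control configuration
#'
#' Thresholds for the automatable exclusion criteria. The coverage rule is
#' the assay's own: a sample is excluded when less than 5% of the embryo is
#' covered by the reporter (GFP) mask, indicating insufficient mRNA for
#' analysis. Saturation "streaking" is inherently a visual call; the
#' automated stand-in flags any channel whose fraction of saturated voxels
#' (at the bit-depth maximum) exceeds `max_saturated_fraction` — a heuristic,
#' documented as such. Damage in the nuclear channel is flagged when the
#' largest connected intra-embryo hole in the DAPI-positive region spans at
#' least `dapi_damage_fraction` of the embryo. Purely visual criteria
#' (off-frame, second embryo, mounting angle, truncated stack) pass through
#' as manual flags from the manifest.
#'
#' @param min_gfp_coverage Exclusion bound: fail if coverage < this (default 0.05).
#' @param max_saturated_fraction Per-channel saturated-voxel fraction trigger
#'   (default 0.01).
#' @param dapi_damage_fraction Hole-size fraction of embryo voxels treated as
#'   damage (default 1/3).
#' @return An object of class `qc_config`.
#' @export
qc_config <- function(min_gfp_coverage = 0.05, max_saturated_fraction = 0.01,
                      dapi_damage_fraction = 1 / 3) {
  structure(list(min_gfp_coverage = min_gfp_coverage,
                 max_saturated_fraction = max_saturated_fraction,
                 dapi_damage_fraction = dapi_damage_fraction),
            class = "qc_config")
}

#' Automatable QC gate for one sample
#'
#' Always returns a result; `passed` is `TRUE` iff `reasons` is empty.
#'
#' @param volume A [channel_volume()].
#' @param masks Named list with at least the `GFP` mask and the `DAPI` mask.
#' @param extent Embryo-extent [region_mask()] (see [embryo_extent()]).
#' @param config A [qc_config()].
#' @param gfp_coverage Precomputed coverage fraction; computed from
#'   `masks$GFP` and `extent` when `NULL`.
#' @param manual_flags Character vector of visual-QC exclusion reasons to
#'   pass through.
#' @param median_notes Optional `;`-separated notes from [region_medians()];
#'   any empty/undefined region is escalated to a QC failure.
#' @return A list: `passed` (logical), `reasons` (character vector drawn from
#'   `low_gfp_coverage`, `saturation_streaking`, `dapi_damage`,
#'   `manual_flag:<flag>`, `empty_region`).
#' @export
qc_check <- function(volume, masks, extent, config = qc_config(),
                     gfp_coverage = NULL, manual_flags = character(),
                     median_notes = "") {
  reasons <- character()
  n_embryo <- sum(extent$voxels)
  if (is.null(gfp_coverage)) {
    gfp_coverage <- if (n_embryo == 0L) 0 else
      sum(masks$GFP$voxels & extent$voxels) / n_embryo
  }
  if (gfp_coverage < config$min_gfp_coverage) {
    reasons <- c(reasons, "low_gfp_coverage")
  }
  satval <- 2^volume$bit_depth - 1
  for (ci in seq_along(volume$channel_names)) {
    frac <- mean(volume$voxels[ci, , , ] >= satval)
    if (frac > config$max_saturated_fraction) {
      reasons <- c(reasons, "saturation_streaking")
      break
    }
  }
  if (n_embryo > 0L && !is.na(extent$source_threshold)) {
    # Damage = an enclosed void in the above-background DAPI signal: a
    # connected below-background component that does not reach the volume
    # border (fill-holes definition), spanning >= the configured fraction
    # of the embryo.
    fg <- get_channel(volume, "DAPI") > extent$source_threshold
    lab <- label_components_3d(!fg)
    if (max(lab) > 0L) {
      d <- dim(fg)
      border <- array(FALSE, dim = d)
      border[c(1L, d[1L]), , ] <- TRUE
      border[, c(1L, d[2L]), ] <- TRUE
      border[, , c(1L, d[3L])] <- TRUE
      touching <- unique(lab[border & lab > 0L])
      sizes <- tabulate(lab[lab > 0L])
      sizes[touching] <- 0L
      if (length(sizes) && max(sizes) >= config$dapi_damage_fraction * n_embryo) {
        reasons <- c(reasons, "dapi_damage")
      }
    }
  }
  if (nzchar(median_notes)) reasons <- c(reasons, "empty_region")
  if (length(manual_flags)) {
    reasons <- c(reasons, paste0("manual_flag:", manual_flags))
  }
  list(passed = length(reasons) == 0L, reasons = reasons)
}
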