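#' Voxelwise GFP normalization of the effector channel
#'
#' Divides the effector channel voxelwise by the reporter (GFP) channel to
#' correct for heterogeneous distribution of the injected construct. Voxels
#' with zero reporter signal are undefined (`NA`) and excluded from all
#' downstream medians rather than clamped with an epsilon, which would
#' silently distort the medians.
#'
#' @param volume A [channel_volume()].
#' @param effector_channel,gfp_channel Channel names.
#' @param zero_policy Only `"exclude"` is implemented (see above).
#' @return A numeric 3D array of ratios (AU/AU) with `NA` where the reporter
#'   is zero; warns if the reporter channel is zero everywhere.
#' @export
normalize_effector <- function(volume, effector_channel = "EFFECTOR",
                               gfp_channel = "GFP",
                               zero_policy = c("exclude")) {
  zero_policy <- match.arg(zero_policy)
  eff <- get_channel(volume, effector_channel)
  gfp <- get_channel(volume, gfp_channel)
  out <- eff / gfp
  out[gfp <= 0] <- NA_real_
  if (all(is.na(out))) {
    warn("Reporter channel is zero everywhere; normalized volume is all-undefined.")
  }
  out
}

# Median over defined voxels in a mask; NA (never 0) when undefined.
masked_median <- function(arr, mask) {
  v <- arr[mask]
  v <- v[!is.na(v)]
  if (length(v) == 0L) NA_real_ else median(v)
}

#' Region-median statistics for one sample
#'
#' The six medians at the core of the quantification pipeline, computed over
#' the imaged 3D volume: raw and GFP-normalized effector signal within each
#' of the nuclear (DAPI), reporter (GFP), and intersection (DAPI+GFP)
#' regions. An even voxel count yields the mean of the two central order
#' statistics. An empty mask, or a mask whose normalized voxels are all
#' undefined, yields `NA` plus a QC note — never a silent zero.
#'
#' @param volume A [channel_volume()].
#' @param normalized Normalized array from [normalize_effector()].
#' @param masks Named list of [region_mask()]s: `DAPI`, `GFP`, `DAPI_GFP`.
#' @param effector_channel Effector channel name.
#' @return A one-row tibble with columns `raw_dapi`, `norm_dapi`, `raw_gfp`,
#'   `norm_gfp`, `raw_dapi_gfp`, `norm_dapi_gfp`, and `median_notes` (empty
#'   string when all six are defined).
#' @export
region_medians <- function(volume, normalized, masks,
                           effector_channel = "EFFECTOR") {
  stopifnot(all(c("DAPI", "GFP", "DAPI_GFP") %in% names(masks)))
  eff <- get_channel(volume, effector_channel)
  for (nm in c("DAPI", "GFP", "DAPI_GFP")) {
    if (!identical(dim(masks[[nm]]$voxels), dim(eff))) {
      abort(sprintf("Mask '%s' shape differs from the volume.", nm))
    }
  }
  if (!identical(dim(normalized), dim(eff))) {
    abort("Normalized array shape differs from the volume.")
  }
  out <- tibble::tibble(
    raw_dapi = masked_median(eff, masks$DAPI$voxels),
    norm_dapi = masked_median(normalized, masks$DAPI$voxels),
    raw_gfp = masked_median(eff, masks$GFP$voxels),
    norm_gfp = masked_median(normalized, masks$GFP$voxels),
    raw_dapi_gfp = masked_median(eff, masks$DAPI_GFP$voxels),
    norm_dapi_gfp = masked_median(normalized, masks$DAPI_GFP$voxels)
  )
  notes <- character()
  for (nm in c("DAPI", "GFP", "DAPI_GFP")) {
    if (!any(masks[[nm]]$voxels)) {
      notes <- c(notes, paste0("empty_region_", tolower(nm)))
    } else if (is.na(masked_median(normalized, masks[[nm]]$voxels))) {
      notes <- c(notes, paste0("undefined_normalized_", tolower(nm)))
    }
  }
  out$median_notes <- paste(notes, collapse = ";")
  out
}

#' Maximum intensity z-projection
#'
#' Per-(y, x) maximum over z. Passing a mask zeroes voxels outside it before
#' projecting — the "nuclear" projection applies the DAPI mask to the
#' effector channel.
#'
#' @param volume A [channel_volume()].
#' @param channel Channel name.
#' @param mask Optional [region_mask()] applied voxelwise before projection.
#' @return A numeric `(y, x)` matrix.
#' @export
max_projection <- function(volume, channel, mask = NULL) {
  arr <- get_channel(volume, channel)
  if (!is.null(mask)) {
    if (!identical(dim(mask$voxels), dim(arr))) {
      abort("Mask shape differs from the volume.")
    }
    arr <- arr * mask$voxels
  }
  d <- dim(arr)
  proj <- matrix(arr[1L, , ], d[2L], d[3L])
  for (zi in seq_len(d[1L])[-1L]) {
    proj <- pmax(proj, matrix(arr[zi, , ], d[2L], d[3L]))
  }
  proj
}

#' Overlap of an activation mask with an illuminated ROI
#'
#' Readout for spatially restricted activation: the fraction of
#' activation-positive voxels inside the illuminated region, its complement,
#' and the Dice coefficient. An empty activation mask is defined as zero
#' overlap and noted.
#'
#' @param activation_mask,illuminated_mask [region_mask()]s of equal shape.
#' @return A one-row tibble: `inside_fraction`, `outside_fraction`, `dice`,
#'   `note`.
#' @export
roi_overlap <- function(activation_mask, illuminated_mask) {
  a <- activation_mask$voxels
  r <- illuminated_mask$voxels
  if (!identical(dim(a), dim(r))) abort("Masks have different shapes.")
  na <- sum(a)
  if (na == 0L) {
    return(tibble::tibble(inside_fraction = 0, outside_fraction = 0, dice = 0,
                          note = "empty_activation_mask"))
  }
  inter <- sum(a & r)
  tibble::tibble(
    inside_fraction = inter / na,
    outside_fraction = 1 - inter / na,
    dice = 2 * inter / (na + sum(r)),
    note = ""
  )
}

#' Quantification configuration
#'
#' @param dapi_threshold,gfp_threshold Manual thresholds in AU, or `NULL` to
#'   use the automated Otsu default (mirroring the user-prompted workflow
#'   with a reproducible stand-in).
#' @param background_threshold Optional manual embryo-extent background
#'   threshold; `NULL` uses two-stage Otsu (see [embryo_extent()]).
#' @param qc A [qc_config()].
#' @return An object of class `quant_config`.
#' @export
quant_config <- function(dapi_threshold = NULL, gfp_threshold = NULL,
                         background_threshold = NULL, qc = qc_config()) {
  structure(list(dapi_threshold = dapi_threshold, gfp_threshold = gfp_threshold,
                 background_threshold = background_threshold, qc = qc),
            class = "quant_config")
}

#' Quantify one sample
#'
#' Runs the full per-sample pipeline: nuclear and reporter thresholds (Otsu
#' or manual), 3D masks and their intersection, voxelwise normalization, the
#' six region medians, GFP coverage of the embryo extent, and the QC gate.
#'
#' @param volume A [channel_volume()] with `DAPI`, `GFP`, `EFFECTOR` channels.
#' @param meta Optional one-row metadata (list or tibble row) with
#'   `sample_id`, `tool`, `condition`, `axis_value`, `bio_replicate`,
#'   `technical_rep`, `manual_flags`.
#' @param config A [quant_config()].
#' @return A one-row tibble: metadata, six medians, `gfp_coverage`,
#'   `qc_passed`, `qc_reasons` (`;`-separated), `median_notes`, and the
#'   thresholds used.
#' @export
quantify_sample <- function(volume, meta = NULL, config = quant_config()) {
  dapi_thr <- config$dapi_threshold %||% auto_threshold(volume, "DAPI")
  gfp_thr <- config$gfp_threshold %||% auto_threshold(volume, "GFP")
  m_dapi <- make_region_mask(volume, "DAPI", dapi_thr, "DAPI")
  m_gfp <- make_region_mask(volume, "GFP", gfp_thr, "GFP")
  m_int <- intersect_masks(m_dapi, m_gfp)
  extent <- embryo_extent(volume, "DAPI", config$background_threshold)
  norm <- normalize_effector(volume)
  med <- region_medians(volume, norm, list(DAPI = m_dapi, GFP = m_gfp,
                                           DAPI_GFP = m_int))
  n_embryo <- sum(extent$voxels)
  coverage <- if (n_embryo == 0L) 0 else sum(m_gfp$voxels & extent$voxels) / n_embryo
  manual_flags <- character()
  if (!is.null(meta)) {
    mf <- meta$manual_flags
    if (is.list(mf)) mf <- mf[[1L]]
    if (length(mf) && !all(is.na(mf))) manual_flags <- as.character(mf)
  }
  qc <- qc_check(volume, masks = list(DAPI = m_dapi, GFP = m_gfp),
                 extent = extent, config = config$qc,
                 gfp_coverage = coverage, manual_flags = manual_flags,
                 median_notes = med$median_notes)
  meta_cols <- tibble::tibble(
    sample_id = if (!is.null(meta)) as.character(meta$sample_id) else NA_character_,
    tool = if (!is.null(meta) && !is.null(meta$tool)) as.character(meta$tool) else NA_character_,
    condition = if (!is.null(meta) && !is.null(meta$condition)) as.character(meta$condition) else NA_character_,
    axis_value = if (!is.null(meta) && !is.null(meta$axis_value)) as.numeric(meta$axis_value) else NA_real_,
    bio_replicate = if (!is.null(meta) && !is.null(meta$bio_replicate)) as.character(meta$bio_replicate) else NA_character_,
    technical_rep = if (!is.null(meta) && !is.null(meta$technical_rep)) as.integer(meta$technical_rep) else NA_integer_
  )
  dplyr::bind_cols(
    meta_cols, med[, setdiff(names(med), "median_notes")],
    tibble::tibble(gfp_coverage = coverage,
                   qc_passed = qc$passed,
                   qc_reasons = paste(qc$reasons, collapse = ";"),
                   median_notes = med$median_notes,
                   dapi_threshold = dapi_thr, gfp_threshold = gfp_thr)
  )
}

#' Quantify every sample of a dataset
#'
#' Accepts either an in-memory `response_dataset` (from the synthetic
#' generators) or a directory containing `manifest.csv` plus per-sample TIFFs
#' (as written by [write_response_dataset()]).
#'
#' @param dataset A `response_dataset` or a directory path.
#' @param config A [quant_config()].
#' @return A tibble with one quantification row per sample.
#' @export
quantify_dataset <- function(dataset, config = quant_config()) {
  if (inherits(dataset, "response_dataset")) {
    rows <- purrr::map(seq_along(dataset$samples), function(i) {
      quantify_sample(dataset$samples[[i]]$volume, dataset$meta[i, ], config)
    })
    return(dplyr::bind_rows(rows))
  }
  if (!dir.exists(dataset)) abort(sprintf("No such dataset directory: '%s'.", dataset))
  man <- load_manifest(file.path(dataset, "manifest.csv"))
  if (!"path" %in% names(man)) abort("Manifest must have a `path` column for on-disk datasets.")
  rows <- purrr::map(seq_len(nrow(man)), function(i) {
    vol <- read_volume(file.path(dataset, man$path[i]),
                       require_channels = c("DAPI", "GFP", "EFFECTOR"))
    quantify_sample(vol, man[i, ], config)
  })
  dplyr::bind_rows(rows)
}
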