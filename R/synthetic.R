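#' Synthetic embryo ground truth
#'
#' Parameterizes a seeded synthetic gastrula-stage embryo: a hemispherical
#' cap of cells (animal pole up, z = 1 at the top of the stack) on a
#' featureless background, with non-overlapping spherical nuclei placed by
#' rejection sampling and mosaic reporter (GFP) expression modeled as smooth
#' random clonal patches. The reporter-positive region covers a controllable
#' fraction of the embryo, emulating the heterogeneous distribution of
#' injected mRNA that motivates voxelwise GFP normalization.
#'
#' @param grid_dim Integer `(z, y, x)` voxel grid.
#' @param voxel_size_um Voxel edge lengths `(z, y, x)` in um; the default
#'   mirrors a 9 um confocal z-interval.
#' @param embryo_radius_um Radius of the hemispherical cap (um).
#' @param n_nuclei Number of nuclei to place (>= 0).
#' @param nucleus_radius_um Nucleus radius (um).
#' @param reporter_coverage Fraction of embryo voxels that are
#'   reporter-positive (mosaic coverage), in (0, 1].
#' @param patch_scale_um Gaussian length scale of mosaic clonal patches (um).
#' @param gfp_au Expected reporter intensity inside reporter-positive voxels (AU).
#' @param dapi_nucleus_au Expected nuclear-stain intensity inside nuclei (AU).
#' @param dapi_cyto_au Expected diffuse nuclear-stain intensity elsewhere in
#'   the embryo (AU); keeps the embryo extent connected for QC.
#' @param background_au Expected intensity outside the embryo (camera offset, AU).
#' @param baseline_effector Effector intensity at zero activation (AU).
#' @param effector_gain Effector AU per reporter AU per unit activation.
#' @param noise_sd Additive Gaussian noise SD (AU), applied to every channel
#'   and clipped to `[0, saturation_value]`.
#' @param saturation_value Intensity ceiling (AU); must exceed
#'   `baseline_effector`.
#' @param seed Integer seed; identical truth + seed produce bit-identical
#'   volumes.
#' @return An object of class `embryo_truth`.
#' @export
embryo_truth <- function(grid_dim = c(64, 128, 128), voxel_size_um = c(9, 6, 6),
                         embryo_radius_um = 300, n_nuclei = 300,
                         nucleus_radius_um = 10, reporter_coverage = 0.5,
                         patch_scale_um = 40, gfp_au = 8000,
                         dapi_nucleus_au = 12000, dapi_cyto_au = 600,
                         background_au = 50, baseline_effector = 200,
                         effector_gain = 0.5, noise_sd = 100,
                         saturation_value = 65535, seed = 1L) {
  if (n_nuclei < 0) abort("`n_nuclei` must be >= 0.")
  if (any(c(embryo_radius_um, nucleus_radius_um, voxel_size_um) <= 0)) {
    abort("All lengths must be positive.")
  }
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (saturation_value <= baseline_effector) {
    abort("`saturation_value` must exceed `baseline_effector`.")
  }
  if (reporter_coverage <= 0 || reporter_coverage > 1) {
    abort("`reporter_coverage` must be in (0, 1].")
  }
  if (any(grid_dim < 1)) abort("Grid dimensions must be positive.")
  structure(
    list(grid_dim = as.integer(grid_dim), voxel_size_um = as.numeric(voxel_size_um),
         embryo_radius_um = embryo_radius_um, n_nuclei = as.integer(n_nuclei),
         nucleus_radius_um = nucleus_radius_um,
         reporter_coverage = reporter_coverage, patch_scale_um = patch_scale_um,
         gfp_au = gfp_au, dapi_nucleus_au = dapi_nucleus_au,
         dapi_cyto_au = dapi_cyto_au, background_au = background_au,
         baseline_effector = baseline_effector, effector_gain = effector_gain,
         noise_sd = noise_sd, saturation_value = saturation_value,
         seed = as.integer(seed)),
    class = "embryo_truth"
  )
}

# Voxel-center coordinate arrays (um) for a (z,y,x) grid.
voxel_coords <- function(grid_dim, voxel_size_um) {
  list(z = (seq_len(grid_dim[1L]) - 0.5) * voxel_size_um[1L],
       y = (seq_len(grid_dim[2L]) - 0.5) * voxel_size_um[2L],
       x = (seq_len(grid_dim[3L]) - 0.5) * voxel_size_um[3L])
}

# Deterministic embryo geometry: extent, nuclei, reporter field. Consumes RNG.
build_embryo_geometry <- function(truth) {
  d <- truth$grid_dim
  vs <- truth$voxel_size_um
  co <- voxel_coords(d, vs)
  R <- truth$embryo_radius_um
  # Sphere center: laterally centered, depth chosen so the cap (z <= cz)
  # starts just below the top of the stack.
  cz <- min(R + 0.05 * d[1L] * vs[1L], d[1L] * vs[1L])
  cy <- d[2L] * vs[2L] / 2
  cx <- d[3L] * vs[3L] / 2
  dz2 <- (co$z - cz)^2
  dy2 <- (co$y - cy)^2
  dx2 <- (co$x - cx)^2
  r2 <- outer(outer(dz2, dy2, `+`), dx2, `+`)
  embryo <- r2 <= R^2 & array(co$z <= cz, dim = d)
  if (!any(embryo)) abort("Embryo cap does not intersect the voxel grid.")

  # Non-overlapping nuclei by rejection sampling inside the cap.
  nr <- truth$nucleus_radius_um
  centers <- matrix(numeric(0), 0, 3)
  attempts <- 0L
  max_attempts <- 200L * max(truth$n_nuclei, 1L)
  while (nrow(centers) < truth$n_nuclei && attempts < max_attempts) {
    attempts <- attempts + 1L
    u <- stats::runif(3)
    cand <- c(cz - u[1L] * (R - nr),
              cy + (2 * u[2L] - 1) * (R - nr),
              cx + (2 * u[3L] - 1) * (R - nr))
    if (sum((cand - c(cz, cy, cx))^2) > (R - nr)^2) next
    if (cand[1L] < nr) next
    if (nrow(centers) > 0 &&
        min(colSums((t(centers) - cand)^2)) < (2 * nr)^2) next
    centers <- rbind(centers, cand)
  }
  nuclei <- array(FALSE, dim = d)
  if (nrow(centers) > 0) {
    for (i in seq_len(nrow(centers))) {
      ctr <- centers[i, ]
      zi <- which(abs(co$z - ctr[1L]) <= nr)
      yi <- which(abs(co$y - ctr[2L]) <= nr)
      xi <- which(abs(co$x - ctr[3L]) <= nr)
      if (!length(zi) || !length(yi) || !length(xi)) next
      loc <- outer(outer((co$z[zi] - ctr[1L])^2, (co$y[yi] - ctr[2L])^2, `+`),
                   (co$x[xi] - ctr[3L])^2, `+`) <= nr^2
      nuclei[zi, yi, xi] <- as.vector(nuclei[zi, yi, xi]) | as.vector(loc)
    }
  }
  nuclei <- nuclei & embryo

  # Mosaic reporter: sum of Gaussian bumps at random in-embryo centers,
  # thresholded at the quantile giving the requested coverage.
  emb_idx <- which(embryo)
  if (truth$reporter_coverage >= 1) {
    reporter <- embryo
  } else {
    n_patch <- max(5L, ceiling(3 / truth$reporter_coverage))
    pick <- emb_idx[ceiling(stats::runif(n_patch) * length(emb_idx))]
    pc <- arrayInd(pick, d)
    field <- array(0, dim = d)
    s2 <- 2 * truth$patch_scale_um^2
    for (i in seq_len(n_patch)) {
      fz <- exp(-(co$z - co$z[pc[i, 1L]])^2 / s2)
      fy <- exp(-(co$y - co$y[pc[i, 2L]])^2 / s2)
      fx <- exp(-(co$x - co$x[pc[i, 3L]])^2 / s2)
      field <- field + outer(outer(fz, fy, `*`), fx, `*`)
    }
    cut <- quantile(field[emb_idx], 1 - truth$reporter_coverage, names = FALSE)
    reporter <- embryo & field > cut
    if (!any(reporter)) reporter <- embryo & field >= cut
  }
  list(embryo = embryo, nuclei = nuclei, reporter = reporter)
}

#' Generate a synthetic multi-channel volume
#'
#' Renders one synthetic embryo as a three-channel volume (`DAPI`, `GFP`,
#' `EFFECTOR`). The expected effector intensity at a voxel is
#' `baseline_effector + effector_gain * activation_level * reporter
#' expectation`, restricted to `roi` when given and to nuclei when
#' `effector_localization = "nuclear"`. Gaussian noise is added, intensities
#' are clipped to `[0, saturation_value]` and rounded to integer counts.
#' The same truth and seed always produce bit-identical output.
#'
#' @param truth An [embryo_truth()].
#' @param activation_level Programmed pathway activation in `[0, 1]`.
#' @param effector_localization `"broad"` (e.g. cytoplasmic ppERK-like) or
#'   `"nuclear"` (e.g. pSmad-like).
#' @param roi Optional 3D index box restricting activation, as a list with
#'   integer ranges `z`, `y`, `x` (each `c(lo, hi)`, 1-based inclusive).
#' @return An object of class `synthetic_sample`: list with `volume`
#'   (a [channel_volume()]), `truth_masks` (ground-truth [region_mask()]s
#'   `nuclei`, `reporter`, `embryo`), `activation_level`, and `truth`.
#' @export
generate_volume <- function(truth, activation_level = 0,
                            effector_localization = c("broad", "nuclear"),
                            roi = NULL) {
  stopifnot(inherits(truth, "embryo_truth"))
  effector_localization <- match.arg(effector_localization)
  if (activation_level < 0 || activation_level > 1) {
    abort("`activation_level` must be in [0, 1].")
  }
  d <- truth$grid_dim
  if (!is.null(roi)) {
    if (!all(c("z", "y", "x") %in% names(roi))) {
      abort("`roi` must be a list with elements z, y, x (index ranges).")
    }
    for (ax in 1:3) {
      rg <- roi[[c("z", "y", "x")[ax]]]
      if (length(rg) != 2L || rg[1L] < 1 || rg[2L] > d[ax] || rg[1L] > rg[2L]) {
        abort(sprintf("`roi` %s-range [%s] is outside the volume bounds (1..%d).",
                      c("z", "y", "x")[ax], paste(rg, collapse = ", "), d[ax]))
      }
    }
  }
  withr::with_seed(truth$seed, {
    geo <- build_embryo_geometry(truth)
    gfp_expect <- truth$gfp_au * geo$reporter
    act <- array(activation_level, dim = d)
    if (!is.null(roi)) {
      box <- array(FALSE, dim = d)
      box[roi$z[1L]:roi$z[2L], roi$y[1L]:roi$y[2L], roi$x[1L]:roi$x[2L]] <- TRUE
      act <- act * box
    }
    if (effector_localization == "nuclear") act <- act * geo$nuclei
    dapi <- truth$background_au +
      (truth$dapi_cyto_au - truth$background_au) * geo$embryo +
      (truth$dapi_nucleus_au - truth$dapi_cyto_au) * geo$nuclei
    gfp <- truth$background_au * (!geo$reporter) + gfp_expect
    eff <- truth$baseline_effector + truth$effector_gain * act * gfp_expect
    vox <- array(0, dim = c(3L, d))
    vox[1L, , , ] <- dapi
    vox[2L, , , ] <- gfp
    vox[3L, , , ] <- eff
    if (truth$noise_sd > 0) {
      vox <- vox + rnorm(length(vox), 0, truth$noise_sd)
    }
    vox <- round(pmin(pmax(vox, 0), truth$saturation_value))
    bit <- if (truth$saturation_value <= 255) 8 else 16
    vol <- channel_volume(vox, c("DAPI", "GFP", "EFFECTOR"),
                          truth$voxel_size_um, bit)
    structure(
      list(volume = vol,
           truth_masks = list(
             nuclei = region_mask(geo$nuclei, "DAPI"),
             reporter = region_mask(geo$reporter, "GFP"),
             embryo = region_mask(geo$embryo, "EMBRYO")),
           activation_level = activation_level,
           effector_localization = effector_localization,
           truth = truth),
      class = "synthetic_sample"
    )
  })
}

#' Programmed logistic response truth
#'
#' The three-parameter logistic `y(x) = c / (1 + exp(-a (x - b)))` with lower
#' asymptote 0 that the synthetic datasets are programmed to follow, on
#' either the time axis (min) or the irradiance axis (W/m2).
#'
#' @param a_true Growth rate (per min or per W/m2); > 0 for `direction =
#'   "on"` on the time axis, < 0 for `direction = "off"`.
#' @param b_true Inflection point (min or W/m2).
#' @param c_true Upper asymptote (AU), >= 0.
#' @param axis `"time"` or `"irradiance"`.
#' @param direction `"on"` (rise) or `"off"` (decay after light removal).
#' @return An object of class `response_truth`.
#' @export
response_truth <- function(a_true, b_true, c_true, axis = c("time", "irradiance"),
                           direction = c("on", "off")) {
  axis <- match.arg(axis)
  direction <- match.arg(direction)
  if (c_true < 0) abort("`c_true` must be >= 0.")
  if (direction == "on" && axis == "time" && a_true <= 0) {
    abort("`a_true` must be > 0 for an 'on' time response.")
  }
  if (direction == "off" && a_true >= 0) {
    abort("`a_true` must be < 0 for an 'off' response.")
  }
  structure(list(a_true = a_true, b_true = b_true, c_true = c_true,
                 axis = axis, direction = direction),
            class = "response_truth")
}

#' Evaluate the programmed logistic response
#' @param truth A [response_truth()].
#' @param x Axis values (min or W/m2).
#' @return `c / (1 + exp(-a (x - b)))`.
#' @export
response_value <- function(truth, x) {
  truth$c_true / (1 + exp(-truth$a_true * (x - truth$b_true)))
}

#' Experimental design for a response dataset
#'
#' @param sample_points Strictly increasing non-negative time points (min) or
#'   irradiances (W/m2). The characterization designs this emulates used 11
#'   fixation time points (e.g. 0, 2, 8, 15, 22, 30, 35, 50, 60, 70, 85 min)
#'   and a 9-step irradiance ladder
#'   (0, 0.02, 0.05, 0.15, 0.46, 1.39, 4.17, 12.50, 50.00 W/m2).
#' @param n_bio_replicates Biological replicates (>= 1).
#' @param n_technical Technical replicates (embryos) per condition (>= 1).
#' @param dark_controls Generate a matched dark control per sample point and
#'   replicate?
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(sample_points, n_bio_replicates = 3,
                              n_technical = 1, dark_controls = TRUE) {
  if (length(sample_points) == 0) abort("`sample_points` must be non-empty.")
  if (any(sample_points < 0)) abort("`sample_points` must be non-negative.")
  if (is.unsorted(sample_points, strictly = TRUE)) {
    abort("`sample_points` must be strictly increasing.")
  }
  if (n_bio_replicates < 1 || n_technical < 1) {
    abort("Replicate counts must be >= 1.")
  }
  structure(list(sample_points = as.numeric(sample_points),
                 n_bio_replicates = as.integer(n_bio_replicates),
                 n_technical = as.integer(n_technical),
                 dark_controls = isTRUE(dark_controls)),
            class = "experiment_design")
}

#' Generate a full synthetic response dataset
#'
#' For each sample point `x` the programmed activation level is the logistic
#' fraction `y(x) / c_true`; matched dark controls are generated at
#' activation 0. Each sample is an independent embryo (its own seeded
#' geometry, mosaic and noise). A ground-truth manifest records all
#' programmed parameters.
#'
#' @param truth A [response_truth()].
#' @param design An [experiment_design()].
#' @param embryo An [embryo_truth()]; per-sample seeds are derived from
#'   `embryo$seed`.
#' @param tool Tool label carried in the metadata (`FGF`, `BMP`, `Nodal`).
#' @param effector_localization Passed to [generate_volume()].
#' @return An object of class `response_dataset`: list with `samples` (list of
#'   `synthetic_sample`), `meta` (tibble: sample_id, tool, condition,
#'   axis_value, bio_replicate, technical_rep, activation_true), and `truth`.
#' @export
generate_response_dataset <- function(truth, design, embryo, tool = "FGF",
                                      effector_localization = c("broad", "nuclear")) {
  stopifnot(inherits(truth, "response_truth"), inherits(design, "experiment_design"),
            inherits(embryo, "embryo_truth"))
  effector_localization <- match.arg(effector_localization)
  grid <- expand.grid(
    technical_rep = seq_len(design$n_technical),
    bio_replicate = seq_len(design$n_bio_replicates),
    axis_value = design$sample_points,
    condition = if (design$dark_controls) c("455nm", "dark") else "455nm",
    stringsAsFactors = FALSE
  )
  act_light <- response_value(truth, grid$axis_value) / max(truth$c_true, .Machine$double.eps)
  grid$activation_true <- ifelse(grid$condition == "dark", 0, pmin(pmax(act_light, 0), 1))
  samples <- vector("list", nrow(grid))
  ids <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    et <- embryo
    et$seed <- (embryo$seed + 7919L * i) %% .Machine$integer.max
    samples[[i]] <- generate_volume(et, grid$activation_true[i],
                                    effector_localization)
    ids[i] <- sprintf("%s_%s_x%g_b%d_t%d", tool, grid$condition[i],
                      grid$axis_value[i], grid$bio_replicate[i],
                      grid$technical_rep[i])
  }
  meta <- tibble::tibble(
    sample_id = ids, tool = tool, condition = grid$condition,
    axis_value = grid$axis_value,
    bio_replicate = as.character(grid$bio_replicate),
    technical_rep = grid$technical_rep,
    activation_true = grid$activation_true,
    manual_flags = replicate(nrow(grid), character(), simplify = FALSE)
  )
  structure(list(samples = samples, meta = meta,
                 truth = list(response = truth, design = design, embryo = embryo,
                              tool = tool,
                              effector_localization = effector_localization)),
            class = "response_dataset")
}

#' Generate a two-phase (on/off) synthetic kinetics dataset
#'
#' Composes a rise phase (light on, `x <= exposure_end`) and an optional
#' decay phase (light removed at `exposure_end`; programmed activation follows
#' the off-logistic in time since removal) into one time-course dataset with
#' matched dark controls, as acquired in an on/off kinetics experiment.
#'
#' @param on_truth A [response_truth()] with `direction = "on"`.
#' @param time_points Full fixation time ladder (min).
#' @param embryo An [embryo_truth()].
#' @param off_truth Optional [response_truth()] with `direction = "off"`
#'   (x measured from light removal).
#' @param exposure_end Light-off time (min), default 30.
#' @param n_bio_replicates,n_technical Replication.
#' @param tool,effector_localization As in [generate_response_dataset()].
#' @return A `response_dataset`.
#' @export
generate_kinetics_dataset <- function(on_truth, time_points, embryo,
                                      off_truth = NULL, exposure_end = 30,
                                      n_bio_replicates = 3, n_technical = 1,
                                      tool = "FGF",
                                      effector_localization = c("broad", "nuclear")) {
  stopifnot(inherits(on_truth, "response_truth"))
  effector_localization <- match.arg(effector_localization)
  design <- experiment_design(time_points, n_bio_replicates, n_technical, TRUE)
  grid <- expand.grid(
    technical_rep = seq_len(n_technical),
    bio_replicate = seq_len(n_bio_replicates),
    axis_value = time_points,
    condition = c("455nm", "dark"),
    stringsAsFactors = FALSE
  )
  act_of_t <- function(t) {
    if (t <= exposure_end || is.null(off_truth)) {
      response_value(on_truth, min(t, exposure_end)) / max(on_truth$c_true, .Machine$double.eps)
    } else {
      response_value(off_truth, t - exposure_end) / max(off_truth$c_true, .Machine$double.eps)
    }
  }
  act <- vapply(grid$axis_value, act_of_t, numeric(1))
  grid$activation_true <- ifelse(grid$condition == "dark", 0, pmin(pmax(act, 0), 1))
  samples <- vector("list", nrow(grid))
  ids <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    et <- embryo
    et$seed <- (embryo$seed + 7919L * i) %% .Machine$integer.max
    samples[[i]] <- generate_volume(et, grid$activation_true[i],
                                    effector_localization)
    ids[i] <- sprintf("%s_%s_x%g_b%d_t%d", tool, grid$condition[i],
                      grid$axis_value[i], grid$bio_replicate[i],
                      grid$technical_rep[i])
  }
  meta <- tibble::tibble(
    sample_id = ids, tool = tool, condition = grid$condition,
    axis_value = grid$axis_value,
    bio_replicate = as.character(grid$bio_replicate),
    technical_rep = grid$technical_rep,
    activation_true = grid$activation_true,
    manual_flags = replicate(nrow(grid), character(), simplify = FALSE)
  )
  structure(list(samples = samples, meta = meta,
                 truth = list(response = on_truth, off_response = off_truth,
                              design = design, embryo = embryo, tool = tool,
                              exposure_end = exposure_end,
                              effector_localization = effector_localization)),
            class = "response_dataset")
}

#' Write a response dataset to disk
#'
#' One multi-page TIFF (+ JSON sidecar) per sample, a `manifest.csv`, and a
#' `truth.json` recording the programmed parameters.
#'
#' @param dataset A `response_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_response_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "response_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(nrow(dataset$meta))
  for (i in seq_along(dataset$samples)) {
    paths[i] <- paste0(dataset$meta$sample_id[i], ".tif")
    write_volume(dataset$samples[[i]]$volume, file.path(dir, paths[i]))
  }
  man <- dataset$meta
  man$path <- paths
  man$manual_flags <- vapply(man$manual_flags, paste, "", collapse = ";")
  readr::write_csv(man, file.path(dir, "manifest.csv"))
  tr <- dataset$truth
  tr$response <- unclass(tr$response)
  if (!is.null(tr$off_response)) tr$off_response <- unclass(tr$off_response)
  tr$design <- unclass(tr$design)
  tr$embryo <- unclass(tr$embryo)
  jsonlite::write_json(tr, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}
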