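#' Boolean 3D region mask
#'
#' @param voxels Logical 3D array `(z, y, x)`.
#' @param region_name Region label, conventionally one of `DAPI`, `GFP`,
#'   `DAPI_GFP`, `EMBRYO`.
#' @param source_threshold The intensity threshold (AU) that produced the
#'   mask, or `NA` when not threshold-derived.
#' @return An object of class `region_mask`.
#' @export
region_mask <- function(voxels, region_name, source_threshold = NA_real_) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L || !is.logical(voxels)) {
    abort("`voxels` must be a logical 3D array (z, y, x).")
  }
  structure(list(voxels = voxels, region_name = as.character(region_name),
                 source_threshold = as.numeric(source_threshold)),
            class = "region_mask")
}

#' @exportS3Method base::print
print.region_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<region_mask> '%s' %d x %d x %d, %d voxels (%.2f%%), threshold %s\n",
              x$region_name, d[1L], d[2L], d[3L], sum(x$voxels),
              100 * mean(x$voxels),
              if (is.na(x$source_threshold)) "NA" else format(x$source_threshold)))
  invisible(x)
}

#' Automatic or manual intensity threshold
#'
#' The automated default is Otsu's method: the threshold maximizing
#' between-class variance of the intensity histogram, computed exactly over
#' the unique intensity values (binned to `n_bins` levels when there are more
#' unique values than bins). The mask rule downstream is strict
#' (`intensity > threshold`), so the returned value is the upper edge of the
#' lower class. `method = "manual"` returns `value` unchanged, mirroring a
#' user-prompted thresholding workflow.
#'
#' @param volume A [channel_volume()] (or bare numeric array).
#' @param channel Channel name (ignored for bare arrays).
#' @param method `"otsu"` or `"manual"`.
#' @param value Threshold in AU, required for `method = "manual"`.
#' @param n_bins Histogram resolution for Otsu on near-continuous data.
#' @return Threshold in AU.
#' @export
auto_threshold <- function(volume, channel = NULL, method = c("otsu", "manual"),
                           value = NULL, n_bins = 256) {
  method <- match.arg(method)
  if (method == "manual") {
    if (is.null(value)) abort("`value` is required for method = 'manual'.")
    return(as.numeric(value))
  }
  x <- if (inherits(volume, "channel_volume")) get_channel(volume, channel) else volume
  x <- as.numeric(x)
  ux <- sort(unique(x))
  if (length(ux) < 2L) abort("Otsu threshold undefined for a constant image.")
  if (length(ux) > n_bins) {
    breaks <- seq(min(x), max(x), length.out = n_bins + 1L)
    counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE), n_bins)
    levels <- (head(breaks, -1L) + breaks[-1L]) / 2
    keep <- counts > 0
    counts <- counts[keep]; levels <- levels[keep]
  } else {
    levels <- ux
    counts <- tabulate(match(x, ux), length(ux))
  }
  otsu_split(levels, counts)
}

# Between-class-variance maximizing split of a weighted histogram.
# Candidate thresholds are the histogram levels; classes are {<= t}, {> t}.
otsu_split <- function(levels, counts) {
  n <- sum(counts)
  w <- counts / n
  mu <- sum(w * levels)
  cw <- cumsum(w)
  cmu <- cumsum(w * levels)
  k <- length(levels) - 1L
  w0 <- cw[seq_len(k)]
  m0 <- cmu[seq_len(k)] / w0
  w1 <- 1 - w0
  m1 <- (mu - cmu[seq_len(k)]) / w1
  sb <- w0 * w1 * (m0 - m1)^2
  levels[which.max(sb)]
}

#' Threshold a channel into a 3D region mask
#'
#' Mask membership is strict: a voxel is in the mask iff its intensity is
#' strictly greater than `threshold` (so a threshold at the global maximum
#' yields an empty mask).
#'
#' @param volume A [channel_volume()].
#' @param channel Channel name.
#' @param threshold Intensity threshold in AU (>= 0).
#' @param region_name Mask label; defaults to the channel name.
#' @return A [region_mask()].
#' @export
make_region_mask <- function(volume, channel, threshold,
                             region_name = channel) {
  if (threshold < 0) abort("`threshold` must be >= 0.")
  arr <- get_channel(volume, channel)
  region_mask(arr > threshold, region_name, threshold)
}

#' Intersect two region masks
#'
#' Voxelwise conjunction; the conventional product of the nuclear (DAPI) and
#' reporter (GFP) masks is the `DAPI_GFP` region used for nuclear-localized
#' effectors.
#'
#' @param m1,m2 [region_mask()] objects of identical shape.
#' @param region_name Label for the intersection (default `DAPI_GFP`).
#' @return A [region_mask()].
#' @export
intersect_masks <- function(m1, m2, region_name = "DAPI_GFP") {
  stopifnot(inherits(m1, "region_mask"), inherits(m2, "region_mask"))
  if (!identical(dim(m1$voxels), dim(m2$voxels))) {
    abort("Masks have different shapes and cannot be intersected.")
  }
  region_mask(m1$voxels & m2$voxels, region_name)
}

# 6-connected component labeling of a logical 3D array via igraph.
# Returns an integer array: 0 background, components numbered by decreasing size.
label_components_3d <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  lab <- array(0L, dim = d)
  if (length(idx) == 0L) return(lab)
  rank <- integer(prod(d))
  rank[idx] <- seq_along(idx)
  coords <- arrayInd(idx, d)
  edges <- integer(0)
  strides <- c(1L, d[1L], d[1L] * d[2L])
  for (ax in 1:3) {
    ok <- coords[, ax] < d[ax]
    nb <- idx[ok] + strides[ax]
    both <- mask[nb]
    if (any(both)) {
      from <- rank[idx[ok][both]]
      to <- rank[nb[both]]
      edges <- c(edges, rbind(from, to))
    }
  }
  g <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)
  ord <- order(comp$csize, decreasing = TRUE)
  relabel <- integer(comp$no)
  relabel[ord] <- seq_len(comp$no)
  lab[idx] <- relabel[comp$membership]
  lab
}

#' Largest connected component of a mask
#'
#' 6-connectivity in 3D.
#'
#' @param mask A [region_mask()] or logical 3D array.
#' @return A logical 3D array marking the largest component (all `FALSE` for
#'   an empty mask).
#' @export
largest_component <- function(mask) {
  m <- if (inherits(mask, "region_mask")) mask$voxels else mask
  lab <- label_components_3d(m)
  lab == 1L & m
}

#' Embryo extent from the nuclear stain
#'
#' The embryo footprint used for coverage-based QC: the largest connected
#' component of the DAPI channel above a low background threshold. By default
#' the background threshold is found by two-stage Otsu — a first Otsu split
#' separates bright nuclei from everything else, and a second Otsu restricted
#' to the sub-nuclear intensities separates diffuse intra-embryo signal from
#' the featureless background.
#'
#' @param volume A [channel_volume()].
#' @param dapi_channel Nuclear stain channel name.
#' @param background_threshold Optional manual background threshold (AU).
#' @return A [region_mask()] named `EMBRYO`.
#' @export
embryo_extent <- function(volume, dapi_channel = "DAPI",
                          background_threshold = NULL) {
  arr <- get_channel(volume, dapi_channel)
  if (is.null(background_threshold)) {
    t1 <- auto_threshold(arr)
    low <- arr[arr <= t1]
    background_threshold <- if (length(unique(low)) < 2L) t1 else auto_threshold(low)
  }
  fg <- arr > background_threshold
  region_mask(largest_component(fg), "EMBRYO", background_threshold)
}
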