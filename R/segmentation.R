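#' Segmentation parameters
#'
#' Controls how TH+ structures are extracted from a volume: an optional
#' high-pass background subtraction, an intensity threshold (absolute or as
#' a percentile of the nonzero voxels), voxel-count bounds on connected
#' components, and the labeling connectivity.
#'
#' @param background_sigma_um Gaussian scale (µm) of the background
#'   estimate subtracted before thresholding; 0 disables.
#' @param threshold absolute intensity threshold. Exactly one of
#'   `threshold` / `threshold_percentile` must be given.
#' @param threshold_percentile percentile (0-100) of the nonzero voxel
#'   intensities used as the threshold.
#' @param min_voxels,max_voxels retained components must have a voxel count
#'   in `[min_voxels, max_voxels]`. `min_voxels = NULL` defaults to the
#'   voxel volume of a 7 µm sphere at the volume's spacing (at least 1).
#' @param connectivity 6, 18 or 26 (default).
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(background_sigma_um = 0, threshold = NULL,
                                threshold_percentile = NULL,
                                min_voxels = NULL, max_voxels = Inf,
                                connectivity = 26L) {
  if (is.null(threshold) && is.null(threshold_percentile))
    threshold_percentile <- 99
  if (!is.null(threshold) && !is.null(threshold_percentile))
    stop("give either threshold or threshold_percentile, not both",
         call. = FALSE)
  if (!is.null(threshold_percentile))
    stopifnot(threshold_percentile >= 0, threshold_percentile <= 100)
  stopifnot(background_sigma_um >= 0, connectivity %in% c(6L, 18L, 26L))
  if (!is.null(min_voxels) && !is.infinite(max_voxels))
    stopifnot(min_voxels <= max_voxels)
  list(background_sigma_um = background_sigma_um, threshold = threshold,
       threshold_percentile = threshold_percentile,
       min_voxels = min_voxels, max_voxels = max_voxels,
       connectivity = as.integer(connectivity))
}

#' Subtract a smooth tissue background
#'
#' Estimates the background as a wide Gaussian smoothing of the volume and
#' returns `max(volume - background, 0)`. With `sigma_um = 0` the volume is
#' returned unchanged.
#'
#' @param volume a [volume3d].
#' @param background_sigma_um Gaussian scale in µm (isotropic in physical
#'   units).
#' @return The background-subtracted [volume3d].
#' @export
subtract_background <- function(volume, background_sigma_um) {
  stopifnot(background_sigma_um >= 0)
  if (background_sigma_um == 0) return(volume)
  bg <- gaussian_blur(volume, background_sigma_um)
  volume$data <- pmax(volume$data - bg$data, 0)
  volume
}

default_min_voxels <- function(spacing_um) {
  max(1L, as.integer(round((4 / 3) * pi * 3.5^3 / prod(spacing_um))))
}

# physical-space shape descriptors of labeled components.
# Principal extents are ranges of voxel-center projections onto the
# eigenvectors of the second-moment (covariance) tensor computed in µm,
# plus the voxel footprint along each eigenvector, so single-voxel
# components have spacing-scale extents and elongation ~ 1.
component_table <- function(labels, n_comp, intensity, spacing, origin) {
  if (n_comp == 0)
    return(data.frame(label = integer(0), voxels = integer(0),
                      volume_um3 = numeric(0), mean_intensity = numeric(0),
                      max_intensity = numeric(0), centroid_z_um = numeric(0),
                      centroid_y_um = numeric(0), centroid_x_um = numeric(0),
                      extent_major_um = numeric(0),
                      extent_mid_um = numeric(0),
                      extent_minor_um = numeric(0), elongation = numeric(0)))
  idx <- which(labels > 0)
  lab <- labels[idx]
  co <- arrayInd(idx, dim(labels))
  coords <- sweep(sweep(co - 0.5, 2, spacing, "*"), 2, origin, "+")
  vals <- intensity[idx]
  ord <- split(seq_along(idx), lab)
  vox_vol <- prod(spacing)
  rows <- lapply(seq_len(n_comp), function(k) {
    sel <- ord[[as.character(k)]]
    pts <- coords[sel, , drop = FALSE]
    n <- length(sel)
    ctr <- colMeans(pts)
    if (n > 1) {
      cen <- sweep(pts, 2, ctr)
      cv <- crossprod(cen) / n
      ev <- eigen(cv, symmetric = TRUE)
      vecs <- ev$vectors
    } else {
      vecs <- diag(3)
    }
    ext <- vapply(1:3, function(j) {
      pr <- pts %*% vecs[, j]
      diff(range(pr)) + sum(abs(vecs[, j]) * spacing)
    }, numeric(1))
    ext <- sort(ext, decreasing = TRUE)
    data.frame(label = k, voxels = n, volume_um3 = n * vox_vol,
               mean_intensity = mean(vals[sel]),
               max_intensity = max(vals[sel]),
               centroid_z_um = ctr[1], centroid_y_um = ctr[2],
               centroid_x_um = ctr[3],
               extent_major_um = ext[1], extent_mid_um = ext[2],
               extent_minor_um = ext[3],
               elongation = ext[1] / ext[3])
  })
  do.call(rbind, rows)
}

new_labeled_mask <- function(labels, components, volume, intensity,
                             threshold, params) {
  structure(list(
    labels = labels, components = components,
    intensity = intensity, threshold = threshold, params = params,
    spacing_um = volume$spacing_um, origin_um = volume$origin_um,
    rostrocaudal_axis = volume$rostrocaudal_axis,
    rostrocaudal_dir = volume$rostrocaudal_dir,
    midline_axis = volume$midline_axis,
    midline_um = midline_coordinate(volume)
  ), class = "labeled_mask")
}

#' @export
print.labeled_mask <- function(x, ...) {
  cat(sprintf("<labeled_mask> %d components, %d mask voxels, threshold %s\n",
              nrow(x$components), sum(x$labels > 0), format(x$threshold)))
  invisible(x)
}

#' Segment TH+ structures by intensity and voxel size
#'
#' Thresholds the (optionally background-subtracted) volume, labels
#' connected components at the configured connectivity, discards components
#' whose voxel count falls outside `[min_voxels, max_voxels]`, and computes
#' physical-space shape descriptors for the survivors. Surviving components
#' are relabeled densely `1..K` in scan order.
#'
#' @param volume a [volume3d].
#' @param params a [segmentation_params()].
#' @return A `labeled_mask`: the label array plus a per-component table
#'   (`voxels`, `volume_um3`, `mean_intensity`, `max_intensity`, centroid,
#'   principal extents in µm, `elongation`).
#' @export
segment <- function(volume, params = segmentation_params()) {
  work <- subtract_background(volume, params$background_sigma_um)
  vals <- work$data
  thr <- if (!is.null(params$threshold)) params$threshold else {
    nz <- vals[vals > 0]
    if (length(nz) == 0) Inf else
      stats::quantile(nz, params$threshold_percentile / 100, names = FALSE)
  }
  binary <- vals >= thr
  d <- dim(vals)
  labels <- array(cc_label_3d(as.logical(binary), d, params$connectivity), d)
  n_raw <- max(labels)
  min_vox <- if (is.null(params$min_voxels))
    default_min_voxels(volume$spacing_um) else params$min_voxels
  if (n_raw > 0) {
    sizes <- tabulate(labels[labels > 0], nbins = n_raw)
    keep <- which(sizes >= min_vox & sizes <= params$max_voxels)
    remap <- integer(n_raw)
    remap[keep] <- seq_along(keep)
    labels[labels > 0] <- remap[labels[labels > 0]]
    n_comp <- length(keep)
  } else n_comp <- 0L
  comps <- component_table(labels, n_comp, vals, volume$spacing_um,
                           volume$origin_um)
  new_labeled_mask(labels, comps, volume, vals, thr, params)
}

#' Exclude vessel-like components from a labeled mask
#'
#' Operationalizes the purge of non-relevant signals (blood vessels
#' occasionally traversing the nuclei) as a joint shape rule in physical
#' units: a component is removed iff its longest principal extent strictly
#' exceeds `max_extent_um` AND its elongation (longest / shortest principal
#' extent) strictly exceeds `max_elongation`. Components at exactly a
#' threshold value are kept. Survivors keep their geometry and descriptors
#' untouched (labels are renumbered densely).
#'
#' @param mask a `labeled_mask` from [segment()].
#' @param max_extent_um extent threshold (µm); perikarya are an order of
#'   magnitude shorter than traversing vessels.
#' @param max_elongation elongation threshold; somata are near-spherical
#'   (elongation close to 1), vessels are thin tubes.
#' @return The filtered `labeled_mask`.
#' @export
exclude_vessels <- function(mask, max_extent_um = 100, max_elongation = 5) {
  stopifnot(max_extent_um > 0, max_elongation > 0)
  comps <- mask$components
  if (nrow(comps) == 0) return(mask)
  drop <- comps$extent_major_um > max_extent_um &
    comps$elongation > max_elongation
  keep <- comps$label[!drop]
  remap <- integer(nrow(comps))
  remap[keep] <- seq_along(keep)
  labels <- mask$labels
  labels[labels > 0] <- remap[labels[labels > 0]]
  comps <- comps[!drop, , drop = FALSE]
  comps$label <- seq_len(nrow(comps))
  rownames(comps) <- NULL
  mask$labels <- labels
  mask$components <- comps
  mask
}
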