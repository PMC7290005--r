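#' Measuring-sphere parameters
#'
#' A measuring sphere is a fixed-diameter ball of voxels placed into the
#' segmented mask; one accepted sphere is one counted perikaryon (or, in
#' the slab analysis, one pathway unit). `fit_fraction` is the minimum
#' fraction of the sphere's voxels that must be uncovered mask voxels for
#' the sphere to be accepted: low enough to tolerate partially blurred
#' somata, high enough to reject thin fibers.
#'
#' @param diameter_um sphere diameter (µm); must exceed the largest voxel
#'   spacing. Default 12 µm, a typical P7 dopaminergic soma scale.
#' @param fit_fraction minimum fraction in `(0, 1]`.
#' @return A `sphere_params` list.
#' @export
sphere_params <- function(diameter_um = 12, fit_fraction = 0.5) {
  stopifnot(diameter_um > 0, fit_fraction > 0, fit_fraction <= 1)
  list(diameter_um = diameter_um, fit_fraction = fit_fraction)
}

# integer voxel offsets (dz, dy, dx) of the sphere stencil at a spacing
sphere_offsets <- function(spacing_um, diameter_um) {
  if (diameter_um <= max(spacing_um))
    stop("sphere diameter must exceed the largest voxel spacing",
         call. = FALSE)
  r <- diameter_um / 2
  rng <- floor(r / spacing_um)
  g <- as.matrix(expand.grid(dz = -rng[1]:rng[1], dy = -rng[2]:rng[2],
                             dx = -rng[3]:rng[3]))
  d2 <- (g[, 1] * spacing_um[1])^2 + (g[, 2] * spacing_um[2])^2 +
    (g[, 3] * spacing_um[3])^2
  g[d2 <= r * r + 1e-9, , drop = FALSE]
}

new_sphere_array <- function(centers_um, roi_name, params) {
  structure(list(centers_um = centers_um, count = nrow(centers_um),
                 roi = roi_name, params = params),
            class = "sphere_array")
}

#' @export
print.sphere_array <- function(x, ...) {
  cat(sprintf("<sphere_array> roi '%s': %d spheres of %g um\n",
              x$roi, x$count, x$params$diameter_um))
  invisible(x)
}

#' Generate a measuring-sphere array inside a reference cuboid
#'
#' Greedy deterministic sphere packing over the mask voxels restricted to
#' the ROI: candidate centers are visited in order of decreasing underlying
#' intensity (ties broken by lowest `(z, y, x)` index); a sphere is
#' accepted iff at least `fit_fraction` of its voxels are uncovered mask
#' voxels and its center is at least one diameter away from every accepted
#' center (so accepted spheres never overlap); accepted spheres mark their
#' voxels covered. The run stops when no acceptable center remains.
#'
#' @param mask a `labeled_mask` from [segment()] (typically after
#'   [exclude_vessels()]).
#' @param roi a [reference_cuboid] in the same physical frame as the mask.
#' @param params a [sphere_params()].
#' @return A `sphere_array` with the accepted centers (µm) and their count.
#' @export
generate_sphere_array <- function(mask, roi, params = sphere_params()) {
  d <- dim(mask$labels)
  roi_vol <- volume3d(mask$labels, mask$spacing_um,
                      rostrocaudal_axis = mask$rostrocaudal_axis,
                      rostrocaudal_dir = mask$rostrocaudal_dir,
                      midline_axis = mask$midline_axis,
                      midline_um = mask$midline_um,
                      origin_um = mask$origin_um)
  rng <- cuboid_index_ranges(roi_vol, roi)
  if (any(lengths(rng) == 0))
    stop(sprintf("ROI '%s' does not intersect the mask frame", roi$name),
         call. = FALSE)
  inroi <- array(FALSE, d)
  inroi[rng[[1]], rng[[2]], rng[[3]]] <- TRUE
  sel <- (mask$labels > 0) & inroi
  offs <- sphere_offsets(mask$spacing_um, params$diameter_um)
  centers <- pack_spheres_cpp(as.numeric(mask$intensity), as.logical(sel),
                              d, offs, params$fit_fraction,
                              mask$spacing_um, params$diameter_um)
  centers_um <- sweep(sweep(centers - 0.5, 2, mask$spacing_um, "*"),
                      2, mask$origin_um, "+")
  colnames(centers_um) <- c("z_um", "y_um", "x_um")
  new_sphere_array(as.data.frame(centers_um), roi$name, params)
}

#' Count TH+ perikarya per reference cuboid
#'
#' Runs [generate_sphere_array()] for every configured ROI. Substantia
#' nigra style per-side ROIs (`left` / `right`) are counted separately and
#' must not overlap each other; `bilateral_midline` ROIs must straddle the
#' mask's midline plane and are counted once.
#'
#' @param mask a `labeled_mask`.
#' @param rois list of [reference_cuboid] objects.
#' @param params a [sphere_params()].
#' @return A `count_report`: data frame with one row per ROI (`roi`,
#'   `laterality`, `count`), with the sphere arrays attached as the
#'   `"spheres"` attribute.
#' @export
count_perikarya <- function(mask, rois, params = sphere_params()) {
  lat <- vapply(rois, `[[`, "", "laterality")
  lefts <- which(lat == "left")
  rights <- which(lat == "right")
  for (i in lefts) for (j in rights) {
    a <- rois[[i]]; b <- rois[[j]]
    if (all(a$min_um < b$max_um & b$min_um < a$max_um))
      stop(sprintf(
        "left/right ROI pair '%s' / '%s' overlap: per-side counting needs disjoint cuboids",
        a$name, b$name), call. = FALSE)
  }
  mid <- mask$midline_um
  for (r in rois[lat == "bilateral_midline"]) {
    a <- axis_index(mask$midline_axis)
    if (!(r$min_um[a] < mid && mid < r$max_um[a]))
      stop(sprintf(
        "bilateral ROI '%s' does not straddle the midline plane at %g um",
        r$name, mid), call. = FALSE)
  }
  arrays <- lapply(rois, function(r) generate_sphere_array(mask, r, params))
  rep <- data.frame(
    roi = vapply(rois, `[[`, "", "name"),
    laterality = lat,
    count = vapply(arrays, `[[`, integer(1), "count")
  )
  attr(rep, "spheres") <- arrays
  class(rep) <- c("count_report", class(rep))
  rep
}
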