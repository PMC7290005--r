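#' Slab specification for pathway-unit counting
#'
#' The pathway-unit statistic intersects the segmented TH+ fascicles with
#' a thin coronal slab laid orthogonally to the rostrocaudal axis at the
#' rostral limit of the A11/A13 cell groups. The slab thickness must not
#' exceed the measuring-sphere diameter (inclusive), a hard constraint of
#' the method.
#'
#' @param thickness_um slab thickness along the rostrocaudal axis (µm).
#' @param sphere_params a [sphere_params()] used for unit counting.
#' @param rostral_limit_um slab position along the rostrocaudal axis; `NULL`
#'   means locate it automatically from a segmented A11-13 mask with
#'   [locate_rostral_limit()].
#' @param lateral_min_um,lateral_max_um optional `(z, y, x)` bounds
#'   restricting the slab on the two non-rostrocaudal axes (the
#'   rostrocaudal entries are ignored); `NULL` spans the full volume, which
#'   is safe because admission rules exclude non-tract structures laterally
#'   only when they reach the slab plane.
#' @param min_fascicle_diameter_um minimum in-plane diameter (µm) for an
#'   intersection window to count as a fascicle; measured as the
#'   area-equivalent diameter of the window's in-plane cross-section.
#' @param min_fascicle_intensity minimum voxel intensity for admission
#'   into the fascicle mask (0 admits every segmented voxel).
#' @return A `slab_spec` list.
#' @export
slab_spec <- function(thickness_um = 12, sphere_params = NULL,
                      rostral_limit_um = NULL,
                      lateral_min_um = NULL, lateral_max_um = NULL,
                      min_fascicle_diameter_um = 10,
                      min_fascicle_intensity = 0) {
  if (is.null(sphere_params))
    sphere_params <- list(diameter_um = 12, fit_fraction = 0.5)
  stopifnot(thickness_um > 0, min_fascicle_diameter_um >= 0,
            min_fascicle_intensity >= 0)
  list(thickness_um = thickness_um, sphere_params = sphere_params,
       rostral_limit_um = rostral_limit_um,
       lateral_min_um = lateral_min_um, lateral_max_um = lateral_max_um,
       min_fascicle_diameter_um = min_fascicle_diameter_um,
       min_fascicle_intensity = min_fascicle_intensity)
}

#' Locate the rostral limit of a labeled mask
#'
#' Returns the physical coordinate, along the configured rostrocaudal
#' axis, of the most-rostral voxel center carrying any label — used to
#' place the measuring slab at the rostral limit of the A11-13 groups.
#'
#' @param mask a nonempty `labeled_mask` (typically the segmentation
#'   restricted to the A11-13 reference cuboid).
#' @return Scalar coordinate in µm.
#' @export
locate_rostral_limit <- function(mask) {
  idx <- which(mask$labels > 0)
  if (length(idx) == 0)
    stop("cannot locate rostral limit: mask is empty", call. = FALSE)
  a <- axis_index(mask$rostrocaudal_axis)
  co <- arrayInd(idx, dim(mask$labels))[, a]
  coord <- mask$origin_um[a] + (co - 0.5) * mask$spacing_um[a]
  if (mask$rostrocaudal_dir > 0) min(coord) else max(coord)
}

#' Place the measuring slab as a reference cuboid
#'
#' Builds the slab cuboid spanning `[rostral_limit, rostral_limit +
#' thickness)` on the rostrocaudal axis (mirrored from the rostral voxel
#' face when the axis direction is negative) and the configured lateral
#' extent on the other two axes. Rejects any thickness strictly greater
#' than the measuring-sphere diameter; equality is the admissible boundary
#' case.
#'
#' @param volume a [volume3d] (or `labeled_mask`) supplying the frame.
#' @param spec a [slab_spec()]; `spec$rostral_limit_um` must be set.
#' @return A [reference_cuboid] named `"slab"`.
#' @export
place_slab <- function(volume, spec) {
  if (spec$thickness_um > spec$sphere_params$diameter_um)
    stop(sprintf(
      "slab thickness (%g um) must not exceed the measuring-sphere diameter (%g um)",
      spec$thickness_um, spec$sphere_params$diameter_um), call. = FALSE)
  if (is.null(spec$rostral_limit_um))
    stop("rostral_limit_um is not set; locate it from an A11-13 mask first",
         call. = FALSE)
  a <- axis_index(volume$rostrocaudal_axis)
  d3 <- if (is.null(dim(volume$data))) dim(volume$labels) else
    dim(volume$data)
  sp <- volume$spacing_um
  lo_all <- volume$origin_um
  hi_all <- volume$origin_um + d3 * sp
  min_um <- lo_all
  max_um <- hi_all
  if (!is.null(spec$lateral_min_um)) min_um <- pmax(min_um, spec$lateral_min_um)
  if (!is.null(spec$lateral_max_um)) max_um <- pmin(max_um, spec$lateral_max_um)
  if (volume$rostrocaudal_dir > 0) {
    min_um[a] <- spec$rostral_limit_um
    max_um[a] <- spec$rostral_limit_um + spec$thickness_um
  } else {
    face <- spec$rostral_limit_um + sp[a] / 2
    min_um[a] <- face - spec$thickness_um
    max_um[a] <- face
  }
  reference_cuboid("slab", min_um, max_um, "bilateral_midline")
}

# area-equivalent in-plane diameter of a window's cross-section:
# 2 * sqrt(area / pi) over the union of occupied in-plane cells. At a 7 um
# axial step the rasterized cross-section of a ~12 um tube loses its corner
# cells, so inscribed-disc style metrics collapse; the area-equivalent
# diameter is stable against that quantization while still separating thin
# fibers from fascicles.
inplane_equivalent_diameter <- function(cells, cell_size) {
  2 * sqrt(nrow(cells) * prod(cell_size) / pi)
}

#' Find fascicle-slab intersection windows
#'
#' Admits mask voxels whose intensity reaches the fascicle admission level
#' (fascicles are brighter than dispersed single fibers), clips the
#' admitted mask to the slab cuboid, labels the clipped voxels with
#' 26-connectivity, and drops windows whose in-plane area-equivalent
#' diameter falls below the fascicle admission diameter. The fraction of admitted in-slab voxels
#' retained in passing windows is recorded for the defasciculation metrics.
#'
#' @param mask a `labeled_mask` of the full volume (vessel exclusion is not
#'   applied here; fascicles are themselves elongated).
#' @param slab the [reference_cuboid] from [place_slab()].
#' @param spec the [slab_spec()].
#' @return An `intersection_windows` object: per-window table (`window`,
#'   `voxels`, `mean_intensity`, centroid, `inplane_diameter_um`), the
#'   voxel index sets, and the total admitted in-slab voxel count.
#' @export
find_intersection_windows <- function(mask, slab, spec) {
  d <- dim(mask$labels)
  frame <- volume3d(mask$labels, mask$spacing_um,
                    rostrocaudal_axis = mask$rostrocaudal_axis,
                    rostrocaudal_dir = mask$rostrocaudal_dir,
                    midline_axis = mask$midline_axis,
                    midline_um = mask$midline_um,
                    origin_um = mask$origin_um)
  in_slab <- cuboid_voxel_mask(frame, slab)
  adm <- (mask$labels > 0) & (mask$intensity >= spec$min_fascicle_intensity)
  clipped <- adm & in_slab
  total_admitted <- sum(clipped)
  win_labels <- array(cc_label_3d(as.logical(clipped), d, 26L), d)
  k <- max(win_labels)
  rc <- axis_index(mask$rostrocaudal_axis)
  lateral <- setdiff(1:3, rc)
  rows <- list()
  voxsets <- list()
  for (w in seq_len(k)) {
    idx <- which(win_labels == w)
    co <- arrayInd(idx, d)
    cells <- unique(co[, lateral, drop = FALSE])
    dia <- inplane_equivalent_diameter(cells, mask$spacing_um[lateral])
    if (dia < spec$min_fascicle_diameter_um) next
    ctr <- colMeans(sweep(sweep(co - 0.5, 2, mask$spacing_um, "*"), 2,
                          mask$origin_um, "+"))
    rows[[length(rows) + 1]] <- data.frame(
      window = length(rows) + 1L, voxels = length(idx),
      mean_intensity = mean(mask$intensity[idx]),
      centroid_z_um = ctr[1], centroid_y_um = ctr[2],
      centroid_x_um = ctr[3], inplane_diameter_um = dia)
    voxsets[[length(voxsets) + 1]] <- idx
  }
  windows <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(window = integer(0), voxels = integer(0),
               mean_intensity = numeric(0), centroid_z_um = numeric(0),
               centroid_y_um = numeric(0), centroid_x_um = numeric(0),
               inplane_diameter_um = numeric(0))
  structure(list(windows = windows, voxel_idx = voxsets, slab = slab,
                 spec = spec, total_admitted_voxels = total_admitted,
                 mask_dim = d, spacing_um = mask$spacing_um,
                 origin_um = mask$origin_um,
                 intensity = mask$intensity,
                 rostrocaudal_axis = mask$rostrocaudal_axis,
                 midline_axis = mask$midline_axis),
            class = "intersection_windows")
}

#' Count pathway units from intersection windows
#'
#' Runs the greedy measuring-sphere packing separately inside each window
#' (the `fit_fraction` is evaluated against the window's own voxels). A
#' single window may generate one or more spheres depending on how massive
#' the passing bundle is; a nonempty window whose packing accepts no sphere
#' still contributes exactly one unit (floor rule). The pathway-unit total
#' is the sum over windows.
#'
#' @param windows an `intersection_windows` object.
#' @param spec the [slab_spec()] (defaults to the one stored in `windows`).
#' @return A `pathway_units` object: per-window unit counts and the total.
#' @export
count_pathway_units <- function(windows, spec = windows$spec) {
  d <- windows$mask_dim
  pars <- spec$sphere_params
  offs <- sphere_offsets(windows$spacing_um, pars$diameter_um)
  per_window <- vapply(windows$voxel_idx, function(idx) {
    m <- logical(prod(d))
    m[idx] <- TRUE
    centers <- pack_spheres_cpp(as.numeric(windows$intensity), m, d, offs,
                                pars$fit_fraction, windows$spacing_um,
                                pars$diameter_um)
    max(1L, nrow(centers))
  }, integer(1))
  structure(list(per_window = per_window, total = sum(per_window),
                 n_windows = length(per_window), spec = spec),
            class = "pathway_units")
}

#' @export
print.pathway_units <- function(x, ...) {
  cat(sprintf("<pathway_units> %d windows, %d units\n", x$n_windows,
              x$total))
  invisible(x)
}

#' Defasciculation metrics of the tract at the slab
#'
#' Quantifies dispersal of the tract: `tract_width_um` is the robust
#' (5th-95th percentile) range of window centroids along the mediolateral
#' axis, and `bundled_fraction` is the fraction of admitted TH+ voxels in
#' the slab that belong to windows passing the fascicle-diameter cut.
#'
#' @param windows an `intersection_windows` object.
#' @param slab the slab cuboid (defaults to the one stored in `windows`).
#' @return List with `tract_width_um`, `bundled_fraction` (NA with
#'   `defined = FALSE` when the slab holds no admitted voxels) and
#'   `n_windows`.
#' @export
defasciculation_metrics <- function(windows, slab = windows$slab) {
  ml <- setdiff(.axes, c(windows$rostrocaudal_axis, "z"))
  ml <- if (length(ml) > 0) ml[1] else "x"
  col <- paste0("centroid_", ml, "_um")
  w <- windows$windows
  width <- if (nrow(w) == 0) 0 else
    diff(stats::quantile(w[[col]], c(0.05, 0.95), names = FALSE))
  defined <- windows$total_admitted_voxels > 0
  bundled <- if (!defined) NA_real_ else
    sum(w$voxels) / windows$total_admitted_voxels
  list(tract_width_um = width, bundled_fraction = bundled,
       defined = defined, n_windows = nrow(w))
}

#' Measure pathway units end-to-end
#'
#' Convenience pipeline: locate the rostral limit from the segmentation
#' restricted to the A11-13 reference cuboid (unless the slab spec fixes
#' the coordinate manually), place the slab, find intersection windows,
#' count units and compute defasciculation metrics.
#'
#' @param mask a `labeled_mask` of the full volume.
#' @param spec a [slab_spec()].
#' @param a11_13_roi a [reference_cuboid] delimiting the A11-13 groups;
#'   required when `spec$rostral_limit_um` is `NULL`.
#' @return List with `slab`, `rostral_limit_um`, `windows`, `units`,
#'   `metrics`.
#' @export
measure_pathway_units <- function(mask, spec = slab_spec(),
                                  a11_13_roi = NULL) {
  if (is.null(spec$rostral_limit_um)) {
    if (is.null(a11_13_roi))
      stop("either spec$rostral_limit_um or a11_13_roi must be given",
           call. = FALSE)
    sub <- mask
    frame <- volume3d(mask$labels, mask$spacing_um,
                      rostrocaudal_axis = mask$rostrocaudal_axis,
                      rostrocaudal_dir = mask$rostrocaudal_dir,
                      midline_axis = mask$midline_axis,
                      midline_um = mask$midline_um,
                      origin_um = mask$origin_um)
    keep <- cuboid_voxel_mask(frame, a11_13_roi)
    sub$labels <- mask$labels * keep
    spec$rostral_limit_um <- locate_rostral_limit(sub)
  }
  slab <- place_slab(mask, spec)
  windows <- find_intersection_windows(mask, slab, spec)
  units <- count_pathway_units(windows, spec)
  list(slab = slab, rostral_limit_um = spec$rostral_limit_um,
       windows = windows, units = units,
       metrics = defasciculation_metrics(windows, slab))
}
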