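#' 3D intensity volume with physical metadata
#'
#' The in-memory representation of a single-channel light-sheet stack.
#' Arrays are ordered `(z, y, x)`; voxel `(i, j, k)` (1-based) has its
#' center at `origin_um + (c(i, j, k) - 0.5) * spacing_um` in micrometers.
#' The anatomical rostrocaudal axis is recorded explicitly so that slab
#' placement and tract statistics are well defined regardless of how the
#' specimen was mounted.
#'
#' @param data numeric 3D array of non-negative intensities, dim `(nz, ny, nx)`.
#' @param spacing_um positive numeric length-3, voxel spacing in µm for
#'   `(z, y, x)`. The light-sheet z-step default used throughout the package
#'   is 7 µm with 5 µm in plane.
#' @param rostrocaudal_axis which array axis (`"z"`, `"y"` or `"x"`) runs
#'   rostro-caudally.
#' @param rostrocaudal_dir `+1` if rostral is at low index, `-1` otherwise.
#' @param midline_axis axis orthogonal to the sagittal midline plane.
#' @param midline_um coordinate of the midline plane in µm; `NULL` means the
#'   center of the volume on `midline_axis`.
#' @param origin_um physical coordinate (µm) of the volume's low corner;
#'   non-zero after cropping so coordinates map back to the parent frame.
#' @param provenance free-text note on where the volume came from.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(data, spacing_um,
                     rostrocaudal_axis = "y", rostrocaudal_dir = 1L,
                     midline_axis = "x", midline_um = NULL,
                     origin_um = c(0, 0, 0), provenance = "") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("data must be a 3D array", call. = FALSE)
  spacing_um <- as.numeric(spacing_um)
  if (length(spacing_um) != 3L || any(!is.finite(spacing_um)) ||
      any(spacing_um <= 0))
    stop("spacing_um must be three strictly positive values", call. = FALSE)
  axis_index(rostrocaudal_axis)
  axis_index(midline_axis)
  if (!rostrocaudal_dir %in% c(-1L, 1L))
    stop("rostrocaudal_dir must be +1 or -1", call. = FALSE)
  structure(list(
    data = data,
    spacing_um = stats::setNames(spacing_um, .axes),
    rostrocaudal_axis = rostrocaudal_axis,
    rostrocaudal_dir = as.integer(rostrocaudal_dir),
    midline_axis = midline_axis,
    midline_um = midline_um,
    origin_um = stats::setNames(as.numeric(origin_um), .axes),
    provenance = provenance
  ), class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> %d x %d x %d voxels (z,y,x), spacing %s um\n",
              d[1], d[2], d[3],
              paste(format(x$spacing_um), collapse = " x ")))
  cat(sprintf("  rostrocaudal axis: %s (dir %+d), midline axis: %s at %s um\n",
              x$rostrocaudal_axis, x$rostrocaudal_dir, x$midline_axis,
              format(midline_coordinate(x))))
  invisible(x)
}

#' Voxel-center coordinates along one axis
#'
#' @param volume a [volume3d].
#' @param axis `"z"`, `"y"` or `"x"`.
#' @return Numeric vector of physical coordinates (µm) of voxel centers.
#' @export
voxel_centers <- function(volume, axis) {
  a <- axis_index(axis)
  volume$origin_um[a] + (seq_len(dim(volume$data)[a]) - 0.5) *
    volume$spacing_um[a]
}

#' Midline plane coordinate of a volume
#'
#' @param volume a [volume3d].
#' @return Coordinate (µm) of the configured midline plane; defaults to the
#'   center of the volume extent on the midline axis.
#' @export
midline_coordinate <- function(volume) {
  if (!is.null(volume$midline_um)) return(volume$midline_um)
  a <- axis_index(volume$midline_axis)
  volume$origin_um[a] + dim(volume$data)[a] * volume$spacing_um[a] / 2
}

#' Axis-aligned rectangular reference cuboid
#'
#' Reference cuboids delimit the counting region of one anatomical
#' structure, in physical (µm) coordinates. Substantia nigra cuboids are
#' tagged `left`/`right` and counted per side; the diencephalic groups use
#' a single `bilateral_midline` cuboid straddling the midline.
#'
#' @param name structure name, e.g. `"SN_left"`.
#' @param min_um,max_um numeric length-3 `(z, y, x)` corners in µm, with
#'   `min_um < max_um` on every axis. Membership is half-open: a voxel
#'   belongs to the cuboid iff its center `c` satisfies
#'   `min_um <= c < max_um` on all axes.
#' @param laterality one of `"left"`, `"right"`, `"bilateral_midline"`.
#' @return An object of class `reference_cuboid`.
#' @export
reference_cuboid <- function(name, min_um, max_um,
                             laterality = c("bilateral_midline", "left",
                                            "right")) {
  laterality <- match.arg(laterality)
  min_um <- stats::setNames(as.numeric(min_um), .axes)
  max_um <- stats::setNames(as.numeric(max_um), .axes)
  if (any(!is.finite(min_um)) || any(!is.finite(max_um)) ||
      any(min_um >= max_um))
    stop("cuboid must satisfy min < max on every axis", call. = FALSE)
  structure(list(name = name, min_um = min_um, max_um = max_um,
                 laterality = laterality),
            class = "reference_cuboid")
}

# indices of voxels whose centers fall inside the cuboid, per axis
cuboid_index_ranges <- function(volume, roi) {
  lapply(seq_along(.axes), function(a) {
    ctr <- voxel_centers(volume, .axes[a])
    which(ctr >= roi$min_um[a] & ctr < roi$max_um[a])
  })
}

# logical array marking voxels inside the cuboid
cuboid_voxel_mask <- function(volume, roi) {
  rng <- cuboid_index_ranges(volume, roi)
  m <- array(FALSE, dim(volume$data))
  if (all(lengths(rng) > 0)) m[rng[[1]], rng[[2]], rng[[3]]] <- TRUE
  m
}

#' Crop a volume to a reference cuboid
#'
#' Returns the sub-volume covering exactly the voxels whose centers fall
#' inside the cuboid (half-open on every axis). The returned volume's
#' `origin_um` is updated so physical coordinates are preserved.
#'
#' @param volume a [volume3d].
#' @param roi a [reference_cuboid] intersecting the volume.
#' @return A cropped [volume3d].
#' @export
crop_volume <- function(volume, roi) {
  rng <- cuboid_index_ranges(volume, roi)
  if (any(lengths(rng) == 0))
    stop(sprintf("ROI '%s' does not intersect the volume", roi$name),
         call. = FALSE)
  out <- volume
  out$data <- volume$data[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  first <- vapply(rng, function(i) i[1], integer(1))
  out$origin_um <- volume$origin_um + (first - 1) * volume$spacing_um
  out
}
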