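#' Write a volume as a multi-page TIFF with a JSON sidecar
#'
#' The canonical on-disk form is a single-channel 16-bit unsigned TIFF, one
#' page per z-plane, plus a JSON sidecar carrying the physical metadata
#' (`spacing_um`, axis mapping, midline, origin). Intensities are rounded
#' to integers and clamped to `[0, 65535]` on write; integer-valued volumes
#' in range therefore round-trip bit-exactly.
#'
#' @param volume a [volume3d].
#' @param path output TIFF path.
#' @param sidecar_path output JSON path; default `paste0(path, ".json")`.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(volume, path, sidecar_path = paste0(path, ".json")) {
  d <- dim(volume$data)
  vals <- pmin(pmax(round(volume$data), 0), 65535)
  pages <- lapply(seq_len(d[1]), function(i)
    matrix(vals[i, , ], nrow = d[2], ncol = d[3]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(
    shape = d,
    spacing_um = unname(volume$spacing_um),
    rostrocaudal_axis = volume$rostrocaudal_axis,
    rostrocaudal_dir = volume$rostrocaudal_dir,
    midline_axis = volume$midline_axis,
    midline_coordinate_um = midline_coordinate(volume),
    origin_um = unname(volume$origin_um),
    provenance = volume$provenance
  )
  jsonlite::write_json(meta, sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a volume from a multi-page TIFF and its JSON sidecar
#'
#' @param path TIFF path.
#' @param sidecar_path JSON sidecar path; default `paste0(path, ".json")`.
#' @return A [volume3d] with intensities on the original integer scale.
#' @export
read_volume <- function(path, sidecar_path = paste0(path, ".json")) {
  if (!file.exists(sidecar_path))
    stop("missing metadata sidecar: ", sidecar_path, call. = FALSE)
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  req <- c("spacing_um", "rostrocaudal_axis")
  if (!all(req %in% names(meta)))
    stop("sidecar lacks required metadata fields (spacing_um, rostrocaudal_axis)",
         call. = FALSE)
  spacing <- as.numeric(meta$spacing_um)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("sidecar spacing_um must be three strictly positive values",
         call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- unique(lapply(pages, dim))
  if (length(dims) != 1)
    stop("TIFF pages have inconsistent dimensions", call. = FALSE)
  ny <- dims[[1]][1]; nx <- dims[[1]][2]; nz <- length(pages)
  data <- array(0, c(nz, ny, nx))
  for (i in seq_len(nz)) data[i, , ] <- round(pages[[i]] * 65535)
  volume3d(
    data, spacing,
    rostrocaudal_axis = meta$rostrocaudal_axis,
    rostrocaudal_dir = if (is.null(meta$rostrocaudal_dir)) 1L else
      as.integer(meta$rostrocaudal_dir),
    midline_axis = if (is.null(meta$midline_axis)) "x" else meta$midline_axis,
    midline_um = meta$midline_coordinate_um,
    origin_um = if (is.null(meta$origin_um)) c(0, 0, 0) else
      as.numeric(meta$origin_um),
    provenance = if (is.null(meta$provenance)) "" else meta$provenance
  )
}

#' Write reference cuboids to a JSON file
#'
#' @param rois list of [reference_cuboid] objects.
#' @param path output JSON path.
#' @return Invisibly, `path`.
#' @export
write_rois <- function(rois, path) {
  out <- lapply(rois, function(r)
    list(name = r$name, min_um = unname(r$min_um), max_um = unname(r$max_um),
         laterality = r$laterality))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read reference cuboids from a JSON file
#'
#' @param path JSON path written by [write_rois()] (or hand-authored in the
#'   same shape).
#' @return List of [reference_cuboid] objects.
#' @export
read_rois <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(r)
    reference_cuboid(r$name, unlist(r$min_um), unlist(r$max_um),
                     laterality = r$laterality))
}

#' Serialize phantom ground truth to JSON
#'
#' @param gt a `ground_truth` object from [generate_phantom()].
#' @param path output JSON path.
#' @return Invisibly, `path`.
#' @export
write_ground_truth <- function(gt, path) {
  jsonlite::write_json(unclass(gt), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
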