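#' Nucleus specification for the phantom generator
#'
#' Describes one catecholaminergic cell group (e.g. SN left/right, VTA,
#' A11-13) as an ellipsoidal envelope filled with bright spherical somata.
#' Somata are placed by rejection sampling so that they lie entirely inside
#' the envelope and respect a minimum pairwise center separation; when
#' `min_separation_um >= soma_diameter_um` all somata are non-touching.
#'
#' @param name nucleus label, e.g. `"SN_left"`, `"VTA"`, `"A11_13"`.
#' @param center_um,semi_axes_um ellipsoid center and semi-axes, µm `(z,y,x)`.
#' @param n_somata number of somata to place.
#' @param soma_diameter_um mean soma diameter (µm); P7 dopaminergic
#'   perikarya are on the order of 12 µm.
#' @param soma_diameter_jitter_um s.d. of the per-soma diameter jitter.
#' @param soma_intensity mean soma intensity (arbitrary 16-bit-scale units).
#' @param soma_intensity_jitter s.d. of the per-soma intensity jitter.
#' @param min_separation_um minimum center-to-center distance between somata.
#' @return A `nucleus_spec` list.
#' @export
nucleus_spec <- function(name, center_um, semi_axes_um, n_somata,
                         soma_diameter_um = 12, soma_diameter_jitter_um = 0.6,
                         soma_intensity = 2000, soma_intensity_jitter = 200,
                         min_separation_um = 16) {
  stopifnot(length(center_um) == 3, length(semi_axes_um) == 3,
            all(semi_axes_um > 0), n_somata >= 0, soma_diameter_um > 0,
            min_separation_um >= 0)
  list(name = name,
       center_um = stats::setNames(as.numeric(center_um), .axes),
       semi_axes_um = stats::setNames(as.numeric(semi_axes_um), .axes),
       n_somata = as.integer(n_somata),
       soma_diameter_um = soma_diameter_um,
       soma_diameter_jitter_um = soma_diameter_jitter_um,
       soma_intensity = soma_intensity,
       soma_intensity_jitter = soma_intensity_jitter,
       min_separation_um = min_separation_um)
}

#' Tract specification for the phantom generator
#'
#' Describes the mesotelencephalic tract as a set of bright tubular
#' fascicles plus dispersed thin fibers, all running rostrocaudally inside
#' a corridor. Each centerline is strictly monotone in the rostrocaudal
#' coordinate, so it crosses every interior coronal plane exactly once.
#' `spread_um` is the lateral scatter of fascicle centerlines about the
#' corridor center and is the generator's "defasciculation" dial: larger
#' values disperse the bundle and widen the tract.
#'
#' @param n_fascicles number of fascicles.
#' @param fascicle_diameter_um length-2 range of fascicle diameters (µm).
#' @param n_dispersed_fibers number of thin dispersed fibers.
#' @param fiber_diameter_um fiber diameter (µm); must still exceed the
#'   largest voxel spacing so that tubes rasterize without gaps.
#' @param fascicle_intensity,fiber_intensity tube intensities.
#' @param rc_range_um length-2: caudal and rostral endpoint coordinates of
#'   the tract along the rostrocaudal axis.
#' @param center_zx_um corridor center on the two non-rostrocaudal axes
#'   `(z, x)`, µm.
#' @param spread_um length-2 half-widths `(z, x)` of the uniform lateral
#'   scatter of fascicle base positions.
#' @param min_separation_um minimum pairwise lateral distance between
#'   fascicle base centerlines.
#' @param wander_um amplitude of the smooth lateral wander added along each
#'   centerline.
#' @param fiber_spread_factor fibers scatter this much wider than fascicles.
#' @param n_control_points control points per centerline.
#' @return A `tract_spec` list.
#' @export
tract_spec <- function(n_fascicles = 12, fascicle_diameter_um = c(11, 13),
                       n_dispersed_fibers = 25, fiber_diameter_um = 8,
                       fascicle_intensity = 2600, fiber_intensity = 1000,
                       rc_range_um = c(620, 90), center_zx_um = c(275, 220),
                       spread_um = c(38, 100), min_separation_um = 28,
                       wander_um = 2, fiber_spread_factor = 1.25,
                       n_control_points = 12) {
  stopifnot(n_fascicles >= 0, n_dispersed_fibers >= 0,
            length(fascicle_diameter_um) == 2, all(fascicle_diameter_um > 0),
            fiber_diameter_um > 0, length(rc_range_um) == 2,
            rc_range_um[1] != rc_range_um[2], length(spread_um) == 2,
            min_separation_um >= 0, wander_um >= 0, n_control_points >= 2)
  list(n_fascicles = as.integer(n_fascicles),
       fascicle_diameter_um = as.numeric(fascicle_diameter_um),
       n_dispersed_fibers = as.integer(n_dispersed_fibers),
       fiber_diameter_um = fiber_diameter_um,
       fascicle_intensity = fascicle_intensity,
       fiber_intensity = fiber_intensity,
       rc_range_um = as.numeric(rc_range_um),
       center_zx_um = as.numeric(center_zx_um),
       spread_um = as.numeric(spread_um),
       min_separation_um = min_separation_um,
       wander_um = wander_um,
       fiber_spread_factor = fiber_spread_factor,
       n_control_points = as.integer(n_control_points))
}

#' Vessel specification for the phantom generator
#'
#' Long straight bright tubes that traverse nucleus envelopes, emulating
#' blood vessels picked up by the TH channel. Their length is at least five
#' diameters so shape-based exclusion is well posed. Paths are rejection
#' sampled to keep a clearance from somata and tract centerlines: the
#' artifact-exclusion stage is only meaningful when vessels do not fuse
#' with genuine structures at the segmentation threshold.
#'
#' @param n_vessels number of vessels.
#' @param diameter_um vessel diameter (µm).
#' @param length_um vessel length (µm); must be `>= 5 * diameter_um`.
#' @param intensity tube intensity.
#' @param target_nuclei names of nuclei the vessels should traverse
#'   (cycled); `NULL` means any nucleus.
#' @param tilt maximum off-axis slope of the (dorsoventral) vessel
#'   direction on the other two axes.
#' @param min_clearance_um minimum surface-to-surface clearance between a
#'   vessel and somata / tract tubes.
#' @return A `vessel_spec` list.
#' @export
vessel_spec <- function(n_vessels = 2, diameter_um = 14, length_um = 140,
                        intensity = 2000,
                        target_nuclei = c("SN_left", "SN_right"),
                        tilt = 0.1, min_clearance_um = 12) {
  stopifnot(n_vessels >= 0, diameter_um > 0, length_um >= 5 * diameter_um,
            tilt >= 0, min_clearance_um >= 0)
  list(n_vessels = as.integer(n_vessels), diameter_um = diameter_um,
       length_um = length_um, intensity = intensity,
       target_nuclei = target_nuclei, tilt = tilt,
       min_clearance_um = min_clearance_um)
}

#' Full phantom specification
#'
#' Bundles the imaging geometry (volume shape, voxel spacing with the 7 µm
#' light-sheet z-step default, rostrocaudal axis mapping), the structural
#' content (nuclei, tract, vessels), the optical blur and the noise model,
#' plus the seed that makes generation bit-reproducible.
#'
#' @param shape integer length-3 volume shape `(nz, ny, nx)`.
#' @param spacing_um voxel spacing `(z, y, x)` in µm; default `c(7, 5, 5)`.
#' @param rostrocaudal_axis,rostrocaudal_dir anatomical axis mapping, as in
#'   [volume3d()].
#' @param midline_axis,midline_um midline plane, as in [volume3d()].
#' @param nuclei list of [nucleus_spec()] objects.
#' @param tract a [tract_spec()], or `NULL` for no tract.
#' @param vessels a [vessel_spec()], or `NULL` for no vessels.
#' @param blur_sigma_um optical blur s.d. per axis `(z, y, x)` in µm;
#'   anisotropic, worse axially, as in light-sheet imaging.
#' @param noise list with `background` (additive offset), `gaussian_sd`
#'   (read noise s.d.) and `poisson_scale` (photon noise: counts are drawn
#'   as `rpois(intensity * scale) / scale`; 0 disables).
#' @param seed integer seed.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape, spacing_um = c(7, 5, 5),
                         rostrocaudal_axis = "y", rostrocaudal_dir = 1L,
                         midline_axis = "x", midline_um = NULL,
                         nuclei = list(), tract = NULL, vessels = NULL,
                         blur_sigma_um = c(5, 3.5, 3.5),
                         noise = list(background = 200, gaussian_sd = 30,
                                      poisson_scale = 0),
                         seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape > 0), length(spacing_um) == 3,
            all(spacing_um > 0), length(blur_sigma_um) == 3,
            all(blur_sigma_um >= 0))
  axis_index(rostrocaudal_axis)
  noise <- utils::modifyList(
    list(background = 0, gaussian_sd = 0, poisson_scale = 0), noise)
  stopifnot(noise$background >= 0, noise$gaussian_sd >= 0,
            noise$poisson_scale >= 0)
  structure(list(shape = shape, spacing_um = as.numeric(spacing_um),
                 rostrocaudal_axis = rostrocaudal_axis,
                 rostrocaudal_dir = as.integer(rostrocaudal_dir),
                 midline_axis = midline_axis, midline_um = midline_um,
                 nuclei = nuclei, tract = tract, vessels = vessels,
                 blur_sigma_um = as.numeric(blur_sigma_um), noise = noise,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# ---- geometry helpers -------------------------------------------------------

# squared distance from points (n x 3 matrix) to segment p-q
point_segment_dist2 <- function(pts, p, q) {
  v <- q - p
  l2 <- sum(v^2)
  dp <- sweep(pts, 2, p)
  if (l2 == 0) return(rowSums(dp^2))
  t <- pmin(pmax((dp %*% v) / l2, 0), 1)
  proj <- dp - t %*% t(v)
  rowSums(proj^2)
}

# densify a polyline to roughly `step` µm spacing
densify_polyline <- function(pts, step = 5) {
  if (nrow(pts) < 2) return(pts)
  out <- list(pts[1, , drop = FALSE])
  for (i in seq_len(nrow(pts) - 1)) {
    p <- pts[i, ]; q <- pts[i + 1, ]
    len <- sqrt(sum((q - p)^2))
    nseg <- max(1L, ceiling(len / step))
    tt <- seq_len(nseg) / nseg
    out[[i + 1]] <- outer(tt, q - p) + rep(p, each = nseg)
  }
  do.call(rbind, out)
}

# ---- rasterization ----------------------------------------------------------

#' Rasterize a tube along a polyline into a volume
#'
#' Sets every voxel whose center lies within `diameter_um / 2` (physical
#' distance) of the polyline to at least `intensity` (existing brighter
#' values are kept). A single-point centerline produces a sphere. Because
#' membership is evaluated against the continuous segment geometry, the
#' rasterized tube is 26-connected along its length whenever the diameter
#' exceeds the largest voxel spacing, which is required.
#'
#' @param volume a [volume3d] to draw into.
#' @param centerline_um n x 3 matrix of `(z, y, x)` points in µm (a bare
#'   length-3 vector is treated as a single point).
#' @param diameter_um tube diameter (µm), `> max(spacing_um)`.
#' @param intensity value painted into the tube.
#' @return The modified [volume3d].
#' @export
rasterize_tube <- function(volume, centerline_um, diameter_um, intensity) {
  if (is.null(dim(centerline_um)))
    centerline_um <- matrix(centerline_um, ncol = 3, byrow = TRUE)
  sp <- volume$spacing_um
  org <- volume$origin_um
  d <- dim(volume$data)
  if (diameter_um <= max(sp))
    stop("tube diameter must exceed the largest voxel spacing",
         call. = FALSE)
  hi_ext <- org + d * sp
  if (any(sweep(centerline_um, 2, org) < -1e-9) ||
      any(sweep(centerline_um, 2, hi_ext) > 1e-9))
    stop("centerline extends outside the volume bounds", call. = FALSE)
  r <- diameter_um / 2
  n <- nrow(centerline_um)
  segs <- if (n == 1) list(c(1L, 1L)) else
    lapply(seq_len(n - 1), function(i) c(i, i + 1L))
  arr <- volume$data
  nz <- d[1]; nzy <- d[1] * d[2]
  for (s in segs) {
    p <- centerline_um[s[1], ]
    q <- centerline_um[s[2], ]
    lo <- pmin(p, q) - r
    hi <- pmax(p, q) + r
    i_lo <- pmax(1L, ceiling((lo - org) / sp + 0.5 - 1e-9))
    i_hi <- pmin(d, floor((hi - org) / sp + 0.5 + 1e-9))
    if (any(i_lo > i_hi)) next
    iz <- i_lo[1]:i_hi[1]; iy <- i_lo[2]:i_hi[2]; ix <- i_lo[3]:i_hi[3]
    g <- as.matrix(expand.grid(iz = iz, iy = iy, ix = ix))
    ctr <- sweep(sweep(g - 0.5, 2, sp, "*"), 2, org, "+")
    inside <- point_segment_dist2(ctr, p, q) <= r * r + 1e-12
    if (!any(inside)) next
    lin <- g[inside, 1] + nz * (g[inside, 2] - 1) + nzy * (g[inside, 3] - 1)
    arr[lin] <- pmax(arr[lin], intensity)
  }
  volume$data <- arr
  volume
}

# ---- structure placement ----------------------------------------------------

place_somata <- function(nuc, max_attempts = 10000L) {
  n <- nuc$n_somata
  if (n == 0)
    return(data.frame(z_um = numeric(0), y_um = numeric(0), x_um = numeric(0),
                      diameter_um = numeric(0), intensity = numeric(0)))
  r <- nuc$soma_diameter_um / 2
  semi <- pmax(nuc$semi_axes_um - r, 1e-6)
  centers <- matrix(NA_real_, n, 3)
  placed <- 0L
  attempts <- 0L
  min2 <- nuc$min_separation_um^2
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop(sprintf(
        "soma placement failed for nucleus '%s' after %d attempts",
        nuc$name, max_attempts), call. = FALSE)
    p <- nuc$center_um + stats::runif(3, -1, 1) * semi
    if (sum(((p - nuc$center_um) / semi)^2) > 1) next
    if (placed > 0 &&
        any(rowSums(sweep(centers[seq_len(placed), , drop = FALSE], 2,
                          p)^2) < min2)) next
    placed <- placed + 1L
    centers[placed, ] <- p
  }
  dia <- pmax(nuc$soma_diameter_um +
                stats::rnorm(n, 0, nuc$soma_diameter_jitter_um),
              nuc$soma_diameter_um * 0.6)
  int <- pmax(nuc$soma_intensity +
                stats::rnorm(n, 0, nuc$soma_intensity_jitter),
              nuc$soma_intensity * 0.5)
  data.frame(z_um = centers[, 1], y_um = centers[, 2], x_um = centers[, 3],
             diameter_um = dia, intensity = int)
}

# smooth monotone centerline from caudal to rostral
make_centerline <- function(rc_range, base_z, base_x, wander, n_ctrl,
                            rc_axis_idx) {
  u <- seq(0, 1, length.out = n_ctrl)
  rc <- rc_range[1] + u * (rc_range[2] - rc_range[1])
  wob <- function() {
    a1 <- stats::runif(1, 0.3, 1) * wander
    a2 <- stats::runif(1, 0, 0.5) * wander
    p1 <- stats::runif(1, 0, 2 * pi)
    p2 <- stats::runif(1, 0, 2 * pi)
    a1 * sin(2 * pi * u + p1) / 1.5 + a2 * sin(4 * pi * u + p2) / 1.5
  }
  zz <- base_z + wob()
  xx <- base_x + wob()
  pts <- matrix(0, n_ctrl, 3)
  lateral <- setdiff(1:3, rc_axis_idx)
  pts[, rc_axis_idx] <- rc
  pts[, lateral[1]] <- if (lateral[1] == 1) zz else xx
  pts[, lateral[2]] <- if (lateral[2] == 3) xx else zz
  pts
}

place_tract <- function(tract, rc_axis_idx, max_attempts = 10000L) {
  nf <- tract$n_fascicles
  bases <- matrix(NA_real_, max(nf, 0L), 2)
  placed <- 0L
  attempts <- 0L
  min2 <- tract$min_separation_um^2
  while (placed < nf) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("fascicle base placement failed: corridor too crowded for the ",
           "requested min_separation_um", call. = FALSE)
    p <- tract$center_zx_um + stats::runif(2, -1, 1) * tract$spread_um
    if (placed > 0 &&
        any(rowSums(sweep(bases[seq_len(placed), , drop = FALSE], 2,
                          p)^2) < min2)) next
    placed <- placed + 1L
    bases[placed, ] <- p
  }
  fascicles <- lapply(seq_len(nf), function(i) {
    list(centerline_um = make_centerline(
           tract$rc_range_um, bases[i, 1], bases[i, 2], tract$wander_um,
           tract$n_control_points, rc_axis_idx),
         diameter_um = stats::runif(1, tract$fascicle_diameter_um[1],
                                    tract$fascicle_diameter_um[2]),
         intensity = tract$fascicle_intensity)
  })
  # dispersed fibers share the corridor depth (z) of the fascicles but
  # scatter wider mediolaterally; keeping them inside the ventral corridor
  # prevents thin fibers from fusing with nucleus somata.
  fibers <- lapply(seq_len(tract$n_dispersed_fibers), function(i) {
    base <- tract$center_zx_um + stats::runif(2, -1, 1) *
      tract$spread_um * c(1, tract$fiber_spread_factor)
    list(centerline_um = make_centerline(
           tract$rc_range_um, base[1], base[2], tract$wander_um * 2,
           tract$n_control_points, rc_axis_idx),
         diameter_um = tract$fiber_diameter_um,
         intensity = tract$fiber_intensity)
  })
  list(fascicles = fascicles, fibers = fibers)
}

place_vessels <- function(spec, somata, tubes, max_attempts = 10000L) {
  vs <- spec$vessels
  if (is.null(vs) || vs$n_vessels == 0) return(list())
  nuclei <- spec$nuclei
  if (!is.null(vs$target_nuclei)) {
    keep <- vapply(nuclei, function(n) n$name %in% vs$target_nuclei,
                   logical(1))
    if (any(keep)) nuclei <- nuclei[keep]
  }
  if (length(nuclei) == 0)
    stop("vessel placement failed: no target nuclei available",
         call. = FALSE)
  ext_hi <- spec$shape * spec$spacing_um
  rv <- vs$diameter_um / 2
  soma_pts <- if (nrow(somata) > 0)
    as.matrix(somata[, c("z_um", "y_um", "x_um")]) else NULL
  soma_r <- if (nrow(somata) > 0) somata$diameter_um / 2 else numeric(0)
  dense_tubes <- lapply(tubes, function(tb)
    list(pts = densify_polyline(tb$centerline_um, 5), r = tb$diameter_um / 2))
  out <- vector("list", vs$n_vessels)
  for (v in seq_len(vs$n_vessels)) {
    nuc <- nuclei[[((v - 1L) %% length(nuclei)) + 1L]]
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      p0 <- nuc$center_um + stats::runif(3, -1, 1) * nuc$semi_axes_um
      if (sum(((p0 - nuc$center_um) / nuc$semi_axes_um)^2) > 1) next
      dir <- c(sample(c(-1, 1), 1),
               vs$tilt * stats::runif(1, -1, 1),
               vs$tilt * stats::runif(1, -1, 1))
      dir <- dir / sqrt(sum(dir^2))
      a <- p0 - dir * vs$length_um / 2
      b <- p0 + dir * vs$length_um / 2
      margin <- rv + 1
      if (any(pmin(a, b) < margin) || any(pmax(a, b) > ext_hi - margin)) next
      if (!is.null(soma_pts)) {
        d2 <- point_segment_dist2(soma_pts, a, b)
        if (any(sqrt(d2) < rv + soma_r + vs$min_clearance_um)) next
      }
      clear <- TRUE
      for (tb in dense_tubes) {
        d2 <- point_segment_dist2(tb$pts, a, b)
        if (any(sqrt(d2) < rv + tb$r + vs$min_clearance_um)) {
          clear <- FALSE; break
        }
      }
      if (!clear) next
      out[[v]] <- list(start_um = a, end_um = b, diameter_um = vs$diameter_um,
                       intensity = vs$intensity)
      ok <- TRUE
      break
    }
    if (!ok)
      stop(sprintf("vessel placement failed for nucleus '%s'", nuc$name),
           call. = FALSE)
  }
  out
}

# ---- generation -------------------------------------------------------------

#' Generate a phantom light-sheet volume with ground truth
#'
#' Draws all structure geometry under the spec's seed, rasterizes somata,
#' fascicles, dispersed fibers and vessels into a clean volume, then applies
#' the optical blur and noise model via [apply_optics_and_noise()]. The
#' same spec and seed always yield bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `volume` (a [volume3d]) and `ground_truth`
#'   (a `ground_truth` object recording every soma center/diameter, every
#'   tube centerline, vessel geometry, and the rostral limit of the A11-13
#'   envelope).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  rc_idx <- axis_index(spec$rostrocaudal_axis)
  geom <- with_seed(spec$seed, {
    somata <- lapply(spec$nuclei, place_somata)
    names(somata) <- vapply(spec$nuclei, `[[`, "", "name")
    tract <- if (!is.null(spec$tract))
      place_tract(spec$tract, rc_idx)
    else list(fascicles = list(), fibers = list())
    all_somata <- if (length(somata) > 0)
      cbind(nucleus = rep(names(somata),
                          vapply(somata, nrow, integer(1))),
            do.call(rbind, c(somata, list(make.row.names = FALSE))))
    else data.frame(nucleus = character(0), z_um = numeric(0),
                    y_um = numeric(0), x_um = numeric(0),
                    diameter_um = numeric(0), intensity = numeric(0))
    vessels <- place_vessels(spec, all_somata,
                             c(tract$fascicles, tract$fibers))
    list(somata = all_somata, fascicles = tract$fascicles,
         fibers = tract$fibers, vessels = vessels)
  })

  vol <- volume3d(array(0, spec$shape), spec$spacing_um,
                  rostrocaudal_axis = spec$rostrocaudal_axis,
                  rostrocaudal_dir = spec$rostrocaudal_dir,
                  midline_axis = spec$midline_axis,
                  midline_um = spec$midline_um,
                  provenance = sprintf("clearcount phantom seed=%d",
                                       spec$seed))
  if (nrow(geom$somata) > 0) {
    for (i in seq_len(nrow(geom$somata))) {
      s <- geom$somata[i, ]
      vol <- rasterize_tube(vol, c(s$z_um, s$y_um, s$x_um),
                            s$diameter_um, s$intensity)
    }
  }
  for (tb in c(geom$fascicles, geom$fibers))
    vol <- rasterize_tube(vol, tb$centerline_um, tb$diameter_um,
                          tb$intensity)
  for (vsl in geom$vessels)
    vol <- rasterize_tube(vol, rbind(vsl$start_um, vsl$end_um),
                          vsl$diameter_um, vsl$intensity)

  a11 <- Filter(function(n) grepl("^A1[12]", n$name), spec$nuclei)
  rostral_limit <- if (length(a11) > 0) {
    edges <- vapply(a11, function(n)
      n$center_um[rc_idx] - spec$rostrocaudal_dir * n$semi_axes_um[rc_idx],
      numeric(1))
    if (spec$rostrocaudal_dir > 0) min(edges) else max(edges)
  } else NULL

  gt <- structure(list(
    seed = spec$seed,
    somata = geom$somata,
    fascicles = geom$fascicles,
    fibers = geom$fibers,
    vessels = geom$vessels,
    a11_13_rostral_limit_um = rostral_limit
  ), class = "ground_truth")

  list(volume = apply_optics_and_noise(vol, spec), ground_truth = gt)
}

gaussian_kernel <- function(sigma_vox) {
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- stats::dnorm(seq(-r, r), sd = sigma_vox)
  k / sum(k)
}

#' Separable Gaussian blur in physical units
#'
#' @param volume a [volume3d].
#' @param sigma_um blur s.d. per axis `(z, y, x)` in µm (a scalar is
#'   recycled); each axis sigma is converted to voxels using that axis'
#'   spacing. Zero sigmas are skipped.
#' @return The blurred [volume3d].
#' @export
gaussian_blur <- function(volume, sigma_um) {
  sigma_um <- rep_len(as.numeric(sigma_um), 3)
  stopifnot(all(sigma_um >= 0))
  arr <- volume$data
  d <- dim(arr)
  for (a in 1:3) {
    sv <- sigma_um[a] / volume$spacing_um[a]
    if (sv <= 0) next
    arr <- array(conv_axis3d(as.numeric(arr), d, gaussian_kernel(sv), a), d)
  }
  volume$data <- arr
  volume
}

#' Apply optical blur and noise to a phantom volume
#'
#' Blur is a separable Gaussian with per-axis sigma given in µm (divided by
#' the voxel spacing of each axis), reflecting the anisotropic axial
#' response of light-sheet imaging; the normalized kernel conserves total
#' intensity to well under 1%. Noise is an additive background offset,
#' optional Poisson photon noise (`rpois(intensity * scale) / scale`) and
#' additive Gaussian read noise, drawn from a generator seeded from
#' `spec$seed`, so repeated calls are bit-identical.
#'
#' @param volume a [volume3d].
#' @param spec the [phantom_spec()] providing `blur_sigma_um` and `noise`.
#' @return The degraded [volume3d].
#' @export
apply_optics_and_noise <- function(volume, spec) {
  if (any(spec$blur_sigma_um > 0))
    volume <- gaussian_blur(volume, spec$blur_sigma_um)
  ns <- spec$noise
  arr <- volume$data
  if (ns$background > 0) arr <- arr + ns$background
  if (ns$poisson_scale > 0 || ns$gaussian_sd > 0) {
    arr <- with_seed(as.numeric(spec$seed) + 999983, {
      n <- length(arr)
      if (ns$poisson_scale > 0)
        arr <- array(stats::rpois(n, pmax(arr, 0) * ns$poisson_scale) /
                       ns$poisson_scale, dim(arr))
      if (ns$gaussian_sd > 0)
        arr <- arr + array(stats::rnorm(n, 0, ns$gaussian_sd), dim(arr))
      arr
    })
  }
  volume$data <- pmax(arr, 0)
  volume
}
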