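#' Phantom preset for soma-count recovery validation
#'
#' Four spacious, well-separated nucleus envelopes (per-side SN, VTA,
#' A11-13) with generous inter-soma spacing, no tract, and optional
#' traversing vessels — the configuration used to validate perikarya-count
#' recovery against ground truth, where somata are guaranteed non-touching
#' and nuclei never share reference-cuboid space.
#'
#' @param seed integer seed.
#' @param n_somata somata per nucleus: scalar or length-4 (SN_left,
#'   SN_right, VTA, A11_13).
#' @param with_vessels add vessels traversing the nuclei.
#' @param min_separation_um minimum soma center separation (µm).
#' @return List with `spec` (a [phantom_spec()]) and `rois` (the four
#'   reference cuboids, SN per side, VTA and A11-13 bilateral).
#' @export
recovery_phantom <- function(seed, n_somata = 40, with_vessels = FALSE,
                             min_separation_um = 20) {
  n <- rep_len(n_somata, 4)
  mk <- function(name, center, n1)
    nucleus_spec(name, center_um = center, semi_axes_um = c(65, 100, 65),
                 n_somata = n1, min_separation_um = min_separation_um)
  nuclei <- list(
    mk("SN_left", c(190, 300, 100), n[1]),
    mk("SN_right", c(190, 300, 400), n[2]),
    mk("VTA", c(190, 140, 250), n[3]),
    mk("A11_13", c(190, 460, 250), n[4])
  )
  rois <- list(
    roi_from_nucleus(nuclei[[1]], "left"),
    roi_from_nucleus(nuclei[[2]], "right"),
    roi_from_nucleus(nuclei[[3]], "bilateral_midline"),
    roi_from_nucleus(nuclei[[4]], "bilateral_midline")
  )
  spec <- phantom_spec(
    shape = c(54L, 120L, 100L), spacing_um = c(7, 5, 5),
    midline_um = 250,
    nuclei = nuclei, tract = NULL,
    vessels = if (with_vessels)
      vessel_spec(n_vessels = 3, target_nuclei = NULL) else NULL,
    blur_sigma_um = c(5, 3.5, 3.5),
    noise = list(background = 200, gaussian_sd = 30, poisson_scale = 0),
    seed = seed
  )
  list(spec = spec, rois = rois)
}

#' Phantom preset for pathway-unit exactness validation
#'
#' A tract-only phantom: `n_fascicles` well-separated fascicles of
#' diameter at most the measuring-sphere diameter, each crossing any
#' coronal plane exactly once, with no nuclei, fibers or vessels. With a
#' slab thinner than or equal to the sphere diameter the pathway-unit
#' count must equal the fascicle count exactly.
#'
#' @param seed integer seed.
#' @param n_fascicles number of fascicles.
#' @return List with `spec` (a [phantom_spec()]) and `slab` (a
#'   [slab_spec()] with a fixed slab coordinate mid-tract).
#' @export
exactness_phantom <- function(seed, n_fascicles = 7) {
  tract <- tract_spec(
    n_fascicles = n_fascicles, fascicle_diameter_um = c(10.5, 12.5),
    n_dispersed_fibers = 0, fascicle_intensity = 3000,
    rc_range_um = c(440, 40), center_zx_um = c(140, 160),
    spread_um = c(55, 95), min_separation_um = 34, wander_um = 2)
  spec <- phantom_spec(
    shape = c(40L, 96L, 64L), spacing_um = c(7, 5, 5),
    nuclei = list(), tract = tract, vessels = NULL,
    blur_sigma_um = c(5, 3.5, 3.5),
    noise = list(background = 200, gaussian_sd = 30, poisson_scale = 0),
    seed = seed
  )
  slab <- slab_spec(thickness_um = 12,
                    sphere_params = sphere_params(diameter_um = 13,
                                                 fit_fraction = 0.4),
                    rostral_limit_um = 240,
                    min_fascicle_diameter_um = 8,
                    min_fascicle_intensity = 1300)
  list(spec = spec, slab = slab)
}
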