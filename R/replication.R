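#' Default simulated-study configuration
#'
#' Defines the phantom "specimen" used by the simulated replication study:
#' a 50 x 144 x 88 voxel volume (7 x 5 x 5 µm spacing, i.e. 350 x 720 x
#' 440 µm) holding per-side SN envelopes, a midline-straddling VTA and
#' A11-13, a ventral corridor of mesotelencephalic fascicles plus
#' dispersed fibers, and vessels traversing the SN. Control-arm structure
#' abundances, per-animal lognormal variation, the batch model, the
#' segmentation/counting parameters and the ROI layout all live here so
#' that a study run is reproducible from the seed alone.
#'
#' @param n_fascicles,n_sn,n_vta,n_a11_13 control-arm abundances: fascicle
#'   count and somata per SN side / VTA / A11-13.
#' @param animal_cv lognormal coefficient of variation of per-animal
#'   abundances.
#' @param batch_sd s.d. of the lognormal day-of-preparation effect applied
#'   to abundances.
#' @param n_batches preparation days per study.
#' @param with_vessels include vessel artifacts (excluded again by the
#'   segmentation shape rule).
#' @return A `study_config` list with the phantom template, segmentation
#'   parameters, sphere parameters, slab spec and ROI definitions.
#' @export
study_config <- function(n_fascicles = 12, n_sn = 28, n_vta = 36,
                         n_a11_13 = 36, animal_cv = 0.08, batch_sd = 0.05,
                         n_batches = 3, with_vessels = TRUE) {
  nuclei <- list(
    SN_left = nucleus_spec("SN_left", center_um = c(160, 560, 80),
                           semi_axes_um = c(48, 100, 58), n_somata = n_sn,
                           min_separation_um = 18),
    SN_right = nucleus_spec("SN_right", center_um = c(160, 560, 360),
                            semi_axes_um = c(48, 100, 58), n_somata = n_sn,
                            min_separation_um = 18),
    VTA = nucleus_spec("VTA", center_um = c(160, 560, 220),
                       semi_axes_um = c(45, 70, 50), n_somata = n_vta,
                       min_separation_um = 18),
    A11_13 = nucleus_spec("A11_13", center_um = c(160, 330, 220),
                          semi_axes_um = c(45, 70, 55), n_somata = n_a11_13,
                          min_separation_um = 18)
  )
  rois <- list(
    SN_left = roi_from_nucleus(nuclei$SN_left, "left"),
    SN_right = roi_from_nucleus(nuclei$SN_right, "right"),
    VTA = roi_from_nucleus(nuclei$VTA, "bilateral_midline"),
    A11_13 = roi_from_nucleus(nuclei$A11_13, "bilateral_midline")
  )
  list(
    shape = c(50L, 144L, 88L),
    spacing_um = c(7, 5, 5),
    midline_um = 220,
    nuclei = nuclei,
    rois = rois,
    tract = tract_spec(n_fascicles = n_fascicles),
    vessels = if (with_vessels)
      vessel_spec(diameter_um = 12, length_um = 160,
                  min_clearance_um = 6) else NULL,
    blur_sigma_um = c(5, 3.5, 3.5),
    noise = list(background = 200, gaussian_sd = 30, poisson_scale = 0),
    seg_params = segmentation_params(threshold = 550),
    vessel_max_extent_um = 100,
    vessel_max_elongation = 5,
    sphere_params = sphere_params(diameter_um = 13, fit_fraction = 0.4),
    slab = slab_spec(thickness_um = 12,
                     lateral_min_um = c(220, 0, 100),
                     lateral_max_um = c(335, Inf, 340),
                     min_fascicle_diameter_um = 8,
                     min_fascicle_intensity = 1300),
    animal_cv = animal_cv, batch_sd = batch_sd, n_batches = n_batches
  )
}

#' Reference cuboid from a nucleus envelope
#'
#' @param nucleus a [nucleus_spec()].
#' @param laterality ROI laterality tag.
#' @param pad_um padding added around the envelope bounding box.
#' @return A [reference_cuboid].
#' @export
roi_from_nucleus <- function(nucleus, laterality = "bilateral_midline",
                             pad_um = 12) {
  reference_cuboid(nucleus$name,
                   nucleus$center_um - nucleus$semi_axes_um - pad_um,
                   nucleus$center_um + nucleus$semi_axes_um + pad_um,
                   laterality)
}

# phantom spec for one simulated animal, with abundances scaled by the
# treated/control ratios and jittered by the animal/batch effects
animal_phantom_spec <- function(config, ratios, seed, jitter = 1) {
  scale_n <- function(n, r) max(0L, as.integer(round(n * r * jitter)))
  nuclei <- config$nuclei
  nuclei$SN_left$n_somata <- scale_n(nuclei$SN_left$n_somata, ratios[["SN"]])
  nuclei$SN_right$n_somata <- scale_n(nuclei$SN_right$n_somata,
                                      ratios[["SN"]])
  nuclei$VTA$n_somata <- scale_n(nuclei$VTA$n_somata, ratios[["VTA"]])
  nuclei$A11_13$n_somata <- scale_n(nuclei$A11_13$n_somata,
                                    ratios[["A11_13"]])
  tract <- config$tract
  tract$n_fascicles <- scale_n(tract$n_fascicles, ratios[["fascicles"]])
  phantom_spec(config$shape, config$spacing_um,
               midline_um = config$midline_um,
               nuclei = unname(nuclei), tract = tract,
               vessels = config$vessels,
               blur_sigma_um = config$blur_sigma_um, noise = config$noise,
               seed = seed)
}

#' Run the full morphometric pipeline on one volume
#'
#' Segmentation, vessel exclusion, per-ROI perikarya counting and
#' slab-based pathway-unit measurement, using a study configuration.
#'
#' @param volume a [volume3d].
#' @param config a [study_config()].
#' @return List with `counts` (a `count_report`), `pathway` (from
#'   [measure_pathway_units()]) and the intermediate `mask`.
#' @export
quantify_volume <- function(volume, config = study_config()) {
  mask <- segment(volume, config$seg_params)
  cells <- exclude_vessels(mask, config$vessel_max_extent_um,
                           config$vessel_max_elongation)
  counts <- count_perikarya(cells, unname(config$rois),
                            config$sphere_params)
  slab <- config$slab
  slab$sphere_params <- config$sphere_params
  pathway <- measure_pathway_units(mask, slab,
                                   a11_13_roi = config$rois$A11_13)
  list(counts = counts, pathway = pathway, mask = mask)
}

#' Simulated replication study: control vs treated phantom cohorts
#'
#' Generates `n_per_group` phantoms per arm with structure abundances
#' scaled by the injected treated/control ratios (and jittered by the
#' per-animal and batch variance model), runs the full pipeline on every
#' phantom, and compares the arms per endpoint with percent changes and
#' batch-stratified permutation p-values. SN counts are summed over the
#' two sides for the group endpoint.
#'
#' @param config a [study_config()].
#' @param n_per_group phantoms per arm.
#' @param effect_sizes named treated/control ratios for `fascicles`, `SN`,
#'   `VTA`, `A11_13`.
#' @param seed master seed; everything (abundance jitter, phantom
#'   generation) derives from it.
#' @return List with `comparisons` (one row per endpoint: means, SEs,
#'   `percent_change`, `p_value`), `records` (per-animal endpoint table)
#'   and `injected` (the injected percent changes).
#' @export
run_replication_study <- function(config = study_config(), n_per_group = 6,
                                  effect_sizes = c(fascicles = 1, SN = 1,
                                                   VTA = 1, A11_13 = 1),
                                  seed = 1L) {
  n <- 2L * n_per_group
  group <- rep(c("control", "treated"), each = n_per_group)
  batch <- paste0("day", rep_len(seq_len(config$n_batches), n))
  seeds <- derive_seeds(seed, n + 1L)
  null_ratios <- c(fascicles = 1, SN = 1, VTA = 1, A11_13 = 1)
  jitters <- with_seed(seeds[n + 1L], {
    bfx <- stats::setNames(exp(stats::rnorm(config$n_batches, 0,
                                            config$batch_sd)),
                           paste0("day", seq_len(config$n_batches)))
    exp(stats::rnorm(n, 0, config$animal_cv)) * bfx[batch]
  })
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ratios <- if (group[i] == "treated") effect_sizes else null_ratios
    spec <- animal_phantom_spec(config, ratios, seeds[i], jitters[i])
    ph <- generate_phantom(spec)
    q <- quantify_volume(ph$volume, config)
    cts <- stats::setNames(q$counts$count, q$counts$roi)
    rows[[i]] <- data.frame(
      animal = sprintf("m%02d", i), group = group[i], batch = batch[i],
      SN = unname(cts["SN_left"] + cts["SN_right"]),
      VTA = unname(cts["VTA"]), A11_13 = unname(cts["A11_13"]),
      fascicles = q$pathway$units$total,
      tract_width_um = q$pathway$metrics$tract_width_um
    )
  }
  records <- do.call(rbind, rows)
  endpoints <- c("fascicles", "SN", "VTA", "A11_13")
  comp_seeds <- derive_seeds(as.numeric(seed) + 1, length(endpoints))
  comparisons <- do.call(rbind, lapply(seq_along(endpoints), function(k) {
    ep <- endpoints[k]
    rec <- animal_records(records$animal, records$group, records[[ep]],
                          records$batch)
    compare_groups(rec, name = ep, seed = comp_seeds[k])
  }))
  comparisons$injected_percent_change <-
    100 * (as.numeric(effect_sizes[endpoints]) - 1)
  list(comparisons = comparisons, records = records,
       injected = stats::setNames(
         100 * (as.numeric(effect_sizes[endpoints]) - 1), endpoints),
       seed = seed)
}
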