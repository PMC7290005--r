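tube_mask <- function(builder, shape = c(40L, 96L, 64L),
                      spacing = c(7, 5, 5), threshold = 50) {
  vol <- volume3d(array(0, shape), spacing)
  vol <- builder(vol)
  segment(vol, segmentation_params(threshold = threshold, min_voxels = 1))
}

test_that("rostral limit localization and its error cases", {
  arr <- array(0, c(8, 10, 8))
  arr[4, 7, 5] <- 10
  m <- segment(volume3d(arr, c(7, 5, 5)),
               segmentation_params(threshold = 5, min_voxels = 1))
  expect_identical(locate_rostral_limit(m), 32.5)  # (7 - 0.5) * 5

  empty <- segment(volume3d(array(0, c(4, 4, 4)), c(7, 5, 5)),
                   segmentation_params(threshold = 1))
  expect_error(locate_rostral_limit(empty), "empty")
})

test_that("rostral limit of a phantom nucleus matches ground truth", {
  spec <- phantom_spec(
    shape = c(36L, 60L, 50L), spacing_um = c(7, 5, 5),
    nuclei = list(nucleus_spec("A11_13", center_um = c(126, 150, 125),
                               semi_axes_um = c(70, 80, 80), n_somata = 40,
                               min_separation_um = 18)),
    blur_sigma_um = c(0, 0, 0),
    noise = list(background = 0, gaussian_sd = 0, poisson_scale = 0),
    seed = 5L)
  ph <- generate_phantom(spec)
  m <- segment(ph$volume, segmentation_params(threshold = 500,
                                              min_voxels = 1))
  found <- locate_rostral_limit(m)
  truth <- ph$ground_truth$a11_13_rostral_limit_um
  # somata sit inside the envelope, so the mask limit trails the envelope
  # boundary by up to a soma diameter; it must never precede it by more
  # than a voxel
  expect_gte(found, truth - 5)
  expect_lte(found, truth + 15)
})

test_that("slab thickness is capped at the sphere diameter, inclusively", {
  vol <- volume3d(array(0, c(10, 100, 10)), c(7, 5, 5))
  ok <- slab_spec(thickness_um = 12, sphere_params = sphere_params(12),
                  rostral_limit_um = 350)
  cub <- place_slab(vol, ok)
  expect_identical(unname(cub$min_um[2]), 350)
  expect_identical(unname(cub$max_um[2]), 362)

  too_thick <- slab_spec(thickness_um = 12.0001,
                         sphere_params = sphere_params(12),
                         rostral_limit_um = 350)
  expect_error(place_slab(vol, too_thick), "not exceed")
})

test_that("disjoint tubes crossing the slab give one window each", {
  n <- 7
  build <- function(vol) {
    for (i in seq_len(n))
      vol <- rasterize_tube(vol, rbind(c(140, 470, 25 + 38 * (i - 1)),
                                       c(140, 10, 25 + 38 * (i - 1))),
                            diameter_um = 12, intensity = 2000)
    vol
  }
  m <- tube_mask(build, shape = c(40L, 96L, 56L), threshold = 500)
  spec <- slab_spec(thickness_um = 12, sphere_params = sphere_params(12),
                    rostral_limit_um = 240, min_fascicle_diameter_um = 8,
                    min_fascicle_intensity = 500)
  slab <- place_slab(m, spec)
  win <- find_intersection_windows(m, slab, spec)
  expect_identical(nrow(win$windows), 7L)
  # oracle: flood fill of the clipped admitted mask
  clip <- (m$labels > 0) & (m$intensity >= 500)
  ys <- 240 <= ((seq_len(96) - 0.5) * 5) & ((seq_len(96) - 0.5) * 5) < 252
  clip[, !ys, ] <- FALSE
  expect_identical(max(oracle_label(clip, 26)), 7L)

  units <- count_pathway_units(win, spec)
  expect_identical(units$total, 7L)
})

test_that("two tubes merging inside the slab form a single window", {
  build <- function(vol) {
    vol <- rasterize_tube(vol, rbind(c(140, 470, 80), c(140, 250, 150),
                                     c(140, 10, 152)),
                          diameter_um = 12, intensity = 2000)
    rasterize_tube(vol, rbind(c(140, 470, 220), c(140, 250, 160),
                              c(140, 10, 162)),
                   diameter_um = 12, intensity = 2000)
  }
  m <- tube_mask(build, shape = c(40L, 96L, 64L), threshold = 500)
  spec <- slab_spec(thickness_um = 12, sphere_params = sphere_params(12),
                    rostral_limit_um = 240, min_fascicle_diameter_um = 8,
                    min_fascicle_intensity = 500)
  win <- find_intersection_windows(m, place_slab(m, spec), spec)
  expect_identical(nrow(win$windows), 1L)
})

test_that("a nonempty window too small for a sphere still counts one unit", {
  build <- function(vol)
    rasterize_tube(vol, rbind(c(140, 242, 100), c(140, 250, 100)),
                   diameter_um = 10, intensity = 2000)
  m <- tube_mask(build, shape = c(40L, 96L, 44L), threshold = 500)
  spec <- slab_spec(thickness_um = 12,
                    sphere_params = sphere_params(16, fit_fraction = 0.9),
                    rostral_limit_um = 240, min_fascicle_diameter_um = 0,
                    min_fascicle_intensity = 500)
  win <- find_intersection_windows(m, place_slab(m, spec), spec)
  expect_identical(nrow(win$windows), 1L)
  units <- count_pathway_units(win, spec)
  expect_identical(units$per_window, 1L)
})

test_that("no fascicle voxels in the slab yields an empty result", {
  m <- tube_mask(function(vol) vol, shape = c(10L, 60L, 10L))
  spec <- slab_spec(thickness_um = 10, sphere_params = sphere_params(12),
                    rostral_limit_um = 100)
  win <- find_intersection_windows(m, place_slab(m, spec), spec)
  expect_identical(nrow(win$windows), 0L)
  expect_identical(count_pathway_units(win, spec)$total, 0L)
})

test_that("unit counts ignore lateral slab over-extension", {
  ex <- exactness_phantom(seed = 91L, n_fascicles = 5)
  ph <- generate_phantom(ex$spec)
  m <- segment(ph$volume, segmentation_params(threshold = 550))
  narrow <- ex$slab
  narrow$lateral_min_um <- c(60, 0, 40)
  narrow$lateral_max_um <- c(230, Inf, 290)
  u1 <- measure_pathway_units(m, narrow)$units$total
  u2 <- measure_pathway_units(m, ex$slab)$units$total  # full lateral extent
  expect_identical(u1, u2)
})

test_that("repeated measurement is exactly reproducible", {
  ex <- exactness_phantom(seed = 92L, n_fascicles = 6)
  ph <- generate_phantom(ex$spec)
  m <- segment(ph$volume, segmentation_params(threshold = 550))
  r1 <- measure_pathway_units(m, ex$slab)
  r2 <- measure_pathway_units(m, ex$slab)
  expect_identical(r1$units$per_window, r2$units$per_window)
  expect_identical(r1$windows$windows, r2$windows$windows)
})

test_that("defasciculation metrics behave at their boundaries", {
  # all windows at one mediolateral position -> width 0
  build <- function(vol) {
    for (z in c(70, 140, 210))
      vol <- rasterize_tube(vol, rbind(c(z, 470, 100), c(z, 10, 100)),
                            diameter_um = 12, intensity = 2000)
    vol
  }
  m <- tube_mask(build, shape = c(40L, 96L, 44L), threshold = 500)
  spec <- slab_spec(thickness_um = 12, sphere_params = sphere_params(12),
                    rostral_limit_um = 240, min_fascicle_diameter_um = 8,
                    min_fascicle_intensity = 500)
  win <- find_intersection_windows(m, place_slab(m, spec), spec)
  met <- defasciculation_metrics(win)
  expect_identical(nrow(win$windows), 3L)
  expect_lt(met$tract_width_um, 3)
  expect_identical(met$bundled_fraction, 1)

  # empty slab -> width 0, bundled fraction undefined
  m0 <- tube_mask(function(vol) vol, shape = c(10L, 60L, 10L))
  spec0 <- slab_spec(thickness_um = 10, sphere_params = sphere_params(12),
                     rostral_limit_um = 100)
  met0 <- defasciculation_metrics(
    find_intersection_windows(m0, place_slab(m0, spec0), spec0))
  expect_identical(met0$tract_width_um, 0)
  expect_false(met0$defined)
})

test_that("tract width grows with the generator's lateral spread", {
  width_for <- function(mult, seed) {
    tr <- tract_spec(n_fascicles = 8, n_dispersed_fibers = 0,
                     fascicle_diameter_um = c(10.5, 12.5),
                     rc_range_um = c(440, 40),
                     center_zx_um = c(140, 160),
                     spread_um = c(20, 30) * mult,
                     min_separation_um = 14, wander_um = 2)
    spec <- phantom_spec(shape = c(40L, 96L, 64L), spacing_um = c(7, 5, 5),
                         nuclei = list(), tract = tr,
                         blur_sigma_um = c(5, 3.5, 3.5),
                         noise = list(background = 200, gaussian_sd = 30,
                                      poisson_scale = 0),
                         seed = seed)
    ph <- generate_phantom(spec)
    m <- segment(ph$volume, segmentation_params(threshold = 550))
    spec_s <- slab_spec(thickness_um = 12,
                        sphere_params = sphere_params(13, 0.4),
                        rostral_limit_um = 240,
                        min_fascicle_diameter_um = 8,
                        min_fascicle_intensity = 1300)
    measure_pathway_units(m, spec_s)$metrics$tract_width_um
  }
  for (seed in c(101, 102, 103))
    expect_gt(width_for(3, seed), width_for(1, seed))
})
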