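# a small clean single-nucleus spec used in several tests
clean_nucleus_spec <- function(seed = 1L, n = 25, blur = c(0, 0, 0),
                               noise = list(background = 0, gaussian_sd = 0,
                                            poisson_scale = 0)) {
  phantom_spec(
    shape = c(36L, 50L, 50L), spacing_um = c(7, 5, 5),
    nuclei = list(nucleus_spec("VTA", center_um = c(126, 125, 125),
                               semi_axes_um = c(80, 90, 90), n_somata = n,
                               min_separation_um = 20)),
    blur_sigma_um = blur, noise = noise, seed = seed)
}

test_that("generation is bit-identical for the same spec and seed", {
  spec <- clean_nucleus_spec(seed = 42L)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$ground_truth, b$ground_truth)

  noisy <- clean_nucleus_spec(seed = 42L,
                              noise = list(background = 100,
                                           gaussian_sd = 25,
                                           poisson_scale = 1))
  n1 <- generate_phantom(noisy)
  n2 <- generate_phantom(noisy)
  expect_identical(n1$volume$data, n2$volume$data)
})

test_that("default imaging geometry records the 7 um z-step", {
  spec <- phantom_spec(shape = c(4L, 4L, 4L))
  ph <- generate_phantom(spec)
  expect_identical(unname(ph$volume$spacing_um[1]), 7)
  expect_identical(unname(ph$volume$spacing_um[2:3]), c(5, 5))
})

test_that("clean phantom yields exactly n_somata components (oracle check)", {
  spec <- clean_nucleus_spec(seed = 7L, n = 25)
  ph <- generate_phantom(spec)
  gt <- ph$ground_truth$somata
  expect_identical(nrow(gt), 25L)
  # all pairwise separations respect the non-touching guarantee
  dd <- as.matrix(dist(gt[, c("z_um", "y_um", "x_um")]))
  diag(dd) <- Inf
  expect_true(all(dd >= 20 - 1e-9))
  half <- min(gt$intensity) / 2
  labels <- oracle_label(ph$volume$data >= half, 26)
  expect_identical(max(labels), 25L)
})

test_that("soma placement fails loudly when the envelope cannot hold them", {
  spec <- phantom_spec(
    shape = c(20L, 20L, 20L), spacing_um = c(7, 5, 5),
    nuclei = list(nucleus_spec("SN_left", center_um = c(70, 50, 50),
                               semi_axes_um = c(20, 20, 20), n_somata = 60,
                               min_separation_um = 25)),
    blur_sigma_um = c(0, 0, 0),
    noise = list(background = 0, gaussian_sd = 0, poisson_scale = 0),
    seed = 1L)
  expect_error(generate_phantom(spec), "SN_left")
})

test_that("rasterized cylinder volume matches the analytic value within 15%", {
  vol <- volume3d(array(0, c(40, 160, 40)), c(7, 5, 5))
  cl <- rbind(c(140, 50, 100), c(140, 750, 100))
  vol <- rasterize_tube(vol, cl, diameter_um = 20, intensity = 100)
  count_vol <- sum(vol$data > 0) * prod(vol$spacing_um)
  analytic <- pi * 10^2 * 700
  expect_lt(abs(count_vol - analytic) / analytic, 0.15)
})

test_that("degenerate single-point centerline rasterizes a sphere", {
  vol <- volume3d(array(0, c(20, 20, 20)), c(5, 5, 5))
  vol <- rasterize_tube(vol, c(50, 50, 50), diameter_um = 24,
                        intensity = 10)
  idx <- which(vol$data > 0)
  co <- arrayInd(idx, dim(vol$data))
  dist <- sqrt(rowSums(sweep(sweep(co - 0.5, 2, c(5, 5, 5), "*"), 2,
                             c(50, 50, 50))^2))
  expect_true(all(dist <= 12 + 1e-9))
  analytic <- (4 / 3) * pi * 12^3
  expect_lt(abs(length(idx) * 125 - analytic) / analytic, 0.15)
})

test_that("two parallel tubes separated by > 1 diameter stay disconnected", {
  vol <- volume3d(array(0, c(20, 40, 40)), c(7, 5, 5))
  vol <- rasterize_tube(vol, rbind(c(70, 20, 60), c(70, 180, 60)), 15, 50)
  vol <- rasterize_tube(vol, rbind(c(70, 20, 140), c(70, 180, 140)), 15, 50)
  labels <- oracle_label(vol$data >= 25, 26)
  expect_identical(max(labels), 2L)
})

test_that("tube rasterization enforces its preconditions", {
  vol <- volume3d(array(0, c(10, 10, 10)), c(7, 5, 5))
  expect_error(rasterize_tube(vol, c(25, 25, 25), diameter_um = 6, 1),
               "diameter")
  expect_error(rasterize_tube(vol, c(500, 25, 25), diameter_um = 10, 1),
               "bounds")
})

test_that("optics stage is the identity when blur and noise are disabled", {
  spec <- clean_nucleus_spec(seed = 3L)
  vol <- volume3d(random_blob_volume(3, c(12, 12, 12)), c(7, 5, 5))
  out <- apply_optics_and_noise(vol, spec)
  expect_identical(out$data, vol$data)
})

test_that("blur conserves total intensity to within 1%", {
  vol <- volume3d(random_blob_volume(4, c(16, 20, 16)), c(7, 5, 5))
  spec <- clean_nucleus_spec(seed = 4L, blur = c(6, 4, 4))
  out <- apply_optics_and_noise(vol, spec)
  expect_lt(abs(sum(out$data) - sum(vol$data)) / sum(vol$data), 0.01)
})

test_that("fascicle centerlines are monotone and cross each plane once", {
  spec <- phantom_spec(
    shape = c(40L, 96L, 64L), spacing_um = c(7, 5, 5),
    tract = tract_spec(n_fascicles = 6, n_dispersed_fibers = 4,
                       rc_range_um = c(440, 40),
                       center_zx_um = c(140, 160), spread_um = c(40, 70)),
    blur_sigma_um = c(0, 0, 0),
    noise = list(background = 0, gaussian_sd = 0, poisson_scale = 0),
    seed = 11L)
  ph <- generate_phantom(spec)
  for (f in c(ph$ground_truth$fascicles, ph$ground_truth$fibers)) {
    ys <- f$centerline_um[, 2]
    expect_true(all(diff(ys) < 0))  # strictly rostrally directed
    for (plane in c(100, 240, 380)) {
      crossings <- sum(diff(sign(ys - plane)) != 0)
      expect_identical(crossings, 1L)
    }
  }
})
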