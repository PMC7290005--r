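mask_from_array <- function(arr, spacing = c(1, 1, 1), threshold = 0.5,
                            midline_um = NULL) {
  segment(volume3d(arr, spacing, midline_um = midline_um),
          segmentation_params(threshold = threshold, min_voxels = 1))
}

full_roi <- function(arr, spacing = c(1, 1, 1), name = "all",
                     laterality = "bilateral_midline") {
  d <- dim(arr)
  reference_cuboid(name, c(0, 0, 0), d * spacing, laterality)
}

test_that("an empty mask yields a count of zero", {
  arr <- array(0, c(8, 8, 8))
  m <- mask_from_array(arr, threshold = 1)
  sa <- generate_sphere_array(m, full_roi(arr), sphere_params(3, 0.5))
  expect_identical(sa$count, 0L)
})

test_that("one isolated soma-sized object gives exactly one sphere", {
  vol <- volume3d(array(0, c(24, 24, 24)), c(7, 5, 5))
  vol <- rasterize_tube(vol, c(84, 60, 60), diameter_um = 12,
                        intensity = 100)
  m <- segment(vol, segmentation_params(threshold = 50, min_voxels = 1))
  sa <- generate_sphere_array(m, full_roi(vol$data, c(7, 5, 5)),
                              sphere_params(12, 0.5))
  expect_identical(sa$count, 1L)
  expect_lt(sqrt(sum((unlist(sa$centers_um) - c(84, 60, 60))^2)), 7)
})

test_that("greedy packing matches the exhaustive oracle on a solid cuboid", {
  arr <- array(0, c(44, 24, 24))
  arr[3:42, 3:22, 3:22] <- 7  # 40 x 20 x 20 solid block, unit spacing
  m <- mask_from_array(arr, threshold = 1)
  sa <- generate_sphere_array(m, full_roi(arr), sphere_params(10, 0.9))
  oracle <- oracle_pack(m$intensity, m$labels > 0, c(1, 1, 1), 10, 0.9)
  expect_identical(sa$count, nrow(oracle))
  # a regular 4 x 2 x 2 grid of spheres is a feasible packing of this
  # block (every grid sphere passes the fit rule and the spacing rule);
  # the greedy scan with lexicographic tie-breaks lands near but not
  # necessarily at that optimum
  grid <- as.matrix(expand.grid(z = c(8, 18, 28, 38), y = c(8, 18),
                                x = c(8, 18)))
  stencil <- clearcount:::sphere_offsets(c(1, 1, 1), 10)
  ok <- apply(grid, 1, function(ctr) {
    st <- sweep(stencil, 2, as.integer(ctr), "+")
    mean(arr[st] >= 1) >= 0.9
  })
  expect_true(all(ok))
  expect_true(min(dist(grid)) >= 10)
  expect_gte(sa$count, 15)
})

test_that("count obeys the covering upper bound", {
  for (seed in 1:4) {
    arr <- random_blob_volume(seed + 50, c(18, 18, 18))
    m <- mask_from_array(arr, threshold = 300)
    sa <- generate_sphere_array(m, full_roi(arr), sphere_params(4, 0.6))
    stencil <- nrow(clearcount:::sphere_offsets(c(1, 1, 1), 4))
    bound <- sum(m$labels > 0) / (0.6 * stencil)
    expect_lte(sa$count, bound)
  }
})

test_that("a two-soma dumbbell counts as two perikarya", {
  vol <- volume3d(array(0, c(24, 30, 24)), c(7, 5, 5))
  vol <- rasterize_tube(vol, c(84, 60, 60), diameter_um = 12, 100)
  vol <- rasterize_tube(vol, c(84, 76, 60), diameter_um = 12, 100)
  # bridge the two so they form one component
  vol <- rasterize_tube(vol, rbind(c(84, 60, 60), c(84, 76, 60)), 10, 100)
  m <- segment(vol, segmentation_params(threshold = 50, min_voxels = 1))
  expect_identical(nrow(m$components), 1L)
  sa <- generate_sphere_array(m, full_roi(vol$data, c(7, 5, 5)),
                              sphere_params(12, 0.5))
  expect_identical(sa$count, 2L)
  oracle <- oracle_pack(m$intensity, m$labels > 0, c(7, 5, 5), 12, 0.5)
  expect_identical(sa$count, nrow(oracle))
})

test_that("counts are invariant under 90-degree rotation at isotropic spacing", {
  arr <- random_blob_volume(61, c(20, 20, 20))
  m <- mask_from_array(arr, threshold = 300)
  sa <- generate_sphere_array(m, full_roi(arr), sphere_params(5, 0.5))
  rot <- aperm(arr, c(1, 3, 2))[, , rev(seq_len(20))]  # 90 deg about z
  m2 <- mask_from_array(rot, threshold = 300)
  sa2 <- generate_sphere_array(m2, full_roi(rot), sphere_params(5, 0.5))
  expect_identical(sa$count, sa2$count)
})

test_that("per-side and bilateral ROI conventions are enforced", {
  arr <- array(0, c(10, 10, 20))
  arr[4:6, 4:6, 3:5] <- 10
  arr[4:6, 4:6, 15:17] <- 10
  m <- mask_from_array(arr, threshold = 5, midline_um = 10)
  left <- reference_cuboid("SN_left", c(0, 0, 0), c(10, 10, 10), "left")
  right <- reference_cuboid("SN_right", c(0, 0, 10), c(10, 10, 20), "right")
  mid <- reference_cuboid("VTA", c(0, 0, 5), c(10, 10, 15),
                          "bilateral_midline")
  rep <- count_perikarya(m, list(left, right, mid), sphere_params(3, 0.5))
  expect_identical(nrow(rep), 3L)
  expect_identical(rep$count[rep$roi == "SN_left"],
                   rep$count[rep$roi == "SN_right"])

  overlap_right <- reference_cuboid("SN_right", c(0, 0, 8), c(10, 10, 20),
                                    "right")
  expect_error(count_perikarya(m, list(left, overlap_right),
                               sphere_params(3, 0.5)), "overlap")

  off_mid <- reference_cuboid("VTA", c(0, 0, 11), c(10, 10, 15),
                              "bilateral_midline")
  expect_error(count_perikarya(m, list(off_mid), sphere_params(3, 0.5)),
               "midline")
})

test_that("greedy packing equals the oracle across random fixtures", {
  for (seed in 1:8) {
    dims <- c(16, 18, 16)
    arr <- random_blob_volume(seed + 70, dims,
                              integer_intensity = seed %% 2 == 0)
    m <- mask_from_array(arr, threshold = 3)
    sa <- generate_sphere_array(m, full_roi(arr), sphere_params(4, 0.5))
    oracle <- oracle_pack(m$intensity, m$labels > 0, c(1, 1, 1), 4, 0.5)
    expect_identical(sa$count, nrow(oracle))
    got <- as.matrix(sa$centers_um) + 0.5  # unit spacing: back to indices
    expect_equal(unname(got), oracle + 0, tolerance = 1e-12)
  }
})
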