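# Centroid seeding: matched filter, MeanShift, boundary filtering.

test_that("matched filter finds a clean particle and ignores noise", {
  model <- imaging_model(snr = 1)
  ps <- micro_particles(24, 24, 24, rot = 40, tilt = 60)
  tomo <- micro_tomogram(ps, box = 48, model = model)  # noise-free
  cen <- matched_filter_localize(tomo, default_disc(), model,
                                 coarse_step = 35)
  expect_equal(nrow(cen), 1L)
  expect_lt(sqrt(sum((cen[1, ] - c(24, 24, 24))^2)), sqrt(3) + 1e-9)
  # pure-noise volume: the adaptive threshold admits (almost) nothing
  set.seed(71)
  noise <- volume(array(rnorm(48^3), rep(48, 3)))
  cen0 <- matched_filter_localize(noise, default_disc(), model,
                                  coarse_step = 35)
  expect_lte(nrow(cen0), 1L)
})

test_that("meanshift finds blob modes and merges by bandwidth", {
  # two disjoint Gaussian blobs
  seg <- array(0, rep(40, 3))
  grid <- as.matrix(expand.grid(1:40, 1:40, 1:40))
  d1 <- sqrt(rowSums(sweep(grid, 2, c(12, 12, 12))^2))
  d2 <- sqrt(rowSums(sweep(grid, 2, c(30, 30, 30))^2))
  seg[grid] <- exp(-d1^2 / 18) + exp(-d2^2 / 18)
  v <- volume(seg)
  cen <- meanshift_centroids(v, bandwidth = 6)
  expect_equal(nrow(cen), 2L)
  ctrs <- rbind(c(11, 11, 11), c(29, 29, 29))  # nm of voxel centres
  for (i in 1:2)
    expect_lt(min(sqrt(colSums((t(ctrs) - cen[i, ])^2))), 1)
  # single blob -> single mode at its centre
  v1 <- volume(array(exp(-d1^2 / 18), rep(40, 3)))
  cen1 <- meanshift_centroids(v1, bandwidth = 6)
  expect_equal(nrow(cen1), 1L)
  expect_lt(sqrt(sum((cen1[1, ] - c(11, 11, 11))^2)), 1)
  # dumbbell: two blobs 10 nm apart resolved at small bandwidth
  d3 <- sqrt(rowSums(sweep(grid, 2, c(22, 12, 12))^2))
  vd <- volume(array(exp(-d1^2 / 8) + exp(-d3^2 / 8), rep(40, 3)))
  expect_equal(nrow(meanshift_centroids(vd, bandwidth = 3)), 2L)
  # centroid count is non-increasing in bandwidth
  expect_lte(nrow(meanshift_centroids(vd, bandwidth = 8)),
             nrow(meanshift_centroids(vd, bandwidth = 3)))
  # empty segmentation warns and returns nothing
  expect_warning(out <- meanshift_centroids(
    volume(array(0, rep(8, 3)))), "empty segmentation")
  expect_equal(nrow(out), 0L)
})

test_that("boundary filter drops lamella-margin and exterior points", {
  pts <- rbind(c(50, 50, 10),    # 10 nm from the lower face: dropped
               c(50, 50, 75),    # mid-plane: kept
               c(200, 50, 75))   # outside the sphere: dropped if given
  keep <- filter_boundary_particles(pts, c(0, 150), margin = 20)
  expect_equal(nrow(keep), 2L)
  sph <- structure(list(center = c(50, 50, 75), radius = 60,
                        rms_residual = 0), class = "sphere_surface")
  keep2 <- filter_boundary_particles(pts, c(0, 150), margin = 20,
                                     surface = sph)
  expect_equal(nrow(keep2), 1L)
  expect_equal(keep2[1, ], c(50, 50, 75))
  # output is a subset and the filter is idempotent
  again <- filter_boundary_particles(keep2, c(0, 150), margin = 20,
                                     surface = sph)
  expect_equal(again, keep2)
  expect_error(filter_boundary_particles(pts, c(10, 5)), "increasing")
})
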