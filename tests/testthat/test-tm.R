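# Exhaustive template matching: score maps, search, NMS, threshold sweep.

test_that("score map peaks at a clean particle with matching pose", {
  model <- imaging_model(snr = 1)
  ps <- micro_particles(24, 24, 24, rot = 30, tilt = 50)
  tomo <- micro_tomogram(ps, box = 48, model = model)
  sm <- ncc_score_map(tomo, default_disc(),
                      quat_from_euler(30, 50, 0), model)
  pk <- which(sm$data == max(sm$data), arr.ind = TRUE)
  expect_equal(as.integer(pk[1, ]), c(25, 25, 25))
  expect_gt(max(sm$data), 0.99)
  expect_lte(max(sm$data), 1 + 1e-12)
})

test_that("constant tomogram scores zero everywhere", {
  v <- volume(array(5, rep(32, 3)))
  sm <- ncc_score_map(v, default_disc(), quat_random(1), imaging_model())
  expect_true(all(sm$data == 0))
})

test_that("FFT score map equals brute-force masked Pearson correlation", {
  set.seed(41)
  model <- imaging_model(snr = 1)
  ps <- micro_particles(c(16, 30), c(20, 28), c(24, 18),
                        rot = c(0, 70), tilt = c(30, 80))
  tomo <- micro_tomogram(ps, box = 48, snr = 2, model = model)
  q <- quat_random(1)
  bank <- build_orientation_bank(default_disc(),
                                 list(quats = q), model)
  sm <- ncc_score_map(tomo, default_disc(), q, model)
  vox <- cbind(sample(12:36, 5), sample(12:36, 5), sample(12:36, 5))
  for (i in 1:5) {
    expect_equal(sm$data[vox[i, 1], vox[i, 2], vox[i, 3]],
                 brute_masked_ncc(tomo, bank$entries[[1]], vox[i, ]),
                 tolerance = 1e-8)
  }
})

test_that("tm_search recovers an isolated particle's pose", {
  model <- imaging_model(snr = 1)
  ps <- micro_particles(24, 24, 24, rot = 110, tilt = 64)
  tomo <- micro_tomogram(ps, box = 48, snr = 5, seed = 3, model = model)
  grid <- rotation_grid(20)
  cands <- tm_search(tomo, default_disc(), grid, model,
                     score_floor = 0.2)
  top <- cands[1, ]
  expect_lt(sqrt(sum((c(top$x, top$y, top$z) - c(24, 24, 24))^2)),
            sqrt(3) + 1e-9)   # within one voxel
  nrm_true <- quat_normal(quat_from_euler(110, 64, 0))
  nrm_got <- quat_normal(quat_from_euler(top$rot, top$tilt, top$psi))
  ang <- acos(min(1, abs(sum(nrm_true * nrm_got)))) * 180 / pi
  expect_lte(ang, 20 + 5)
})

test_that("noise-only tomogram yields nothing at a high floor", {
  set.seed(42)
  noise <- volume(array(rnorm(40^3), rep(40, 3)))
  cands <- tm_search(noise, default_disc(), rotation_grid(40),
                     imaging_model(), score_floor = 0.8)
  expect_equal(nrow(cands), 0L)
})

test_that("two well-separated particles are both recovered", {
  model <- imaging_model(snr = 1)
  ps <- micro_particles(c(14, 44), c(24, 24), c(24, 24),
                        rot = c(0, 45), tilt = c(20, 75))
  tomo <- micro_tomogram(ps, box = 58, snr = 5, model = model)
  cands <- tm_search(tomo, default_disc(), rotation_grid(20), model,
                     score_floor = 0.3)
  pred <- nms_distance_cutoff(cands, 4)
  m <- match_particles(ps, pred, dist_tol = 5.5)
  expect_equal(m$tp, 2L)
})

test_that("NMS keeps the stronger of a close pair and respects chains", {
  two <- particle_set(x = c(10, 13), y = c(10, 10), z = c(10, 10),
                      score = c(0.8, 0.6))
  out <- nms_distance_cutoff(two, 4)
  expect_equal(out$score, 0.8)
  # chain A-B-C: d(A,B) = 3, d(B,C) = 3, d(A,C) = 6, CCC A > B > C
  chain <- particle_set(x = c(10, 13, 16), y = 10, z = 10,
                        score = c(0.9, 0.8, 0.7))
  out <- nms_distance_cutoff(chain, 4)
  expect_setequal(out$x, c(10, 16))
  # all survivors when already separated
  far <- particle_set(x = c(0, 10, 20), y = 0, z = 0,
                      score = c(0.5, 0.6, 0.7))
  expect_equal(nrow(nms_distance_cutoff(far, 4)), 3L)
})

test_that("threshold sweep contracts hold", {
  gt <- micro_particles(c(10, 30), c(10, 30), c(10, 30))
  pred <- particle_set(x = c(10, 30, 50), y = c(10, 30, 50),
                       z = c(10, 30, 50), score = c(0.9, 0.5, 0.2))
  tab <- ccc_threshold_sweep(pred, gt, thresholds = c(0, 0.4, 0.6, 0.95),
                             dist_tol = 5.5)
  # threshold above every score: no predictions, precision and recall 0
  expect_equal(tab$n_pred[4], 0L)
  expect_equal(tab$precision[4], 0)
  expect_equal(tab$recall[4], 0)
  # recall is non-increasing in threshold and maximal at threshold 0
  expect_true(all(diff(tab$recall) <= 1e-12))
  expect_equal(tab$recall[1], max(tab$recall))
  # the best row is the argmax over f1
  expect_equal(attr(tab, "best")$f1, max(tab$f1))
})
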