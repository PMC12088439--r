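# Matching, precision/recall/F1, orientation diagnostics.

test_that("identical sets match perfectly", {
  set.seed(51)
  gt <- micro_particles(runif(5, 10, 40), runif(5, 10, 40),
                        runif(5, 10, 40), rot = runif(5, 0, 360),
                        tilt = runif(5, 0, 180))
  m <- match_particles(gt, gt, dist_tol = 5.5, ang_tol = 30)
  expect_equal(m$tp, 5L)
  expect_equal(m$fp, 0L)
  expect_equal(m$fn, 0L)
  expect_equal(max(m$pairs$distance), 0)
})

test_that("a distant prediction is both a false positive and a miss", {
  gt <- micro_particles(10, 10, 10)
  pred <- micro_particles(20, 10, 10)
  m <- match_particles(gt, pred, dist_tol = 5.5)
  expect_equal(c(m$tp, m$fp, m$fn), c(0L, 1L, 1L))
})

test_that("crossing pairs get the minimal-cost assignment", {
  # gt at 0 and 4; preds at 3 and 5 (tolerance 5.5).  Greedy by listed
  # order could pair gt1-pred1 (d=3) + gt2-pred2 (d=1) cost 4; the
  # alternative pairing costs 5 + 1 = 6.  Enumerating both pairings by
  # hand: optimal total cost is 4.
  gt <- micro_particles(c(0, 4), c(0, 0), c(0, 0))
  pred <- micro_particles(c(3, 5), c(0, 0), c(0, 0))
  m <- match_particles(gt, pred, dist_tol = 5.5)
  expect_equal(m$tp, 2L)
  expect_equal(sort(m$pairs$distance), c(1, 3))
  # and matching is symmetric up to transposing FP <-> FN
  gt2 <- micro_particles(c(0, 4, 20), c(0, 0, 0), c(0, 0, 0))
  m1 <- match_particles(gt2, pred, dist_tol = 5.5)
  m2 <- match_particles(pred, gt2, dist_tol = 5.5)
  expect_equal(m1$tp, m2$tp)
  expect_equal(m1$fp, m2$fn)
  expect_equal(m1$fn, m2$fp)
})

test_that("angular tolerance vetoes well-positioned wrong orientations", {
  gt <- micro_particles(10, 10, 10, tilt = 0)
  pred <- micro_particles(10, 10, 10, tilt = 50)
  expect_equal(match_particles(gt, pred, 5.5)$tp, 1L)
  expect_equal(match_particles(gt, pred, 5.5, ang_tol = 30)$tp, 0L)
  # antipodal normals count as identical orientations
  pred2 <- micro_particles(10, 10, 10, tilt = 180)
  m <- match_particles(gt, pred2, 5.5, ang_tol = 5)
  expect_equal(m$tp, 1L)
})

test_that("precision/recall/F1 arithmetic", {
  m <- structure(list(tp = 3L, fp = 2L, fn = 1L,
                      pairs = data.frame()), class = "match_result")
  pr <- precision_recall_f1(m)
  expect_equal(unname(pr), c(0.6, 0.75, 2 * 0.45 / 1.35))
  perfect <- structure(list(tp = 4L, fp = 0L, fn = 0L,
                            pairs = data.frame()), class = "match_result")
  expect_equal(unname(precision_recall_f1(perfect)), c(1, 1, 1))
  none <- structure(list(tp = 0L, fp = 0L, fn = 3L,
                         pairs = data.frame()), class = "match_result")
  expect_equal(unname(precision_recall_f1(none)), c(0, 0, 0))
})

test_that("sinusoidal reference has mean angle of one radian", {
  set.seed(52)
  od <- orientation_distribution(quat_random(20000))
  mids <- (od$breaks[-1] + od$breaks[-10]) / 2
  expect_equal(sum(mids * od$reference), 57.3, tolerance = 1)
  expect_gt(od$ks_p, 0.01)
  expect_equal(sum(od$freq), 1)
})

test_that("face-on-only sets concentrate in the first bin", {
  q <- quat_from_euler(runif(50, 0, 360), 0, 0)
  od <- orientation_distribution(q)
  expect_equal(od$freq[1], 1)
  expect_error(orientation_distribution(particle_set()), "empty")
})
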