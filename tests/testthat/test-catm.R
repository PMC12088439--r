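# CATM: local matching, clash logic, greedy placement with pairwise
# resolution, the full pipeline, and assignment merging.

# a small bank shared across tests (coarse grid keeps them fast)
catm_bank <- function(step = 30, model = imaging_model(snr = 1)) {
  build_orientation_bank(default_disc(), rotation_grid(step), model)
}

test_that("local matching recovers an isolated particle's pose", {
  model <- imaging_model(snr = 1)
  ps <- micro_particles(24, 24, 24, rot = 200, tilt = 45)
  tomo <- micro_tomogram(ps, box = 48, snr = 5, model = model)
  grid <- rotation_grid(20)
  cl <- local_match(tomo, default_disc(), anchor = c(25.2, 23.1, 24.4),
                    search_radius = 5, grid = grid, model = model,
                    retain_threshold = 0.3)
  expect_false(is.null(cl))
  expect_true(all(diff(cl$ccc) <= 0))
  expect_true(all(cl$ccc >= 0.3))
  top <- cl[1, ]
  expect_lt(sqrt(sum((c(top$x, top$y, top$z) - c(24, 24, 24))^2)),
            sqrt(3) + 1e-9)
  nrm_true <- quat_normal(quat_from_euler(200, 45, 0))
  nrm_got <- quat_normal(grid$quats[top$orient, , drop = FALSE])
  expect_lte(acos(min(1, abs(sum(nrm_true * nrm_got)))) * 180 / pi,
             20 + 5)
})

test_that("anchors in pure noise are unassigned", {
  set.seed(61)
  noise <- volume(array(rnorm(40^3), rep(40, 3)))
  cl <- local_match(noise, default_disc(), anchor = c(20, 20, 20),
                    search_radius = 4, grid = rotation_grid(30),
                    model = imaging_model(), retain_threshold = 0.3)
  expect_null(cl)
})

test_that("clash_check geometry: separated, stacked, touching discs", {
  mask <- build_steric_mask(default_disc())
  qz <- c(1, 0, 0, 0)
  expect_false(clash_check(c(0, 0, 0), qz, c(20, 0, 0), qz, mask))
  # coaxial discs 3 nm apart face-to-face overlap heavily
  expect_true(clash_check(c(0, 0, 0), qz, c(0, 0, 3), qz, mask))
  # edge-to-edge at exactly the diameter: no shared voxel centre
  expect_false(clash_check(c(0, 0, 0), qz, c(11, 0, 0), qz, mask,
                           tolerance_voxels = 0))
})

test_that("greedy placement follows candidate lists and resolves ties", {
  bank <- catm_bank(40)
  mk <- function(x, y, z, orient, ccc)
    data.frame(orient = orient, ccc = ccc, x = x, y = y, z = z)
  # two far-apart particles: everyone gets their top candidate
  lists <- list(`1` = mk(10, 10, 10, 1, 0.9),
                `2` = mk(40, 40, 40, 1, 0.8))
  out <- greedy_place(lists, bank)
  expect_equal(nrow(out$placed), 2L)
  expect_equal(sort(out$placed$score), c(0.8, 0.9))
  # top candidate clashes with a stronger particle; 2nd does not
  o_face <- which.max(abs(quat_normal(bank$grid$quats)[, 3]))
  lists <- list(
    `1` = mk(20, 20, 20, o_face, 0.9),
    `2` = rbind(mk(20, 20, 23, o_face, 0.85),    # clashes with 1
                mk(20, 20, 27, o_face, 0.6)))    # clear
  out <- greedy_place(lists, bank)
  expect_equal(nrow(out$placed), 2L)
  expect_equal(out$placed$score[out$placed$id == 2], 0.6)
  # equal CCC: processing order breaks ties by particle id
  lists <- list(`2` = mk(10, 10, 10, 1, 0.7),
                `1` = mk(10.5, 10, 10, 1, 0.7))
  out <- greedy_place(lists, bank)
  expect_equal(out$placed$id[1], 1L)
})

test_that("pairwise resolution finds the compatible pair or drops one", {
  bank <- catm_bank(40)
  o_face <- which.max(abs(quat_normal(bank$grid$quats)[, 3]))
  o_side <- which.min(abs(quat_normal(bank$grid$quats)[, 3]))
  mk <- function(x, y, z, orient, ccc)
    data.frame(orient = orient, ccc = ccc, x = x, y = y, z = z)
  # stacked scenario: centres 6 nm apart along z.  Side-on discs span
  # their 11 nm diameter along z and clash; face-on discs stack with a
  # small gap and are compatible.
  p <- rbind(mk(20, 20, 26, o_side, 0.8), mk(20, 20, 26, o_face, 0.7))
  q <- rbind(mk(20, 20, 20, o_side, 0.9), mk(20, 20, 20, o_face, 0.75))
  res <- resolve_pairwise(p, q, occupancy = list(), bank)
  expect_false(is.null(res))
  expect_equal(res$p$orient, o_face)
  expect_equal(res$q$orient, o_face)
  expect_equal(res$ccc_sum, 0.7 + 0.75)
  # all combinations clash: no resolution
  p2 <- mk(20, 20, 23, o_face, 0.8)
  q2 <- mk(20, 20, 20, o_face, 0.9)
  expect_null(resolve_pairwise(p2, q2, list(), bank))
  # a pair otherwise compatible is vetoed by third-party occupancy
  occ <- list(catmtools:::placed_keys(
    bank$entries[[o_face]]$offsets, c(20, 20, 29), 1))
  res3 <- resolve_pairwise(p, q, occ, bank)
  # p's face-on candidate at z=26 clashes with the occupant at z=29
  expect_true(is.null(res3) || res3$p$orient != o_face)
})

test_that("greedy + pairwise placement matches the enumeration oracle", {
  # stacked-pair fixture: candidates force a clash at the top combination
  model <- imaging_model(snr = 1)
  ps <- micro_particles(c(24, 24), c(24, 24), c(21, 27))
  tomo <- micro_tomogram(ps, box = 48, snr = 2, seed = 7, model = model)
  grid <- rotation_grid(25)
  cfg <- catm_config()
  pred <- run_catm(tomo, default_disc(),
                   cbind(c(24.5, 23.6), c(24, 24.2), c(21.4, 26.8)),
                   model = model, config = cfg, grid = grid)
  expect_equal(nrow(pred), 2L)
  # no clashing pair in the output
  mask <- build_steric_mask(default_disc())
  q <- ps_quats(pred)
  tol <- floor(cfg$catm$clash_fraction * sum(mask$data))
  expect_false(clash_check(c(pred$x[1], pred$y[1], pred$z[1]), q[1, ],
                           c(pred$x[2], pred$y[2], pred$z[2]), q[2, ],
                           mask, tolerance_voxels = tol))
})

test_that("run_catm with no centroids returns an empty set", {
  tomo <- volume(array(rnorm(32^3), rep(32, 3)))
  out <- run_catm(tomo, default_disc(), matrix(numeric(0), 0, 3))
  expect_equal(nrow(out), 0L)
  expect_equal(nrow(attr(out, "rejected")), 0L)
})

test_that("run_catm output poses come from the candidate lists", {
  model <- imaging_model(snr = 1)
  ps <- micro_particles(c(16, 32), c(16, 32), c(24, 24),
                        rot = c(10, 250), tilt = c(30, 75))
  tomo <- micro_tomogram(ps, box = 48, snr = 3, model = model)
  grid <- rotation_grid(25)
  cfg <- catm_config()
  pred <- run_catm(tomo, default_disc(), ps_positions(ps),
                   model = model, config = cfg, grid = grid)
  oi <- attr(pred, "orient_index")
  expect_true(all(oi %in% seq_len(nrow(grid$quats))))
  # orientations are exactly grid orientations
  for (i in seq_len(nrow(pred))) {
    q1 <- quat_from_euler(pred$rot[i], pred$tilt[i], pred$psi[i])
    expect_lt(quat_geodesic(q1, grid$quats[oi[i], , drop = FALSE]), 1e-6)
  }
})

test_that("merge_assignments removes overlaid refined particles and
           restores missing primary ones", {
  mask <- build_steric_mask(default_disc())
  primary <- micro_particles(c(10, 30, 50), c(10, 30, 50), c(10, 30, 50))
  # refined: first two collapsed onto nearly one position, third missing
  refined <- micro_particles(c(10, 10.5), c(10, 10.4), c(10, 10.3))
  out <- merge_assignments(primary, refined, mask,
                           collapse_radius = 2, match_radius = 5.5)
  log <- attr(out, "merge_log")
  expect_equal(log$overlaid_removed, 1L)
  expect_equal(log$restored_from_primary, 2L)
  expect_equal(nrow(out), 3L)
  # identical sets pass through unchanged
  same <- merge_assignments(primary, primary, mask)
  expect_equal(nrow(same), nrow(primary))
  expect_equal(attr(same, "merge_log")$overlaid_removed, 0L)
  # frame mismatch errors
  a <- primary; attr(a, "frame") <- "tomo1"
  b <- primary; attr(b, "frame") <- "tomo2"
  expect_error(merge_assignments(a, b, mask), "frame mismatch")
})
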