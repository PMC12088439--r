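# Ground-truth sampling, rendering, and benchmark composition.

test_that("single particle in a large box is accepted with any seed", {
  for (seed in 1:3) {
    gt <- sample_particle_configuration(60, 1, 0, seed = seed)
    expect_equal(nrow(gt), 1L)
  }
})

test_that("orientation marginal of sampled configurations is sinusoidal", {
  # pool disc-normal angles over many small configurations
  ang <- unlist(lapply(1:40, function(s) {
    gt <- sample_particle_configuration(50, 4, 0, seed = s)
    angle_to_axis(ps_quats(gt))
  }))
  ks <- stats::ks.test(ang * pi / 180, function(t) 1 - cos(t))
  expect_gt(ks$p.value, 0.01)
})

test_that("infeasible density errors out", {
  expect_error(
    sample_particle_configuration(20, 3, 0, seed = 1, max_attempts = 200),
    "density infeasible")
})

test_that("sampled configurations have no steric overlap", {
  gt <- sample_particle_configuration(48, 8, 4, seed = 5)
  offs <- attr(gt, "mask_offsets")
  P <- ps_positions(gt)
  for (i in seq_len(nrow(gt) - 1)) {
    for (j in (i + 1):nrow(gt)) {
      ki <- catmtools:::placed_keys(offs[[i]], P[i, ], 1)
      kj <- catmtools:::placed_keys(offs[[j]], P[j, ], 1)
      expect_equal(catmtools:::overlap_count(ki, kj), 0)
    }
  }
})

test_that("rendering is linear and conserves per-particle density", {
  tmpl <- list(nucleosome = default_disc())
  empty <- render_volume(particle_set(), tmpl, rep(32, 3), 1)
  expect_true(all(empty$data == 0))
  # single particle at the grid centre, identity orientation
  ps <- micro_particles(15, 15, 15)
  one <- render_volume(ps, tmpl, rep(31, 3), 1)
  t0 <- default_disc()
  d <- dim(t0$data)[1]
  sub <- one$data[16 - 7 + seq_len(d) - 1, 16 - 7 + seq_len(d) - 1,
                  16 - 7 + seq_len(d) - 1]
  rel_l2 <- sqrt(sum((sub - t0$data)^2) / sum(t0$data^2))
  expect_lt(rel_l2, 0.01)
  # two disjoint particles render as the exact sum of singles
  psa <- micro_particles(12, 12, 12, tilt = 40)
  psb <- micro_particles(36, 36, 36, rot = 30, tilt = 70)
  both <- micro_particles(c(12, 36), c(12, 36), c(12, 36),
                          rot = c(0, 30), tilt = c(40, 70))
  va <- render_volume(psa, tmpl, rep(48, 3), 1)
  vb <- render_volume(psb, tmpl, rep(48, 3), 1)
  vab <- render_volume(both, tmpl, rep(48, 3), 1)
  expect_equal(vab$data, va$data + vb$data, tolerance = 1e-12)
  # integrated density = n_particles * template sum within 1%
  expect_equal(sum(vab$data), 2 * sum(t0$data), tolerance = 0.01)
})

test_that("out-of-bounds particles error with the particle index", {
  tmpl <- list(nucleosome = default_disc())
  ps <- micro_particles(c(16, 2), c(16, 2), c(16, 2))
  expect_error(render_volume(ps, tmpl, rep(32, 3), 1), "particle 2")
})

test_that("benchmark generation is deterministic given the seed", {
  cfg <- catm_config()
  cfg$simulate$box_nm <- 48
  cfg$simulate$n_nucleosomes <- 6
  cfg$simulate$n_dna <- 3
  a <- generate_benchmark(cfg, seed = 4)
  b <- generate_benchmark(cfg, seed = 4)
  expect_identical(a$tomogram$data, b$tomogram$data)
  expect_identical(a$gt$x, b$gt$x)
  expect_equal(sum(a$gt$kind == "nucleosome"), 6)
  # snr = Inf, full tilt fan: tomogram equals the CTF-modulated render
  cfg$simulate$snr <- Inf
  cfg$simulate$tilt_min <- -90; cfg$simulate$tilt_max <- 90
  c1 <- generate_benchmark(cfg, seed = 4)
  expect_equal(c1$tomogram$data, apply_ctf(c1$clean, c1$model)$data,
               tolerance = 1e-8)
})
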