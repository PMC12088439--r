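# Interface geometry, contact graphs, entropy, assortativity, DBSCAN.

sphere_points <- function(n, center, radius, seed = 1) {
  set.seed(seed)
  u <- matrix(rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  sweep(u * radius, 2, center, `+`)
}

test_that("sphere fit is exact on exact data and robust to noise", {
  P <- sphere_points(100, c(0, 0, 0), 500)
  s <- fit_sphere(P)
  expect_equal(s$center, c(0, 0, 0), tolerance = 1e-6)
  expect_equal(s$radius, 500, tolerance = 1e-6)
  expect_lt(s$rms_residual, 1e-8)
  # sigma = 5 nm annotation noise, n = 500: radius within 1%
  set.seed(81)
  Pn <- sphere_points(500, c(100, -50, 20), 500, seed = 2) +
    matrix(rnorm(1500, sd = 5), 500, 3)
  sn <- fit_sphere(Pn)
  expect_lt(abs(sn$radius - 500) / 500, 0.01)
  expect_lt(sqrt(sum((sn$center - c(100, -50, 20))^2)), 10)
})

test_that("sphere-fit radius recovery at 1% noise is unbiased within 1%", {
  set.seed(82)
  r_hat <- vapply(1:10, function(i) {
    P <- sphere_points(500, c(0, 0, 0), 200, seed = 100 + i) +
      matrix(rnorm(1500, sd = 2), 500, 3)
    fit_sphere(P)$radius
  }, 0)
  expect_lt(abs(mean(r_hat) - 200) / 200, 0.01)
})

test_that("degenerate sphere inputs error", {
  expect_error(fit_sphere(matrix(rnorm(9), 3, 3)), "underdetermined")
  coplanar <- cbind(runif(10), runif(10), 1)
  expect_error(fit_sphere(coplanar), "underdetermined")
})

test_that("surface distance and normal follow the sign convention", {
  s <- structure(list(center = c(0, 0, 0), radius = 100,
                      rms_residual = 0), class = "sphere_surface")
  out <- surface_distance_and_normal(c(100, 0, 0), s)
  expect_equal(out$distance, 0)
  expect_equal(out$normal[1, ], c(1, 0, 0))
  out2 <- surface_distance_and_normal(c(0, 0, 50), s)
  expect_equal(out2$distance, 50)
  expect_equal(out2$normal[1, ], c(0, 0, 1))
  # exterior points have negative distance
  expect_lt(surface_distance_and_normal(c(0, 150, 0), s)$distance, 0)
  expect_error(surface_distance_and_normal(c(0, 0, 0), s), "undefined")
})

test_that("plane fit recovers a tilted interface", {
  set.seed(83)
  xy <- matrix(runif(600, -50, 50), 300, 2)
  z <- 0.2 * xy[, 1] - 0.1 * xy[, 2] + 5 + rnorm(300, sd = 0.5)
  pl <- fit_plane(cbind(xy, z))
  true_n <- c(-0.2, 0.1, 1); true_n <- true_n / sqrt(sum(true_n^2))
  expect_gt(abs(sum(pl$normal * true_n)), 0.999)
  d <- plane_distance_and_normal(cbind(0, 0, 5), pl)
  expect_lt(abs(d$distance), 0.5)
  expect_error(fit_plane(cbind(1:5, 2 * (1:5), 3 * (1:5))),
               "underdetermined")
})

test_that("contact graph edges follow the steric criterion", {
  mask <- build_steric_mask(default_disc())
  # coaxial stacked discs at 6 nm centre distance: small surface gap
  ps <- micro_particles(c(20, 20, 50), c(20, 20, 20), c(20, 26, 20))
  g <- build_contact_graph(ps, mask, gap_threshold = 1)
  expect_equal(igraph::ecount(g), 1L)
  expect_true(igraph::are_adjacent(g, 1, 2))
  # symmetric adjacency
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  expect_equal(A, t(A))
})

test_that("interior lattice nodes have the lattice coordination number", {
  # 3x3x3 cubic lattice of face-on discs below the centre threshold
  sp <- 11.5
  g3 <- expand.grid(x = 0:2, y = 0:2, z = 0:2) * sp
  ps <- micro_particles(g3$x, g3$y, g3$z)
  g <- build_contact_graph(ps, criterion = "center",
                           center_threshold = 12)
  deg <- igraph::degree(g)
  interior <- which(g3$x == sp & g3$y == sp & g3$z == sp)
  expect_equal(unname(deg[interior]), 6)
  corner <- which(g3$x == 0 & g3$y == 0 & g3$z == 0)
  expect_equal(unname(deg[corner]), 3)
})

test_that("valence distribution basics", {
  g0 <- igraph::make_empty_graph(4, directed = FALSE)
  vd <- valence_distribution(g0)
  expect_equal(vd$p[vd$valence == 0], 1)
  tri <- igraph::make_ring(3)
  expect_equal(valence_distribution(tri)$p, c(0, 0, 1))
  path3 <- igraph::make_graph(c(1, 2, 2, 3), directed = FALSE)
  vdp <- valence_distribution(path3)
  expect_equal(vdp$p, c(0, 2 / 3, 1 / 3))
})

test_that("normalized entropy endpoints and closed-form case", {
  expect_equal(normalized_entropy(rep(1 / 5, 5)), 1)
  expect_equal(normalized_entropy(c(0, 1, 0)), 0)
  expect_equal(normalized_entropy(c(0.75, 0.25)),
               -(0.75 * log(0.75) + 0.25 * log(0.25)) / log(2),
               tolerance = 1e-12)
  expect_equal(normalized_entropy(c(0.75, 0.25)), 0.8113, tolerance = 1e-4)
  # in [0, 1] for random distributions; 1 iff uniform
  set.seed(84)
  for (i in 1:20) {
    p <- runif(sample(2:6, 1)); p <- p / sum(p)
    h <- normalized_entropy(p)
    expect_gte(h, 0); expect_lte(h, 1)
    if (max(abs(p - 1 / length(p))) > 1e-3) expect_lt(h, 1)
  }
  expect_error(normalized_entropy(c(0.5, 0.4)), "invalid")
})

test_that("assortativity: cliques, bipartite closed form, shuffling", {
  # two disconnected monochromatic cliques -> +1
  g <- igraph::disjoint_union(igraph::make_full_graph(4),
                              igraph::make_full_graph(4))
  lab <- rep(c("a", "b"), each = 4)
  expect_equal(assortativity_classes(g, lab), 1)
  # complete bipartite: mixing matrix has zero trace, a = b = 1/2,
  # r = (0 - 1/2) / (1 - 1/2) = -1 by hand
  gb <- igraph::make_full_bipartite_graph(3, 4)
  labb <- c(rep("a", 3), rep("b", 4))
  expect_equal(assortativity_classes(gb, labb), -1)
  # random labels on a large graph: coefficient near 0
  set.seed(85)
  ge <- igraph::sample_gnp(400, 0.02)
  labr <- sample(c("a", "b"), 400, TRUE)
  expect_lt(abs(assortativity_classes(ge, labr)), 0.1)
  expect_warning(r1 <- assortativity_classes(ge, rep("a", 400)),
                 "single class")
  expect_true(is.nan(r1))
})

test_that("DBSCAN matches the brute-force oracle and labels basics", {
  set.seed(86)
  # two tight blobs of 50 points each, far apart: 2 clusters, no noise
  P <- rbind(matrix(rnorm(150, sd = 3), 50, 3),
             matrix(rnorm(150, sd = 3), 50, 3) + 100)
  lab <- dbscan_clusters(P, eps = 12, min_pts = 3)
  expect_equal(length(unique(lab[lab > 0])), 2L)
  expect_true(all(lab > 0))
  # sparse points with demanding min_pts: all noise
  Ps <- matrix(runif(60, 0, 500), 20, 3)
  expect_true(all(dbscan_clusters(Ps, eps = 10, min_pts = 10) == 0))
  # random mixed fixture agrees with an independent implementation
  Pm <- rbind(matrix(rnorm(90, sd = 4), 30, 3),
              matrix(rnorm(90, sd = 4), 30, 3) + 60,
              matrix(runif(60, -100, 160), 20, 3))
  for (eps in c(8, 15)) {
    a <- dbscan_clusters(Pm, eps = eps, min_pts = 4)
    b <- oracle_dbscan(Pm, eps = eps, min_pts = 4)
    expect_true(same_partition(a, b))
  }
  # invariance to input permutation up to relabelling
  perm <- sample(nrow(Pm))
  a <- dbscan_clusters(Pm, 12, 4)
  b <- dbscan_clusters(Pm[perm, ], 12, 4)
  expect_true(same_partition(a[perm], b))
})

test_that("cluster size distribution and depth profile contracts", {
  labels <- c(rep(1, 4), rep(2, 4), rep(3, 20), 0, 0)
  csd <- cluster_size_distribution(labels)
  expect_equal(csd$size, c(4, 20))
  expect_equal(csd$cum_fraction, c(2 / 3, 1))
  expect_warning(e <- cluster_size_distribution(rep(0, 5)), "no clusters")
  expect_equal(nrow(e), 0L)
  # all-clustered particles give fraction 1 in every occupied bin
  s <- structure(list(center = c(0, 0, 0), radius = 100,
                      rms_residual = 0), class = "sphere_surface")
  ps <- micro_particles(c(10, 20, 30, 80), 0, 0)
  prof <- cluster_fraction_vs_depth(ps, rep(1, 4), s, bin_width = 10,
                                    min_count = 1)
  expect_true(all(prof$fraction_clustered == 1))
  expect_true(all(prof$n > 0))
})

test_that("planted condensate statistics are recovered", {
  ps <- generate_condensate(radius_nm = 200, n_stacks = 12,
                            stack_size = 4, n_singles = 30, seed = 3)
  mask <- build_steric_mask(default_disc())
  an <- analyze_condensate(ps, mask, surface = attr(ps, "surface"))
  planted <- attr(ps, "planted_valence")
  # entropy of the planted valence distribution, recovered within 0.02
  expect_equal(an$entropy, normalized_entropy(planted),
               tolerance = 0.02 / normalized_entropy(planted))
  # planted cluster-size mode recovered exactly
  csd <- an$cluster_sizes
  expect_equal(csd$size[which.max(csd$count)], 4L)
  expect_equal(sum(an$labels > 0), 48)
  # interface shell holds fewer clustered particles than the deep bins
  prof <- an$depth_profile[an$depth_profile$reliable, ]
  shallow <- prof$fraction_clustered[prof$depth_lo < 30]
  deep <- prof$fraction_clustered[prof$depth_lo >= 60]
  expect_lt(max(shallow), min(deep))
})

test_that("perimeter annotations recover the condensate sphere", {
  s <- structure(list(center = c(10, -20, 5), radius = 250,
                      rms_residual = 0), class = "sphere_surface")
  pts <- sphere_perimeter_points(s, n_slices = 9, pts_per_slice = 40,
                                 sigma_nm = 2, seed = 4)
  fit <- fit_sphere(pts)
  expect_lt(abs(fit$radius - 250) / 250, 0.01)
  expect_lt(sqrt(sum((fit$center - s$center)^2)), 5)
})
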