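# Synthetic condensates with planted higher-order structure, used to
# validate the spatial-analysis stage end to end: face-to-face nucleosome
# stacks (planted clusters with a known size and a known valence
# distribution) deep in a spherical condensate, plus isolated nucleosomes
# in a shell near the interface.

#' Generate a condensate with planted clusters and known valences
#'
#' Plants `n_stacks` coaxial face-to-face stacks of `stack_size` discs
#' (consecutive discs in steric contact: valence 2 inside a stack, 1 at
#' its ends) at depths of at least `deep_min` nm from the interface, and
#' `n_singles` isolated discs (valence 0) within `shallow_max` nm of the
#' interface.  Groups are kept at least `min_separation` nm apart so no
#' accidental contacts or cluster merges arise.
#'
#' @param radius_nm condensate sphere radius (centre at the origin).
#' @param n_stacks,stack_size planted cluster count and size.
#' @param n_singles isolated nucleosome count.
#' @param spacing_nm centre spacing inside a stack (just above the disc
#'   height: touching faces).
#' @param deep_min,shallow_max depth bands (nm) for stacks and singles.
#' @param min_separation minimum distance between particles of different
#'   groups, nm.
#' @param seed integer seed.
#' @param max_attempts rejection-sampling cap per group.
#' @return A `particle_set` with attributes `surface` (the true
#'   `sphere_surface`), `planted_labels` (cluster id per particle, 0 =
#'   single), `planted_valence` (the planted valence distribution as a
#'   data.frame) and `stack_size`.
#' @export
generate_condensate <- function(radius_nm = 220, n_stacks = 30,
                                stack_size = 4, n_singles = 60,
                                spacing_nm = 5.7, deep_min = 60,
                                shallow_max = 30, min_separation = 16,
                                seed = 1L, max_attempts = 20000) {
  if (shallow_max >= deep_min)
    stop("need shallow_max < deep_min to separate the depth bands")
  old <- .Random.seed_safe(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  all_pos <- matrix(numeric(0), 0, 3)
  rows <- list()
  labels <- integer()
  rand_in_band <- function(dmin, dmax) {
    # uniform position with depth in [dmin, dmax] from the surface
    for (a in seq_len(max_attempts)) {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      r3 <- stats::runif(1)^(1 / 3) * radius_nm
      p <- u * r3
      d <- radius_nm - sqrt(sum(p^2))
      if (d >= dmin && d <= dmax) return(p)
    }
    stop("density infeasible: no position found in depth band")
  }
  try_place <- function(members) {
    if (nrow(all_pos) == 0L) return(TRUE)
    dmin <- min(sqrt(outer(rowSums(members^2), rowSums(all_pos^2), `+`) -
                       2 * members %*% t(all_pos)))
    dmin >= min_separation
  }
  gid <- 0L
  for (s in seq_len(n_stacks)) {
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      ctr <- rand_in_band(deep_min + spacing_nm * stack_size / 2,
                          radius_nm)
      ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
      t_off <- (seq_len(stack_size) - (stack_size + 1) / 2) * spacing_nm
      members <- t(vapply(t_off, function(t) ctr + t * ax, numeric(3)))
      if (all(radius_nm - sqrt(rowSums(members^2)) >= deep_min) &&
          try_place(members)) { ok <- TRUE; break }
    }
    if (!ok) stop("density infeasible: could not place stack ", s)
    gid <- gid + 1L
    q <- quat_from_normal(ax)
    eul <- quat_to_euler(q)
    for (m in seq_len(stack_size)) {
      rows[[length(rows) + 1L]] <-
        c(members[m, ], eul$rot, eul$tilt, eul$psi)
      labels <- c(labels, gid)
    }
    all_pos <- rbind(all_pos, members)
  }
  for (s in seq_len(n_singles)) {
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      p <- rand_in_band(6, shallow_max)
      if (try_place(rbind(p))) { ok <- TRUE; break }
    }
    if (!ok) stop("density infeasible: could not place single ", s)
    q <- quat_random(1)
    eul <- quat_to_euler(q)
    rows[[length(rows) + 1L]] <- c(p, eul$rot, eul$tilt, eul$psi)
    labels <- c(labels, 0L)
    all_pos <- rbind(all_pos, p)
  }
  M <- do.call(rbind, rows)
  ps <- particle_set(x = M[, 1], y = M[, 2], z = M[, 3], rot = M[, 4],
                     tilt = M[, 5], psi = M[, 6])
  n_tot <- nrow(ps)
  pv <- data.frame(
    valence = 0:2,
    p = c(n_singles,
          2 * n_stacks,
          max(0, stack_size - 2) * n_stacks) / n_tot)
  attr(ps, "surface") <- structure(
    list(center = c(0, 0, 0), radius = radius_nm, rms_residual = 0),
    class = "sphere_surface")
  attr(ps, "planted_labels") <- labels
  attr(ps, "planted_valence") <- pv
  attr(ps, "stack_size") <- stack_size
  ps
}

#' Noisy perimeter annotations of a spherical interface
#'
#' Emulates manually delineated condensate perimeters on tomographic
#' slices: circles of the sphere cross-section at several z heights,
#' perturbed with isotropic Gaussian noise.
#'
#' @param surface a `sphere_surface`.
#' @param n_slices number of z slices.
#' @param pts_per_slice points per slice.
#' @param sigma_nm annotation noise, nm.
#' @param z_fraction slices span this central fraction of the diameter.
#' @param seed integer seed.
#' @return n x 3 matrix of points, nm.
#' @export
sphere_perimeter_points <- function(surface, n_slices = 9,
                                    pts_per_slice = 40, sigma_nm = 2,
                                    z_fraction = 0.8, seed = 1L) {
  old <- .Random.seed_safe(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  zs <- surface$center[3] +
    seq(-z_fraction, z_fraction, length.out = n_slices) * surface$radius
  out <- NULL
  for (z in zs) {
    rho <- sqrt(max(0, surface$radius^2 - (z - surface$center[3])^2))
    th <- stats::runif(pts_per_slice, 0, 2 * pi)
    pts <- cbind(surface$center[1] + rho * cos(th),
                 surface$center[2] + rho * sin(th), z)
    out <- rbind(out, pts + matrix(stats::rnorm(length(pts), sd = sigma_nm),
                                   nrow(pts), 3))
  }
  out
}

#' Full spatial analysis of a condensate particle set
#'
#' Fits the interface sphere (unless one is supplied), builds the contact
#' graph, computes the valence distribution and its normalized entropy,
#' DBSCAN clusters with size distribution and depth profile, the
#' angle-to-interface distribution, and (when class labels are present)
#' the attribute assortativity.
#'
#' @param particles a `particle_set`.
#' @param mask steric mask `tomo_volume` for the contact criterion.
#' @param surface optional `sphere_surface`; otherwise fitted from
#'   `perimeter_points`.
#' @param perimeter_points optional n x 3 interface annotations, nm.
#' @param config configuration list (see [catm_config()]), `analysis`
#'   section.
#' @return list: `surface`, `graph`, `valence`, `entropy`, `labels`,
#'   `cluster_sizes`, `depth_profile`, `interface_angles`,
#'   `assortativity`.
#' @export
analyze_condensate <- function(particles, mask, surface = NULL,
                               perimeter_points = NULL,
                               config = catm_config()) {
  ac <- config$analysis
  if (is.null(surface)) {
    if (is.null(perimeter_points))
      stop("supply either a surface or perimeter_points")
    surface <- fit_sphere(perimeter_points)
  }
  g <- build_contact_graph(particles, mask,
                           criterion = ac$contact_criterion,
                           gap_threshold = ac$gap_threshold,
                           center_threshold = ac$center_threshold)
  vd <- valence_distribution(g)
  ent <- normalized_entropy(vd, support = ac$entropy_support)
  labels <- dbscan_clusters(particles, eps = ac$dbscan_eps,
                            min_pts = ac$dbscan_minpts)
  csd <- if (any(labels > 0)) cluster_size_distribution(labels)
         else suppressWarnings(cluster_size_distribution(labels))
  prof <- cluster_fraction_vs_depth(particles, labels, surface,
                                    bin_width = ac$depth_bin)
  sdn <- surface_distance_and_normal(ps_positions(particles), surface)
  ia <- angle_to_interface(ps_quats(particles), sdn$normal)
  asc <- if (!all(is.na(particles$class_label)) &&
             length(unique(particles$class_label)) > 1L)
    assortativity_classes(g, as.character(particles$class_label))
  else NA_real_
  list(surface = surface, graph = g, valence = vd, entropy = ent,
       labels = labels, cluster_sizes = csd, depth_profile = prof,
       interface_angles = ia, assortativity = asc)
}
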