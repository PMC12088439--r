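# Condensate-interface geometry and higher-order organization statistics:
# least-squares sphere (and plane) fits of annotated interfaces, signed
# surface distances and normals, steric contact graphs with valence
# distribution / normalized entropy / attribute assortativity, DBSCAN
# clustering and depth-resolved cluster occupancy.

#' Least-squares sphere fit
#'
#' Algebraic (Coope) fit followed by Gauss-Newton refinement of the
#' geometric residuals `|p - c| - r`.
#'
#' @param points n x 3 matrix of surface points, nm (n >= 4,
#'   non-coplanar).
#' @return list (`sphere_surface`): `center`, `radius`, `rms_residual`.
#' @export
fit_sphere <- function(points) {
  P <- rbind(points)
  if (nrow(P) < 4) stop("sphere underdetermined: need >= 4 points")
  A <- cbind(2 * P, 1)
  b <- rowSums(P^2)
  qr_ <- qr(A)
  if (qr_$rank < 4) stop("sphere underdetermined: points are coplanar")
  sol <- qr.coef(qr_, b)
  ctr <- sol[1:3]
  r <- sqrt(sol[4] + sum(ctr^2))
  for (it in 1:25) {                       # Gauss-Newton on |p-c| - r
    dvec <- sqrt(colSums((t(P) - ctr)^2))
    res <- dvec - r
    J <- cbind(-sweep(P, 2, ctr) / dvec, -1)
    step <- tryCatch(qr.coef(qr(J), -res), error = function(e) rep(0, 4))
    if (any(!is.finite(step))) break
    ctr <- ctr + step[1:3]; r <- r + step[4]
    if (sqrt(sum(step^2)) < 1e-10 * max(1, r)) break
  }
  dvec <- sqrt(colSums((t(P) - ctr)^2))
  structure(list(center = unname(ctr), radius = unname(r),
                 rms_residual = sqrt(mean((dvec - r)^2))),
            class = "sphere_surface")
}

#' Signed distance to a sphere surface and outward normal
#'
#' Distance is positive inside the sphere, negative outside; the normal
#' is the outward radial unit vector at the nearest surface point.
#'
#' @param p position(s), nm: length-3 vector or n x 3 matrix.
#' @param s a `sphere_surface` from [fit_sphere()].
#' @return list: `distance` (nm), `normal` (n x 3).
#' @export
surface_distance_and_normal <- function(p, s) {
  P <- rbind(p)
  rel <- unname(sweep(P, 2, s$center))
  d <- unname(sqrt(rowSums(rel^2)))
  if (any(d < 1e-12))
    stop("normal undefined at the sphere centre")
  list(distance = s$radius - d, normal = rel / d)
}

#' Least-squares plane fit
#'
#' Total-least-squares plane through a point cloud (smallest principal
#' component), for flat interfaces such as the air-water interface of a
#' blotted sample.
#'
#' @param points n x 3 matrix, nm (n >= 3, not collinear).
#' @return list (`plane_surface`): `point` (centroid), `normal` (unit),
#'   `rms_residual`.
#' @export
fit_plane <- function(points) {
  P <- rbind(points)
  if (nrow(P) < 3) stop("plane underdetermined: need >= 3 points")
  ctr <- colMeans(P)
  sv <- svd(sweep(P, 2, ctr))
  if (sv$d[2] < 1e-10 * max(sv$d))
    stop("plane underdetermined: points are collinear")
  nrm <- sv$v[, 3]
  res <- as.numeric(sweep(P, 2, ctr) %*% nrm)
  structure(list(point = ctr, normal = nrm,
                 rms_residual = sqrt(mean(res^2))),
            class = "plane_surface")
}

#' Signed distance to a fitted plane and its normal
#' @param p position(s), nm.
#' @param s a `plane_surface` from [fit_plane()].
#' @return list: `distance` (signed, along the normal), `normal` (n x 3).
#' @export
plane_distance_and_normal <- function(p, s) {
  P <- rbind(p)
  d <- unname(as.numeric(sweep(P, 2, s$point) %*% s$normal))
  list(distance = d,
       normal = matrix(s$normal, nrow(P), 3, byrow = TRUE))
}

# ---- contact graph ---------------------------------------------------------

# Boundary voxels of a mask offset set (those with < 6 face neighbours in
# the set) -- enough for surface-gap distances.
boundary_offsets <- function(off) {
  keys <- voxel_keys(off)
  nb <- 0L
  for (d in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))) {
    nb <- nb + (voxel_keys(sweep(off, 2, d, `+`)) %in% keys)
  }
  off[nb < 6L, , drop = FALSE]
}

#' Build the steric contact graph of a particle set
#'
#' Edge (i, j) when the particles' steric-mask surfaces approach within
#' `gap_threshold` nm (`criterion = "steric"`), or when centre distance is
#' at most `center_threshold` nm (`criterion = "center"`).  The criterion
#' used is recorded in the graph attributes.
#'
#' @param particles a `particle_set`.
#' @param mask steric mask `tomo_volume` (steric criterion).
#' @param criterion `"steric"` or `"center"`.
#' @param gap_threshold nm surface gap for the steric criterion.
#' @param center_threshold nm for the centre-distance criterion.
#' @return An igraph graph; vertex attribute `class` carries
#'   `class_label` when present.
#' @export
build_contact_graph <- function(particles, mask = NULL,
                                criterion = c("steric", "center"),
                                gap_threshold = 1, center_threshold = 12) {
  criterion <- match.arg(criterion)
  n <- nrow(particles)
  if (n == 0L) stop("empty particle set")
  P <- ps_positions(particles)
  edges <- NULL
  if (criterion == "center") {
    for (i in seq_len(n - 1)) {
      d <- sqrt(colSums((t(P[(i + 1):n, , drop = FALSE]) - P[i, ])^2))
      j <- which(d <= center_threshold)
      if (length(j)) edges <- rbind(edges, cbind(i, i + j))
    }
  } else {
    if (is.null(mask)) stop("steric criterion requires a mask")
    vs <- mask$voxel_size
    q <- ps_quats(particles)
    boffs <- lapply(seq_len(n), function(i)
      boundary_offsets(rotated_mask_offsets(mask, q[i, ])) * vs)
    reach <- max(sqrt(rowSums(mask_offsets(mask)^2))) * vs + vs
    # surfaces within d - 2*reach can never touch; d <= gap always touch
    for (i in seq_len(n - 1)) {
      d <- sqrt(colSums((t(P[(i + 1):n, , drop = FALSE]) - P[i, ])^2))
      for (j in which(d <= 2 * reach + gap_threshold)) {
        jj <- i + j
        A <- sweep(boffs[[i]], 2, P[i, ], `+`)
        B <- sweep(boffs[[jj]], 2, P[jj, ], `+`)
        mind <- sqrt(min(outer(rowSums(A^2), rowSums(B^2), `+`) -
                           2 * A %*% t(B)))
        # voxelization halves: allow one voxel diagonal of slack
        if (mind <= gap_threshold + sqrt(3) * vs)
          edges <- rbind(edges, cbind(i, jj))
      }
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (!is.null(edges))
    g <- igraph::add_edges(g, as.vector(t(edges)))
  g <- igraph::simplify(g)
  igraph::V(g)$name <- as.character(particles$id)
  if (!all(is.na(particles$class_label)))
    igraph::V(g)$class <- as.character(particles$class_label)
  g$criterion <- criterion
  g$threshold <- if (criterion == "steric") gap_threshold
                 else center_threshold
  g
}

#' Valence (degree) distribution of a contact graph
#'
#' @param g an igraph graph.
#' @return data.frame with `valence` (0..max) and `p` (fractions summing
#'   to 1).
#' @export
valence_distribution <- function(g) {
  deg <- igraph::degree(g)
  kmax <- max(deg, 0)
  counts <- tabulate(deg + 1L, nbins = kmax + 1L)
  data.frame(valence = 0:kmax, p = counts / sum(counts))
}

#' Normalized Shannon entropy of a valence distribution
#'
#' Entropy divided by `log(K)`: 1 for a uniform distribution over the K
#' valence categories, 0 when a single valence is populated.  By default
#' K spans the contiguous support 0..max observed valence;
#' `support = "observed"` counts only populated categories.
#'
#' @param dist data.frame from [valence_distribution()] (or a numeric
#'   vector of probabilities).
#' @param support `"contiguous"` (default) or `"observed"`.
#' @return Normalized entropy in [0, 1].
#' @export
normalized_entropy <- function(dist, support = c("contiguous", "observed")) {
  support <- match.arg(support)
  p <- if (is.data.frame(dist)) dist$p else as.numeric(dist)
  if (!length(p) || any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("invalid distribution")
  K <- if (support == "contiguous") length(p) else sum(p > 0)
  if (K <= 1) return(0)
  pz <- p[p > 0]
  H <- -sum(pz * log(pz))
  H / log(K)
}

#' Attribute assortativity of a labelled contact graph
#'
#' Standard categorical assortativity (trace of the edge mixing matrix
#' against its random expectation), in [-1, 1]; +1 for purely
#' within-class edges.  With a single class present the coefficient is
#' undefined and NaN is returned with a warning.
#'
#' @param g an igraph graph with a `class` vertex attribute (or supply
#'   `labels`).
#' @param labels optional per-vertex class labels.
#' @return Assortativity coefficient.
#' @export
assortativity_classes <- function(g, labels = NULL) {
  if (is.null(labels)) labels <- igraph::V(g)$class
  if (is.null(labels) || any(is.na(labels)))
    stop("every node must be labelled")
  if (length(unique(labels)) < 2L) {
    warning("single class present: assortativity undefined")
    return(NaN)
  }
  igraph::assortativity_nominal(g, as.integer(factor(labels)))
}

# ---- clustering ------------------------------------------------------------

#' DBSCAN clustering of particle centres
#'
#' Classical DBSCAN on 3D positions: core points have at least `min_pts`
#' neighbours (including themselves) within `eps`; clusters are the
#' connected components of core points plus their border points;
#' remaining points are noise (label 0).
#'
#' @param particles a `particle_set` or n x 3 position matrix (nm).
#' @param eps neighbourhood radius, nm.
#' @param min_pts minimum neighbourhood size for a core point.
#' @return Integer cluster labels (0 = noise), in input order.
#' @export
dbscan_clusters <- function(particles, eps = 12, min_pts = 3) {
  if (eps <= 0) stop("eps must be positive")
  if (min_pts < 1) stop("min_pts must be >= 1")
  P <- if (is.data.frame(particles)) ps_positions(particles)
       else rbind(particles)
  n <- nrow(P)
  if (n == 0L) return(integer())
  D <- as.matrix(stats::dist(P))
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(nb, length, 0L) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nb[[i]]
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) queue <- c(queue, nb[[j]][labels[nb[[j]]] == 0L])
      }
    }
  }
  labels
}

#' Cumulative distribution of cluster sizes
#'
#' @param labels integer labels from [dbscan_clusters()] (0 = noise).
#' @return data.frame `size`, `count`, `cum_fraction` (cumulative fraction
#'   of clusters with size <= `size`); zero rows with a warning when
#'   there are no clusters.
#' @export
cluster_size_distribution <- function(labels) {
  sizes <- table(labels[labels > 0])
  if (!length(sizes)) {
    warning("no clusters")
    return(data.frame(size = integer(), count = integer(),
                      cum_fraction = numeric()))
  }
  tab <- table(as.integer(sizes))
  size <- as.integer(names(tab))
  data.frame(size = size, count = as.integer(tab),
             cum_fraction = cumsum(as.integer(tab)) / sum(tab))
}

#' Fraction of clustered particles versus depth from the interface
#'
#' Bins particles by distance from the condensate surface and reports the
#' fraction carrying a non-noise cluster label per bin.  Bins with fewer
#' than `min_count` particles are flagged (`reliable = FALSE`), not
#' reported as 0/0.
#'
#' @param particles a `particle_set`.
#' @param labels cluster labels from [dbscan_clusters()].
#' @param surface a `sphere_surface`.
#' @param bin_width depth bin width, nm.
#' @param min_count minimum particles for a reliable bin.
#' @return data.frame: `depth_lo`, `depth_hi`, `n`, `fraction_clustered`,
#'   `reliable`.
#' @export
cluster_fraction_vs_depth <- function(particles, labels, surface,
                                      bin_width = 10, min_count = 5) {
  sd_ <- surface_distance_and_normal(ps_positions(particles), surface)
  depth <- sd_$distance
  lo <- floor(min(depth) / bin_width) * bin_width
  breaks <- seq(lo, max(depth) + bin_width, by = bin_width)
  bin <- cut(depth, breaks, include.lowest = TRUE, right = FALSE)
  out <- do.call(rbind, lapply(levels(bin), function(b) {
    sel <- which(bin == b)
    i <- match(b, levels(bin))
    data.frame(depth_lo = breaks[i], depth_hi = breaks[i + 1],
               n = length(sel),
               fraction_clustered = if (length(sel))
                 mean(labels[sel] > 0) else NA_real_,
               reliable = length(sel) >= min_count)
  }))
  out[out$n > 0, , drop = FALSE]
}

#' Export a contact graph as GraphML and edge-list CSV
#'
#' @param g an igraph graph.
#' @param path_graphml,path_csv output paths (NULL to skip either).
#' @return Invisibly, NULL.
#' @export
write_contact_graph <- function(g, path_graphml = NULL, path_csv = NULL) {
  if (!is.null(path_graphml))
    igraph::write_graph(g, path_graphml, format = "graphml")
  if (!is.null(path_csv)) {
    el <- igraph::as_edgelist(g)
    utils::write.csv(data.frame(from = el[, 1], to = el[, 2]),
                     path_csv, row.names = FALSE)
  }
  invisible(NULL)
}
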