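# Scoring of predicted particle sets against ground truth: optimal
# one-to-one matching within a distance (and optionally angular)
# tolerance, precision/recall/F1, and the orientation-distribution
# diagnostic against the sinusoidal reference of uniformly random
# orientations.

#' Match predictions to ground truth (optimal one-to-one assignment)
#'
#' Builds the bipartite graph of (gt, pred) pairs within `dist_tol` nm
#' (and, when `ang_tol` is given, within the symmetry-reduced angular
#' tolerance of the disc normals) and extracts a maximum-cardinality
#' matching minimizing total distance (maximum-weight bipartite matching
#' with a cardinality-dominant weight offset).
#'
#' @param gt,pred `particle_set`s in the same coordinate frame.
#' @param dist_tol distance tolerance, nm.
#' @param ang_tol angular tolerance in degrees (antipodal-reduced disc
#'   normal angle), or NULL for position-only matching.
#' @return A `match_result` list: `tp`, `fp`, `fn` counts and `pairs`
#'   data.frame (gt_id, pred_id, distance, angular_error).
#' @export
match_particles <- function(gt, pred, dist_tol = 5.5, ang_tol = NULL) {
  if (dist_tol <= 0) stop("dist_tol must be positive")
  ng <- nrow(gt); np <- nrow(pred)
  empty <- data.frame(gt_id = integer(), pred_id = integer(),
                      distance = numeric(), angular_error = numeric())
  if (ng == 0L || np == 0L)
    return(structure(list(tp = 0L, fp = np, fn = ng, pairs = empty),
                     class = "match_result"))
  pg <- ps_positions(gt); pp <- ps_positions(pred)
  qg <- ps_quats(gt); qp <- ps_quats(pred)
  ngp <- quat_normal(qg); npp <- quat_normal(qp)
  edges <- NULL
  for (i in seq_len(ng)) {
    d <- sqrt(colSums((t(pp) - pg[i, ])^2))
    cand <- which(d <= dist_tol)
    if (!length(cand)) next
    ang <- acos(pmin(1, abs(npp[cand, , drop = FALSE] %*% ngp[i, ]))) *
      180 / pi
    if (!is.null(ang_tol)) {
      ok <- ang <= ang_tol
      cand <- cand[ok]; ang <- ang[ok]
    }
    if (length(cand))
      edges <- rbind(edges, cbind(i, cand, d[cand], ang))
  }
  if (is.null(edges) || nrow(edges) == 0L)
    return(structure(list(tp = 0L, fp = np, fn = ng, pairs = empty),
                     class = "match_result"))
  # cardinality-dominant weights: C > n * dist_tol
  C <- (min(ng, np) + 1) * dist_tol
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, ng), rep(TRUE, np)),
    edges = as.vector(t(cbind(edges[, 1], ng + edges[, 2]))))
  mm <- igraph::max_bipartite_match(
    g, weights = C + (dist_tol - edges[, 3]))
  mate <- mm$matching[seq_len(ng)]
  paired_g <- which(!is.na(mate))
  paired_p <- mate[paired_g] - ng
  key <- paste(edges[, 1], edges[, 2])
  sel <- match(paste(paired_g, paired_p), key)
  pairs <- data.frame(gt_id = gt$id[paired_g], pred_id = pred$id[paired_p],
                      distance = edges[sel, 3],
                      angular_error = edges[sel, 4])
  tp <- nrow(pairs)
  structure(list(tp = tp, fp = np - tp, fn = ng - tp, pairs = pairs),
            class = "match_result")
}

#' Precision, recall and F1 of a match result
#'
#' Precision is 0 when there are no predictions; F1 is 0 when both
#' precision and recall are 0.
#'
#' @param m a `match_result` from [match_particles()].
#' @return Named numeric vector `precision`, `recall`, `f1`.
#' @export
precision_recall_f1 <- function(m) {
  p <- if (m$tp + m$fp > 0) m$tp / (m$tp + m$fp) else 0
  r <- if (m$tp + m$fn > 0) m$tp / (m$tp + m$fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}

#' Orientation distribution against the sinusoidal reference
#'
#' Histograms the angle between each disc normal and `axis` on [0, 90]
#' degrees and compares it to the sin(theta) density of uniformly random
#' orientations (CDF `1 - cos(theta)`), via a Kolmogorov-Smirnov test.
#'
#' @param ps a `particle_set` (or n x 4 quaternion matrix).
#' @param axis reference axis (default beam direction z).
#' @param n_bins number of equal-width bins on [0, 90].
#' @return list: `breaks`, `freq` (observed bin fractions), `reference`
#'   (sinusoidal bin fractions), `ks_stat`, `ks_p`, `angles`.
#' @export
orientation_distribution <- function(ps, axis = c(0, 0, 1), n_bins = 9) {
  if (nrow(ps) == 0L) stop("empty particle set")
  q <- if (is.matrix(ps)) ps else ps_quats(ps)
  ang <- angle_to_axis(q, axis)
  breaks <- seq(0, 90, length.out = n_bins + 1)
  h <- hist(ang, breaks = breaks, plot = FALSE)
  freq <- h$counts / sum(h$counts)
  ref <- diff(1 - cos(breaks * pi / 180))
  ref <- ref / sum(ref)
  ks <- suppressWarnings(
    stats::ks.test(ang * pi / 180, function(t) 1 - cos(pmin(pmax(t, 0),
                                                            pi / 2))))
  list(breaks = breaks, freq = freq, reference = ref,
       ks_stat = unname(ks$statistic), ks_p = ks$p.value, angles = ang)
}

#' Plot an orientation distribution
#'
#' @param od result of [orientation_distribution()].
#' @param main plot title.
#' @return Invisibly, `od`.
#' @export
plot_orientation_distribution <- function(od, main = "Orientation vs axis") {
  mids <- (od$breaks[-1] + od$breaks[-length(od$breaks)]) / 2
  plot(mids, od$freq, type = "b", pch = 19, xlab = "angle to axis (deg)",
       ylab = "frequency", main = main,
       ylim = range(0, od$freq, od$reference))
  lines(mids, od$reference, lty = 2)
  legend("topleft", legend = c("observed", "sin(theta) reference"),
         lty = c(1, 2), pch = c(19, NA), bty = "n")
  invisible(od)
}
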