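# Initial particle centroids.  The reference pipeline seeds CATM from a
# learned segmentation; this module offers (i) a classical matched-filter
# detector pooled over a coarse orientation set, (ii) MeanShift mode
# extraction from an externally produced segmentation volume, and (iii)
# boundary filtering against the lamella faces / condensate surface.

#' Matched-filter particle localization
#'
#' Orientation-pooled masked-NCC response (max over a coarse rotation
#' grid), thresholded adaptively at `median + mad_k * MAD` of the pooled
#' map, with greedy peak merging within `merge_radius`.
#'
#' @param tomogram a `tomo_volume`.
#' @param template a cubic `tomo_volume` template.
#' @param model an [imaging_model()].
#' @param coarse_step coarse angular step, degrees.
#' @param mad_k threshold multiplier on the MAD.
#' @param merge_radius nm; peaks closer than this are merged (best kept).
#' @param mask_threshold steric-mask threshold fraction.
#' @param floor_value absolute lower bound on the adaptive threshold.
#' @return n x 3 matrix of centroids (nm) with attribute `scores`.
#' @export
matched_filter_localize <- function(tomogram, template,
                                    model = imaging_model(),
                                    coarse_step = 30, mad_k = 5,
                                    merge_radius = 6,
                                    mask_threshold = 0.5,
                                    floor_value = 0.25) {
  grid <- rotation_grid(coarse_step)
  bank <- build_orientation_bank(template, grid, model, mask_threshold)
  sc <- score_stream(tomogram, bank)
  thr <- max(stats::median(sc$best) + mad_k * stats::mad(sc$best),
             floor_value)
  pk <- local_maxima_3d(sc$best, thr)
  if (nrow(pk) == 0L) {
    out <- matrix(numeric(0), 0, 3)
    attr(out, "scores") <- numeric(0)
    return(out)
  }
  ccc <- sc$best[pk]
  pos <- sweep((pk - 1) * tomogram$voxel_size, 2, tomogram$origin, `+`)
  cand <- particle_set(pos[, 1], pos[, 2], pos[, 3], score = ccc)
  kept <- nms_distance_cutoff(cand, merge_radius)
  out <- ps_positions(kept)
  attr(out, "scores") <- kept$score
  out
}

#' MeanShift centroids of a segmentation volume
#'
#' Gaussian-kernel mean shift over the foreground voxel cloud (voxel
#' values act as weights); converged modes closer than half the bandwidth
#' are merged, one centroid per basin.
#'
#' @param segmentation probability or binary `tomo_volume`.
#' @param bandwidth kernel bandwidth, nm.
#' @param foreground_fraction voxels above this fraction of the maximum
#'   are foreground.
#' @param max_iter,tol convergence controls.
#' @return n x 3 matrix of centroids, nm (0 x 3 with a warning when the
#'   segmentation is empty).
#' @export
meanshift_centroids <- function(segmentation, bandwidth = 8,
                                foreground_fraction = 0.05,
                                max_iter = 100, tol = NULL) {
  stopifnot(is_volume(segmentation))
  vs <- segmentation$voxel_size
  mx <- max(segmentation$data)
  if (mx <= 0) {
    warning("empty segmentation: no foreground voxels")
    return(matrix(numeric(0), 0, 3))
  }
  sel <- which(segmentation$data > foreground_fraction * mx,
               arr.ind = TRUE)
  if (nrow(sel) == 0L) {
    warning("empty segmentation: no foreground voxels")
    return(matrix(numeric(0), 0, 3))
  }
  w <- segmentation$data[sel]
  P <- sweep((sel - 1) * vs, 2, segmentation$origin, `+`)
  if (is.null(tol)) tol <- 0.01 * bandwidth
  shift_once <- function(x) {
    d2 <- colSums((t(P) - x)^2)
    k <- w * exp(-d2 / (2 * bandwidth^2))
    colSums(P * k) / sum(k)
  }
  X <- P
  for (it in seq_len(max_iter)) {
    shift_max <- 0
    for (i in seq_len(nrow(X))) {
      new <- shift_once(X[i, ])
      shift_max <- max(shift_max, sqrt(sum((new - X[i, ])^2)))
      X[i, ] <- new
    }
    if (shift_max < tol) break
  }
  # candidate modes, heaviest basin first
  ord <- order(-w)
  modes <- matrix(numeric(0), 0, 3)
  for (i in ord) {
    if (nrow(modes) == 0L ||
        min(sqrt(colSums((t(modes) - X[i, ])^2))) > bandwidth / 2)
      modes <- rbind(modes, X[i, ])
  }
  # saddle rejection: seeds on a symmetry plane can converge onto the
  # saddle between two basins; a saddle has higher kernel density one
  # bandwidth away toward either flanking mode, a true mode does not
  density_at <- function(x)
    sum(w * exp(-colSums((t(P) - x)^2) / (2 * bandwidth^2)))
  is_max <- vapply(seq_len(nrow(modes)), function(i) {
    f0 <- density_at(modes[i, ])
    for (ax in 1:3) for (sgn in c(-1, 1)) {
      off <- numeric(3); off[ax] <- sgn * bandwidth
      if (density_at(modes[i, ] + off) > f0) return(FALSE)
    }
    TRUE
  }, TRUE)
  if (any(is_max)) modes <- modes[is_max, , drop = FALSE]
  unname(modes)
}

#' Filter particles near lamella faces or outside the condensate
#'
#' Drops points within `margin` nm of either lamella face and, when a
#' fitted condensate surface is supplied, points outside it.
#'
#' @param points n x 3 matrix (nm) or a `particle_set`.
#' @param lamella_z_range length-2 nm range of the lamella along z.
#' @param margin exclusion margin from each face, nm (default 20).
#' @param surface optional [fit_sphere()] result; exterior points are
#'   dropped.
#' @return Filtered object of the same type.
#' @export
filter_boundary_particles <- function(points, lamella_z_range,
                                      margin = 20, surface = NULL) {
  if (length(lamella_z_range) != 2L || diff(lamella_z_range) <= 0)
    stop("lamella_z_range must be an increasing length-2 range")
  is_ps <- inherits(points, "particle_set") || is.data.frame(points)
  P <- if (is_ps) ps_positions(points) else rbind(points)
  keep <- P[, 3] >= lamella_z_range[1] + margin &
          P[, 3] <= lamella_z_range[2] - margin
  if (!is.null(surface)) {
    d <- surface$radius -
      sqrt(colSums((t(P) - surface$center)^2))
    keep <- keep & d >= 0
  }
  if (is_ps) as_particle_set(points[keep, , drop = FALSE])
  else P[keep, , drop = FALSE]
}
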