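# Synthetic tomograms with known ground truth.  Particles (nucleosome
# discs + free DNA rods) are placed uniformly at random in position and
# orientation subject to pairwise steric non-overlap, rendered onto the
# grid, then degraded by CTF, additive noise and the missing wedge.

#' Sample a random non-overlapping particle configuration
#'
#' Positions are uniform inside the box (with a margin keeping each
#' particle fully inside), orientations uniform on SO(3).  Rejection
#' sampling enforces pairwise steric non-overlap of the voxelized masks.
#'
#' @param box_nm box edge length(s), nm (scalar or length-3).
#' @param n_nucleosomes,n_dna particle counts.
#' @param shapes named list with `nucleosome` and `dna` [particle_shape()]s.
#' @param voxel_size nm/voxel used for mask voxelization.
#' @param seed integer seed.
#' @param max_attempts consecutive rejections tolerated before declaring
#'   the density infeasible.
#' @param mask_threshold steric-mask threshold fraction.
#' @return A `particle_set` with `kind` column, plus attributes
#'   `box_nm`, `achieved_density` (particles/nm^3) and `mask_offsets`.
#' @export
sample_particle_configuration <- function(box_nm, n_nucleosomes, n_dna = 0,
                                          shapes = NULL, voxel_size = 1,
                                          seed = 1L, max_attempts = 20000,
                                          mask_threshold = 0.5) {
  box <- rep_len(box_nm, 3)
  if (is.null(shapes))
    shapes <- list(nucleosome = particle_shape(),
                   dna = particle_shape("dna_rod"))
  tmpl <- list(
    nucleosome = build_nucleosome_template(shapes$nucleosome, voxel_size),
    dna = build_dna_template(shapes$dna, voxel_size))
  masks <- lapply(tmpl, build_steric_mask, threshold_fraction = mask_threshold)
  circum <- c(
    nucleosome = sqrt((shapes$nucleosome$diameter / 2)^2 +
                      (shapes$nucleosome$height_or_length / 2)^2),
    dna = sqrt((shapes$dna$diameter / 2)^2 +
               (shapes$dna$height_or_length / 2)^2))
  # keep the whole template grid (not just the particle) inside the box
  grid_half <- vapply(tmpl, function(tm)
    ((dim(tm$data)[1] - 1) / 2 + 1) * voxel_size, 0)
  kinds <- c(rep("nucleosome", n_nucleosomes), rep("dna", n_dna))
  n <- length(kinds)
  old <- .Random.seed_safe(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  pos <- matrix(NA_real_, n, 3)
  quats <- matrix(NA_real_, n, 4)
  offs <- vector("list", n)
  keys <- vector("list", n)
  placed <- 0L
  while (placed < n) {
    k <- kinds[placed + 1L]
    margin <- grid_half[[k]]
    if (any(box <= 2 * margin))
      stop("density infeasible: box too small for particle margin")
    rejections <- 0L
    repeat {
      p <- margin + stats::runif(3) * (box - 2 * margin)
      q <- quat_random(1)
      off <- rotated_mask_offsets(masks[[k]], q)
      kk <- placed_keys(off, p, voxel_size)
      ok <- TRUE
      if (placed > 0L) {
        d <- sqrt(colSums((t(pos[seq_len(placed), , drop = FALSE]) - p)^2))
        for (j in which(d < circum[[k]] + max(circum) + 2 * voxel_size)) {
          if (overlap_count(kk, keys[[j]]) > 0L) { ok <- FALSE; break }
        }
      }
      if (ok) break
      rejections <- rejections + 1L
      if (rejections > max_attempts)
        stop(sprintf(
          "density infeasible: %d consecutive rejections at %d/%d particles (achieved density %.3g /nm^3)",
          rejections, placed, n, placed / prod(box)))
    }
    placed <- placed + 1L
    pos[placed, ] <- p
    quats[placed, ] <- q
    offs[[placed]] <- off
    keys[[placed]] <- kk
  }
  eul <- quat_to_euler(quats)
  ps <- particle_set(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                     rot = eul$rot, tilt = eul$tilt, psi = eul$psi,
                     kind = kinds)
  attr(ps, "box_nm") <- box
  attr(ps, "achieved_density") <- n / prod(box)
  attr(ps, "mask_offsets") <- offs
  ps
}

#' Render a particle configuration onto a voxel grid
#'
#' The clean forward model: the sum of rotated, translated templates,
#' resampled by trilinear interpolation.  Linear in template amplitude.
#'
#' @param gt a `particle_set` (positions nm, ZYZ Eulers).
#' @param templates named list of `tomo_volume` templates, one per value of
#'   `gt$kind`.
#' @param dims grid dimensions (length-3 integer).
#' @param voxel_size nm/voxel.
#' @param origin nm position of the centre of voxel `[1,1,1]`.
#' @return A `tomo_volume`.
#' @export
render_volume <- function(gt, templates, dims, voxel_size = 1,
                          origin = c(0, 0, 0)) {
  dat <- array(0, dims)
  if (nrow(gt) == 0L)
    return(volume(dat, voxel_size, origin))
  quats <- ps_quats(gt)
  for (i in seq_len(nrow(gt))) {
    tm <- templates[[gt$kind[i]]]
    if (is.null(tm)) stop("no template for kind ", gt$kind[i])
    td <- dim(tm$data)
    half <- (td - 1) / 2
    tctr <- (td + 1) / 2
    p <- c(gt$x[i], gt$y[i], gt$z[i])
    cidx <- (p - origin) / voxel_size + 1        # fractional centre index
    lo <- floor(cidx - half) ; hi <- ceiling(cidx + half)
    if (any(lo < 1) || any(hi > dims))
      stop("particle ", gt$id[i], " out of bounds")
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    g <- as.matrix(expand.grid(x = ix, y = iy, z = iz))
    rel <- sweep(g, 2, cidx) * voxel_size        # nm offsets from centre
    R <- quat_rotmat(quats[i, ])
    src <- (rel %*% R) / voxel_size +
      matrix(tctr, nrow(rel), 3, byrow = TRUE)   # R^-1 x in template idx
    vals <- trilinear_sample(tm$data, src)
    dat[cbind(g[, 1], g[, 2], g[, 3])] <-
      dat[cbind(g[, 1], g[, 2], g[, 3])] + vals
  }
  volume(dat, voxel_size, origin)
}

#' Jittered ground-truth centroids
#'
#' Emulates the output quality of an upstream segmentation/localization
#' step by perturbing true centres with isotropic Gaussian noise.
#'
#' @param gt a `particle_set`.
#' @param sigma_nm jitter standard deviation per axis, nm.
#' @param seed integer seed.
#' @param kinds which kinds to emit centroids for (default nucleosomes).
#' @return n x 3 matrix of centroids, nm.
#' @export
perturb_centroids <- function(gt, sigma_nm = 1.5, seed = 1L,
                              kinds = "nucleosome") {
  sel <- gt$kind %in% kinds
  p <- ps_positions(gt)[sel, , drop = FALSE]
  old <- .Random.seed_safe(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  p + matrix(stats::rnorm(length(p), sd = sigma_nm), nrow(p), 3)
}

#' Generate one synthetic benchmark tomogram
#'
#' Composition of the full forward model: sample configuration, render,
#' CTF, additive noise at the configured SNR, then the missing wedge (the
#' wedge acts on the noisy volume, as in a reconstruction from a limited
#' tilt fan).  Deterministic given `seed`.
#'
#' @param config configuration list (see [catm_config()]).
#' @param seed integer seed driving both the configuration and the noise.
#' @param write_dir optional directory; if given, writes `tomogram.mrc`,
#'   `ground_truth.star`, `ground_truth.csv` and a JSON run log.
#' @return list with `tomogram` (`tomo_volume`), `gt` (`particle_set`),
#'   `clean` (noise-free render), `model` ([imaging_model()]),
#'   `templates`, `masks`.
#' @export
generate_benchmark <- function(config = catm_config(), seed = 1L,
                               write_dir = NULL) {
  s <- config$simulate
  tp <- config$template
  shapes <- list(
    nucleosome = particle_shape("nucleosome_disc", tp$nucleosome_diameter,
                                tp$nucleosome_height, tp$amplitude),
    dna = particle_shape("dna_rod", tp$dna_diameter, tp$dna_length,
                         tp$amplitude))
  gt <- sample_particle_configuration(
    s$box_nm, s$n_nucleosomes, s$n_dna, shapes, s$voxel_size,
    seed = seed, max_attempts = s$max_attempts,
    mask_threshold = tp$mask_threshold)
  templates <- list(
    nucleosome = build_nucleosome_template(shapes$nucleosome, s$voxel_size),
    dna = build_dna_template(shapes$dna, s$voxel_size))
  masks <- lapply(templates, build_steric_mask,
                  threshold_fraction = tp$mask_threshold)
  dims <- rep(round(s$box_nm / s$voxel_size), 3)
  clean <- render_volume(gt, templates, dims, s$voxel_size)
  model <- imaging_model(s$tilt_min, s$tilt_max, s$defocus_um, s$voltage_kv,
                         s$cs_mm, s$amplitude_contrast, s$snr, seed)
  tomo <- apply_ctf(clean, model)
  if (is.finite(s$snr)) tomo <- add_noise(tomo, s$snr, seed = seed + 7919L)
  tomo <- apply_missing_wedge(tomo, s$tilt_min, s$tilt_max)
  if (!is.null(write_dir)) {
    dir.create(write_dir, recursive = TRUE, showWarnings = FALSE)
    write_mrc(tomo, file.path(write_dir, "tomogram.mrc"))
    write_star_particles(gt, file.path(write_dir, "ground_truth.star"),
                         voxel_size = s$voxel_size)
    write_csv_particles(gt, file.path(write_dir, "ground_truth.csv"))
    jsonlite::write_json(
      list(seed = seed, n_particles = nrow(gt), snr = s$snr,
           achieved_density = attr(gt, "achieved_density"),
           box_nm = s$box_nm, voxel_size = s$voxel_size,
           tilt = c(s$tilt_min, s$tilt_max)),
      file.path(write_dir, "run_log.json"), auto_unbox = TRUE, digits = NA)
  }
  list(tomogram = tomo, gt = gt, clean = clean, model = model,
       templates = templates, masks = masks)
}
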