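# The simulated-tomogram benchmark: generate tomograms with known ground
# truth, run baseline TM (with a CCC threshold sweep) and CATM on each,
# and score both against the ground truth, position-only and with
# orientation agreement required.

#' Run the simulated benchmark over several tomograms
#'
#' For each seed: simulate a tomogram, run exhaustive TM (orientation
#' search + NMS + CCC threshold sweep) and CATM (seeded with jittered
#' ground-truth centroids emulating the upstream segmentation, or with the
#' matched-filter localizer), and evaluate precision/recall/F1 against
#' ground truth.
#'
#' @param seeds integer seeds, one tomogram each.
#' @param config configuration list (see [catm_config()]).
#' @param localizer `"perturbed"` (default) or `"matched_filter"`.
#' @param run_tm,run_catm logical switches.
#' @param progress print progress messages.
#' @return list with `per_tomogram` (list of per-seed results) and
#'   `summary` (mean TM max-F1 position / with-orientation, mean CATM F1
#'   position / with-orientation, orientation KS statistics).
#' @export
run_benchmark <- function(seeds = 1:3, config = catm_config(),
                          localizer = c("perturbed", "matched_filter"),
                          run_tm = TRUE, run_catm = TRUE,
                          progress = FALSE) {
  localizer <- match.arg(localizer)
  s <- config$simulate
  model <- imaging_model(s$tilt_min, s$tilt_max, s$defocus_um,
                         s$voltage_kv, s$cs_mm, s$amplitude_contrast,
                         s$snr)
  tp <- config$template
  template <- build_nucleosome_template(
    particle_shape("nucleosome_disc", tp$nucleosome_diameter,
                   tp$nucleosome_height, tp$amplitude), s$voxel_size)
  grid <- rotation_grid(config$tm$angular_step)
  bank_tm <- if (run_tm)
    build_orientation_bank(template, grid, model, tp$mask_threshold)
  per <- list()
  for (seed in seeds) {
    if (progress) message("tomogram seed ", seed)
    sim <- generate_benchmark(config, seed = seed)
    gt_nuc <- as_particle_set(sim$gt[sim$gt$kind == "nucleosome", ,
                                     drop = FALSE])
    res <- list(seed = seed, n_nucleosomes = nrow(gt_nuc))
    if (run_tm) {
      cands <- tm_search(sim$tomogram, template, model = model,
                         score_floor = config$tm$score_floor,
                         bank = bank_tm, progress = progress)
      pred_tm <- nms_distance_cutoff(cands, config$tm$nms_cutoff)
      sweep_tab <- ccc_threshold_sweep(
        pred_tm, gt_nuc, thresholds = config$tm$sweep_thresholds,
        dist_tol = config$evaluate$dist_tol,
        ang_tol = config$evaluate$ang_tol)
      best_pos <- sweep_tab[which.max(sweep_tab$f1), ]
      best_ang <- sweep_tab[which.max(sweep_tab$f1_ang), ]
      tm_best <- as_particle_set(
        pred_tm[!is.na(pred_tm$score) &
                  pred_tm$score >= best_pos$threshold, , drop = FALSE])
      res$tm <- list(sweep = sweep_tab, max_f1_pos = best_pos$f1,
                     max_f1_ang = best_ang$f1_ang,
                     best_threshold = best_pos$threshold,
                     pred = tm_best)
    }
    if (run_catm) {
      centroids <- if (localizer == "perturbed")
        perturb_centroids(sim$gt, config$catm$centroid_sigma,
                          seed = seed + 104729L)
      else matched_filter_localize(sim$tomogram, template, model,
                                   config$localize$coarse_step,
                                   config$localize$mad_k,
                                   config$localize$merge_radius,
                                   tp$mask_threshold)
      pred_catm <- run_catm(sim$tomogram, template, centroids,
                            model = model, config = config, grid = grid,
                            progress = progress)
      m_pos <- match_particles(gt_nuc, pred_catm,
                               dist_tol = config$evaluate$dist_tol)
      m_ang <- match_particles(gt_nuc, pred_catm,
                               dist_tol = config$evaluate$dist_tol,
                               ang_tol = config$evaluate$ang_tol)
      res$catm <- list(
        f1_pos = precision_recall_f1(m_pos)[["f1"]],
        f1_ang = precision_recall_f1(m_ang)[["f1"]],
        pred = pred_catm,
        rejected = attr(pred_catm, "rejected"))
    }
    res$gt <- gt_nuc
    per[[as.character(seed)]] <- res
  }
  summary <- list(seeds = seeds)
  if (run_tm) {
    summary$tm_max_f1_pos <- mean(vapply(per, function(r)
      r$tm$max_f1_pos, 0))
    summary$tm_max_f1_ang <- mean(vapply(per, function(r)
      r$tm$max_f1_ang, 0))
  }
  if (run_catm) {
    summary$catm_f1_pos <- mean(vapply(per, function(r) r$catm$f1_pos, 0))
    summary$catm_f1_ang <- mean(vapply(per, function(r) r$catm$f1_ang, 0))
  }
  list(per_tomogram = per, summary = summary)
}

#' Pooled orientation diagnostics of a benchmark run
#'
#' Pools particles over the benchmark tomograms and returns the
#' angle-to-beam distribution of ground truth, TM (at its best
#' threshold) and CATM assignments.
#'
#' @param bench result of [run_benchmark()].
#' @param n_bins histogram bins on [0, 90] degrees.
#' @return list of [orientation_distribution()] results (`gt`, `tm`,
#'   `catm`, present when available).
#' @export
benchmark_orientation_diagnostics <- function(bench, n_bins = 9) {
  pool <- function(field) {
    qs <- lapply(bench$per_tomogram, function(r) {
      ps <- switch(field, gt = r$gt, tm = r$tm$pred, catm = r$catm$pred)
      if (is.null(ps) || nrow(ps) == 0L) NULL else ps_quats(ps)
    })
    qs <- qs[!vapply(qs, is.null, TRUE)]
    if (!length(qs)) return(NULL)
    orientation_distribution(do.call(rbind, qs), n_bins = n_bins)
  }
  out <- list(gt = pool("gt"))
  if (!is.null(bench$per_tomogram[[1]]$tm)) out$tm <- pool("tm")
  if (!is.null(bench$per_tomogram[[1]]$catm)) out$catm <- pool("catm")
  out
}
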