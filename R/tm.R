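# Baseline exhaustive template matching: every voxel is scored against
# every grid orientation, each voxel retains only its best orientation,
# local maxima above a floor become candidates, and candidates within a
# centre-to-centre distance cutoff are thinned greedily by CCC
# (non-maximum suppression).

#' Exhaustive template matching search
#'
#' @param tomogram a `tomo_volume`.
#' @param template a cubic `tomo_volume` template.
#' @param grid a [rotation_grid()].
#' @param model an [imaging_model()] (degrades the template like the data).
#' @param score_floor minimum CCC for a candidate local maximum.
#' @param mask_threshold,lowpass_nm template degradation options.
#' @param bank optional precomputed [build_orientation_bank()] (overrides
#'   `grid`).
#' @param progress print progress messages.
#' @return A `particle_set` of match candidates (positions nm, grid
#'   orientations, `score` = CCC), sorted by descending CCC.
#' @export
tm_search <- function(tomogram, template, grid = rotation_grid(15),
                      model = imaging_model(), score_floor = 0.1,
                      mask_threshold = 0.5, lowpass_nm = NULL,
                      bank = NULL, progress = FALSE) {
  if (is.null(bank))
    bank <- build_orientation_bank(template, grid, model, mask_threshold,
                                   lowpass_nm)
  sc <- score_stream(tomogram, bank, progress = progress)
  pk <- local_maxima_3d(sc$best, score_floor)
  if (nrow(pk) == 0L) return(particle_set())
  ccc <- sc$best[pk]
  oidx <- sc$orient[pk]
  pos <- sweep((pk - 1) * tomogram$voxel_size, 2, tomogram$origin, `+`)
  quats <- do.call(rbind, lapply(bank$entries[oidx], `[[`, "quat"))
  eul <- quat_to_euler(quats)
  ord <- order(-ccc)
  ps <- particle_set(x = pos[ord, 1], y = pos[ord, 2], z = pos[ord, 3],
                     rot = eul$rot[ord], tilt = eul$tilt[ord],
                     psi = eul$psi[ord], score = ccc[ord])
  attr(ps, "orient_index") <- oidx[ord]
  ps
}

#' Non-maximum suppression by centre distance
#'
#' Greedy by descending CCC (ties broken by particle id): a candidate is
#' kept only if no already-kept candidate lies within `cutoff` nm.
#'
#' @param cands a `particle_set` of candidates.
#' @param cutoff centre-to-centre distance cutoff, nm (default 4, slightly
#'   smaller than the nucleosome height).
#' @return The surviving `particle_set`.
#' @export
nms_distance_cutoff <- function(cands, cutoff = 4) {
  if (cutoff <= 0) stop("cutoff must be positive")
  n <- nrow(cands)
  if (n == 0L) return(cands)
  ord <- order(-cands$score, cands$id)
  pos <- ps_positions(cands)[ord, , drop = FALSE]
  keep <- logical(n)
  kept <- matrix(numeric(0), 0, 3)
  for (i in seq_len(n)) {
    if (nrow(kept) == 0L ||
        min(sqrt(colSums((t(kept) - pos[i, ])^2))) >= cutoff) {
      keep[i] <- TRUE
      kept <- rbind(kept, pos[i, ])
    }
  }
  out <- cands[ord[keep], , drop = FALSE]
  oi <- attr(cands, "orient_index")
  if (!is.null(oi)) attr(out, "orient_index") <- oi[ord[keep]]
  as_particle_set(out)
}

#' Precision/recall/F1 over a sweep of CCC thresholds
#'
#' Scores the prediction set against ground truth at each CCC threshold,
#' both position-only and (if `ang_tol` is given) requiring orientation
#' agreement for a true positive.
#'
#' @param pred a `particle_set` with CCC scores.
#' @param gt ground-truth `particle_set` (nucleosomes are scored; other
#'   kinds in `gt` are dropped).
#' @param thresholds CCC thresholds to sweep.
#' @param dist_tol matching distance tolerance, nm.
#' @param ang_tol angular tolerance in degrees, or NULL for position-only.
#' @return data.frame with one row per threshold (`threshold`,
#'   `n_pred`, `precision`, `recall`, `f1`, and `*_ang` columns when
#'   `ang_tol` is given); attribute `best` holds the argmax-F1 row.
#' @export
ccc_threshold_sweep <- function(pred, gt, thresholds = seq(0.1, 0.7, 0.025),
                                dist_tol = 5.5, ang_tol = NULL) {
  gt <- gt[gt$kind == "nucleosome" | !("kind" %in% names(gt)), ,
           drop = FALSE]
  rows <- lapply(thresholds, function(th) {
    sub <- as_particle_set(pred[!is.na(pred$score) & pred$score >= th, ,
                                drop = FALSE])
    m <- match_particles(gt, sub, dist_tol = dist_tol)
    pr <- precision_recall_f1(m)
    out <- data.frame(threshold = th, n_pred = nrow(sub),
                      precision = pr[["precision"]],
                      recall = pr[["recall"]], f1 = pr[["f1"]])
    if (!is.null(ang_tol)) {
      ma <- match_particles(gt, sub, dist_tol = dist_tol, ang_tol = ang_tol)
      pra <- precision_recall_f1(ma)
      out$precision_ang <- pra[["precision"]]
      out$recall_ang <- pra[["recall"]]
      out$f1_ang <- pra[["f1"]]
    }
    out
  })
  tab <- do.call(rbind, rows)
  attr(tab, "best") <- tab[which.max(tab$f1), , drop = FALSE]
  tab
}
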