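# Context-aware template matching.  Around each seed centroid, the
# low-passed tomogram is matched locally against every grid orientation
# and a list of candidate poses above a retention threshold is kept.
# Particles are then mapped back into the volume in descending order of
# their best CCC; steric clashes with previously placed particles are
# resolved first from the particle's own alternative candidates, then by
# joint pairwise optimization with its nearest placed neighbour, and if
# no sterically compatible combination exists only the stronger particle
# survives.

# Precompute padded Fourier transforms of each bank entry for the local
# matching window.
bank_local_fft <- function(bank, search_radius) {
  vs <- bank$voxel_size
  ht <- (bank$template_dim - 1) / 2
  sr <- ceiling(search_radius / vs)
  ns <- 2 * (ht + sr) + 1
  pad <- max(32, 2^ceiling(log2(ns)))
  dims <- rep(pad, 3)
  perm <- make_flip_perm(dims)
  Fts <- vector("list", length(bank$entries))
  for (o in seq_along(bank$entries)) {
    e <- bank$entries[[o]]
    Z <- stats::fft(array(
      pack_complex(pad_wrap(e$offsets, e$tvals, dims),
                   pad_wrap(e$offsets, rep(1, e$n), dims)), dims))
    sp <- hermitian_split(Z, perm)
    Fts[[o]] <- list(Ft = sp$a, Fm = sp$b)
  }
  off <- as.matrix(expand.grid(x = -sr:sr, y = -sr:sr, z = -sr:sr))
  off <- off[rowSums(off^2) <= (search_radius / vs)^2, , drop = FALSE]
  a0 <- ht + sr + 1
  lin <- (off[, 1] + a0) + pad * (off[, 2] + a0 - 1) +
    pad^2 * (off[, 3] + a0 - 1)
  list(Fts = Fts, pad = pad, ht = ht, sr = sr, ns = ns,
       offsets = off, lin_idx = lin, a0 = a0, perm = perm)
}

local_match_impl <- function(fdata, dims, vs, origin, bank, lf, anchor,
                            retain_threshold) {
  av <- round((anchor - origin) / vs) + 1
  rad <- lf$ht + lf$sr
  sub <- array(0, rep(lf$ns, 3))
  lo <- av - rad; hi <- av + rad
  slo <- pmax(lo, 1); shi <- pmin(hi, dims)
  if (any(slo > shi)) return(NULL)            # anchor outside volume
  sub[(slo[1] - lo[1] + 1):(shi[1] - lo[1] + 1),
      (slo[2] - lo[2] + 1):(shi[2] - lo[2] + 1),
      (slo[3] - lo[3] + 1):(shi[3] - lo[3] + 1)] <-
    fdata[slo[1]:shi[1], slo[2]:shi[2], slo[3]:shi[3]]
  big <- array(0, rep(lf$pad, 3))
  big[seq_len(lf$ns), seq_len(lf$ns), seq_len(lf$ns)] <- sub
  pdims <- rep(lf$pad, 3)
  Zs <- stats::fft(array(pack_complex(big, big^2), pdims))
  sp <- hermitian_split(Zs, lf$perm)
  N <- prod(pdims)
  eps_sd <- max(stats::sd(sub), 0) * 1e-6 + 1e-300
  out <- vector("list", length(bank$entries))
  for (o in seq_along(bank$entries)) {
    e <- bank$entries[[o]]
    ft <- lf$Fts[[o]]
    pr <- spectrum_products(sp$a, sp$b, ft$Ft, ft$Fm)
    W <- stats::fft(array(pr$Q1, pdims), inverse = TRUE)
    C2 <- stats::fft(array(pr$Q2, pdims), inverse = TRUE)
    ncc <- ncc_combine(W, C2, N, e$n, eps_sd)[lf$lin_idx]
    j <- which.max(ncc)
    if (length(j) && ncc[j] >= retain_threshold) {
      pv <- av + lf$offsets[j, ]
      out[[o]] <- c(orient = o, ccc = ncc[j],
                    x = (pv[1] - 1) * vs + origin[1],
                    y = (pv[2] - 1) * vs + origin[2],
                    z = (pv[3] - 1) * vs + origin[3])
    }
  }
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out) || nrow(out) == 0L) return(NULL)
  df <- as.data.frame(out)
  df[order(-df$ccc), , drop = FALSE]
}

#' Local template matching around an anchor point
#'
#' Extracts the matching window around `anchor`, scores every grid
#' orientation at every position within `search_radius`, and returns the
#' per-orientation best poses with CCC at or above `retain_threshold`,
#' sorted by descending CCC.  An empty result means the particle is
#' unassigned.
#'
#' @param tomogram a `tomo_volume` (low-pass it first for the CATM
#'   pipeline; [run_catm()] does this for you).
#' @param template a cubic `tomo_volume` template.
#' @param anchor seed position, nm (length-3).
#' @param search_radius nm around the anchor (default 5).
#' @param grid a [rotation_grid()].
#' @param model an [imaging_model()].
#' @param retain_threshold CCC retention floor (default 0.3).
#' @param mask_threshold,lowpass_nm template degradation options.
#' @param bank,bank_fft optional precomputed [build_orientation_bank()]
#'   and its local transforms (internal reuse).
#' @return data.frame of candidates (`orient`, `ccc`, `x`, `y`, `z`) or
#'   NULL when no candidate reaches the threshold.
#' @export
local_match <- function(tomogram, template, anchor, search_radius = 5,
                        grid = rotation_grid(15), model = imaging_model(),
                        retain_threshold = 0.3, mask_threshold = 0.5,
                        lowpass_nm = NULL, bank = NULL, bank_fft = NULL) {
  if (search_radius < 0) stop("search_radius must be >= 0")
  if (is.null(bank))
    bank <- build_orientation_bank(template, grid, model, mask_threshold,
                                   lowpass_nm)
  if (is.null(bank_fft)) bank_fft <- bank_local_fft(bank, search_radius)
  local_match_impl(tomogram$data, dim(tomogram$data),
                   tomogram$voxel_size, tomogram$origin,
                   bank, bank_fft, anchor, retain_threshold)
}

# clash tolerance in voxels for a pair of bank entries
tol_voxels <- function(clash_fraction, na, nb)
  floor(clash_fraction * min(na, nb))

#' Jointly optimize a clashing pair of particles
#'
#' Evaluates the cross-product of two particles' candidate lists against
#' the occupancy of all other placed particles; returns the sterically
#' compatible pair maximizing the summed CCC, or NULL if none exists.
#'
#' @param p_cands,q_cands candidate data.frames from [local_match()].
#' @param occupancy list of voxel-key vectors of the other placed
#'   particles (excluding q).
#' @param bank an `orientation_bank`.
#' @param clash_fraction mask-overlap fraction counting as a clash.
#' @return list(`p` = row of `p_cands`, `q` = row of `q_cands`,
#'   `ccc_sum`) or NULL.
#' @export
resolve_pairwise <- function(p_cands, q_cands, occupancy, bank,
                             clash_fraction = 0.05) {
  vs <- bank$voxel_size
  keys_of <- function(row) {
    e <- bank$entries[[row$orient]]
    placed_keys(e$offsets, c(row$x, row$y, row$z), vs)
  }
  n_of <- function(row) bank$entries[[row$orient]]$n
  free_vs_occ <- function(keys, n) {
    for (ok in occupancy) {
      if (overlap_count(keys, ok) > tol_voxels(clash_fraction, n, n))
        return(FALSE)
    }
    TRUE
  }
  pk <- lapply(seq_len(nrow(p_cands)), function(i) keys_of(p_cands[i, ]))
  qk <- lapply(seq_len(nrow(q_cands)), function(i) keys_of(q_cands[i, ]))
  p_ok <- vapply(seq_len(nrow(p_cands)),
                 function(i) free_vs_occ(pk[[i]], n_of(p_cands[i, ])), TRUE)
  best <- NULL
  for (j in seq_len(nrow(q_cands))) {
    if (!free_vs_occ(qk[[j]], n_of(q_cands[j, ]))) next
    for (i in which(p_ok)) {
      tol <- tol_voxels(clash_fraction, n_of(p_cands[i, ]),
                        n_of(q_cands[j, ]))
      if (overlap_count(pk[[i]], qk[[j]]) > tol) next
      s <- p_cands$ccc[i] + q_cands$ccc[j]
      if (is.null(best) || s > best$ccc_sum)
        best <- list(p = p_cands[i, ], q = q_cands[j, ], ccc_sum = s)
    }
  }
  best
}

#' Greedy steric-aware placement of candidate lists
#'
#' Processes particles in descending order of their best candidate CCC
#' (ties broken by particle id).  Each particle is placed at its best
#' candidate that does not clash with previously placed particles; if
#' every candidate clashes, the conflict is escalated to
#' [resolve_pairwise()] with the nearest placed neighbour, and if that
#' fails only the particle with the higher CCC survives.
#'
#' @param cand_lists named list of candidate data.frames (NULL entries =
#'   unassigned particles).
#' @param bank the `orientation_bank` the candidates refer to.
#' @param clash_fraction mask-overlap fraction counting as a clash.
#' @return list: `placed` (`particle_set` with `score` = CCC), `rejected`
#'   data.frame (id, reason), `events` (pairwise resolution log).
#' @export
greedy_place <- function(cand_lists, bank, clash_fraction = 0.05) {
  vs <- bank$voxel_size
  ids <- names(cand_lists)
  if (is.null(ids)) ids <- as.character(seq_along(cand_lists))
  has <- !vapply(cand_lists, is.null, TRUE)
  rejected <- data.frame(id = ids[!has],
                         reason = rep("unassigned", sum(!has)),
                         stringsAsFactors = FALSE)
  live <- which(has)
  top <- vapply(cand_lists[live], function(d) d$ccc[1], 0)
  ord <- live[order(-top, ids[live])]
  reach <- max(vapply(bank$entries, function(e)
    max(sqrt(rowSums(e$offsets^2))), 0)) * vs
  placed <- list(id = character(), pos = matrix(numeric(0), 0, 3),
                 orient = integer(), ccc = numeric(), keys = list())
  events <- list()
  keys_of <- function(row) placed_keys(bank$entries[[row$orient]]$offsets,
                                       c(row$x, row$y, row$z), vs)
  clash_with <- function(row, keys, skip = 0L) {
    if (length(placed$id) == 0L) return(FALSE)
    n <- bank$entries[[row$orient]]$n
    d <- sqrt(colSums((t(placed$pos) - c(row$x, row$y, row$z))^2))
    for (j in which(d < 2 * reach + 2 * vs)) {
      if (j == skip) next
      nj <- bank$entries[[placed$orient[j]]]$n
      if (overlap_count(keys, placed$keys[[j]]) >
          tol_voxels(clash_fraction, n, nj)) return(j)
    }
    FALSE
  }
  add_placed <- function(pid, row, keys) {
    placed$id <<- c(placed$id, pid)
    placed$pos <<- rbind(placed$pos, c(row$x, row$y, row$z))
    placed$orient <<- c(placed$orient, row$orient)
    placed$ccc <<- c(placed$ccc, row$ccc)
    placed$keys <<- c(placed$keys, list(keys))
  }
  drop_placed <- function(j) {
    placed$id <<- placed$id[-j]
    placed$pos <<- placed$pos[-j, , drop = FALSE]
    placed$orient <<- placed$orient[-j]
    placed$ccc <<- placed$ccc[-j]
    placed$keys <<- placed$keys[-j]
  }
  for (pi in ord) {
    cl <- cand_lists[[pi]]
    pid <- ids[pi]
    done <- FALSE
    for (i in seq_len(nrow(cl))) {
      k <- keys_of(cl[i, ])
      if (identical(clash_with(cl[i, ], k), FALSE)) {
        add_placed(pid, cl[i, ], k)
        done <- TRUE
        break
      }
    }
    if (done) next
    # all own candidates clash: pair with the nearest placed neighbour
    anchor <- c(cl$x[1], cl$y[1], cl$z[1])
    d <- sqrt(colSums((t(placed$pos) - anchor)^2))
    qj <- which.min(d)
    qid <- placed$id[qj]
    q_cands <- cand_lists[[match(qid, ids)]]
    occ <- placed$keys[-qj]
    res <- resolve_pairwise(cl, q_cands, occ, bank, clash_fraction)
    if (!is.null(res)) {
      drop_placed(qj)
      add_placed(qid, res$q, keys_of(res$q))
      add_placed(pid, res$p, keys_of(res$p))
      events <- c(events, list(list(p = pid, q = qid,
                                    outcome = "pair_resolved")))
      next
    }
    if (cl$ccc[1] > placed$ccc[qj]) {
      # p is the stronger particle: displace q if p then fits
      fit <- NULL
      for (i in seq_len(nrow(cl))) {
        k <- keys_of(cl[i, ])
        if (identical(clash_with(cl[i, ], k, skip = qj), FALSE)) {
          fit <- list(row = cl[i, ], keys = k)
          break
        }
      }
      if (!is.null(fit)) {
        drop_placed(qj)
        rejected <- rbind(rejected,
                          data.frame(id = qid, reason = "clash_lower_ccc"))
        add_placed(pid, fit$row, fit$keys)
        events <- c(events, list(list(p = pid, q = qid,
                                      outcome = "q_displaced")))
        next
      }
    }
    rejected <- rbind(rejected,
                      data.frame(id = pid, reason = "clash_lower_ccc"))
    events <- c(events, list(list(p = pid, q = qid,
                                  outcome = "p_rejected")))
  }
  quats <- if (length(placed$orient))
    do.call(rbind, lapply(bank$entries[placed$orient], `[[`, "quat"))
  else matrix(numeric(0), 0, 4)
  eul <- quat_to_euler(quats)
  ps <- particle_set(x = placed$pos[, 1], y = placed$pos[, 2],
                     z = placed$pos[, 3], rot = eul$rot, tilt = eul$tilt,
                     psi = eul$psi, score = placed$ccc,
                     id = as.integer(placed$id))
  attr(ps, "orient_index") <- placed$orient
  list(placed = ps, rejected = rejected, events = events)
}

#' Run the full CATM pipeline
#'
#' Low-passes the tomogram, matches locally around every seed centroid
#' with multi-candidate retention, then places particles greedily with
#' steric-clash resolution.
#'
#' @param tomogram a `tomo_volume`.
#' @param template a cubic `tomo_volume` template.
#' @param centroids n x 3 matrix of seed positions, nm.
#' @param model an [imaging_model()].
#' @param config configuration list (see [catm_config()]); the `catm`
#'   section supplies search radius, retention threshold, clash fraction
#'   and low-pass resolution.
#' @param grid a [rotation_grid()] (default from `config$tm$angular_step`).
#' @param progress print progress messages.
#' @return A `particle_set` of placed particles with attributes
#'   `rejected` (data.frame id/reason, including unassigned seeds) and
#'   `events` (pairwise-resolution log).
#' @export
run_catm <- function(tomogram, template, centroids,
                     model = imaging_model(), config = catm_config(),
                     grid = NULL, progress = FALSE) {
  cc <- config$catm
  if (is.null(grid)) grid <- rotation_grid(config$tm$angular_step)
  centroids <- rbind(centroids)
  if (nrow(centroids) == 0L) {
    ps <- particle_set()
    attr(ps, "rejected") <- data.frame(id = character(),
                                       reason = character())
    attr(ps, "events") <- list()
    return(ps)
  }
  ft <- lowpass_volume(tomogram, cc$lowpass_nm)
  bank <- build_orientation_bank(template, grid, model,
                                 config$template$mask_threshold,
                                 lowpass_nm = cc$lowpass_nm)
  lf <- bank_local_fft(bank, cc$search_radius)
  lists <- vector("list", nrow(centroids))
  names(lists) <- as.character(seq_len(nrow(centroids)))
  for (i in seq_len(nrow(centroids))) {
    lists[[i]] <- local_match_impl(ft$data, dim(ft$data), ft$voxel_size,
                                   ft$origin, bank, lf, centroids[i, ],
                                   cc$retain_threshold)
    if (progress && i %% 20 == 0)
      message("  local match ", i, "/", nrow(centroids))
  }
  out <- greedy_place(lists, bank, cc$clash_fraction)
  ps <- out$placed
  attr(ps, "rejected") <- out$rejected
  attr(ps, "events") <- out$events
  ps
}

#' Merge a primary and a refined particle set
#'
#' Starts from the refined set, removes particles whose positions have
#' collapsed onto an earlier particle within `collapse_radius` (a known
#' refinement artifact), then restores primary-set particles that have no
#' counterpart within `match_radius` in the refined set, provided they
#' create no steric clash.
#'
#' @param primary,refined `particle_set`s in the same tomogram frame (a
#'   `frame` attribute, when present on both, must agree).
#' @param mask steric mask `tomo_volume`.
#' @param collapse_radius nm de-duplication radius.
#' @param match_radius nm counterpart-search radius.
#' @param clash_fraction mask-overlap fraction counting as a clash.
#' @return Merged `particle_set` with attribute `merge_log`.
#' @export
merge_assignments <- function(primary, refined, mask, collapse_radius = 2,
                              match_radius = 5.5, clash_fraction = 0.05) {
  fa <- attr(primary, "frame"); fb <- attr(refined, "frame")
  if (!is.null(fa) && !is.null(fb) && !identical(fa, fb))
    stop("frame mismatch between primary and refined particle sets")
  vs <- mask$voxel_size
  # 1. de-duplicate refined, keeping the first by listed order
  keep <- logical(nrow(refined))
  kept_pos <- matrix(numeric(0), 0, 3)
  for (i in seq_len(nrow(refined))) {
    p <- c(refined$x[i], refined$y[i], refined$z[i])
    if (nrow(kept_pos) == 0L ||
        min(sqrt(colSums((t(kept_pos) - p)^2))) >= collapse_radius) {
      keep[i] <- TRUE
      kept_pos <- rbind(kept_pos, p)
    }
  }
  merged <- refined[keep, , drop = FALSE]
  n_dropped <- sum(!keep)
  # occupancy of the kept refined particles
  mq <- quat_from_euler(merged$rot, merged$tilt, merged$psi)
  occ <- lapply(seq_len(nrow(merged)), function(i)
    placed_keys(rotated_mask_offsets(mask, mq[i, ]),
                c(merged$x[i], merged$y[i], merged$z[i]), vs))
  nmask <- sum(mask$data > 0.5)
  tol <- floor(clash_fraction * nmask)
  # 2. restore primary particles missing from refined
  restored <- 0L
  pq <- ps_quats(primary)
  for (i in seq_len(nrow(primary))) {
    p <- c(primary$x[i], primary$y[i], primary$z[i])
    if (nrow(merged) > 0 &&
        min(sqrt(colSums((t(ps_positions(merged)) - p)^2))) <= match_radius)
      next
    k <- placed_keys(rotated_mask_offsets(mask, pq[i, ]), p, vs)
    if (any(vapply(occ, function(ok) overlap_count(k, ok) > tol, TRUE)))
      next
    merged <- rbind(merged, primary[i, , drop = FALSE])
    occ <- c(occ, list(k))
    restored <- restored + 1L
  }
  merged <- as_particle_set(merged)
  attr(merged, "merge_log") <- list(overlaid_removed = n_dropped,
                                    restored_from_primary = restored)
  merged
}
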