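# Independent oracles used to check the fast implementations.

# Masked Pearson correlation of a bank entry with the tomogram at one
# voxel, by explicit summation (no FFTs).
brute_masked_ncc <- function(tomo, entry, voxel) {
  idx <- sweep(entry$offsets, 2, voxel, `+`)
  d <- dim(tomo$data)
  if (any(idx < 1) || any(idx[, 1] > d[1]) || any(idx[, 2] > d[2]) ||
      any(idx[, 3] > d[3])) return(NA_real_)
  f <- tomo$data[idx]
  if (stats::sd(f) == 0) return(0)
  stats::cor(f, entry$tvals)
}

# Exhaustive clash-free assignment maximizing summed CCC: each particle
# takes one of its candidates or is dropped.  Recursion with
# branch-and-bound pruning; exact for the micro-instances used in tests.
oracle_optimal_placement <- function(cand_lists, bank,
                                     clash_fraction = 0.05) {
  vs <- bank$voxel_size
  keys <- lapply(cand_lists, function(cl) {
    if (is.null(cl)) return(list())
    lapply(seq_len(nrow(cl)), function(i)
      catmtools:::placed_keys(bank$entries[[cl$orient[i]]]$offsets,
                              c(cl$x[i], cl$y[i], cl$z[i]), vs))
  })
  nmask <- lapply(cand_lists, function(cl) {
    if (is.null(cl)) return(integer())
    vapply(cl$orient, function(o) bank$entries[[o]]$n, 0L)
  })
  n <- length(cand_lists)
  pair_ok <- function(i, ci, j, cj) {
    tol <- floor(clash_fraction * min(nmask[[i]][ci], nmask[[j]][cj]))
    catmtools:::overlap_count(keys[[i]][[ci]], keys[[j]][[cj]]) <= tol
  }
  best_rest <- vapply(seq_len(n), function(i) {
    if (is.null(cand_lists[[i]])) 0 else max(cand_lists[[i]]$ccc)
  }, 0)
  suffix <- rev(cumsum(rev(best_rest)))
  best <- list(sum = -Inf, choice = NULL)
  recurse <- function(i, choice, total) {
    if (i > n) {
      if (total > best$sum) best <<- list(sum = total, choice = choice)
      return()
    }
    if (total + suffix[i] <= best$sum) return()
    opts <- if (is.null(cand_lists[[i]])) integer() else
      seq_len(nrow(cand_lists[[i]]))
    for (ci in opts) {
      ok <- TRUE
      for (j in seq_len(i - 1)) {
        if (choice[j] > 0 && !pair_ok(i, ci, j, choice[j])) {
          ok <- FALSE; break
        }
      }
      if (ok) recurse(i + 1, c(choice[seq_len(i - 1)], ci),
                      total + cand_lists[[i]]$ccc[ci])
    }
    recurse(i + 1, c(choice[seq_len(i - 1)], 0L), total)  # drop particle
  }
  recurse(1, integer(n), 0)
  best
}

# Independent DBSCAN: core points from the pairwise distance matrix,
# clusters as connected components of the core-core eps graph (igraph),
# border points attached to any adjacent core cluster.
oracle_dbscan <- function(P, eps, min_pts) {
  D <- as.matrix(stats::dist(P))
  n <- nrow(P)
  core <- rowSums(D <= eps) >= min_pts
  labels <- integer(n)
  if (any(core)) {
    A <- (D <= eps) & outer(core, core, `&`)
    diag(A) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(A[core, core, drop = FALSE],
                                             mode = "undirected")
    comp <- igraph::components(g)$membership
    labels[core] <- comp
    for (i in which(!core)) {
      nb <- which(D[i, ] <= eps & core)
      if (length(nb)) labels[i] <- labels[nb[1]]
    }
  }
  labels
}

# Partition equality up to label renaming (noise label 0 fixed).
same_partition <- function(a, b) {
  if (!identical(a == 0, b == 0)) return(FALSE)
  ok <- TRUE
  for (l in unique(a[a > 0])) {
    sel <- a == l
    ok <- ok && length(unique(b[sel])) == 1 && all(b[sel] > 0) &&
      all(a[b == b[which(sel)[1]]] == l)
  }
  ok
}
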