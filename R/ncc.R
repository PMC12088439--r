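# Locally normalized cross-correlation (masked NCC / FLCF) between a
# degraded template and a tomogram, computed with FFTs.  The template is
# rotated first, then degraded with the same missing wedge and CTF as the
# data (matched filtering against the forward model), restricted to its
# rotated steric mask, and standardized to zero mean / unit variance
# under that mask.  The score at voxel v is the Pearson correlation
# between the standardized template and the data voxels under the mask
# centred at v, in [-1, 1].
#
# Two real volumes ride in each complex FFT (packing trick); the
# Hermitian halves are separated in compiled code, so a full score map
# costs 3 FFTs per orientation plus single-pass elementwise kernels.

flip_index <- function(n) c(1L, if (n > 1L) n:2L)

# 1-based linear indices of -k for every k of a 3D spectrum.
make_flip_perm <- function(dims) {
  fx <- flip_index(dims[1]); fy <- flip_index(dims[2])
  fz <- flip_index(dims[3])
  as.integer(outer(outer(fx, (fy - 1L) * dims[1], `+`),
                   (fz - 1L) * dims[1] * dims[2], `+`))
}

conj_flip <- function(Z) {
  d <- dim(Z)
  Conj(Z[flip_index(d[1]), flip_index(d[2]), flip_index(d[3])])
}

# Packed transforms of the tomogram: F(f) and F(f^2).
tomo_transforms <- function(f, perm = NULL) {
  if (is.null(perm)) perm <- make_flip_perm(dim(f))
  Z <- stats::fft(array(pack_complex(f, f^2), dim(f)))
  sp <- hermitian_split(Z, perm)
  list(Ff = sp$a, Ff2 = sp$b, perm = perm,
       eps_sd = max(stats::sd(f), 0) * 1e-6 + 1e-300)
}

# Degrade a rotated template on a padded grid: missing wedge, CTF and
# optional Gaussian low-pass, all in the lab frame.
filter_template <- function(rot_data, voxel_size, model, pad = 48,
                            lowpass_nm = NULL, wedge = TRUE, ctf = TRUE) {
  nt <- dim(rot_data)[1]
  pad <- max(pad, nt)
  big <- array(0, rep(pad, 3))
  o <- floor((pad - nt) / 2)
  big[o + seq_len(nt), o + seq_len(nt), o + seq_len(nt)] <- rot_data
  H <- array(1, rep(pad, 3))
  if (wedge) H <- H * wedge_mask(rep(pad, 3), model$tilt_min, model$tilt_max)
  if (ctf) H <- H * ctf_array(rep(pad, 3), voxel_size, model)
  if (!is.null(lowpass_nm) && is.finite(lowpass_nm)) {
    k <- fft_freqs(pad, voxel_size)
    k2 <- outer(outer(k^2, k^2, `+`), k^2, `+`)
    H <- H * exp(-k2 * lowpass_nm^2 / 2)
  }
  out <- fft_inv_real(stats::fft(big) * H)
  out[o + seq_len(nt), o + seq_len(nt), o + seq_len(nt)]
}

#' Precompute a bank of rotated, degraded, standardized templates
#'
#' One entry per orientation of `grid`: the rotated steric mask (as voxel
#' offsets from the template centre) and the degraded template values
#' standardized under that mask.
#'
#' @param template a cubic `tomo_volume` template.
#' @param grid a [rotation_grid()].
#' @param model an [imaging_model()]; its tilt range and optics degrade the
#'   template exactly as the data.
#' @param mask_threshold steric-mask threshold fraction.
#' @param lowpass_nm optional Gaussian low-pass (nm) matching a low-passed
#'   tomogram.
#' @param wedge,ctf logical; apply the wedge / CTF to the template.
#' @return An `orientation_bank` list.
#' @export
build_orientation_bank <- function(template, grid, model,
                                   mask_threshold = 0.5,
                                   lowpass_nm = NULL,
                                   wedge = TRUE, ctf = TRUE) {
  mask0 <- build_steric_mask(template, mask_threshold)
  nq <- nrow(grid$quats)
  entries <- vector("list", nq)
  for (o in seq_len(nq)) {
    q <- grid$quats[o, ]
    rot <- rotate_volume(template, q)
    rmask <- rotate_volume(mask0, q)
    filt <- filter_template(rot$data, template$voxel_size, model,
                            lowpass_nm = lowpass_nm,
                            wedge = wedge, ctf = ctf)
    sel <- which(rmask$data >= 0.5, arr.ind = TRUE)
    vals <- filt[sel]
    mu <- mean(vals)
    sdv <- sqrt(mean((vals - mu)^2))   # population sd: sum(tvals^2) = n
    if (!is.finite(sdv) || sdv <= 0)
      stop("degenerate template after filtering (orientation ", o, ")")
    d <- dim(template$data)
    ctr <- (d + 1) / 2
    entries[[o]] <- list(
      quat = q,
      offsets = sweep(sel, 2, ctr),            # integer voxel offsets
      tvals = (vals - mu) / sdv,               # zero mean, unit sd on mask
      n = length(vals))
  }
  structure(list(entries = entries, grid = grid, model = model,
                 voxel_size = template$voxel_size,
                 template_dim = dim(template$data)[1],
                 mask_threshold = mask_threshold,
                 lowpass_nm = lowpass_nm),
            class = "orientation_bank")
}

# Place offset/value pairs into a zero array of size `dims` centred at the
# origin voxel with wraparound (correlation convention).
pad_wrap <- function(offsets, values, dims) {
  idx <- sweep(offsets, 2, dims, function(o, n) (o %% n) + 1)
  arr <- array(0, dims)
  arr[idx] <- values
  arr
}

# Masked-NCC score map for one bank entry given the tomogram transforms.
ncc_map_entry <- function(tt, entry, dims) {
  tpad <- pad_wrap(entry$offsets, entry$tvals, dims)
  mpad <- pad_wrap(entry$offsets, rep(1, entry$n), dims)
  Z <- stats::fft(array(pack_complex(tpad, mpad), dims))
  sp <- hermitian_split(Z, tt$perm)
  pr <- spectrum_products(tt$Ff, tt$Ff2, sp$a, sp$b)
  W <- stats::fft(array(pr$Q1, dims), inverse = TRUE)
  C2 <- stats::fft(array(pr$Q2, dims), inverse = TRUE)
  array(ncc_combine(W, C2, prod(dims), entry$n, tt$eps_sd), dims)
}

#' Score map of one template orientation against a tomogram
#'
#' Per-voxel locally normalized cross-correlation of the rotated,
#' wedge/CTF-degraded template with the tomogram (template centre at each
#' voxel).  Zero-variance neighbourhoods score 0.
#'
#' @param tomogram a `tomo_volume`.
#' @param template a cubic `tomo_volume` template (smaller than the
#'   tomogram).
#' @param q orientation quaternion (length 4).
#' @param model an [imaging_model()].
#' @param mask_threshold,lowpass_nm,wedge,ctf passed to
#'   [build_orientation_bank()].
#' @return A `tomo_volume` of CCC values in `[-1, 1]`.
#' @export
ncc_score_map <- function(tomogram, template, q, model,
                          mask_threshold = 0.5, lowpass_nm = NULL,
                          wedge = TRUE, ctf = TRUE) {
  stopifnot(is_volume(tomogram), is_volume(template))
  if (any(dim(template$data) > dim(tomogram$data)))
    stop("template must be smaller than the tomogram")
  grid1 <- list(quats = rbind(as.numeric(q)), step_deg = NA, mode = "single")
  bank <- build_orientation_bank(template, grid1, model, mask_threshold,
                                 lowpass_nm, wedge, ctf)
  dims <- dim(tomogram$data)
  tt <- tomo_transforms(tomogram$data)
  m <- ncc_map_entry(tt, bank$entries[[1]], dims)
  volume(m, tomogram$voxel_size, tomogram$origin)
}

# Streamed orientation search: per-voxel best score and best orientation
# index over all bank entries.
score_stream <- function(tomogram, bank, progress = FALSE) {
  dims <- dim(tomogram$data)
  tt <- tomo_transforms(tomogram$data)
  best <- array(-Inf, dims)
  borient <- array(0L, dims)
  for (o in seq_along(bank$entries)) {
    m <- ncc_map_entry(tt, bank$entries[[o]], dims)
    best_update(best, borient, m, o)
    if (progress && o %% 10 == 0)
      message("  orientation ", o, "/", length(bank$entries))
  }
  list(best = best, orient = borient)
}

# 26-neighbourhood local maxima (greater than or equal to all
# neighbours, above `floor`); border voxels excluded.
local_maxima_3d <- function(arr, floor_value) {
  d <- dim(arr)
  core <- function(a) a[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)]
  ok <- core(arr) >= floor_value
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    nb <- arr[(2 + dx):(d[1] - 1 + dx), (2 + dy):(d[2] - 1 + dy),
              (2 + dz):(d[3] - 1 + dz)]
    ok <- ok & (core(arr) >= nb)
    if (!any(ok)) break
  }
  w <- which(ok, arr.ind = TRUE)
  w + 1L  # back to full-array indices
}
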