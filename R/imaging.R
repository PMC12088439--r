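# Forward degradation model for tomograms: missing wedge (a Fourier-space
# projection onto the sampled tilt fan, tilt axis = y), phase-contrast CTF,
# and additive white Gaussian noise at a stated SNR.

#' Imaging model for the tomogram forward simulation
#'
#' @param tilt_min,tilt_max stage tilt range, degrees (beam along z at 0).
#' @param defocus_um defocus in micrometres (positive = underfocus).
#' @param voltage_kv acceleration voltage, kV.
#' @param cs_mm spherical aberration, mm.
#' @param amplitude_contrast amplitude-contrast fraction in [0, 1].
#' @param snr signal-to-noise ratio (signal variance / noise variance).
#' @param seed integer seed for the noise field.
#' @return An `imaging_model` list.
#' @export
imaging_model <- function(tilt_min = -60, tilt_max = 60, defocus_um = 4,
                          voltage_kv = 300, cs_mm = 2.7,
                          amplitude_contrast = 0.07, snr = 1,
                          seed = 1L) {
  if (!(tilt_min >= -90 && tilt_min < tilt_max && tilt_max <= 90))
    stop("require -90 <= tilt_min < tilt_max <= 90")
  if (snr <= 0) stop("snr must be positive")
  if (amplitude_contrast < 0 || amplitude_contrast > 1)
    stop("amplitude_contrast must be in [0, 1]")
  structure(list(tilt_min = tilt_min, tilt_max = tilt_max,
                 defocus_um = defocus_um, voltage_kv = voltage_kv,
                 cs_mm = cs_mm, amplitude_contrast = amplitude_contrast,
                 snr = snr, seed = as.integer(seed)),
            class = "imaging_model")
}

# FFT sample frequencies along one axis, cycles/nm.
fft_freqs <- function(n, voxel_size) {
  k <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1))
  k / (n * voxel_size)
}

fft_inv_real <- function(F) Re(stats::fft(F, inverse = TRUE)) / length(F)

#' Fourier mask of the sampled tilt fan
#'
#' 1 where the direction of (kx, kz) lies inside the tilt fan (tilt axis =
#' y), 0 in the missing wedge.  The DC column kx = kz = 0 is retained.
#'
#' @param dims volume dimensions.
#' @param tilt_min,tilt_max tilt range in degrees.
#' @return 3D 0/1 array.
#' @export
wedge_mask <- function(dims, tilt_min = -60, tilt_max = 60) {
  kx <- fft_freqs(dims[1], 1)
  kz <- fft_freqs(dims[3], 1)
  psi <- atan2(rep(kz, each = length(kx)), rep(kx, length(kz))) * 180 / pi
  # (kx, kz) and -(kx, kz) are the same sampled line
  keep <- (psi >= tilt_min & psi <= tilt_max) |
    (psi - 180 >= tilt_min & psi - 180 <= tilt_max) |
    (psi + 180 >= tilt_min & psi + 180 <= tilt_max) |
    (rep(kx == 0, length(kz)) & rep(kz == 0, each = length(kx)))
  keep_xz <- matrix(as.numeric(keep), length(kx), length(kz))
  aperm(array(rep(keep_xz, dims[2]), dim = c(dims[1], dims[3], dims[2])),
        c(1, 3, 2))
}

#' Apply the missing wedge to a volume
#'
#' Zeroes Fourier coefficients outside the sampled tilt fan; an idempotent
#' linear projection.  Tilt range of (-90, 90) is the identity.
#'
#' @param v a `tomo_volume`.
#' @param tilt_min,tilt_max tilt range in degrees.
#' @return Filtered `tomo_volume` (real-valued).
#' @export
apply_missing_wedge <- function(v, tilt_min = -60, tilt_max = 60) {
  stopifnot(is_volume(v))
  if (!(tilt_min >= -90 && tilt_min < tilt_max && tilt_max <= 90))
    stop("require -90 <= tilt_min < tilt_max <= 90")
  W <- wedge_mask(dim(v$data), tilt_min, tilt_max)
  out <- fft_inv_real(stats::fft(v$data) * W)
  volume(array(out, dim(v$data)), v$voxel_size, v$origin)
}

#' Relativistic electron wavelength
#' @param voltage_kv acceleration voltage in kV.
#' @return wavelength in nm.
#' @export
electron_wavelength <- function(voltage_kv) {
  V <- voltage_kv * 1000
  1.226426 / sqrt(V * (1 + 0.97845e-6 * V)) # nm
}

#' Phase-contrast transfer function
#'
#' `CTF(k) = -(sqrt(1 - A^2) sin(chi) + A cos(chi))` with aberration phase
#' `chi(k) = pi lambda df k^2 - (pi/2) Cs lambda^3 k^4` (df > 0 =
#' underfocus).  `CTF(0) = -A`: low frequencies carry inverted contrast.
#'
#' @param k spatial frequency, cycles/nm (vector).
#' @param model an [imaging_model()].
#' @return CTF values in [-1, 1].
#' @export
ctf_value <- function(k, model) {
  lambda <- electron_wavelength(model$voltage_kv)
  df <- model$defocus_um * 1e3        # nm
  cs <- model$cs_mm * 1e6             # nm
  chi <- pi * lambda * df * k^2 - (pi / 2) * cs * lambda^3 * k^4
  A <- model$amplitude_contrast
  -(sqrt(1 - A^2) * sin(chi) + A * cos(chi))
}

ctf_array <- function(dims, voxel_size, model) {
  kx <- fft_freqs(dims[1], voxel_size)
  ky <- fft_freqs(dims[2], voxel_size)
  kz <- fft_freqs(dims[3], voxel_size)
  k2 <- outer(outer(kx^2, ky^2, `+`), kz^2, `+`)
  array(ctf_value(sqrt(k2), model), dims)
}

#' Apply CTF modulation to a volume
#'
#' Multiplies the Fourier transform by the radially symmetric
#' [ctf_value()] transfer function.
#'
#' @param v a `tomo_volume`.
#' @param model an [imaging_model()].
#' @return Modulated `tomo_volume`.
#' @export
apply_ctf <- function(v, model) {
  stopifnot(is_volume(v))
  H <- ctf_array(dim(v$data), v$voxel_size, model)
  out <- fft_inv_real(stats::fft(v$data) * H)
  volume(array(out, dim(v$data)), v$voxel_size, v$origin)
}

#' Add white Gaussian noise at a given SNR
#'
#' Noise variance is `var(v) / snr`.  `snr = Inf` returns the input.
#'
#' @param v a `tomo_volume`.
#' @param snr signal variance / noise variance, > 0.
#' @param seed integer seed.
#' @return Noisy `tomo_volume`.
#' @export
add_noise <- function(v, snr, seed = 1L) {
  stopifnot(is_volume(v))
  if (snr <= 0) stop("snr must be positive")
  if (is.infinite(snr)) return(v)
  s2 <- stats::var(as.vector(v$data))
  if (s2 <= 0) stop("zero signal variance: cannot set noise level")
  old <- .Random.seed_safe()
  set.seed(seed)
  noise <- stats::rnorm(length(v$data), sd = sqrt(s2 / snr))
  .Random.seed_restore(old)
  volume(v$data + array(noise, dim(v$data)), v$voxel_size, v$origin)
}

#' Gaussian low-pass filter
#'
#' Attenuates the spectrum by `exp(-(k * resolution_nm)^2 / 2)`; the
#' amplitude at `k = 1/resolution_nm` is `exp(-1/2)`.
#'
#' @param v a `tomo_volume`.
#' @param resolution_nm nominal resolution (nm); `Inf`/`NULL` = no-op.
#' @return Filtered `tomo_volume`.
#' @export
lowpass_volume <- function(v, resolution_nm) {
  stopifnot(is_volume(v))
  if (is.null(resolution_nm) || !is.finite(resolution_nm)) return(v)
  d <- dim(v$data)
  kx <- fft_freqs(d[1], v$voxel_size)
  ky <- fft_freqs(d[2], v$voxel_size)
  kz <- fft_freqs(d[3], v$voxel_size)
  k2 <- outer(outer(kx^2, ky^2, `+`), kz^2, `+`)
  G <- array(exp(-k2 * resolution_nm^2 / 2), d)
  out <- fft_inv_real(stats::fft(v$data) * G)
  volume(array(out, d), v$voxel_size, v$origin)
}

# Save/restore the global RNG state so seeded helpers do not perturb the
# caller's random stream.
.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
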