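# Parametric particle templates.  The nucleosome is modelled as a soft-edged
# cylinder ("flattened disc", 11 x 5.5 nm by default); free DNA as a thin
# soft-edged rod 2 nm across.  Both have their symmetry axis along local z
# and are centred in a cubic grid whose centre voxel sits at the origin.

#' Particle shape description
#'
#' @param kind `"nucleosome_disc"` or `"dna_rod"`.
#' @param diameter disc or rod diameter, nm.
#' @param height_or_length disc height or rod length, nm.
#' @param density_amplitude peak density value (arbitrary units).
#' @return A `particle_shape` list.
#' @export
particle_shape <- function(kind = c("nucleosome_disc", "dna_rod"),
                           diameter = if (kind == "dna_rod") 2 else 11,
                           height_or_length = if (kind == "dna_rod") 10 else 5.5,
                           density_amplitude = 1) {
  kind <- match.arg(kind)
  if (diameter <= 0) stop("diameter must be positive")
  if (height_or_length <= 0) stop("height_or_length must be positive")
  structure(list(kind = kind, diameter = diameter,
                 height_or_length = height_or_length,
                 density_amplitude = density_amplitude),
            class = "particle_shape")
}

# 1-voxel cosine taper centred on the nominal boundary: 1 half a voxel
# inside, 0 half a voxel outside, exactly 1/2 on the boundary (so the
# half-maximum steric mask recovers the nominal shape).
soft_edge <- function(t, edge) {
  u <- pmin(1, pmax(0, t / edge + 0.5))
  0.5 * (1 + cos(pi * u))
}

template_grid <- function(half_extent_nm, voxel_size) {
  nhalf <- ceiling((half_extent_nm + 1.5 * voxel_size) / voxel_size)
  n <- 2L * nhalf + 1L
  coords <- (seq_len(n) - nhalf - 1) * voxel_size
  list(n = n, coords = coords, origin = rep(coords[1], 3))
}

build_cylinder <- function(radius, half_height, amplitude, voxel_size,
                           half_extent) {
  g <- template_grid(half_extent, voxel_size)
  r <- sqrt(outer(g$coords^2, g$coords^2, `+`))        # in-plane radius
  rad_w <- soft_edge(r - radius, voxel_size)
  ax_w <- soft_edge(abs(g$coords) - half_height, voxel_size)
  dat <- array(0, dim = rep(g$n, 3))
  for (k in seq_len(g$n)) dat[, , k] <- amplitude * rad_w * ax_w[k]
  volume(dat, voxel_size = voxel_size, origin = g$origin)
}

#' Build a parametric nucleosome disc template
#'
#' Soft-edged cylinder density of the given diameter and height, axis along
#' local z, centred in a cubic grid.
#'
#' @param shape a [particle_shape()] of kind `"nucleosome_disc"`.
#' @param voxel_size nm per voxel; must resolve the disc
#'   (`voxel_size <= diameter / 4`).
#' @return A `tomo_volume` template.
#' @export
build_nucleosome_template <- function(shape = particle_shape(),
                                      voxel_size = 1) {
  if (shape$kind != "nucleosome_disc")
    stop("shape kind must be nucleosome_disc")
  if (voxel_size > shape$diameter / 4)
    stop("template under-resolved: voxel_size must be <= diameter/4")
  build_cylinder(shape$diameter / 2, shape$height_or_length / 2,
                 shape$density_amplitude, voxel_size,
                 half_extent = max(shape$diameter,
                                   shape$height_or_length) / 2)
}

#' Build a straight DNA rod template
#'
#' Soft-edged rod of the given length along local z, 2 nm in diameter by
#' default.
#'
#' @param shape a [particle_shape()] of kind `"dna_rod"`; `height_or_length`
#'   is the rod length.
#' @param voxel_size nm per voxel; must be `<= diameter / 2` for a rod.
#' @return A `tomo_volume` template.
#' @export
build_dna_template <- function(shape = particle_shape("dna_rod"),
                               voxel_size = 1) {
  if (shape$kind != "dna_rod") stop("shape kind must be dna_rod")
  if (voxel_size > shape$diameter / 2)
    stop("template under-resolved: voxel_size too coarse for rod diameter")
  build_cylinder(shape$diameter / 2, shape$height_or_length / 2,
                 shape$density_amplitude, voxel_size,
                 half_extent = max(shape$diameter,
                                   shape$height_or_length) / 2)
}

#' Binary steric mask of a template
#'
#' Voxels at or above `threshold_fraction` of the template maximum.  Used
#' for clash tests and contact criteria; voxel centres inside the mask are
#' treated as occupied (half-sample convention).
#'
#' @param template a `tomo_volume`.
#' @param threshold_fraction in (0, 1); default 0.5.
#' @return A `tomo_volume` with 0/1 data.
#' @export
build_steric_mask <- function(template, threshold_fraction = 0.5) {
  stopifnot(is_volume(template))
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("threshold_fraction must be in (0, 1)")
  thr <- threshold_fraction * max(template$data)
  m <- array(as.numeric(template$data >= thr), dim = dim(template$data))
  if (sum(m) == 0) stop("empty steric mask")
  volume(m, voxel_size = template$voxel_size, origin = template$origin)
}

# ---- resampling ------------------------------------------------------------

# Trilinear interpolation of a 3D array at fractional 1-based indices;
# points outside the grid evaluate to `fill`.
trilinear_sample <- function(arr, idx, fill = 0) {
  d <- dim(arr)
  i0 <- floor(idx)
  f <- idx - i0
  val <- numeric(nrow(idx))
  ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
        idx[, 2] >= 1 & idx[, 2] <= d[2] &
        idx[, 3] >= 1 & idx[, 3] <= d[3]
  if (!any(ok)) return(val)
  i0 <- i0[ok, , drop = FALSE]
  fr <- f[ok, , drop = FALSE]
  # clamp the upper corner so edge points stay in range
  i1 <- pmin(i0 + 1L, matrix(d, nrow(i0), 3, byrow = TRUE))
  i0 <- pmax(i0, 1L)
  at <- function(ix, iy, iz) arr[cbind(ix, iy, iz)]
  fx <- fr[, 1]; fy <- fr[, 2]; fz <- fr[, 3]
  v <-
    at(i0[, 1], i0[, 2], i0[, 3]) * (1 - fx) * (1 - fy) * (1 - fz) +
    at(i1[, 1], i0[, 2], i0[, 3]) * fx * (1 - fy) * (1 - fz) +
    at(i0[, 1], i1[, 2], i0[, 3]) * (1 - fx) * fy * (1 - fz) +
    at(i1[, 1], i1[, 2], i0[, 3]) * fx * fy * (1 - fz) +
    at(i0[, 1], i0[, 2], i1[, 3]) * (1 - fx) * (1 - fy) * fz +
    at(i1[, 1], i0[, 2], i1[, 3]) * fx * (1 - fy) * fz +
    at(i0[, 1], i1[, 2], i1[, 3]) * (1 - fx) * fy * fz +
    at(i1[, 1], i1[, 2], i1[, 3]) * fx * fy * fz
  val[ok] <- v
  val
}

#' Rotate a template volume about its grid centre
#'
#' Resamples `v` under the rotation `q` (template frame to world frame) by
#' trilinear interpolation; voxels mapped from outside the grid are zero.
#'
#' @param v a cubic `tomo_volume` template.
#' @param q length-4 (or 1 x 4) unit quaternion.
#' @return A `tomo_volume` of the same dimensions.
#' @export
rotate_volume <- function(v, q) {
  stopifnot(is_volume(v))
  d <- dim(v$data)
  ctr <- (d + 1) / 2
  R <- quat_rotmat(as.numeric(q))
  g <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                             z = seq_len(d[3])))
  rel <- sweep(g, 2, ctr)
  src <- rel %*% R + matrix(ctr, nrow(rel), 3, byrow = TRUE)  # R^-1 x = x R
  out <- trilinear_sample(v$data, src)
  volume(array(out, dim = d), voxel_size = v$voxel_size, origin = v$origin)
}

#' Rasterize an atomic model into a density template
#'
#' Gaussian-per-atom rasterization for users who prefer a structure-derived
#' template over the parametric disc.  Coordinates are centred before
#' rasterization.
#'
#' @param coords n x 3 matrix of atom coordinates, nm.
#' @param voxel_size nm per voxel.
#' @param sigma Gaussian width per atom, nm.
#' @param weights per-atom weights (default 1).
#' @return A `tomo_volume` template.
#' @export
rasterize_atoms <- function(coords, voxel_size = 1, sigma = 0.5,
                            weights = NULL) {
  coords <- rbind(coords)
  if (is.null(weights)) weights <- rep(1, nrow(coords))
  coords <- sweep(coords, 2, colMeans(coords))
  half <- max(abs(coords)) + 3 * sigma
  g <- template_grid(half, voxel_size)
  dat <- array(0, rep(g$n, 3))
  for (a in seq_len(nrow(coords))) {
    gx <- exp(-((g$coords - coords[a, 1])^2) / (2 * sigma^2))
    gy <- exp(-((g$coords - coords[a, 2])^2) / (2 * sigma^2))
    gz <- exp(-((g$coords - coords[a, 3])^2) / (2 * sigma^2))
    dat <- dat + weights[a] * (outer(outer(gx, gy), gz))
  }
  volume(dat, voxel_size = voxel_size, origin = g$origin)
}
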