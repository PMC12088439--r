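# Orientations are proper rotations, stored as unit quaternions (w, x, y, z),
# one per row of a 4-column matrix.  At I/O boundaries they are expressed as
# ZYZ Euler angles in degrees: R = Rz(rot) %*% Ry(tilt) %*% Rz(psi), the
# rotation that carries the template frame into the tomogram frame.  The disc
# normal is the rotated z axis, R %*% c(0,0,1), which is independent of psi.

#' Quaternion from ZYZ Euler angles (degrees)
#'
#' @param rot,tilt,psi Euler angles in degrees; vectors are recycled to a
#'   common length.
#' @return n x 4 matrix of unit quaternions (w, x, y, z).
#' @export
quat_from_euler <- function(rot, tilt, psi) {
  n <- max(length(rot), length(tilt), length(psi))
  a <- rep_len(rot, n) * pi / 180
  b <- rep_len(tilt, n) * pi / 180
  g <- rep_len(psi, n) * pi / 180
  qa <- cbind(cos(a / 2), 0, 0, sin(a / 2))
  qb <- cbind(cos(b / 2), 0, sin(b / 2), 0)
  qg <- cbind(cos(g / 2), 0, 0, sin(g / 2))
  quat_multiply(quat_multiply(qa, qb), qg)
}

#' ZYZ Euler angles (degrees) from quaternions
#'
#' At the gimbal degeneracy (tilt near 0 or 180 degrees) psi is set to 0 and
#' the full in-plane angle is carried by rot.
#'
#' @param q n x 4 quaternion matrix (rows need not be exactly unit norm).
#' @return data.frame with columns `rot`, `tilt`, `psi` in degrees.
#' @export
quat_to_euler <- function(q) {
  q <- quat_canonical(q)
  out <- matrix(0, nrow(q), 3)
  for (i in seq_len(nrow(q))) {
    R <- quat_rotmat(q[i, ])
    c33 <- max(-1, min(1, R[3, 3]))
    tilt <- acos(c33)
    if (sin(tilt) > 1e-9) {
      rot <- atan2(R[2, 3], R[1, 3])
      psi <- atan2(R[3, 2], -R[3, 1])
    } else {
      # Rz(rot +/- psi) only is determined
      rot <- atan2(R[2, 1], R[1, 1]) * sign(c33)
      psi <- 0
    }
    out[i, ] <- c(rot, tilt, psi) * 180 / pi
  }
  data.frame(rot = out[, 1], tilt = out[, 2], psi = out[, 3])
}

#' Quaternion (Hamilton) product, rowwise
#' @param a,b n x 4 quaternion matrices (recycled rowwise if needed).
#' @return n x 4 matrix.
#' @export
quat_multiply <- function(a, b) {
  a <- rbind(a); b <- rbind(b)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) < n) a <- a[rep_len(seq_len(nrow(a)), n), , drop = FALSE]
  if (nrow(b) < n) b <- b[rep_len(seq_len(nrow(b)), n), , drop = FALSE]
  w <- a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4]
  x <- a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3]
  y <- a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2]
  z <- a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1]
  cbind(w, x, y, z, deparse.level = 0)
}

quat_conjugate <- function(q) {
  q <- rbind(q)
  cbind(q[, 1], -q[, 2], -q[, 3], -q[, 4], deparse.level = 0)
}

quat_canonical <- function(q) {
  q <- rbind(q)
  q <- q / sqrt(rowSums(q^2))
  flip <- q[, 1] < 0
  q[flip, ] <- -q[flip, , drop = FALSE]
  q
}

#' Rotation matrix of a single quaternion
#' @param q length-4 unit quaternion.
#' @return 3 x 3 rotation matrix.
#' @export
quat_rotmat <- function(q) {
  q <- as.numeric(q) / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Quaternion from axis and angle
#' @param axis length-3 vector (normalized internally).
#' @param angle_deg rotation angle in degrees.
#' @return 1 x 4 quaternion matrix.
#' @export
quat_from_axis_angle <- function(axis, angle_deg) {
  a <- angle_deg * pi / 180
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-12) return(matrix(c(1, 0, 0, 0), 1))
  axis <- axis / nrm
  matrix(c(cos(a / 2), sin(a / 2) * axis), 1)
}

#' Uniform random rotations
#' @param n number of rotations.
#' @return n x 4 quaternion matrix drawn uniformly from SO(3).
#' @export
quat_random <- function(n) {
  q <- matrix(stats::rnorm(4 * n), n, 4)
  quat_canonical(q)
}

#' Rotated z axis (disc normal) of each quaternion
#' @param q n x 4 quaternion matrix.
#' @return n x 3 matrix of unit normals.
#' @export
quat_normal <- function(q) {
  q <- rbind(q)
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  s <- rowSums(q^2)
  cbind(2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)) / s
}

#' Geodesic distance between rotations, degrees
#' @param a,b quaternion matrices (rowwise, recycled).
#' @return rotation angle of `a^-1 b` in degrees, in `[0, 180]`.
#' @export
quat_geodesic <- function(a, b) {
  a <- quat_canonical(a); b <- quat_canonical(b)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) < n) a <- a[rep_len(seq_len(nrow(a)), n), , drop = FALSE]
  if (nrow(b) < n) b <- b[rep_len(seq_len(nrow(b)), n), , drop = FALSE]
  d <- abs(rowSums(a * b))
  2 * acos(pmin(1, d)) * 180 / pi
}

#' Quaternion rotating the z axis onto a given direction
#' @param n n x 3 matrix of directions (normalized internally).
#' @return n x 4 quaternion matrix with zero in-plane angle.
#' @export
quat_from_normal <- function(n) {
  n <- rbind(n)
  n <- n / sqrt(rowSums(n^2))
  out <- matrix(0, nrow(n), 4)
  for (i in seq_len(nrow(n))) {
    v <- n[i, ]
    if (v[3] > 1 - 1e-12) {
      out[i, ] <- c(1, 0, 0, 0)
    } else if (v[3] < -1 + 1e-12) {
      out[i, ] <- c(0, 1, 0, 0)   # 180 deg about x
    } else {
      axis <- c(-v[2], v[1], 0)   # z x v
      ang <- acos(max(-1, min(1, v[3]))) * 180 / pi
      out[i, ] <- quat_from_axis_angle(axis, ang)
    }
  }
  out
}

#' Angle between a disc normal and a fixed axis
#'
#' Antipodal-invariant: `acos(|normal . axis|)`, in `[0, 90]` degrees.
#'
#' @param q n x 4 quaternion matrix (the particle orientations).
#' @param axis unit 3-vector (defaults to the beam direction z).
#' @return numeric vector of angles in degrees.
#' @export
angle_to_axis <- function(q, axis = c(0, 0, 1)) {
  nrm <- sqrt(sum(axis^2))
  if (abs(nrm - 1) > 1e-6) stop("axis must be a unit vector")
  nn <- quat_normal(q)
  acos(pmin(1, abs(nn %*% axis))) * 180 / pi
}

#' Angle between disc normals and per-particle surface normals
#'
#' @param q n x 4 quaternion matrix.
#' @param normals n x 3 matrix of unit surface normals (rows recycled).
#' @return angles in degrees in `[0, 90]`, antipodal-invariant.
#' @export
angle_to_interface <- function(q, normals) {
  q <- rbind(q); normals <- rbind(normals)
  n <- max(nrow(q), nrow(normals))
  if (nrow(normals) < n)
    normals <- normals[rep_len(seq_len(nrow(normals)), n), , drop = FALSE]
  normals <- normals / sqrt(rowSums(normals^2))
  nn <- quat_normal(q)
  acos(pmin(1, abs(rowSums(nn * normals)))) * 180 / pi
}

# ---- rotation grids --------------------------------------------------------

fibonacci_hemisphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- i / n
  phi <- 2 * pi * i * (sqrt(5) - 1) / 2
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Max over a dense probe set of the (antipodal) angle to the nearest grid
# direction, in degrees.
covering_radius <- function(dirs, probes = 4000) {
  p <- fibonacci_hemisphere(probes)
  d <- abs(p %*% t(dirs))
  max(acos(pmin(1, apply(d, 1, max)))) * 180 / pi
}

#' Orientation search grid
#'
#' For the in-plane-symmetric disc template (`mode = "disc"`) the grid
#' samples disc-normal directions on the hemisphere (antipodal directions
#' are equivalent) so that no direction is further than `step_deg` from a
#' grid point.  `mode = "so3"` additionally samples the in-plane angle in
#' steps of `step_deg` for asymmetric templates.
#'
#' @param step_deg angular step in degrees (maximum covering radius).
#' @param mode `"disc"` (default) or `"so3"`.
#' @return list with `quats` (n x 4), `dirs` (n x 3 for disc mode),
#'   `step_deg`, `mode`.
#' @export
rotation_grid <- function(step_deg = 15, mode = c("disc", "so3")) {
  mode <- match.arg(mode)
  if (step_deg <= 0 || step_deg > 90) stop("step_deg must be in (0, 90]")
  sr <- step_deg * pi / 180
  n <- max(4L, ceiling(1.9 / (1 - cos(sr))))
  dirs <- fibonacci_hemisphere(n)
  while (covering_radius(dirs) > step_deg) {
    n <- ceiling(n * 1.25)
    dirs <- fibonacci_hemisphere(n)
  }
  quats <- quat_from_normal(dirs)
  if (mode == "so3") {
    psis <- seq(0, 360 - step_deg, by = step_deg)
    qp <- quat_from_euler(0, 0, psis)
    quats <- do.call(rbind, lapply(seq_len(nrow(quats)), function(i)
      quat_multiply(quats[rep(i, nrow(qp)), , drop = FALSE], qp)))
    dirs <- dirs[rep(seq_len(n), each = nrow(qp)), , drop = FALSE]
  }
  list(quats = quats, dirs = dirs, step_deg = step_deg, mode = mode)
}
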