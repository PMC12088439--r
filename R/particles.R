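# Particle tables.  A particle_set is a data.frame with one row per
# particle: position in nm, orientation as ZYZ Euler angles in degrees,
# a matching score, a particle kind and an optional class label.

#' Construct a particle set
#'
#' @param x,y,z positions in nm.
#' @param rot,tilt,psi ZYZ Euler angles, degrees.
#' @param score per-particle score (e.g. CCC); NA if unknown.
#' @param kind particle species (default `"nucleosome"`).
#' @param class_label optional class attribute (e.g. subtomogram class).
#' @param id particle identifiers (default 1..n).
#' @return A `particle_set` data.frame.
#' @export
particle_set <- function(x = numeric(), y = numeric(), z = numeric(),
                         rot = 0, tilt = 0, psi = 0, score = NA_real_,
                         kind = "nucleosome", class_label = NA,
                         id = NULL) {
  n <- length(x)
  if (length(y) == 1L) y <- rep_len(y, n)
  if (length(z) == 1L) z <- rep_len(z, n)
  if (length(y) != n || length(z) != n) stop("x, y, z lengths differ")
  if (is.null(id)) id <- seq_len(n)
  df <- data.frame(id = id, x = x, y = y, z = z,
                   rot = rep_len(rot, n), tilt = rep_len(tilt, n),
                   psi = rep_len(psi, n), score = rep_len(score, n),
                   kind = rep_len(kind, n),
                   class_label = rep_len(class_label, n),
                   stringsAsFactors = FALSE)
  class(df) <- c("particle_set", "data.frame")
  df
}

as_particle_set <- function(df) {
  class(df) <- c("particle_set", "data.frame")
  df
}

#' Positions of a particle set as an n x 3 matrix (nm)
#' @param ps a `particle_set`.
#' @return n x 3 numeric matrix.
#' @export
ps_positions <- function(ps) cbind(ps$x, ps$y, ps$z)

#' Orientations of a particle set as quaternions
#' @param ps a `particle_set`.
#' @return n x 4 quaternion matrix.
#' @export
ps_quats <- function(ps) quat_from_euler(ps$rot, ps$tilt, ps$psi)

# ---- STAR / CSV I/O --------------------------------------------------------
# STAR (loose Relion dialect): coordinates in voxels, ZYZ Euler angles in
# degrees, score in _rlnAutopickFigureOfMerit.  CSV: positions in nm.

star_cols <- c(x = "_rlnCoordinateX", y = "_rlnCoordinateY",
               z = "_rlnCoordinateZ", rot = "_rlnAngleRot",
               tilt = "_rlnAngleTilt", psi = "_rlnAnglePsi",
               score = "_rlnAutopickFigureOfMerit",
               class_label = "_rlnClassNumber")

#' Write particles as a STAR file
#'
#' Coordinates are written in voxel units (`position_nm / voxel_size`).
#'
#' @param ps a `particle_set`.
#' @param path output path.
#' @param voxel_size nm per voxel of the reference tomogram.
#' @return `path`, invisibly.
#' @export
write_star_particles <- function(ps, path, voxel_size = 1) {
  lines <- c("", "data_particles", "", "loop_",
             paste0(star_cols[c("x", "y", "z", "rot", "tilt", "psi",
                                "score")], " #", 1:7))
  vals <- cbind(ps$x, ps$y, ps$z) / voxel_size
  rows <- sprintf("%.6f %.6f %.6f %.6f %.6f %.6f %.6f",
                  vals[, 1], vals[, 2], vals[, 3],
                  ps$rot, ps$tilt, ps$psi,
                  ifelse(is.na(ps$score), 0, ps$score))
  writeLines(c(lines, rows), path)
  invisible(path)
}

#' Read particles from a STAR file
#'
#' @param path STAR file with a `loop_` of `_rlnCoordinateX/Y/Z` (voxels)
#'   and optionally ZYZ Euler angle and score columns.
#' @param voxel_size nm per voxel used to convert coordinates to nm.
#' @param euler_convention only `"zyz"` is supported; anything else errors.
#' @return A `particle_set` (positions in nm).
#' @export
read_star_particles <- function(path, voxel_size = 1,
                                euler_convention = "zyz") {
  if (!identical(tolower(euler_convention), "zyz"))
    stop("unknown Euler convention: ", euler_convention)
  if (!file.exists(path)) stop("STAR file not found: ", path)
  txt <- trimws(readLines(path))
  txt <- txt[nzchar(txt)]
  li <- which(txt == "loop_")
  if (!length(li)) stop("no loop_ block in STAR file")
  body <- txt[(li[1] + 1):length(txt)]
  is_tag <- grepl("^_", body)
  tags <- sub("\\s+#.*$", "", body[seq_len(which.min(is_tag) - 1)])
  rows <- body[!is_tag]
  rows <- rows[!grepl("^data_", rows)]
  if (!length(rows)) return(particle_set())
  mat <- do.call(rbind, strsplit(rows, "\\s+"))
  colnames(mat) <- tags
  getcol <- function(tag, default = NULL) {
    if (tag %in% tags) as.numeric(mat[, tag])
    else default
  }
  for (ax in c("x", "y", "z"))
    if (!(star_cols[[ax]] %in% tags))
      stop("missing mandatory STAR column: ", star_cols[[ax]])
  n <- nrow(mat)
  particle_set(x = getcol(star_cols[["x"]]) * voxel_size,
               y = getcol(star_cols[["y"]]) * voxel_size,
               z = getcol(star_cols[["z"]]) * voxel_size,
               rot = getcol(star_cols[["rot"]], rep(0, n)),
               tilt = getcol(star_cols[["tilt"]], rep(0, n)),
               psi = getcol(star_cols[["psi"]], rep(0, n)),
               score = getcol(star_cols[["score"]], rep(NA_real_, n)),
               class_label = getcol(star_cols[["class_label"]],
                                    rep(NA, n)))
}

#' Write particles as CSV (positions in nm)
#' @param ps a `particle_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_csv_particles <- function(ps, path) {
  utils::write.csv(as.data.frame(ps), path, row.names = FALSE)
  invisible(path)
}

#' Read particles from CSV (positions in nm)
#'
#' Requires columns `x`, `y`, `z`; orientation/score/kind columns are
#' optional.
#'
#' @param path CSV path.
#' @return A `particle_set`.
#' @export
read_csv_particles <- function(path) {
  if (!file.exists(path)) stop("CSV file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (cc in c("x", "y", "z"))
    if (!cc %in% names(df)) stop("missing mandatory column: ", cc)
  n <- nrow(df)
  pick <- function(cc, default) if (cc %in% names(df)) df[[cc]] else default
  particle_set(x = df$x, y = df$y, z = df$z,
               rot = pick("rot", rep(0, n)), tilt = pick("tilt", rep(0, n)),
               psi = pick("psi", rep(0, n)),
               score = pick("score", rep(NA_real_, n)),
               kind = pick("kind", rep("nucleosome", n)),
               class_label = pick("class_label", rep(NA, n)),
               id = pick("id", NULL))
}

#' Read particles from STAR or CSV, by extension
#' @param path file path ending in `.star` or `.csv`.
#' @param voxel_size nm/voxel (STAR only).
#' @return A `particle_set`.
#' @export
read_particles <- function(path, voxel_size = 1) {
  if (grepl("\\.star$", path, ignore.case = TRUE))
    read_star_particles(path, voxel_size)
  else if (grepl("\\.csv$", path, ignore.case = TRUE))
    read_csv_particles(path)
  else stop("unsupported particle file extension: ", path)
}
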