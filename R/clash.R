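# Steric-clash machinery shared by the simulator, CATM and the contact
# graph.  A placed particle occupies the voxel centres of its rotated
# steric mask (half-sample convention: a voxel belongs to the particle if
# its centre lies inside the mask support).  Two particles clash when the
# occupied voxel sets of their masks share more than `tolerance_voxels`
# voxels.

# Integer voxel offsets (relative to the template centre voxel) of the
# nonzero voxels of a mask volume.
mask_offsets <- function(mask) {
  d <- dim(mask$data)
  ctr <- (d + 1) / 2
  w <- which(mask$data > 0.5, arr.ind = TRUE)
  sweep(w, 2, ctr)
}

# Offsets of a mask rotated by quaternion q (binarized after trilinear
# resampling).
rotated_mask_offsets <- function(mask, q) {
  rv <- rotate_volume(mask, q)
  d <- dim(rv$data)
  ctr <- (d + 1) / 2
  w <- which(rv$data >= 0.5, arr.ind = TRUE)
  sweep(w, 2, ctr)
}

# Encode voxel triplets as scalar keys for fast set intersection.
.KEYB <- 4096
voxel_keys <- function(ijk) {
  (ijk[, 1] + .KEYB / 2) + .KEYB * (ijk[, 2] + .KEYB / 2) +
    .KEYB^2 * (ijk[, 3] + .KEYB / 2)
}

# Occupied voxel keys of a mask offset set placed at position pos (nm).
placed_keys <- function(offsets, pos, voxel_size) {
  base <- round(pos / voxel_size)
  voxel_keys(sweep(offsets, 2, base, `+`))
}

overlap_count <- function(keys_a, keys_b) sum(keys_a %in% keys_b)

#' Steric clash test between two placed particles
#'
#' Rotates the steric mask into each particle's orientation, voxelizes both
#' at the particle positions and counts shared voxels.
#'
#' @param pos_a,pos_b particle positions, nm (length-3).
#' @param quat_a,quat_b orientations (length-4 quaternions).
#' @param mask steric mask `tomo_volume` (see [build_steric_mask()]).
#' @param tolerance_voxels overlap up to this many voxels is not a clash.
#' @return TRUE iff the masks overlap in more than `tolerance_voxels`
#'   voxels.
#' @export
clash_check <- function(pos_a, quat_a, pos_b, quat_b, mask,
                        tolerance_voxels = 0) {
  vs <- mask$voxel_size
  ka <- placed_keys(rotated_mask_offsets(mask, quat_a), pos_a, vs)
  kb <- placed_keys(rotated_mask_offsets(mask, quat_b), pos_b, vs)
  overlap_count(ka, kb) > tolerance_voxels
}
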