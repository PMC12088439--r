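# Shared fixtures, built in code at test time.

default_disc <- function() build_nucleosome_template(particle_shape(), 1)
default_rod <- function() build_dna_template(particle_shape("dna_rod"), 1)

# A small clean tomogram holding the given particles (nucleosomes by
# default), degraded with wedge + CTF (no noise unless snr is finite).
micro_tomogram <- function(ps, box = 48, snr = Inf, seed = 1L,
                           model = imaging_model(snr = 1)) {
  tmpl <- list(nucleosome = default_disc(), dna = default_rod())
  clean <- render_volume(ps, tmpl, rep(box, 3), 1)
  out <- apply_ctf(clean, model)
  if (is.finite(snr)) out <- add_noise(out, snr, seed = seed)
  apply_missing_wedge(out, model$tilt_min, model$tilt_max)
}

micro_particles <- function(x, y, z, rot = 0, tilt = 0, psi = 0) {
  n <- max(length(x), length(y), length(z))
  ps <- particle_set(x = rep_len(x, n), y = rep_len(y, n),
                     z = rep_len(z, n), rot = rot, tilt = tilt,
                     psi = psi)
  ps$kind <- "nucleosome"
  ps
}
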