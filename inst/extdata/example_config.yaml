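# Example configuration override for catmtools.  Any subset of the
# defaults in catm_config() can be overridden; unspecified values keep
# their defaults.  Lengths in nm, angles in degrees.
simulate:
  box_nm: 96
  n_nucleosomes: 75
  n_dna: 38
  snr: 0.05
tm:
  angular_step: 15
  nms_cutoff: 4
catm:
  search_radius: 5
  retain_threshold: 0.3
evaluate:
  dist_tol: 5.5
  ang_tol: 30
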