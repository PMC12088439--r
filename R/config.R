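# Every tunable default of the pipeline lives here, in one nested list.
# YAML config files override these defaults; check_config() validates the
# result before any run.

#' Default pipeline configuration
#'
#' Returns the full nested list of defaults used by the simulator, both
#' matchers and the evaluation/analysis stages.  Lengths are nm, angles
#' degrees.
#'
#' @return Nested named list.
#' @export
catm_config <- function() {
  list(
    template = list(
      nucleosome_diameter = 11,     # nm, canonical disc diameter
      nucleosome_height = 5.5,      # nm
      dna_diameter = 2,             # nm
      dna_length = 10,              # nm
      amplitude = 1,
      mask_threshold = 0.5          # steric mask at half maximum
    ),
    simulate = list(
      box_nm = 96,                  # cubic box edge
      voxel_size = 1,               # nm/voxel
      n_nucleosomes = 75,           # condensate-like number density
      n_dna = 38,
      tilt_min = -60, tilt_max = 60,
      defocus_um = 4, voltage_kv = 300, cs_mm = 2.7,
      amplitude_contrast = 0.07,
      snr = 0.05,                   # calibrated against the benchmark
      max_attempts = 20000
    ),
    tm = list(
      angular_step = 15,            # degrees
      score_floor = 0.1,            # local-maxima floor before NMS
      nms_cutoff = 4,               # nm, slightly under the disc height
      sweep_thresholds = seq(0.1, 0.7, by = 0.025)
    ),
    catm = list(
      search_radius = 5,            # nm around each seed centroid
      retain_threshold = 0.3,       # CCC floor for candidate retention
      clash_fraction = 0.05,        # mask-volume overlap fraction = clash
      lowpass_nm = 2,               # Gaussian low-pass before local matching
      centroid_sigma = 1.5,         # nm jitter of benchmark seed centroids
      collapse_radius = 2,          # nm, merge_assignments de-duplication
      match_radius = 5.5            # nm, merge_assignments counterpart search
    ),
    localize = list(
      coarse_step = 20,             # degrees, pooled matched filter
      mad_k = 5,                    # adaptive threshold = median + k * MAD
      merge_radius = 6,             # nm
      meanshift_bandwidth = 8       # nm
    ),
    evaluate = list(
      dist_tol = 5.5,               # nm (half disc diameter)
      ang_tol = 30,                 # degrees, position+orientation scoring
      n_bins = 9                    # orientation histogram bins on [0, 90]
    ),
    analysis = list(
      gap_threshold = 1,            # nm surface gap for contact edges
      center_threshold = 12,        # nm fallback centre-distance criterion
      contact_criterion = "steric", # or "center"
      dbscan_eps = 12,              # nm
      dbscan_minpts = 3,
      depth_bin = 10,               # nm
      boundary_margin = 20,         # nm from lamella faces
      entropy_support = "contiguous" # valence categories 0..max observed
    )
  )
}

merge_config <- function(base, override) {
  if (is.null(override)) return(base)
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Load a configuration, optionally overridden from YAML
#'
#' @param path optional YAML file whose entries override [catm_config()].
#' @return Validated configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- catm_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  check_config(cfg)
  cfg
}

#' Validate a configuration list
#'
#' Checks presence, type and range of every field used by the pipeline;
#' stops with the offending field name otherwise.
#'
#' @param cfg configuration list.
#' @return `cfg`, invisibly.
#' @export
check_config <- function(cfg) {
  need_pos <- function(section, field) {
    v <- cfg[[section]][[field]]
    if (is.null(v) || !is.numeric(v) || any(v <= 0))
      stop("config ", section, "$", field, " must be a positive number")
  }
  for (f in c("nucleosome_diameter", "nucleosome_height", "dna_diameter",
              "dna_length")) need_pos("template", f)
  if (cfg$template$mask_threshold <= 0 || cfg$template$mask_threshold >= 1)
    stop("config template$mask_threshold must be in (0, 1)")
  for (f in c("box_nm", "voxel_size", "snr")) need_pos("simulate", f)
  s <- cfg$simulate
  if (!(s$tilt_min >= -90 && s$tilt_min < s$tilt_max && s$tilt_max <= 90))
    stop("config simulate$tilt_min/tilt_max invalid")
  for (f in c("angular_step", "nms_cutoff")) need_pos("tm", f)
  for (f in c("search_radius", "retain_threshold", "clash_fraction"))
    need_pos("catm", f)
  for (f in c("dist_tol", "ang_tol")) need_pos("evaluate", f)
  for (f in c("gap_threshold", "center_threshold", "dbscan_eps",
              "depth_bin")) need_pos("analysis", f)
  invisible(cfg)
}
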