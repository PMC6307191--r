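#' Network labels used by the synthetic parcellation
#'
#' The eight intrinsic connectivity networks modeled by the cohort generator,
#' matching the merged network scheme used for group analyses.
#'
#' @return Character vector of eight network names.
#' @export
fc_networks <- function() {
  c("auditory", "salience", "frontoparietal", "default",
    "dorsal_attention", "ventral_attention", "sensorimotor", "visual")
}

#' Simulation parameters for the synthetic BOLD cohort generator
#'
#' Bundles every tunable of the generator with defaults that emulate the
#' acquisition this pipeline targets: two 8.5-minute runs at TR = 0.8 s
#' (620 frames per run), a mirror-symmetric block parcellation with eight
#' intrinsic networks, block-structured ROI covariance with extra homotopic
#' coupling, a shared global-signal component, WM/CSF/face confound signals
#' that leak into gray matter, and Poisson-placed motion spikes whose rate may
#' differ by group.
#'
#' Fisher-z coupling targets are specified on the latent (noise-free) ROI
#' correlation scale. `within_z` may be a single value or a named per-network
#' vector; `between_z` a single value or a full 8x8 symmetric matrix.
#'
#' @param grid_shape Integer triple of voxel grid dimensions; the first axis
#'   must be even so a mid-sagittal plane exists between the two middle slices.
#' @param n_rois_per_hemisphere Number of ROIs per hemisphere (>= 8 so every
#'   network has at least one ROI per hemisphere).
#' @param n_none_per_hemisphere How many of those ROIs per hemisphere carry no
#'   network assignment (`"none"`), mimicking unassigned parcels; they are
#'   excluded from network-level analyses but kept for ROI-level and
#'   homotopic analyses.
#' @param none_z Fisher-z coupling of cells involving a `"none"` ROI.
#' @param roi_block Edge length in voxels of each cubic ROI block.
#' @param network_labels The eight network names.
#' @param tr_seconds Repetition time in seconds.
#' @param n_frames_per_run Frames per run.
#' @param n_runs Number of runs per subject.
#' @param within_z Target within-network Fisher z (scalar or named vector).
#' @param between_z Target between-network Fisher z (scalar or 8x8 matrix).
#' @param homotopic_z Extra Fisher z added to mirror-pair cells.
#' @param global_amp Standard deviation of the shared global signal relative
#'   to the unit-SD ROI signals.
#' @param confound_amp Amplitude at which each tissue confound (WM, CSF, face)
#'   leaks into gray-matter voxels.
#' @param noise_sd Voxelwise white-noise standard deviation.
#' @param ar_phi AR(1) coefficient of the temporal coloring applied to all
#'   latent signals (concentrates power at low frequencies).
#' @param subject_z_sd Between-subject SD of network-level coupling
#'   parameters (within, between, homotopic), on the Fisher-z scale.
#' @param spike_rate Named per-group expected number of supra-threshold motion
#'   spikes per run of `n_frames_per_run` frames.
#' @param spike_fd_mm Framewise displacement magnitude of one motion spike.
#' @param drift_sd_mm Per-frame SD of the translation drift random walk.
#' @param drift_sd_rad Per-frame SD of the rotation drift random walk.
#' @param head_radius_mm Head radius used to convert rotations to mm.
#' @param voxel_size_mm Isotropic voxel edge length in mm.
#' @param seed Default integer seed.
#' @return An object of class `sim_params` (a validated list).
#' @export
sim_params <- function(grid_shape = c(16L, 16L, 10L),
                       n_rois_per_hemisphere = 16L,
                       roi_block = 2L,
                       network_labels = fc_networks(),
                       tr_seconds = 0.8,
                       n_frames_per_run = 620L,
                       n_runs = 2L,
                       n_none_per_hemisphere = 0L,
                       within_z = 0.25,
                       between_z = 0.10,
                       homotopic_z = 0.15,
                       none_z = 0.10,
                       global_amp = 0.4,
                       confound_amp = 0.1,
                       noise_sd = 1.0,
                       ar_phi = 0.35,
                       subject_z_sd = 0.05,
                       spike_rate = c(LVCP = 178, HVCP = 105, NT = 97),
                       spike_fd_mm = 0.6,
                       drift_sd_mm = 0.01,
                       drift_sd_rad = 2e-4,
                       head_radius_mm = 50,
                       voxel_size_mm = 2,
                       seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 2L))
    stopf("grid_shape must be three integers >= 2")
  if (grid_shape[1] %% 2L != 0L)
    stopf("grid_shape first axis must be even so a mid-sagittal plane exists")
  if (length(network_labels) != 8L || anyDuplicated(network_labels))
    stopf("network_labels must be 8 distinct names")
  if (n_rois_per_hemisphere - n_none_per_hemisphere < 8L)
    stopf("need >= 8 network-assigned ROIs per hemisphere")
  if (tr_seconds <= 0) stopf("tr_seconds must be positive")
  if (n_frames_per_run < 2L) stopf("n_frames_per_run must be >= 2")

  nk <- length(network_labels)
  if (length(within_z) == 1L) {
    within_z <- stats::setNames(rep(within_z, nk), network_labels)
  } else {
    if (!all(network_labels %in% names(within_z)))
      stopf("within_z must be named for every network")
    within_z <- within_z[network_labels]
  }
  if (length(between_z) == 1L) {
    bz <- matrix(between_z, nk, nk, dimnames = list(network_labels, network_labels))
    diag(bz) <- NA_real_
    between_z <- bz
  } else {
    between_z <- as.matrix(between_z)
    if (!isTRUE(all.equal(between_z[lower.tri(between_z)],
                          t(between_z)[lower.tri(between_z)])))
      stopf("between_z must be symmetric")
    dimnames(between_z) <- list(network_labels, network_labels)
  }
  if (!all(is.finite(c(within_z, between_z[upper.tri(between_z)], homotopic_z))))
    stopf("coupling z-values must be finite")
  amps <- c(global_amp = global_amp, confound_amp = confound_amp,
            noise_sd = noise_sd, subject_z_sd = subject_z_sd,
            spike_fd_mm = spike_fd_mm)
  if (any(amps < 0)) stopf("amplitudes and rates must be non-negative")
  if (any(spike_rate < 0)) stopf("spike_rate must be non-negative")
  if (ar_phi < 0 || ar_phi >= 1) stopf("ar_phi must be in [0, 1)")

  p <- list(grid_shape = grid_shape,
            n_rois_per_hemisphere = as.integer(n_rois_per_hemisphere),
            n_none_per_hemisphere = as.integer(n_none_per_hemisphere),
            none_z = none_z,
            roi_block = as.integer(roi_block),
            network_labels = network_labels,
            tr_seconds = tr_seconds,
            n_frames_per_run = as.integer(n_frames_per_run),
            n_runs = as.integer(n_runs),
            within_z = within_z, between_z = between_z,
            homotopic_z = homotopic_z,
            global_amp = global_amp, confound_amp = confound_amp,
            noise_sd = noise_sd, ar_phi = ar_phi,
            subject_z_sd = subject_z_sd,
            spike_rate = spike_rate, spike_fd_mm = spike_fd_mm,
            drift_sd_mm = drift_sd_mm, drift_sd_rad = drift_sd_rad,
            head_radius_mm = head_radius_mm,
            voxel_size_mm = voxel_size_mm,
            seed = as.integer(seed))
  class(p) <- "sim_params"
  p
}

#' Default per-group cohort specifications
#'
#' Encodes the study conditions of the cohort the generator emulates: group
#' sizes 17/20/19 (LVCP/HVCP/NT), age, sex-ratio and composite-IQ
#' distributions per group, group-dependent motion (per-subject retained
#' fractions drawn from `mf_frac_mean`/`mf_frac_sd`, matched to the emulated
#' cohort's motion-free volume means and SDs; set `mf_frac_mean` to `NULL`
#' to use the group's fixed `spike_rate` instead), and the
#' planted connectivity effects: the LVCP group has within-network coupling
#' reduced by 0.15 z in the default, salience, auditory and frontoparietal
#' networks, default-to-dorsal-attention between-network coupling raised by
#' 0.15 z, and an IQ-dependent global coupling shift (lower IQ, higher
#' connectivity).
#'
#' @param params A `sim_params` object.
#' @param effects One of `"planted"` (the defaults above), `"null"` (no group
#'   differences in coupling, motion, or IQ slope).
#' @return Named list of group specifications (class `group_specs`).
#' @export
default_group_specs <- function(params = sim_params(), effects = c("planted", "null")) {
  effects <- match.arg(effects)
  base <- list(
    LVCP = list(n = 17L, age_mean = 12.26, age_sd = 3.34,
                sex_p_female = 3 / 17, iq_mean = 54.0, iq_sd = 17.50,
                iq_range = c(25, 79), spike_rate = params$spike_rate[["LVCP"]],
                mf_frac_mean = 0.508, mf_frac_sd = 0.275,
                within_z_delta = c(default = -0.15, salience = -0.15,
                                   auditory = -0.15, frontoparietal = -0.15),
                between_z_delta = list(list("default", "dorsal_attention", 0.15)),
                homotopic_z_delta = 0,
                iq_z_slope = -0.002),
    HVCP = list(n = 20L, age_mean = 12.64, age_sd = 2.87,
                sex_p_female = 5 / 20, iq_mean = 106.85, iq_sd = 13.64,
                iq_range = c(80, 130), spike_rate = params$spike_rate[["HVCP"]],
                mf_frac_mean = 0.689, mf_frac_sd = 0.197,
                within_z_delta = NULL, between_z_delta = NULL,
                homotopic_z_delta = 0, iq_z_slope = 0),
    NT = list(n = 19L, age_mean = 11.76, age_sd = 2.61,
              sex_p_female = 5 / 19, iq_mean = 111.76, iq_sd = 13.05,
              iq_range = c(80, 134), spike_rate = params$spike_rate[["NT"]],
              mf_frac_mean = 0.713, mf_frac_sd = 0.231,
              within_z_delta = NULL, between_z_delta = NULL,
              homotopic_z_delta = 0, iq_z_slope = 0)
  )
  if (effects == "null") {
    for (g in names(base)) {
      base[[g]]$within_z_delta <- NULL
      base[[g]]$between_z_delta <- NULL
      base[[g]]$iq_z_slope <- 0
      base[[g]]$spike_rate <- params$spike_rate[["NT"]]
      base[[g]]$mf_frac_mean <- base$NT$mf_frac_mean
      base[[g]]$mf_frac_sd <- base$NT$mf_frac_sd
    }
  }
  base$LVCP$age_range <- base$HVCP$age_range <- base$NT$age_range <- c(7, 17)
  class(base) <- "group_specs"
  base
}
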