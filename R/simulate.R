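# Synthetic BOLD cohort generator.

#' Simulate a six-parameter rigid-body motion trace
#'
#' Smooth low-amplitude random-walk drift on all six parameters (three
#' translations in mm, three rotations in radians) plus Poisson-placed
#' sustained head-position steps ("spikes") whose framewise displacement
#' equals `spike_fd_mm`. The expected number of spikes in a run of
#' `params$n_frames_per_run` frames is `spike_rate`; each spiked transition
#' independently displaces one random translation axis.
#'
#' @param params A [sim_params()] object.
#' @param spike_rate Expected spikes per run: a number, or a group label
#'   indexing `params$spike_rate`.
#' @param n_frames Number of frames (defaults to `params$n_frames_per_run`).
#' @param seed Integer seed.
#' @return Matrix `n_frames` x 6 with columns `trans_x`, `trans_y`, `trans_z`
#'   (mm) and `rot_x`, `rot_y`, `rot_z` (radians).
#' @export
simulate_motion <- function(params, spike_rate = 0,
                            n_frames = params$n_frames_per_run, seed = 1L) {
  if (is.character(spike_rate)) {
    if (!spike_rate %in% names(params$spike_rate))
      stopf("no spike_rate defined for group '%s'", spike_rate)
    spike_rate <- params$spike_rate[[spike_rate]]
  }
  set.seed(seed)
  n <- as.integer(n_frames)
  m <- cbind(
    vapply(1:3, function(i) cumsum(stats::rnorm(n, 0, params$drift_sd_mm)),
           numeric(n)),
    vapply(1:3, function(i) cumsum(stats::rnorm(n, 0, params$drift_sd_rad)),
           numeric(n)))
  colnames(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  p <- spike_rate / params$n_frames_per_run
  if (p > 0) {
    spiked <- which(stats::runif(n - 1) < p) + 1L  # transition into frame t
    for (t in spiked) {
      axis <- sample.int(3L, 1L)
      step <- sample(c(-1, 1), 1L) * params$spike_fd_mm
      m[t:n, axis] <- m[t:n, axis] + step
    }
  }
  m
}

# Latent per-run signal draws shared by the voxel and ROI generation paths.
draw_run_signals <- function(params, R_chol, n, seed) {
  set.seed(seed)
  nR <- ncol(R_chol)
  list(S = ar1_noise(n, nR, params$ar_phi) %*% R_chol,
       g = drop(ar1_noise(n, 1L, params$ar_phi)),
       wm = drop(ar1_noise(n, 1L, params$ar_phi)),
       csf = drop(ar1_noise(n, 1L, params$ar_phi)),
       face = drop(ar1_noise(n, 1L, params$ar_phi)))
}

#' Simulate one subject's BOLD runs
#'
#' Draws ROI time series from a zero-mean multivariate normal with the given
#' (or internally built) correlation matrix, temporally colored by an AR(1)
#' kernel; adds a shared global-signal series scaled by `global_amp` to all
#' in-brain voxels; paints ROI signals onto their voxel blocks with white
#' voxel noise; fills WM/CSF/face blocks with their own confound series, which
#' also leak into gray matter at `confound_amp`. All generating series,
#' motion, framewise displacement and supra-threshold spike frames are stored
#' in `$truth`. Deterministic given `seed`.
#'
#' With `voxel = FALSE` an exact ROI-level equivalent is generated instead of
#' voxel volumes: because the nuisance-regression residual operator is linear
#' and shared across voxels, downstream results computed from ROI block means
#' are identical in distribution (and identical in value when `noise_sd = 0`);
#' measured confound series (eroded-core WM/CSF means, face mean, in-brain
#' mean) are carried alongside the ROI matrix.
#'
#' @param params A [sim_params()] object.
#' @param phenotype One-row data.frame (or list) with `subject_id`, `group`,
#'   `age_years`, `sex`, `iq_composite`.
#' @param atlas Parcellation from [build_symmetric_parcellation()].
#' @param masks Tissue masks from [build_tissue_masks()].
#' @param seed Integer seed.
#' @param group_spec Optional group specification (from
#'   [default_group_specs()]); supplies spike rate, planted coupling deltas,
#'   between-subject jitter and the IQ slope.
#' @param covariance Optional pre-built correlation matrix; overrides
#'   `group_spec` coupling (no subject jitter applied).
#' @param voxel Generate voxel volumes (`TRUE`) or the exact ROI-level
#'   equivalent (`FALSE`).
#' @return A `synthetic_subject`: phenotype, `runs` (list of `bold_run` or
#'   `roi_run`), `motion` (list of matrices), and `truth`.
#' @export
simulate_subject <- function(params, phenotype, atlas, masks, seed,
                             group_spec = NULL, covariance = NULL,
                             voxel = TRUE) {
  nR <- nrow(atlas$roi_table)
  if (is.null(covariance)) {
    if (is.null(group_spec)) {
      covariance <- build_roi_covariance(params, atlas)
    } else {
      tp <- subject_target_params(params, group_spec,
                                 phenotype$iq_composite, subseed(seed, 0L, 5L))
      covariance <- build_roi_covariance(params, atlas, tp$within_z,
                                         tp$between_z, tp$homotopic_z)
    }
  }
  if (ncol(covariance) != nR)
    stopf("covariance dimension (%d) does not match ROI count (%d)",
          ncol(covariance), nR)
  U <- chol(covariance)
  spike_rate <- group_spec$spike_rate %||% 0
  a <- params$global_amp
  lam <- params$confound_amp
  sig <- params$noise_sd
  n <- params$n_frames_per_run

  gm_idx <- lapply(atlas$roi_table$id, function(id) which(atlas$labels == id))
  nv <- lengths(gm_idx)
  wm_core <- erode_mask(masks$wm)
  csf_core <- erode_mask(masks$csf)
  counts <- c(gm = sum(nv), wm = sum(masks$wm), csf = sum(masks$csf),
              face = sum(masks$face), brain = sum(masks$brain),
              wm_core = sum(wm_core), csf_core = sum(csf_core))

  runs <- vector("list", params$n_runs)
  motion <- vector("list", params$n_runs)
  truth_runs <- vector("list", params$n_runs)
  for (r in seq_len(params$n_runs)) {
    motion[[r]] <- simulate_motion(params, spike_rate, n, subseed(seed, r, 1L))
    sg <- draw_run_signals(params, U, n, subseed(seed, r, 2L))
    shared_gm <- a * sg$g + lam * (sg$wm + sg$csf + sg$face)
    set.seed(subseed(seed, r, 3L))
    run_id <- sprintf("run-%02d", r)
    if (voxel) {
      flat <- matrix(0, prod(params$grid_shape), n)
      for (i in seq_len(nR))
        flat[gm_idx[[i]], ] <- matrix(sg$S[, i] + shared_gm, nv[i], n,
                                      byrow = TRUE)
      wmv <- which(masks$wm); csfv <- which(masks$csf); fv <- which(masks$face)
      flat[wmv, ] <- matrix(sg$wm + a * sg$g, length(wmv), n, byrow = TRUE)
      flat[csfv, ] <- matrix(sg$csf + a * sg$g, length(csfv), n, byrow = TRUE)
      flat[fv, ] <- matrix(sg$face, length(fv), n, byrow = TRUE)
      if (sig > 0) {
        act <- c(unlist(gm_idx), wmv, csfv, fv)
        flat[act, ] <- flat[act, ] +
          matrix(stats::rnorm(length(act) * n, 0, sig), length(act), n)
      }
      runs[[r]] <- structure(
        list(data = array(flat, c(params$grid_shape, n)),
             tr_seconds = params$tr_seconds, run_id = run_id,
             subject_id = phenotype$subject_id),
        class = "bold_run")
    } else {
      E <- if (sig > 0)
        sweep(matrix(stats::rnorm(n * nR), n, nR), 2, sig / sqrt(nv), "*")
      else matrix(0, n, nR)
      roi_raw <- sg$S + outer(shared_gm, rep(1, nR)) + E
      mn <- function(sz) if (sig > 0) stats::rnorm(n, 0, sig / sqrt(sz)) else 0
      e_wm <- mn(counts[["wm"]]); e_csf <- mn(counts[["csf"]])
      gm_sum <- drop(roi_raw %*% nv)
      brain_mean <- (gm_sum +
        counts[["wm"]] * (sg$wm + a * sg$g + e_wm) +
        counts[["csf"]] * (sg$csf + a * sg$g + e_csf)) / counts[["brain"]]
      conf_meas <- list(
        wm = sg$wm + a * sg$g + mn(counts[["wm_core"]]),
        csf = sg$csf + a * sg$g + mn(counts[["csf_core"]]),
        face = sg$face + mn(counts[["face"]]),
        brain_mean = brain_mean)
      runs[[r]] <- structure(
        list(roi_data = roi_raw, confounds_meas = conf_meas,
             tr_seconds = params$tr_seconds, run_id = run_id,
             subject_id = phenotype$subject_id),
        class = "roi_run")
    }
    fd <- compute_framewise_displacement(motion[[r]], params$head_radius_mm)
    truth_runs[[r]] <- list(signals = sg$S, global = sg$g,
                            confounds = list(wm = sg$wm, csf = sg$csf,
                                             face = sg$face),
                            fd = fd, spike_frames = which(fd > 0.2))
  }
  cm <- lapply(truth_runs, function(tr) build_censor_mask(tr$fd))
  structure(list(
    phenotype = as.data.frame(phenotype, stringsAsFactors = FALSE),
    runs = runs, motion = motion, masks = masks,
    truth = list(covariance = covariance,
                 target_z = attr(covariance, "target_z"),
                 runs = truth_runs,
                 n_motion_free = sum(vapply(cm, function(x) x$n_motion_free,
                                            integer(1))),
                 counts = counts),
    type = if (voxel) "voxel" else "roi", seed = seed),
    class = "synthetic_subject")
}

# Latent mean whose truncated-normal mean equals the target (inverts the
# truncation bias so emulated cohort moments are matched).
truncnorm_latent_mean <- function(target, sd, lo, hi) {
  tmean <- function(mu) {
    a <- (lo - mu) / sd; b <- (hi - mu) / sd
    p <- stats::pnorm(b) - stats::pnorm(a)
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / p
  }
  stats::uniroot(function(mu) tmean(mu) - target,
                 lower = target - 3 * sd, upper = target + 3 * sd,
                 tol = 1e-8)$root
}

# Truncated-normal draws by rejection (bounds always well inside the bulk).
rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Simulate a full three-group cohort
#'
#' Draws per-group phenotypes (age, sex, composite IQ) from the configured
#' distributions, applies each group's coupling deltas, spike rates and IQ
#' slope, and simulates every subject. Group invariants are enforced: LVCP
#' composite IQ <= 79, HVCP/NT >= 80.
#'
#' @param params A [sim_params()] object.
#' @param groups Group specifications (default [default_group_specs()]).
#' @param seed Integer seed (default `params$seed`).
#' @param voxel Generate voxel volumes (`TRUE`) or ROI-level equivalents
#'   (`FALSE`, default; exact for all downstream summaries and far lighter).
#' @return An `fc_cohort`: `subjects` (list of `synthetic_subject`),
#'   `phenotypes` (data.frame), `atlas`, `masks`, and a ground-truth
#'   `manifest`.
#' @export
simulate_cohort <- function(params = sim_params(),
                            groups = default_group_specs(params),
                            seed = params$seed, voxel = FALSE) {
  for (g in names(groups)) {
    if (groups[[g]]$n < 2L) stopf("group %s must have n >= 2", g)
    rng <- groups[[g]]$iq_range
    if (g == "LVCP" && rng[2] > 79)
      stopf("LVCP iq_range must lie at or below 79")
    if (g != "LVCP" && rng[1] < 80)
      stopf("%s iq_range must lie at or above 80", g)
  }
  atlas <- build_symmetric_parcellation(params)
  masks <- build_tissue_masks(params, atlas)

  phen <- list(); k <- 0L
  for (gi in seq_along(groups)) {
    g <- names(groups)[gi]
    sp <- groups[[g]]
    set.seed(subseed(seed, gi, 10L))
    phen[[g]] <- data.frame(
      subject_id = sprintf("sub-%s%02d", g, seq_len(sp$n)),
      group = g,
      age_years = round(rtruncnorm(sp$n, sp$age_mean, sp$age_sd,
                                   sp$age_range[1], sp$age_range[2]), 1),
      sex = ifelse(stats::runif(sp$n) < sp$sex_p_female, "F", "M"),
      iq_composite = round(rtruncnorm(sp$n, sp$iq_mean, sp$iq_sd,
                                      sp$iq_range[1], sp$iq_range[2])),
      stringsAsFactors = FALSE)
  }
  phenotypes <- do.call(rbind, phen)
  rownames(phenotypes) <- NULL
  # guard against degenerate single-sex groups (covariate must be estimable)
  for (g in names(groups)) {
    sx <- phenotypes$sex[phenotypes$group == g]
    if (length(unique(sx)) == 1L) {
      i <- which(phenotypes$group == g)[1L]
      phenotypes$sex[i] <- setdiff(c("M", "F"), sx[1L])
    }
  }

  subjects <- vector("list", nrow(phenotypes))
  for (i in seq_len(nrow(phenotypes))) {
    ph <- phenotypes[i, ]
    gspec <- groups[[ph$group]]
    if (!is.null(gspec$mf_frac_mean)) {
      # per-subject motion burden: retained fraction ~ truncated normal with
      # the group's moments; kept fraction under the censor rule is (1 - p)^2
      set.seed(subseed(seed, i, 21L))
      mu <- truncnorm_latent_mean(gspec$mf_frac_mean, gspec$mf_frac_sd,
                                  0.17, 0.98)
      frac <- rtruncnorm(1L, mu, gspec$mf_frac_sd, 0.17, 0.98)
      gspec$spike_rate <- (1 - sqrt(frac)) * params$n_frames_per_run
    }
    subjects[[i]] <- simulate_subject(params, ph, atlas, masks,
                                      seed = subseed(seed, i, 20L),
                                      group_spec = gspec,
                                      voxel = voxel)
  }
  names(subjects) <- phenotypes$subject_id
  manifest <- data.frame(
    subject_id = phenotypes$subject_id, group = phenotypes$group,
    n_motion_free = vapply(subjects, function(s) s$truth$n_motion_free,
                           integer(1)),
    n_spike_frames = vapply(subjects, function(s)
      sum(lengths(lapply(s$truth$runs, `[[`, "spike_frames"))), integer(1)))
  structure(list(params = params, groups = groups, subjects = subjects,
                 phenotypes = phenotypes, atlas = atlas, masks = masks,
                 manifest = manifest, seed = seed),
            class = "fc_cohort")
}
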