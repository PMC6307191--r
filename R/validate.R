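# Simulation validation studies: planted-effect recovery and null
# calibration of the full pipeline.

#' Parameters of the scaled-down recovery benchmark
#'
#' A controlled cohort design for parameter-recovery studies: 32 ROIs
#' (16 per hemisphere, two per network per hemisphere), one 600-frame run,
#' equal low motion across groups and no IQ slope, so that only the two
#' planted effects distinguish the groups: the LVCP within-network deficit of
#' 0.15 z (default, salience, auditory, frontoparietal) and the LVCP
#' default-to-dorsal-attention between-network excess of 0.15 z.
#'
#' @param seed Integer seed.
#' @return List with `params` and `groups` ready for [simulate_cohort()].
#' @export
recovery_benchmark_spec <- function(seed = 1L) {
  params <- sim_params(n_rois_per_hemisphere = 16L, n_frames_per_run = 600L,
                       n_runs = 1L, seed = seed)
  groups <- default_group_specs(params)
  for (g in names(groups)) {
    groups[[g]]$spike_rate <- 30
    groups[[g]]$mf_frac_mean <- NULL
    groups[[g]]$iq_z_slope <- 0
  }
  list(params = params, groups = groups)
}

# One full pipeline pass on an in-memory cohort; returns family tables.
cohort_family_tables <- function(cohort, use_gsr = FALSE,
                                 min_volumes = 200L) {
  pairs <- homotopic_pairs(cohort$atlas)
  bundles <- list()
  nmf <- c()
  for (sid in names(cohort$subjects)) {
    pp <- preprocess_subject(cohort$subjects[[sid]], use_gsr = use_gsr,
                             min_volumes = min_volumes)
    nmf[sid] <- pp$n_motion_free
    if (!pp$usable) next
    ts <- extract_roi_timeseries(pp, cohort$atlas, min_volumes = min_volumes)
    bundles[[sid]] <- compute_connectivity(ts, cohort$atlas, pairs)
  }
  phen <- cohort$phenotypes[cohort$phenotypes$subject_id %in% names(bundles), ]
  design <- cohort_design(phen, nmf, if (use_gsr) "gsr" else "nogsr")
  list(tables = run_family_analyses(bundles, design), design = design,
       bundles = bundles)
}

#' Planted-effect recovery across replicate cohorts
#'
#' Simulates replicate benchmark cohorts ([recovery_benchmark_spec()]),
#' runs the full non-GSR pipeline on each, and records whether the
#' FDR-flagged effects include every planted effect (the four within-network
#' deficits via the ANCOVA family and the default-dorsal-attention
#' between-network excess via the LVCP-vs-NT contrast family), plus the flag
#' rate in the four unplanted within-network cells.
#'
#' @param n_reps Number of replicate cohorts.
#' @param seed Integer seed.
#' @param min_volumes Usability minimum (the benchmark run is 600 frames).
#' @return Data frame with one row per replicate: `all_within_flagged`,
#'   `between_flagged`, `all_planted_flagged`, `n_unplanted_within_flagged`.
#' @export
planted_effect_recovery <- function(n_reps = 50L, seed = 1L,
                                    min_volumes = 200L) {
  spec <- recovery_benchmark_spec(seed)
  planted_nets <- c("default", "salience", "auditory", "frontoparietal")
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    co <- simulate_cohort(spec$params, spec$groups,
                          seed = subseed(seed, r, 77L), voxel = FALSE)
    ft <- cohort_family_tables(co, use_gsr = FALSE,
                               min_volumes = min_volumes)$tables
    w <- ft$within_network
    direction_ok <- w$mean_LVCP[match(planted_nets, w$effect)] <
      w$mean_HVCP[match(planted_nets, w$effect)]
    all_within <- all(w$flag[w$effect %in% planted_nets]) && all(direction_ok)
    b <- ft$between_network
    target <- grepl("default", b$effect) & grepl("dorsal_attention", b$effect)
    between <- b$flag_LVCP_NT[target] && b$t_LVCP_NT[target] > 0
    out[[r]] <- data.frame(
      all_within_flagged = all_within,
      between_flagged = between,
      all_planted_flagged = all_within && between,
      n_unplanted_within_flagged = sum(w$flag[!w$effect %in% planted_nets]))
  }
  do.call(rbind, out)
}

#' Full-pipeline type-I error on null cohorts
#'
#' Simulates replicate cohorts with no group differences (identical coupling,
#' motion and IQ behavior across groups), runs the full pipeline, and counts
#' uncorrected rejections at `alpha` over the within-network ANCOVA and
#' between-network t families.
#'
#' @param n_reps Number of replicate null cohorts.
#' @param seed Integer seed.
#' @param alpha Nominal level.
#' @param n_per_group Subjects per group (reduced size for replication).
#' @return List: `rate` (overall empirical rejection rate), `n_tests`,
#'   `flag_rate` (FDR-corrected any-flag rate per family, averaged).
#' @export
null_pipeline_calibration <- function(n_reps = 50L, seed = 1L, alpha = 0.05,
                                      n_per_group = 10L) {
  params <- sim_params(n_rois_per_hemisphere = 16L, n_frames_per_run = 300L,
                       n_runs = 1L, seed = seed)
  groups <- default_group_specs(params, effects = "null")
  for (g in names(groups)) {
    groups[[g]]$n <- n_per_group
    groups[[g]]$spike_rate <- 15
    groups[[g]]$mf_frac_mean <- NULL
  }
  rej <- 0L; ntest <- 0L; any_flag <- 0L; nfam <- 0L
  for (r in seq_len(n_reps)) {
    co <- simulate_cohort(params, groups, seed = subseed(seed, r, 99L),
                          voxel = FALSE)
    ft <- cohort_family_tables(co, use_gsr = FALSE,
                               min_volumes = 100L)$tables
    ps <- c(ft$within_network$p, ft$between_network$p_LVCP_NT,
            ft$between_network$p_LVCP_HVCP)
    rej <- rej + sum(ps < alpha); ntest <- ntest + length(ps)
    any_flag <- any_flag + any(ft$within_network$flag) +
      any(ft$between_network$flag_LVCP_NT)
    nfam <- nfam + 2L
  }
  list(rate = rej / ntest, n_tests = ntest, flag_rate = any_flag / nfam)
}
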