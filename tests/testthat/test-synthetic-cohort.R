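# Cohort generator: parcellation geometry, covariance targets, motion,
# subject simulation, cohort assembly.

test_that("parcellation is mirror-symmetric with one ROI per network per hemisphere", {
  p <- sim_params(n_rois_per_hemisphere = 8L)
  atlas <- build_symmetric_parcellation(p)
  tab <- atlas$roi_table
  expect_equal(nrow(tab), 16L)
  counts <- table(tab$merged_network, tab$hemisphere)
  expect_true(all(counts == 1L))
  # right centroids are exact mirrors of left centroids
  mp <- atlas$mirror_pairs
  expect_equal(tab$x[match(mp$right, tab$id)], -tab$x[match(mp$left, tab$id)])
  expect_equal(tab$y[match(mp$right, tab$id)], tab$y[match(mp$left, tab$id)])

  # mirroring the label volume and remapping ids via the pair table
  # reproduces the volume exactly
  lab <- atlas$labels
  flipped <- lab[dim(lab)[1]:1, , ]
  remap <- seq_len(max(lab))
  remap[mp$left] <- mp$right
  remap[mp$right] <- mp$left
  remapped <- array(0L, dim(lab))
  remapped[flipped > 0] <- remap[flipped[flipped > 0]]
  expect_identical(remapped, lab)
})

test_that("20 ROIs per hemisphere on a 40x40x24 grid: no overlap, >= 8 voxels each", {
  p <- sim_params(grid_shape = c(40L, 40L, 24L), n_rois_per_hemisphere = 20L)
  atlas <- build_symmetric_parcellation(p)
  sizes <- table(atlas$labels[atlas$labels > 0])
  expect_equal(length(sizes), 40L)
  expect_true(all(sizes >= 8))
  # exhaustive voxel-label check: every labeled voxel belongs to exactly one
  # ROI (labels are single-valued by construction), and each ROI is contained
  # in one hemisphere
  tab <- atlas$roi_table
  for (i in seq_len(nrow(tab))) {
    vox <- which(atlas$labels == tab$id[i], arr.ind = TRUE)
    xs <- fcpipe:::voxel_world(vox[, 1], 1, atlas$affine)
    expect_true(all(xs < 0) || all(xs > 0))
  }
})

test_that("grid too small for requested ROIs raises a sizing error", {
  expect_error(build_symmetric_parcellation(
    sim_params(grid_shape = c(4L, 12L, 4L), n_rois_per_hemisphere = 16L)),
    "grid too small")
})

test_that("covariance targets: zero coupling gives identity, cells match tanh", {
  g <- tiny_geometry(tiny_params(within_z = 0, between_z = 0,
                                 homotopic_z = 0, none_z = 0))
  R <- build_roi_covariance(g$params, g$atlas)
  expect_equal(unname(R), diag(nrow(g$atlas$roi_table)), ignore_attr = TRUE)

  p2 <- tiny_params(within_z = c(default = 0.4, auditory = 0.25,
                                 salience = 0.25, frontoparietal = 0.25,
                                 dorsal_attention = 0.25,
                                 ventral_attention = 0.25,
                                 sensorimotor = 0.25, visual = 0.25))
  g2 <- tiny_geometry(p2)
  R2 <- build_roi_covariance(p2, g2$atlas)
  tab <- g2$atlas$roi_table
  dflt <- which(tab$merged_network == "default" & tab$hemisphere == "L")
  expect_equal(R2[dflt[1], dflt[2]], tanh(0.4), tolerance = 1e-12)
  # positive definiteness of any valid output
  expect_gt(min(eigen(R2, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_equal(attr(R2, "repair"), 0)
})

test_that("infeasible coupling values error; near-singular targets are repaired", {
  g <- tiny_geometry()
  expect_error(build_roi_covariance(g$params, g$atlas, within_z = Inf),
               "finite")
  # strong uniform coupling with much stronger homotopic cells can break PD;
  # the repair is reported and the result is PD
  R <- build_roi_covariance(g$params, g$atlas, within_z = 2.5,
                            between_z = matrix(2.4, 8, 8,
                              dimnames = list(fc_networks(), fc_networks())),
                            homotopic_z = -4.5)
  expect_gt(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_gt(attr(R, "repair"), 0)
})

test_that("null motion yields zero FD and no censored frames", {
  p <- tiny_params(drift_sd_mm = 0, drift_sd_rad = 0)
  m <- simulate_motion(p, spike_rate = 0, seed = 1L)
  fd <- compute_framewise_displacement(m)
  expect_equal(fd, rep(0, nrow(m)))
  expect_equal(build_censor_mask(fd)$n_motion_free, nrow(m))
})

test_that("censored fraction matches the analytic expectation of the rule", {
  # spike probability q per transition; a frame is kept when neither adjacent
  # transition spiked: P(keep) ~ (1 - q)^2 (drift alone never crosses 0.2 mm)
  p <- sim_params(n_frames_per_run = 400L, n_runs = 1L)
  rate <- 0.5 * 400  # q = 0.5 -> expected kept fraction 0.25
  kept <- vapply(1:100, function(s) {
    m <- simulate_motion(p, spike_rate = rate, n_frames = 400L, seed = s)
    build_censor_mask(compute_framewise_displacement(m))$n_motion_free
  }, integer(1))
  expectation <- 400 * (1 - 0.5)^2
  expect_lt(abs(mean(kept) - expectation) / expectation, 0.10)
})

test_that("group-dependent spike rates reproduce the motion ordering", {
  p <- sim_params()
  kept <- function(group, s) {
    m <- simulate_motion(p, spike_rate = group, n_frames = 620L, seed = s)
    build_censor_mask(compute_framewise_displacement(m))$n_motion_free
  }
  lv <- mean(vapply(1:20, function(s) kept("LVCP", s), integer(1)))
  nt <- mean(vapply(1:20, function(s) kept("NT", s), integer(1)))
  expect_lt(lv, nt)
  # retained fractions sit near the emulated cohort's (~0.51 and ~0.71)
  expect_lt(abs(lv / 620 - 0.51), 0.07)
  expect_lt(abs(nt / 620 - 0.71), 0.07)
})

test_that("subject simulation is deterministic and truth spikes match FD", {
  g <- tiny_geometry()
  ph <- tiny_phenotype()
  gs <- default_group_specs(g$params)$NT
  s1 <- simulate_subject(g$params, ph, g$atlas, g$masks, seed = 9L,
                         group_spec = gs, voxel = TRUE)
  s2 <- simulate_subject(g$params, ph, g$atlas, g$masks, seed = 9L,
                         group_spec = gs, voxel = TRUE)
  expect_identical(s1$runs[[1]]$data, s2$runs[[1]]$data)
  expect_identical(s1$motion, s2$motion)
  fd <- compute_framewise_displacement(s1$motion[[1]])
  expect_identical(s1$truth$runs[[1]]$spike_frames, which(fd > 0.2))
})

test_that("replicate-averaged empirical correlations converge to the target", {
  # noise, global and confound leak off: only the latent ROI draws remain
  p <- sim_params(n_rois_per_hemisphere = 8L, n_frames_per_run = 1240L,
                  n_runs = 1L, noise_sd = 0, global_amp = 0,
                  confound_amp = 0, subject_z_sd = 0)
  atlas <- build_symmetric_parcellation(p)
  masks <- build_tissue_masks(p, atlas)
  R_target <- build_roi_covariance(p, atlas)
  acc <- 0
  for (s in 1:10) {
    sub <- simulate_subject(p, tiny_phenotype(), atlas, masks, seed = s,
                            voxel = FALSE)
    acc <- acc + stats::cor(sub$runs[[1]]$roi_data)
  }
  emp <- acc / 10
  expect_lt(max(abs(emp - unclass(R_target))), 0.05)
})

test_that("empirical correlation error decays monotonically with run length", {
  p0 <- sim_params(n_rois_per_hemisphere = 8L, n_runs = 1L, noise_sd = 0,
                   global_amp = 0, confound_amp = 0, subject_z_sd = 0)
  atlas <- build_symmetric_parcellation(p0)
  masks <- build_tissue_masks(p0, atlas)
  R_target <- unclass(build_roi_covariance(p0, atlas))
  err <- vapply(c(200L, 1600L, 12800L), function(n) {
    p <- sim_params(n_rois_per_hemisphere = 8L, n_frames_per_run = n,
                    n_runs = 1L, noise_sd = 0, global_amp = 0,
                    confound_amp = 0, subject_z_sd = 0)
    m <- 0
    for (s in 1:3) {
      sub <- simulate_subject(p, tiny_phenotype(), atlas, masks, seed = s,
                              voxel = FALSE)
      m <- m + mean(abs(stats::cor(sub$runs[[1]]$roi_data) - R_target))
    }
    m / 3
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("mean pairwise correlation increases monotonically with global amplitude", {
  means <- vapply(c(0, 0.5, 1.0), function(a) {
    p <- tiny_params(global_amp = a)
    g <- tiny_geometry(p)
    out <- 0
    for (s in 1:20) {
      sub <- simulate_subject(p, tiny_phenotype(), g$atlas, g$masks,
                              seed = s, voxel = FALSE)
      r <- stats::cor(sub$runs[[1]]$roi_data)
      out <- out + mean(r[upper.tri(r)])
    }
    out / 20
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("default cohort has 17 + 20 + 19 = 56 subjects with valid phenotypes", {
  p <- sim_params(n_frames_per_run = 10L, n_runs = 1L, noise_sd = 0)
  co <- simulate_cohort(p, seed = 2L, voxel = FALSE)
  expect_equal(length(co$subjects), 56L)
  expect_equal(as.integer(table(co$phenotypes$group)[c("LVCP", "HVCP", "NT")]),
               c(17L, 20L, 19L))
  expect_true(all(co$phenotypes$iq_composite[co$phenotypes$group == "LVCP"] <= 79))
  expect_true(all(co$phenotypes$iq_composite[co$phenotypes$group != "LVCP"] >= 80))
  expect_true(all(co$phenotypes$age_years >= 7 & co$phenotypes$age_years <= 17))
})

test_that("null cohort applies identical coupling targets across groups", {
  p <- sim_params(n_frames_per_run = 10L, n_runs = 1L, subject_z_sd = 0,
                  noise_sd = 0)
  gs <- default_group_specs(p, effects = "null")
  for (g in names(gs)) gs[[g]]$n <- 2L
  co <- simulate_cohort(p, gs, seed = 4L, voxel = FALSE)
  zt <- lapply(co$subjects, function(s) s$truth$target_z)
  for (k in 2:length(zt)) expect_equal(zt[[k]], zt[[1]])
})

test_that("planted within-default deficit is recovered at the generating level", {
  # LVCP within-default z set 0.15 below NT; the mean within-default Fisher z
  # difference across replicate cohorts recovers 0.15 within 2 SE
  p <- sim_params(n_rois_per_hemisphere = 16L, n_frames_per_run = 300L,
                  n_runs = 1L, noise_sd = 0, global_amp = 0, confound_amp = 0)
  gs <- default_group_specs(p)
  for (g in names(gs)) {
    gs[[g]]$n <- 4L
    gs[[g]]$spike_rate <- 0
    gs[[g]]$mf_frac_mean <- NULL
    gs[[g]]$iq_z_slope <- 0
  }
  gs$LVCP$within_z_delta <- c(default = -0.15)
  gs$LVCP$between_z_delta <- NULL
  atlas <- build_symmetric_parcellation(p)
  dflt <- which(atlas$roi_table$merged_network == "default")
  diffs <- vapply(1:50, function(r) {
    co <- simulate_cohort(p, gs, seed = r, voxel = FALSE)
    wm <- vapply(co$subjects, function(s) {
      z <- atanh(stats::cor(s$runs[[1]]$roi_data[, dflt]))
      mean(z[upper.tri(z)])
    }, numeric(1))
    grp <- co$phenotypes$group
    mean(wm[grp == "NT"]) - mean(wm[grp == "LVCP"])
  }, numeric(1))
  se <- stats::sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - 0.15), 2 * se + 1e-9)
})

test_that("cohorts are fully reproducible for a fixed seed", {
  p <- sim_params(n_frames_per_run = 50L, n_runs = 2L)
  gs <- default_group_specs(p)
  for (g in names(gs)) gs[[g]]$n <- 2L
  c1 <- simulate_cohort(p, gs, seed = 7L, voxel = FALSE)
  c2 <- simulate_cohort(p, gs, seed = 7L, voxel = FALSE)
  expect_identical(c1$phenotypes, c2$phenotypes)
  expect_identical(c1$subjects[[1]]$runs[[1]]$roi_data,
                   c2$subjects[[1]]$runs[[1]]$roi_data)
  expect_identical(c1$manifest, c2$manifest)
})
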