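# Covariate-adjusted inference, FDR, IQ correlations, GSR contrast.

make_design <- function(n = c(LVCP = 10L, HVCP = 10L, NT = 10L), seed = 1L) {
  set.seed(seed)
  phen <- do.call(rbind, lapply(names(n), function(g) {
    data.frame(subject_id = sprintf("s-%s%02d", g, seq_len(n[[g]])),
               group = g,
               age_years = stats::runif(n[[g]], 7, 17),
               sex = sample(c("M", "F"), n[[g]], replace = TRUE),
               iq_composite = round(stats::runif(n[[g]], 40, 130)))
  }))
  nmf <- stats::setNames(round(stats::runif(nrow(phen), 300, 1100)),
                         phen$subject_id)
  cohort_design(phen, nmf)
}

test_that("ANCOVA reduces to one-way ANOVA when covariates carry no weight", {
  # covariates constructed orthogonal to the group indicators: the group F
  # from the covariate model equals the sequential ANOVA F with group first
  d <- make_design(seed = 3L)
  d$age_years <- stats::residuals(stats::lm(d$age_years ~ d$group)) + 12
  d$n_motion_free <- stats::residuals(stats::lm(d$n_motion_free ~ d$group)) + 600
  d$sex <- rep_len(c("M", "F"), nrow(d))  # balanced within groups
  set.seed(4)
  v <- stats::rnorm(nrow(d)) + 0.8 * (d$group == "LVCP")
  a <- ancova_three_group(v, d)
  expect_equal(a$df[1], 2L)
  seq_aov <- summary(stats::aov(v ~ d$group + d$age_years + factor(d$sex) +
                                  d$n_motion_free))[[1]]
  expect_equal(a$F, seq_aov$`F value`[1], tolerance = 1e-8)
})

test_that("ANCOVA type-I error is nominal under the null", {
  d <- make_design(seed = 5L)
  rej <- 0L
  for (r in 1:1000) {
    set.seed(r)
    p <- ancova_three_group(stats::rnorm(nrow(d)), d)$p
    rej <- rej + (p < 0.05)
  }
  expect_gte(rej / 1000, 0.03)
  expect_lte(rej / 1000, 0.07)
})

test_that("ANCOVA power reaches 0.8 for a 0.15 z deficit at the study group sizes", {
  d <- make_design(n = c(LVCP = 17L, HVCP = 20L, NT = 19L), seed = 6L)
  hits <- 0L
  for (r in 1:200) {
    set.seed(r)
    v <- stats::rnorm(nrow(d), sd = 0.12) - 0.15 * (d$group == "LVCP")
    hits <- hits + (ancova_three_group(v, d)$p < 0.05)
  }
  expect_gte(hits / 200, 0.8)
})

test_that("a covariate fully explaining the group difference removes the effect", {
  set.seed(7)
  n <- 20L
  # group differs only through age, and the value is a pure age effect
  phen <- data.frame(subject_id = sprintf("s%02d", 1:(3 * n)),
                     group = rep(c("LVCP", "HVCP", "NT"), each = n),
                     age_years = c(stats::runif(n, 7, 11),
                                   stats::runif(n, 10, 14),
                                   stats::runif(n, 13, 17)),
                     sex = rep_len(c("M", "F"), 3 * n),
                     iq_composite = 100)
  nmf <- stats::setNames(rep(600, 3 * n) + stats::rnorm(3 * n), phen$subject_id)
  d <- cohort_design(phen, nmf)
  v <- 0.1 * d$age_years + stats::rnorm(3 * n, sd = 0.02)
  a <- ancova_three_group(v, d)
  expect_gt(a$p, 0.05)
  # without adjustment the raw group means differ strongly
  expect_lt(summary(stats::aov(v ~ d$group))[[1]]$`Pr(>F)`[1], 1e-4)
})

test_that("ANCOVA errors on constant covariates", {
  d <- make_design(seed = 8L)
  d$sex <- "M"
  expect_error(ancova_three_group(stats::rnorm(nrow(d)), d), "sex")
})

test_that("pooled t test matches the textbook case and the ANCOVA contrast direction", {
  tt <- two_group_ttest(c(1, 2, 3, 2, 3, 4),
                        rep(c("a", "b"), each = 3), "a", "b")
  expect_equal(tt$t, -1.224745, tolerance = 1e-6)
  expect_equal(tt$df, 4L)
  # agrees with stats::t.test pooled variant
  st <- stats::t.test(c(1, 2, 3), c(2, 3, 4), var.equal = TRUE)
  expect_equal(tt$t, unname(st$statistic), tolerance = 1e-12)
  expect_equal(tt$p, st$p.value, tolerance = 1e-12)

  same <- two_group_ttest(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3), "a", "b")
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(two_group_ttest(rep(1, 6), rep(c("a", "b"), 3), "a", "b"),
               "zero pooled variance")

  d <- make_design(seed = 9L)
  set.seed(10)
  v <- stats::rnorm(nrow(d)) - 0.5 * (d$group == "LVCP")
  a <- ancova_three_group(v, d)
  tt2 <- two_group_ttest(v, as.character(d$group), "LVCP", "NT")
  ct <- a$contrasts[a$contrasts$contrast == "LVCP - NT", ]
  expect_equal(sign(ct$t), sign(tt2$t))
})

test_that("BH correction matches the hand step-up example and the brute-force oracle", {
  out <- fdr_bh(c(0.01, 0.02, 0.03, 0.04, 0.05))
  expect_true(all(out$flag))
  expect_equal(out$q[5], 0.05)
  expect_equal(fdr_bh(0.04)$q, 0.04)
  expect_error(fdr_bh(numeric(0)), "empty")
  expect_error(fdr_bh(c(0.5, 1.2)), "p values")

  for (s in 1:200) {
    set.seed(s)
    p <- stats::runif(sample(3:40, 1))^sample(1:3, 1)
    out <- fdr_bh(p)
    expect_equal(out$q, bh_oracle(p), tolerance = 1e-12)
    # q monotone nondecreasing in p, flags consistent with threshold
    expect_true(all(diff(out$q[order(out$p)]) >= -1e-12))
    expect_equal(out$flag, out$q <= 0.05)
  }
})

test_that("BH controls the any-discovery rate under a global null (m = 333)", {
  any_disc <- vapply(1:1000, function(s) {
    set.seed(s)
    any(fdr_bh(stats::runif(333))$flag)
  }, logical(1))
  expect_lte(mean(any_disc), 0.06)
})

test_that("IQ-connectivity correlations detect a planted monotone effect", {
  d <- make_design(n = c(LVCP = 12L, HVCP = 4L, NT = 4L), seed = 11L)
  ids <- d$subject_id
  nR <- 10L
  set.seed(12)
  base <- matrix(stats::rnorm(nR * nR), nR, nR)
  bundles <- lapply(seq_along(ids), function(i) {
    slope <- if (d$group[i] == "LVCP") -0.004 * (d$iq_composite[i] - 70) else 0
    z <- base + slope + matrix(stats::rnorm(nR * nR, sd = 0.02), nR, nR)
    z <- (z + t(z)) / 2
    diag(z) <- NaN
    structure(list(zmat = z, stream = "nogsr"), class = "connectivity_result")
  })
  names(bundles) <- ids
  res <- iq_connectivity_correlation(bundles, d, "LVCP")
  expect_gt(res$frac_negative, 0.9)
  # null group shows no systematic direction
  res_nt <- tryCatch(iq_connectivity_correlation(bundles, d, "NT"),
                     error = function(e) NULL)
  expect_true(is.null(res_nt) || abs(res_nt$frac_negative - 0.5) < 0.45)

  d2 <- d[d$group != "LVCP" | d$subject_id %in% ids[1:2], ]
  expect_error(iq_connectivity_correlation(bundles, d2, "LVCP"), ">= 3")
})

test_that("identical streams give full sign agreement and zero median shift", {
  spec <- recovery_benchmark_spec(seed = 21L)
  for (g in names(spec$groups)) spec$groups[[g]]$n <- 4L
  co <- simulate_cohort(spec$params, spec$groups, seed = 21L, voxel = FALSE)
  ft <- fcpipe:::cohort_family_tables(co, use_gsr = FALSE, min_volumes = 200L)
  gc <- gsr_contrast(ft$tables, ft$tables, ft$bundles, ft$bundles, ft$design)
  expect_true(all(gc$sign_agreement == 1))
  expect_equal(gc$median_diff_shift, 0)
  expect_equal(gc$median_z["gsr", ], gc$median_z["nogsr", ])
})

test_that("a generalized shared-variance group difference vanishes under GSR", {
  # HVCP carries a uniform coupling excess on every cell -- an extra shared
  # component, the signature of a stronger global signal. Without GSR the
  # LVCP - HVCP median difference is broadly negative; GSR recenters both
  # groups' medians near zero and removes the generalized difference.
  p <- sim_params(n_frames_per_run = 400L, n_runs = 1L,
                  n_rois_per_hemisphere = 16L, subject_z_sd = 0.02)
  gs <- default_group_specs(p, effects = "null")
  for (g in names(gs)) {
    gs[[g]]$n <- 6L; gs[[g]]$spike_rate <- 5; gs[[g]]$mf_frac_mean <- NULL
  }
  nets <- fc_networks()
  gs$HVCP$within_z_delta <- stats::setNames(rep(0.3, 8), nets)
  prs <- utils::combn(nets, 2)
  gs$HVCP$between_z_delta <- lapply(seq_len(ncol(prs)), function(k)
    list(prs[1, k], prs[2, k], 0.3))
  co <- simulate_cohort(p, gs, seed = 13L, voxel = FALSE)
  ft_no <- fcpipe:::cohort_family_tables(co, use_gsr = FALSE, min_volumes = 200L)
  ft_gs <- fcpipe:::cohort_family_tables(co, use_gsr = TRUE, min_volumes = 200L)
  gc <- gsr_contrast(ft_gs$tables, ft_no$tables, ft_gs$bundles,
                     ft_no$bundles, ft_no$design)
  expect_lt(gc$median_z["nogsr", "LVCP"] - gc$median_z["nogsr", "HVCP"], -0.1)
  expect_lt(abs(gc$median_z["gsr", "LVCP"]), 0.06)
  expect_lt(abs(gc$median_z["gsr", "HVCP"]), 0.06)
  expect_lt(abs(gc$median_diff_shift -
                  (gc$median_z["gsr", "LVCP"] - gc$median_z["gsr", "HVCP"]) +
                  (gc$median_z["nogsr", "LVCP"] -
                     gc$median_z["nogsr", "HVCP"])), 1e-12)
})

test_that("family tables carry consistent flags, sizes and q monotonicity", {
  spec <- recovery_benchmark_spec(seed = 31L)
  for (g in names(spec$groups)) spec$groups[[g]]$n <- 5L
  co <- simulate_cohort(spec$params, spec$groups, seed = 31L, voxel = FALSE)
  ft <- fcpipe:::cohort_family_tables(co, use_gsr = FALSE, min_volumes = 200L)
  t <- ft$tables
  expect_equal(attr(t$homotopic, "family_size"),
               sum(co$atlas$roi_table$hemisphere == "L"))
  expect_equal(nrow(t$between_network), choose(8, 2))
  expect_equal(nrow(t$within_network), 8L)
  expect_equal(nrow(t$net_to_roi), nrow(co$atlas$roi_table))
  for (fam in names(t)) {
    tab <- t[[fam]]
    pq <- list(c("p", "q", "flag"), c("p_LVCP_NT", "q_LVCP_NT", "flag_LVCP_NT"),
               c("p_LVCP_HVCP", "q_LVCP_HVCP", "flag_LVCP_HVCP"))
    for (cols in pq) {
      if (!all(cols %in% names(tab))) next
      o <- order(tab[[cols[1]]])
      expect_true(all(diff(tab[[cols[2]]][o]) >= -1e-12))
      expect_equal(tab[[cols[3]]], tab[[cols[2]]] <= 0.05)
    }
  }
  # missing bundle is reported by id
  expect_error(run_family_analyses(ft$bundles[-1], ft$design),
               ft$design$subject_id[1])
})
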