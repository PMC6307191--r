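# Covariate-adjusted group inference and FDR over connectivity summaries.

#' Build the cohort design table
#'
#' @param phenotypes Phenotype data.frame (`subject_id`, `group`, `age_years`,
#'   `sex`, `iq_composite`).
#' @param n_motion_free Named vector of kept-volume counts per subject.
#' @param stream Stream label ("gsr"/"nogsr").
#' @return A `cohort_design` data.frame with `group` as a factor
#'   (LVCP/HVCP/NT).
#' @export
cohort_design <- function(phenotypes, n_motion_free, stream = "nogsr") {
  d <- phenotypes
  d$n_motion_free <- as.numeric(n_motion_free[d$subject_id])
  if (anyNA(d$n_motion_free) || anyNA(d$age_years) || anyNA(d$sex))
    stopf("missing covariates in design")
  d$group <- factor(d$group, levels = intersect(c("LVCP", "HVCP", "NT"),
                                                unique(d$group)))
  if (any(table(d$group) < 2L)) stopf("need >= 2 subjects per group")
  attr(d, "stream") <- stream
  class(d) <- c("cohort_design", class(d))
  d
}

#' Three-group ANCOVA with age, sex and motion covariates
#'
#' Ordinary least squares of the per-subject value on an intercept, two group
#' indicator columns, age, sex and number of motion-free volumes. The group
#' effect is tested by model comparison (F with 2 numerator degrees of
#' freedom); pairwise group contrasts are unprotected t statistics from the
#' same fit; adjusted group means are predictions at the sample means of the
#' covariates.
#'
#' @param values Per-subject numeric vector (design row order).
#' @param design A [cohort_design()] table.
#' @return List: `F`, `p`, `df`, `adjusted_means`, `contrasts` (data.frame of
#'   pairwise t / p), `fit`.
#' @export
ancova_three_group <- function(values, design) {
  if (length(values) != nrow(design)) stopf("values length != design rows")
  d <- data.frame(value = values, group = design$group,
                  age_years = design$age_years,
                  sex = factor(design$sex),
                  n_motion_free = design$n_motion_free)
  for (cl in c("age_years", "n_motion_free"))
    if (stats::sd(d[[cl]]) == 0) stopf("covariate '%s' is constant", cl)
  if (nlevels(d$sex) < 2L) stopf("covariate 'sex' is constant")
  full <- stats::lm(value ~ group + age_years + sex + n_motion_free, data = d)
  if (anyNA(stats::coef(full))) {
    bad <- names(which(is.na(stats::coef(full))))
    stopf("rank-deficient ANCOVA design; aliased: %s",
          paste(bad, collapse = ", "))
  }
  reduced <- stats::lm(value ~ age_years + sex + n_motion_free, data = d)
  an <- stats::anova(reduced, full)
  Fv <- an$F[2]
  p <- an$`Pr(>F)`[2]

  cf <- stats::coef(full)
  V <- stats::vcov(full)
  lev <- levels(d$group)
  gcol <- function(g) if (g == lev[1]) 0 else cf[[paste0("group", g)]]
  gvar <- function(a, b) {
    ca <- cb <- rep(0, length(cf)); names(ca) <- names(cb) <- names(cf)
    if (a != lev[1]) ca[paste0("group", a)] <- 1
    if (b != lev[1]) cb[paste0("group", b)] <- 1
    w <- ca - cb
    drop(t(w) %*% V %*% w)
  }
  pairs <- utils::combn(lev, 2)
  contrasts <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    est <- gcol(a) - gcol(b)
    se <- sqrt(gvar(a, b))
    tv <- est / se
    data.frame(contrast = paste(a, "-", b), estimate = est, t = tv,
               p = 2 * stats::pt(-abs(tv), df = full$df.residual))
  }))
  base <- data.frame(age_years = mean(d$age_years),
                     sex = factor(levels(d$sex)[1], levels = levels(d$sex)),
                     n_motion_free = mean(d$n_motion_free))
  # sex-balanced adjusted means: average predictions over sex levels
  adj <- vapply(lev, function(g) {
    mean(vapply(levels(d$sex), function(sx) {
      nd <- base; nd$sex <- factor(sx, levels = levels(d$sex)); nd$group <-
        factor(g, levels = lev)
      unname(stats::predict(full, nd))
    }, numeric(1)))
  }, numeric(1))
  list(F = Fv, p = p, df = c(2L, full$df.residual),
       adjusted_means = adj, contrasts = contrasts, fit = full)
}

#' Pooled-variance two-sample t test
#'
#' Student t with pooled variance, two-tailed p value.
#'
#' @param values Numeric vector.
#' @param groups Group label per value.
#' @param a,b The two labels to compare (difference `a - b`).
#' @return List: `t`, `p`, `df`, `estimate` (mean difference).
#' @export
two_group_ttest <- function(values, groups, a, b) {
  xa <- values[groups == a]
  xb <- values[groups == b]
  if (length(xa) < 2L || length(xb) < 2L) stopf("need >= 2 per group")
  na <- length(xa); nb <- length(xb)
  sp2 <- ((na - 1) * stats::var(xa) + (nb - 1) * stats::var(xb)) / (na + nb - 2)
  if (sp2 == 0) stopf("zero pooled variance")
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tv <- (mean(xa) - mean(xb)) / se
  df <- na + nb - 2
  list(t = tv, p = 2 * stats::pt(-abs(tv), df), df = df,
       estimate = mean(xa) - mean(xb))
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up q values over one family of p values, with significance flags at
#' `q <= alpha` (the step-up rule rejects at equality).
#'
#' @param p Vector of p values in \[0, 1\].
#' @param alpha Flag threshold (default 0.05).
#' @param family Family label recorded with the result.
#' @return Data frame: `p`, `q`, `flag`, with attribute `family`.
#' @export
fdr_bh <- function(p, alpha = 0.05, family = "") {
  if (length(p) == 0L) stopf("empty p-value family")
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) stopf("p values must be in [0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(p = p, q = q, flag = q <= alpha)
  attr(out, "family") <- family
  out
}

group_values <- function(bundles, extract) {
  vapply(bundles, extract, numeric(1))
}

#' Run every family of group analyses for one processing stream
#'
#' Families, each corrected separately with Benjamini-Hochberg FDR exactly
#' over its own tests:
#' \itemize{
#'   \item `within_network`: per-network mean within-network z, three-group
#'     ANCOVA (age, sex, motion-free volumes), family = networks.
#'   \item `between_network`: per network pair, pooled t tests for LVCP vs NT
#'     and LVCP vs HVCP (each contrast its own FDR family over the pairs),
#'     plus the covariate GLM check (group F from the full ANCOVA).
#'   \item `net_to_roi`: per ROI, network-mean-to-ROI z, LVCP vs NT t test,
#'     family = all ROIs.
#'   \item `homotopic`: per mirror pair, LVCP vs HVCP and LVCP vs NT t tests,
#'     per-contrast FDR over pairs.
#' }
#'
#' @param bundles Named list of `connectivity_result` (one stream), design
#'   row order.
#' @param design A [cohort_design()] table.
#' @param alpha FDR flag threshold.
#' @return Named list of `group_stat_table` data.frames.
#' @export
run_family_analyses <- function(bundles, design, alpha = 0.05) {
  miss <- setdiff(design$subject_id, names(bundles))
  if (length(miss))
    stopf("missing connectivity bundles for: %s", paste(miss, collapse = ", "))
  bundles <- bundles[design$subject_id]
  groups <- as.character(design$group)
  if (!all(c("LVCP", "HVCP", "NT") %in% groups))
    stopf("run_family_analyses needs all three groups in the design")
  stream <- bundles[[1]]$stream

  nets <- names(bundles[[1]]$within_mean)
  within <- do.call(rbind, lapply(nets, function(k) {
    v <- group_values(bundles, function(b) b$within_mean[[k]])
    gm <- tapply(v, groups, mean)
    a <- ancova_three_group(v, design)
    data.frame(effect = k, mean_LVCP = gm[["LVCP"]], mean_HVCP = gm[["HVCP"]],
               mean_NT = gm[["NT"]], statistic = a$F, p = a$p)
  }))
  within <- cbind(within, fdr_bh(within$p, alpha)[c("q", "flag")])

  bz <- bundles[[1]]$between_z
  prs <- which(upper.tri(bz), arr.ind = TRUE)
  pair_names <- paste(rownames(bz)[prs[, 1]], colnames(bz)[prs[, 2]],
                      sep = " ~ ")
  between <- do.call(rbind, lapply(seq_len(nrow(prs)), function(k) {
    v <- group_values(bundles, function(b) b$between_z[prs[k, 1], prs[k, 2]])
    t_nt <- two_group_ttest(v, groups, "LVCP", "NT")
    t_hv <- two_group_ttest(v, groups, "LVCP", "HVCP")
    glm_check <- ancova_three_group(v, design)
    data.frame(effect = pair_names[k],
               mean_LVCP = mean(v[groups == "LVCP"]),
               mean_HVCP = mean(v[groups == "HVCP"]),
               mean_NT = mean(v[groups == "NT"]),
               t_LVCP_NT = t_nt$t, p_LVCP_NT = t_nt$p,
               t_LVCP_HVCP = t_hv$t, p_LVCP_HVCP = t_hv$p,
               glm_F = glm_check$F, glm_p = glm_check$p)
  }))
  b1 <- fdr_bh(between$p_LVCP_NT, alpha)
  b2 <- fdr_bh(between$p_LVCP_HVCP, alpha)
  between$q_LVCP_NT <- b1$q; between$flag_LVCP_NT <- b1$flag
  between$q_LVCP_HVCP <- b2$q; between$flag_LVCP_HVCP <- b2$flag

  ntr <- bundles[[1]]$net_to_roi
  net_to_roi <- do.call(rbind, lapply(seq_len(nrow(ntr)), function(k) {
    v <- group_values(bundles, function(b) b$net_to_roi$z[k])
    tt <- two_group_ttest(v, groups, "LVCP", "NT")
    data.frame(effect = sprintf("roi_%d", ntr$roi_id[k]),
               member = ntr$member[k],
               mean_LVCP = mean(v[groups == "LVCP"]),
               mean_NT = mean(v[groups == "NT"]),
               statistic = tt$t, p = tt$p)
  }))
  net_to_roi <- cbind(net_to_roi, fdr_bh(net_to_roi$p, alpha)[c("q", "flag")])

  hz_ids <- names(bundles[[1]]$homotopic_z)
  homotopic <- do.call(rbind, lapply(seq_along(hz_ids), function(k) {
    v <- group_values(bundles, function(b) b$homotopic_z[[k]])
    t_hv <- two_group_ttest(v, groups, "LVCP", "HVCP")
    t_nt <- two_group_ttest(v, groups, "LVCP", "NT")
    data.frame(effect = sprintf("pair_%s", hz_ids[k]),
               mean_LVCP = mean(v[groups == "LVCP"]),
               mean_HVCP = mean(v[groups == "HVCP"]),
               mean_NT = mean(v[groups == "NT"]),
               t_LVCP_HVCP = t_hv$t, p_LVCP_HVCP = t_hv$p,
               t_LVCP_NT = t_nt$t, p_LVCP_NT = t_nt$p)
  }))
  h1 <- fdr_bh(homotopic$p_LVCP_HVCP, alpha)
  h2 <- fdr_bh(homotopic$p_LVCP_NT, alpha)
  homotopic$q_LVCP_HVCP <- h1$q; homotopic$flag_LVCP_HVCP <- h1$flag
  homotopic$q_LVCP_NT <- h2$q; homotopic$flag_LVCP_NT <- h2$flag

  out <- list(within_network = within, between_network = between,
              net_to_roi = net_to_roi, homotopic = homotopic)
  for (nm in names(out)) {
    attr(out[[nm]], "family") <- nm
    attr(out[[nm]], "family_size") <- nrow(out[[nm]])
    attr(out[[nm]], "stream") <- stream
    class(out[[nm]]) <- c("group_stat_table", class(out[[nm]]))
  }
  out
}

#' Pairwise IQ-connectivity correlation within a subgroup
#'
#' Pearson correlation, across the subjects of one group, between composite
#' IQ and the Fisher-z connectivity of every ROI pair.
#'
#' @param bundles Named list of `connectivity_result`.
#' @param design A [cohort_design()] table (supplies IQ and group).
#' @param group Subgroup to analyze (default LVCP).
#' @return List: `r_mat` (ROI x ROI Pearson r of z vs IQ, NaN diagonal), `n`,
#'   `frac_negative` (fraction of pairs with negative r).
#' @export
iq_connectivity_correlation <- function(bundles, design, group = "LVCP") {
  keep <- design$subject_id[design$group == group]
  if (length(keep) < 3L) stopf("need >= 3 subjects in subgroup %s", group)
  iq <- design$iq_composite[match(keep, design$subject_id)]
  if (stats::sd(iq) == 0) stopf("IQ is constant in subgroup")
  zs <- lapply(bundles[keep], `[[`, "zmat")
  nR <- ncol(zs[[1]])
  flat <- vapply(zs, function(z) z[upper.tri(z)], numeric(sum(upper.tri(zs[[1]]))))
  r <- apply(flat, 1, function(v) stats::cor(v, iq))
  r_mat <- matrix(NaN, nR, nR, dimnames = dimnames(zs[[1]]))
  r_mat[upper.tri(r_mat)] <- r
  r_mat[lower.tri(r_mat)] <- t(r_mat)[lower.tri(r_mat)]
  list(r_mat = r_mat, n = length(keep), frac_negative = mean(r < 0))
}

#' Correlation between IQ and a scalar connectivity summary
#'
#' @param values Per-subject summary (design order).
#' @param design A [cohort_design()] table.
#' @param group Optional subgroup restriction.
#' @return List: `r`, `p`, `n`.
#' @export
iq_summary_correlation <- function(values, design, group = NULL) {
  idx <- if (is.null(group)) seq_len(nrow(design))
         else which(design$group == group)
  if (length(idx) < 3L) stopf("need >= 3 subjects")
  ct <- stats::cor.test(values[idx], design$iq_composite[idx])
  list(r = unname(ct$estimate), p = ct$p.value, n = length(idx))
}

median_connection_by_group <- function(bundles, design) {
  vapply(split(design$subject_id, design$group), function(ids) {
    stats::median(unlist(lapply(bundles[ids],
                                function(b) off_diag(b$zmat))))
  }, numeric(1))
}

#' Contrast group-difference patterns between GSR and non-GSR streams
#'
#' Reports, per family: the median pairwise connection z per group per
#' stream, the sign-agreement fraction of the group-difference t statistics
#' between streams, and the shift in the median LVCP-HVCP difference.
#'
#' @param tables_gsr,tables_nogsr Outputs of [run_family_analyses()] for the
#'   two streams of the same cohort.
#' @param bundles_gsr,bundles_nogsr The per-subject connectivity bundles.
#' @param design A [cohort_design()] table.
#' @return List: `median_z` (group x stream), `sign_agreement` (per family),
#'   `median_diff_shift`.
#' @export
gsr_contrast <- function(tables_gsr, tables_nogsr, bundles_gsr,
                         bundles_nogsr, design) {
  if (!identical(sort(names(bundles_gsr)), sort(names(bundles_nogsr))))
    stopf("GSR and non-GSR streams cover different subjects")
  med <- rbind(gsr = median_connection_by_group(bundles_gsr, design),
               nogsr = median_connection_by_group(bundles_nogsr, design))
  tcol <- list(between_network = "t_LVCP_HVCP",
               homotopic = "t_LVCP_HVCP")
  sign_agreement <- vapply(names(tcol), function(f) {
    a <- tables_gsr[[f]][[tcol[[f]]]]
    b <- tables_nogsr[[f]][[tcol[[f]]]]
    mean(sign(a) == sign(b))
  }, numeric(1))
  diff_shift <- (med["gsr", "LVCP"] - med["gsr", "HVCP"]) -
    (med["nogsr", "LVCP"] - med["nogsr", "HVCP"])
  list(median_z = med, sign_agreement = sign_agreement,
       median_diff_shift = diff_shift)
}
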