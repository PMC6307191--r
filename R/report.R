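# Human-readable report figures, regenerated deterministically from the
# pipeline's output tables alone (no raw data needed).

#' Render report figures from pipeline output tables
#'
#' Reads the TSV tables written by [run_pipeline()] under `dir` and renders:
#' a per-subject motion bar chart (acquired vs motion-free volumes),
#' within-network connectivity boxplots by group with significance asterisks,
#' a between-network group-difference matrix with FDR asterisks, homotopic
#' t-statistic histograms with FDR-passing bins highlighted, and (when
#' present) the GSR-vs-non-GSR median summary.
#'
#' @param dir Pipeline output directory.
#' @param streams Streams to render (default: whatever is present).
#' @return Character vector of figure file names (relative to `dir`).
#' @export
make_report <- function(dir, streams = NULL) {
  if (is.null(streams)) {
    streams <- c("nogsr", "gsr")
    streams <- streams[file.exists(file.path(
      dir, sprintf("stats_%s_within_network.tsv", streams)))]
  }
  figs <- character(0)
  pngf <- function(name, code, width = 900, height = 600) {
    path <- file.path(dir, name)
    grDevices::png(path, width = width, height = height)
    on.exit(grDevices::dev.off(), add = TRUE)
    code()
    figs <<- c(figs, name)
  }

  usab <- read_tsv(file.path(dir, "usability.tsv"))
  phen <- read_tsv(file.path(dir, "phenotypes.tsv"))
  usab <- merge(usab, phen, by = "subject_id")
  usab <- usab[order(usab$group, usab$subject_id), ]
  pngf("fig_motion.png", function() {
    graphics::barplot(usab$n_motion_free,
                      names.arg = usab$subject_id, las = 2, cex.names = 0.6,
                      col = c(LVCP = "firebrick", HVCP = "steelblue",
                              NT = "gray60")[usab$group],
                      ylab = "motion-free volumes",
                      main = "Motion-free volumes per subject")
    graphics::abline(h = 200, lty = 2)
  })

  for (st in streams) {
    within <- read_tsv(file.path(dir, sprintf("stats_%s_within_network.tsv", st)))
    summ <- read_tsv(file.path(dir, sprintf("subject_summaries_%s.tsv", st)))
    summ <- merge(summ, phen[, c("subject_id", "group")], by = "subject_id")
    summ$group <- factor(summ$group, c("LVCP", "HVCP", "NT"))
    pngf(sprintf("fig_within_%s.png", st), function() {
      op <- graphics::par(mfrow = c(2, 4), mar = c(3, 3, 3, 1))
      on.exit(graphics::par(op), add = TRUE)
      for (k in seq_len(nrow(within))) {
        nk <- within$effect[k]
        sub <- summ[summ$network == nk, ]
        graphics::boxplot(within_mean_z ~ group, data = sub, main = nk,
                          ylab = "within-network z", xlab = "")
        if (isTRUE(within$flag[k]))
          graphics::mtext("*", side = 3, line = -1.2, cex = 2)
      }
    })

    between <- read_tsv(file.path(dir, sprintf("stats_%s_between_network.tsv", st)))
    nets <- unique(unlist(strsplit(between$effect, " ~ ")))
    nn <- length(nets)
    tm <- matrix(NA_real_, nn, nn, dimnames = list(nets, nets))
    for (k in seq_len(nrow(between))) {
      ab <- strsplit(between$effect[k], " ~ ")[[1]]
      tm[ab[1], ab[2]] <- tm[ab[2], ab[1]] <- between$t_LVCP_NT[k]
    }
    pngf(sprintf("fig_between_%s.png", st), function() {
      graphics::image(seq_len(nn), seq_len(nn), tm, axes = FALSE,
                      xlab = "", ylab = "",
                      main = sprintf("LVCP vs NT between-network t (%s)", st),
                      col = grDevices::hcl.colors(21, "Blue-Red 2"))
      graphics::axis(1, seq_len(nn), nets, las = 2, cex.axis = 0.7)
      graphics::axis(2, seq_len(nn), nets, las = 2, cex.axis = 0.7)
      flagged <- between[between$flag_LVCP_NT, "effect"]
      for (f in flagged) {
        ab <- strsplit(f, " ~ ")[[1]]
        i <- match(ab[1], nets); j <- match(ab[2], nets)
        graphics::text(c(i, j), c(j, i), "*", cex = 2)
      }
    })

    hom <- read_tsv(file.path(dir, sprintf("stats_%s_homotopic.tsv", st)))
    pngf(sprintf("fig_homotopic_%s.png", st), function() {
      op <- graphics::par(mfrow = c(1, 2))
      on.exit(graphics::par(op), add = TRUE)
      for (ct in c("LVCP_HVCP", "LVCP_NT")) {
        tv <- hom[[paste0("t_", ct)]]
        fl <- hom[[paste0("flag_", ct)]]
        h <- graphics::hist(tv, breaks = 20, plot = FALSE)
        bin_flag <- vapply(seq_along(h$mids), function(b) {
          inb <- tv >= h$breaks[b] & tv < h$breaks[b + 1]
          any(fl[inb])
        }, logical(1))
        graphics::plot(h, col = ifelse(bin_flag, "firebrick", "gray80"),
                       main = sprintf("homotopic t, %s (%s)", ct, st),
                       xlab = "t statistic")
      }
    })
  }

  gc_path <- file.path(dir, "gsr_contrast.json")
  if (file.exists(gc_path)) {
    gc <- jsonlite::read_json(gc_path, simplifyVector = TRUE)
    pngf("fig_gsr_medians.png", function() {
      mz <- as.matrix(as.data.frame(gc$median_z))
      graphics::barplot(mz, beside = TRUE, legend.text = rownames(mz),
                        ylab = "median connection z",
                        main = "Median connection by group and stream")
      graphics::abline(h = 0, lty = 2)
    })
  }
  figs
}
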