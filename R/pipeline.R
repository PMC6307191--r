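# End-to-end orchestration: simulate -> preprocess -> connectivity ->
# group statistics -> report, with a serializable config and a checksum
# manifest.

#' Pipeline run configuration
#'
#' Defaults equal the analysis parameters the pipeline is built around:
#' FD threshold 0.2 mm, 200-volume usability minimum, 0.001-0.1 Hz passband,
#' and both GSR streams.
#'
#' @param output_dir Output directory.
#' @param seed Integer seed for the whole run.
#' @param fd_threshold_mm Censoring threshold (> 0).
#' @param min_volumes Usability minimum.
#' @param band Passband in Hz.
#' @param gsr `"on"`, `"off"`, or `"both"`.
#' @param effects Cohort effects: `"planted"` or `"null"`.
#' @param voxel Simulate voxel volumes (`TRUE`) or exact ROI-level
#'   equivalents (`FALSE`).
#' @param figures Render report figures.
#' @param params_overrides Named list of [sim_params()] arguments.
#' @param group_n Optional named vector overriding group sizes.
#' @return A validated `run_config` list.
#' @export
run_config <- function(output_dir = "fcpipe_out", seed = 1L,
                       fd_threshold_mm = 0.2, min_volumes = 200L,
                       band = c(0.001, 0.1), gsr = c("both", "on", "off"),
                       effects = c("planted", "null"), voxel = FALSE,
                       figures = FALSE, params_overrides = list(),
                       group_n = NULL) {
  gsr <- match.arg(gsr)
  effects <- match.arg(effects)
  if (fd_threshold_mm <= 0) stopf("config error at fd_threshold_mm: must be > 0")
  if (min_volumes < 1) stopf("config error at min_volumes: must be >= 1")
  if (length(band) != 2L || band[1] < 0 || band[2] <= band[1])
    stopf("config error at band: need 0 <= lo < hi")
  cfg <- list(output_dir = output_dir, seed = as.integer(seed),
              fd_threshold_mm = fd_threshold_mm,
              min_volumes = as.integer(min_volumes), band = band, gsr = gsr,
              effects = effects, voxel = voxel, figures = figures,
              params_overrides = params_overrides, group_n = group_n)
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a run configuration as YAML
#'
#' @param cfg A `run_config`.
#' @param path YAML file path.
#' @return `write_run_config`: the path; `read_run_config`: the config.
#' @export
write_run_config <- function(cfg, path) {
  cfg <- unclass(cfg)
  # named atomic vectors serialize as YAML maps only as lists
  cfg$params_overrides <- lapply(cfg$params_overrides, function(x)
    if (is.atomic(x) && !is.null(names(x))) as.list(x) else x)
  if (!is.null(cfg$group_n)) cfg$group_n <- as.list(cfg$group_n)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$params_overrides <- lapply(raw$params_overrides, function(x)
    if (is.list(x)) unlist(x) else x)
  if (!is.null(raw$group_n)) raw$group_n <- unlist(raw$group_n)
  do.call(run_config, raw)
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  cfg$output_dir <- NULL  # location does not affect results
  yaml::write_yaml(unclass(cfg), f)
  unname(tools::md5sum(f))
}

#' Run the full pipeline
#'
#' Simulates the configured cohort, preprocesses and extracts connectivity
#' for each GSR stream, runs every family of group statistics, writes all
#' tables and a checksum manifest under `cfg$output_dir`, and (optionally)
#' renders report figures. If a manifest from an identical configuration and
#' seed is already present and all recorded outputs verify, the run is
#' skipped and the recorded manifest returned (resumable / idempotent).
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with `manifest`, `tables` (per stream),
#'   `gsr_contrast` (when both streams ran), `design`, and `cohort`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg)
  man_path <- file.path(out, "manifest.json")
  if (file.exists(man_path)) {
    prev <- jsonlite::read_json(man_path, simplifyVector = TRUE)
    files <- file.path(out, names(prev$files))
    if (identical(prev$config_hash, hash) && all(file.exists(files)) &&
        identical(unname(tools::md5sum(files)), unname(unlist(prev$files)))) {
      message("outputs up to date; skipping recompute")
      return(invisible(list(manifest = prev, tables = NULL,
                            gsr_contrast = NULL)))
    }
  }
  t0 <- Sys.time()

  params <- do.call(sim_params, c(list(seed = cfg$seed),
                                  cfg$params_overrides))
  groups <- default_group_specs(params, effects = cfg$effects)
  if (!is.null(cfg$group_n))
    for (g in names(cfg$group_n)) groups[[g]]$n <- as.integer(cfg$group_n[[g]])
  cohort <- simulate_cohort(params, groups, seed = cfg$seed,
                            voxel = cfg$voxel)

  streams <- switch(cfg$gsr, on = "gsr", off = "nogsr",
                    both = c("nogsr", "gsr"))
  pairs <- homotopic_pairs(cohort$atlas)
  bundles <- list()
  usability <- NULL
  for (st in streams) {
    bl <- list()
    urows <- list()
    for (sid in names(cohort$subjects)) {
      pp <- preprocess_subject(cohort$subjects[[sid]],
                               use_gsr = (st == "gsr"),
                               fd_threshold_mm = cfg$fd_threshold_mm,
                               min_volumes = cfg$min_volumes,
                               band = cfg$band)
      urows[[sid]] <- data.frame(subject_id = sid,
                                 n_motion_free = pp$n_motion_free,
                                 usable = pp$usable)
      if (!pp$usable) next
      ts <- extract_roi_timeseries(pp, cohort$atlas,
                                   min_volumes = cfg$min_volumes)
      bl[[sid]] <- compute_connectivity(ts, cohort$atlas, pairs)
    }
    bundles[[st]] <- bl
    if (is.null(usability)) usability <- do.call(rbind, urows)
  }

  usable_ids <- usability$subject_id[usability$usable]
  nmf <- stats::setNames(usability$n_motion_free, usability$subject_id)
  phen <- cohort$phenotypes[cohort$phenotypes$subject_id %in% usable_ids, ]
  tables <- list()
  summaries <- list()
  for (st in streams) {
    design <- cohort_design(phen, nmf, stream = st)
    tables[[st]] <- run_family_analyses(bundles[[st]], design)
    summaries[[st]] <- do.call(rbind, lapply(names(bundles[[st]]), function(sid) {
      b <- bundles[[st]][[sid]]
      data.frame(subject_id = sid, stream = st,
                 network = names(b$within_mean),
                 within_mean_z = unname(b$within_mean),
                 median_z = stats::median(off_diag(b$zmat)))
    }))
  }
  design <- cohort_design(phen, nmf)
  contrast <- NULL
  if (length(streams) == 2L) {
    contrast <- gsr_contrast(tables$gsr, tables$nogsr, bundles$gsr,
                             bundles$nogsr, design)
  }

  # ---- write outputs -------------------------------------------------------
  files <- character(0)
  put <- function(df, name) {
    write_tsv(df, file.path(out, name))
    files <<- c(files, name)
  }
  put(cohort$phenotypes, "phenotypes.tsv")
  put(usability, "usability.tsv")
  put(cohort$manifest, "truth_manifest.tsv")
  for (st in streams) {
    for (fam in names(tables[[st]]))
      put(as.data.frame(tables[[st]][[fam]]),
          sprintf("stats_%s_%s.tsv", st, fam))
    put(summaries[[st]], sprintf("subject_summaries_%s.tsv", st))
  }
  if (!is.null(contrast)) {
    jsonlite::write_json(contrast, file.path(out, "gsr_contrast.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, "gsr_contrast.json")
  }
  cfg_rec <- cfg
  cfg_rec$output_dir <- NULL  # implied by location; keeps manifests portable
  write_run_config(cfg_rec, file.path(out, "config.yaml"))
  files <- c(files, "config.yaml")
  if (cfg$figures) files <- c(files, make_report(out, streams))

  manifest <- list(
    config_hash = hash,
    package_version = as.character(utils::packageVersion("fcpipe")),
    seed = cfg$seed,
    files = as.list(tools::md5sum(file.path(out, files))) |>
      stats::setNames(files),
    usability = stats::setNames(as.list(usability$usable),
                                usability$subject_id),
    timing_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(manifest = manifest, tables = tables,
                 gsr_contrast = contrast, design = design, cohort = cohort,
                 bundles = bundles))
}
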