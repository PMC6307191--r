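# ROI time-series extraction and connectivity summaries.

#' Extract censored, concatenated ROI time series
#'
#' Computes the per-frame mean over each ROI's labeled voxels (or takes the
#' ROI columns directly for ROI-level runs), centers each column per run
#' using the kept frames, drops censored frames, and concatenates runs in
#' order.
#'
#' @param cleaned Preprocessed subject from [preprocess_subject()], or a list
#'   of cleaned runs.
#' @param atlas Parcellation with a label volume (not needed for ROI-level
#'   runs).
#' @param censor_masks Per-run censor masks (taken from `cleaned` when it is
#'   a `preprocessed_subject`).
#' @param min_volumes Usability minimum; extraction refuses subjects with
#'   fewer kept frames.
#' @return A `roi_timeseries`: `mat` (kept frames x ROIs), `kept` (per-run
#'   kept indices), `subject_id`, `stream`, `n_motion_free`.
#' @export
extract_roi_timeseries <- function(cleaned, atlas, censor_masks = NULL,
                                   min_volumes = 200L) {
  if (inherits(cleaned, "preprocessed_subject")) {
    censor_masks <- cleaned$censor_masks
    runs <- cleaned$cleaned_runs
    stream <- cleaned$stream
    subject_id <- cleaned$subject_id
  } else {
    runs <- cleaned
    stream <- "nogsr"
    subject_id <- runs[[1]]$subject_id %||% "subject"
  }
  nmf <- sum(vapply(censor_masks, function(x) x$n_motion_free, integer(1)))
  if (nmf < min_volumes)
    stopf("subject %s has %d motion-free volumes (< %d); not usable",
          subject_id, nmf, min_volumes)
  pieces <- vector("list", length(runs))
  kept_idx <- vector("list", length(runs))
  for (r in seq_along(runs)) {
    run <- runs[[r]]
    keep <- censor_masks[[r]]$keep
    if (inherits(run, "roi_run")) {
      m <- run$roi_data
    } else {
      d <- dim(run$data)
      if (!is.null(atlas$labels) && !all(dim(atlas$labels) == d[1:3]))
        stopf("atlas label volume does not match run grid")
      flat <- matrix(run$data, prod(d[1:3]), d[4])
      lab <- as.vector(atlas$labels)
      gm <- lab > 0L
      ids <- atlas$roi_table$id
      missing <- ids[!(ids %in% lab[gm])]
      if (length(missing))
        stopf("ROIs with zero voxels in label volume: %s",
              paste(missing, collapse = ", "))
      sums <- rowsum(flat[gm, , drop = FALSE], lab[gm])
      counts <- as.vector(table(lab[gm])[as.character(sort(unique(lab[gm])))])
      m <- t(sums / counts)
      m <- m[, match(ids, sort(unique(lab[gm]))), drop = FALSE]
    }
    if (length(keep) != nrow(m))
      stopf("censor mask length != run frames")
    mu <- colMeans(m[keep, , drop = FALSE])
    m <- sweep(m, 2, mu, "-")
    pieces[[r]] <- m[keep, , drop = FALSE]
    kept_idx[[r]] <- which(keep)
  }
  mat <- do.call(rbind, pieces)
  colnames(mat) <- atlas$roi_table$name
  structure(list(mat = mat, kept = kept_idx, subject_id = subject_id,
                 stream = stream, n_motion_free = nrow(mat)),
            class = "roi_timeseries")
}

#' ROI-by-ROI Fisher-z connectivity matrix
#'
#' Pearson correlation between every pair of ROI time series, Fisher
#' transformed (z = atanh r). The diagonal is undefined and stored as NaN.
#'
#' @param ts A `roi_timeseries` or a plain frames-x-ROIs matrix.
#' @return Symmetric Fisher-z matrix with NaN diagonal.
#' @export
fisher_connectivity <- function(ts) {
  m <- if (inherits(ts, "roi_timeseries")) ts$mat else as.matrix(ts)
  if (nrow(m) < 3L) stopf("need >= 3 kept frames for correlation")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stopf("zero-variance ROI time series: %s",
          paste(colnames(m)[sds == 0] %||% which(sds == 0), collapse = ", "))
  r <- stats::cor(m)
  od <- abs(r[upper.tri(r)])
  if (any(od >= 1 - 1e-12))
    stopf("degenerate ROI pair with |r| = 1 (duplicated series?)")
  z <- atanh(r)
  diag(z) <- NaN
  z
}

analysis_networks <- function(atlas) {
  nets <- intersect(atlas$network_labels %||% fc_networks(),
                    unique(atlas$roi_table$merged_network))
  setdiff(nets, "none")
}

#' Network-level connectivity summaries
#'
#' Network mean time series (mean of member ROI columns), between-network
#' synchrony (Fisher z of the Pearson correlation between network mean series
#' for every network pair), and mean within-network connectivity (mean of the
#' ROI-pair Fisher-z entries inside each network). ROIs with merged network
#' `"none"` are excluded.
#'
#' @param ts A `roi_timeseries`.
#' @param atlas The parcellation.
#' @param zmat Optional precomputed [fisher_connectivity()] matrix.
#' @return List with `network_ts` (frames x networks), `between_z` (networks
#'   x networks, NaN diagonal), `within_mean` (named vector; NaN with a
#'   warning for single-ROI networks).
#' @export
network_level <- function(ts, atlas, zmat = NULL) {
  m <- ts$mat
  tab <- atlas$roi_table
  nets <- analysis_networks(atlas)
  unknown <- setdiff(unique(tab$merged_network), c(nets, "none"))
  if (length(unknown))
    stopf("unknown network labels in atlas: %s", paste(unknown, collapse = ", "))
  if (is.null(zmat)) zmat <- fisher_connectivity(ts)
  network_ts <- vapply(nets, function(k) {
    rowMeans(m[, tab$merged_network == k, drop = FALSE])
  }, numeric(nrow(m)))
  between_z <- atanh(stats::cor(network_ts))
  diag(between_z) <- NaN
  within_mean <- vapply(nets, function(k) {
    idx <- which(tab$merged_network == k)
    if (length(idx) < 2L) {
      warning(sprintf("network %s has a single ROI; within-network mean is NaN",
                      k), call. = FALSE)
      return(NaN)
    }
    sub <- zmat[idx, idx]
    mean(sub[upper.tri(sub)])
  }, numeric(1))
  list(network_ts = network_ts, between_z = between_z,
       within_mean = within_mean)
}

#' Homotopic mirror pairing of ROIs
#'
#' For every ROI, mirrors its centroid across the mid-sagittal plane (world x
#' negated) and selects the contralateral ROI whose centroid is nearest in
#' Euclidean distance; ties break toward the lower ROI id. On an exactly
#' symmetric atlas this is the mirror bijection with zero distances. The
#' pairing is directional nearest-neighbor; non-mutual assignments are
#' flagged.
#'
#' @param atlas The parcellation (both hemispheres non-empty).
#' @return Data frame (one row per ROI): `roi_id`, `hemisphere`,
#'   `partner_id`, `distance_mm`, `mutual`.
#' @export
homotopic_pairs <- function(atlas) {
  tab <- atlas$roi_table
  if (!all(c("L", "R") %in% tab$hemisphere))
    stopf("both hemispheres must be non-empty")
  cent <- as.matrix(tab[, c("x", "y", "z")])
  partner <- integer(nrow(tab))
  dist_mm <- numeric(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    if (tab$x[i] == 0)
      warning(sprintf("ROI %d centroid lies on the midline", tab$id[i]),
              call. = FALSE)
    mirrored <- c(-cent[i, 1], cent[i, 2:3])
    contra <- which(tab$hemisphere != tab$hemisphere[i])
    d2 <- colSums((t(cent[contra, , drop = FALSE]) - mirrored)^2)
    best <- contra[order(d2, tab$id[contra])[1]]
    partner[i] <- tab$id[best]
    dist_mm[i] <- sqrt(min(d2))
  }
  mutual <- vapply(seq_len(nrow(tab)), function(i) {
    j <- match(partner[i], tab$id)
    partner[j] == tab$id[i]
  }, logical(1))
  data.frame(roi_id = tab$id, hemisphere = tab$hemisphere,
             partner_id = partner, distance_mm = dist_mm, mutual = mutual)
}

#' Homotopic connectivity values
#'
#' Fisher-z connectivity for each left-hemisphere ROI and its mirror partner.
#'
#' @param zmat Matrix from [fisher_connectivity()].
#' @param pairs Pairing from [homotopic_pairs()].
#' @param atlas The parcellation (maps ids to matrix indices).
#' @return Named numeric vector (names = left ROI ids), one z per pair.
#' @export
homotopic_connectivity <- function(zmat, pairs, atlas) {
  left <- pairs[pairs$hemisphere == "L", , drop = FALSE]
  ids <- atlas$roi_table$id
  i <- match(left$roi_id, ids)
  j <- match(left$partner_id, ids)
  if (anyNA(i) || anyNA(j) || max(c(i, j)) > ncol(zmat))
    stopf("pairs do not match zmat dimension")
  stats::setNames(zmat[cbind(i, j)], left$roi_id)
}

#' Connectivity between one network's mean series and every ROI
#'
#' Fisher z of the Pearson correlation between the named network's mean time
#' series and each ROI column; member ROIs are included and flagged.
#'
#' @param ts A `roi_timeseries`.
#' @param atlas The parcellation.
#' @param network Network name (one of the eight analysis networks).
#' @return Data frame: `roi_id`, `z`, `member`.
#' @export
network_to_roi <- function(ts, atlas, network = "default") {
  tab <- atlas$roi_table
  if (!network %in% tab$merged_network)
    stopf("network '%s' not present in atlas", network)
  member <- tab$merged_network == network
  net_ts <- rowMeans(ts$mat[, member, drop = FALSE])
  r <- drop(stats::cor(net_ts, ts$mat))
  r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  data.frame(roi_id = tab$id, z = atanh(r), member = member)
}

#' All connectivity summaries for one subject and one stream
#'
#' @param ts A `roi_timeseries`.
#' @param atlas The parcellation.
#' @param pairs Optional precomputed [homotopic_pairs()].
#' @param net_to_roi_network Network for the network-to-ROI map.
#' @return A `connectivity_result`: `zmat`, `network_ts`, `between_z`,
#'   `within_mean`, `homotopic_z`, `net_to_roi`, `subject_id`, `stream`,
#'   `n_motion_free`.
#' @export
compute_connectivity <- function(ts, atlas, pairs = NULL,
                                 net_to_roi_network = "default") {
  zmat <- fisher_connectivity(ts)
  nl <- network_level(ts, atlas, zmat)
  if (is.null(pairs)) pairs <- homotopic_pairs(atlas)
  structure(list(zmat = zmat, network_ts = nl$network_ts,
                 between_z = nl$between_z, within_mean = nl$within_mean,
                 homotopic_z = homotopic_connectivity(zmat, pairs, atlas),
                 net_to_roi = network_to_roi(ts, atlas, net_to_roi_network),
                 subject_id = ts$subject_id, stream = ts$stream,
                 n_motion_free = ts$n_motion_free),
            class = "connectivity_result")
}
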