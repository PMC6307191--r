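# Preprocessing: framewise displacement, censoring, erosion, confound
# extraction, and nuisance regression with simultaneous bandpass filtering.

#' Framewise displacement from six rigid-body motion parameters
#'
#' FD at frame t (t >= 2) is the sum of absolute differences of the three
#' translations (mm) plus `head_radius_mm` times the sum of absolute
#' differences of the three rotations (radians) between frames t-1 and t.
#' The first frame has FD 0 by convention (FD is a transition quantity).
#'
#' @param motion Matrix with >= 2 rows and 6 columns (trans mm, rot rad).
#' @param head_radius_mm Head radius for rotation-to-mm conversion.
#' @return Numeric vector of per-frame FD in mm.
#' @export
compute_framewise_displacement <- function(motion, head_radius_mm = 50) {
  motion <- as.matrix(motion)
  if (nrow(motion) < 2L || ncol(motion) != 6L)
    stopf("motion must have >= 2 frames and 6 columns")
  if (!all(is.finite(motion))) stopf("motion parameters must be finite")
  d <- abs(diff(motion))
  c(0, rowSums(d[, 1:3, drop = FALSE]) +
      head_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
}

#' Censor mask from a framewise-displacement series
#'
#' For every frame t whose FD exceeds the threshold (FD(t) measures the
#' displacement between frames t-1 and t), both frames adjacent to the motion
#' event -- t-1 and t -- are dropped; all other frames are kept.
#'
#' @param fd Per-frame FD series (first element 0).
#' @param threshold_mm Censoring threshold in mm (default 0.2).
#' @param min_volumes Minimum kept volumes for a usable scan (default 200);
#'   the `usable` flag here reflects this call's frames only -- subject-level
#'   usability is decided on the concatenated total by
#'   [preprocess_subject()].
#' @return A `censor_mask`: list with `keep` (logical), `fd_mm`,
#'   `threshold_mm`, `n_motion_free`, `usable`.
#' @export
build_censor_mask <- function(fd, threshold_mm = 0.2, min_volumes = 200L) {
  if (threshold_mm <= 0) stopf("threshold_mm must be positive")
  n <- length(fd)
  viol <- which(fd > threshold_mm)
  drop <- unique(c(viol, viol - 1L))
  drop <- drop[drop >= 1L]
  keep <- rep(TRUE, n)
  keep[drop] <- FALSE
  structure(list(keep = keep, fd_mm = fd, threshold_mm = threshold_mm,
                 n_motion_free = sum(keep),
                 usable = sum(keep) >= min_volumes),
            class = "censor_mask")
}

#' Erode a binary mask by one voxel
#'
#' Retains the voxels whose full face-adjacent 6-neighborhood lies inside the
#' mask, i.e. all voxels at least one voxel removed from the mask boundary
#' (volume faces count as boundary). The result may be empty; emptiness is
#' flagged in the `"empty"` attribute for the caller to handle.
#'
#' @param mask Logical (or 0/1) 3D array.
#' @return Logical 3D array with attribute `empty`.
#' @export
erode_mask <- function(mask) {
  mask <- mask != 0
  if (length(dim(mask)) != 3L) stopf("mask must be a 3D array")
  if (!any(mask)) stopf("mask is empty")
  d <- dim(mask)
  shift <- function(m, ax, by) {
    out <- array(FALSE, d)
    src <- dst <- lapply(d, seq_len)
    if (by == 1L) { dst[[ax]] <- 2:d[ax]; src[[ax]] <- 1:(d[ax] - 1L) }
    else { dst[[ax]] <- 1:(d[ax] - 1L); src[[ax]] <- 2:d[ax] }
    out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    out
  }
  er <- mask
  for (ax in 1:3) er <- er & shift(mask, ax, 1L) & shift(mask, ax, -1L)
  attr(er, "empty") <- !any(er)
  er
}

mask_mean_series <- function(flat, mask) {
  idx <- which(mask)
  if (length(idx) == 1L) flat[idx, ] else colMeans(flat[idx, , drop = FALSE])
}

#' Extract the nuisance confound matrix for one run
#'
#' Columns: the six motion parameters, mean time series over the eroded WM
#' and CSF masks, mean over the (unchanged) face mask and, when `use_gsr`,
#' the mean signal over all in-brain voxels. All columns are centered.
#' Columns that are constant (e.g. motion parameters of a motionless scan)
#' carry no information beyond the model intercept and are dropped; dropped
#' names are recorded in the `"dropped"` attribute.
#'
#' @param run A `bold_run` (4D data) from the generator or [read_bold_nifti()].
#' @param masks List with logical arrays `wm`, `csf`, `face`, `brain`.
#' @param motion Matrix of six motion parameters for this run.
#' @param use_gsr Include the global (in-brain mean) signal column.
#' @return Centered numeric matrix (frames x regressors) with column names
#'   `motion_1..6`, `wm`, `csf`, `face`, and `global` when `use_gsr`.
#' @export
extract_confounds <- function(run, masks, motion, use_gsr = FALSE) {
  data <- run$data
  n <- dim(data)[4]
  if (nrow(motion) != n) stopf("motion rows (%d) != run frames (%d)",
                               nrow(motion), n)
  flat <- matrix(data, prod(dim(data)[1:3]), n)
  wm_er <- erode_mask(masks$wm)
  if (attr(wm_er, "empty"))
    stopf("erosion eliminated the WM mask; supply a thicker mask")
  csf_er <- erode_mask(masks$csf)
  if (attr(csf_er, "empty"))
    stopf("erosion eliminated the CSF mask; supply a thicker mask")
  cm <- cbind(motion,
              wm = mask_mean_series(flat, wm_er),
              csf = mask_mean_series(flat, csf_er),
              face = mask_mean_series(flat, masks$face))
  colnames(cm)[1:6] <- paste0("motion_", 1:6)
  if (use_gsr) cm <- cbind(cm, global = mask_mean_series(flat, masks$brain))
  finish_confounds(cm)
}

# Shared tail of confound assembly: center, drop constant columns.
finish_confounds <- function(cm) {
  cm <- center_cols(cm)
  const <- apply(cm, 2, function(x) all(abs(x - x[1]) < 1e-12))
  dropped <- colnames(cm)[const]
  cm <- cm[, !const, drop = FALSE]
  attr(cm, "dropped") <- dropped
  cm
}

.design_cache <- new.env(parent = emptyenv())

# QR of [intercept, out-of-band DCT columns], cached by geometry.
bandpass_design_qr <- function(n, tr, band) {
  key <- paste(n, tr, band[1], band[2], sep = "_")
  if (!is.null(.design_cache[[key]])) return(.design_cache[[key]])
  f <- dct_frequencies(n, tr)
  ks <- which(f < band[1] | f > band[2])
  B <- cbind(intercept = rep(1, n),
             if (length(ks)) dct_basis(n, ks))
  qb <- qr(B)
  .design_cache[[key]] <- qb
  qb
}

#' Nuisance regression with simultaneous bandpass filtering
#'
#' Per voxel (or column), removes by ordinary least squares -- in one
#' simultaneous fit -- an intercept, the confound columns, and a discrete
#' cosine basis spanning every frequency outside the passband; the residuals
#' are returned. Residuals are exactly orthogonal to every regressor
#' (realized by sequential orthogonal projection, which is algebraically
#' identical to the simultaneous fit).
#'
#' @param run A `bold_run` (cleaned copy returned), a `roi_run`, or a plain
#'   frames-x-series matrix (requires `tr`).
#' @param confounds Centered confound matrix from [extract_confounds()].
#' @param band Passband in Hz (default 0.001-0.1). With run lengths of
#'   minutes the lower edge lies below the frequency resolution, so near-DC
#'   trends are handled by the intercept/low-k cosine columns only.
#' @param tr Repetition time in seconds (taken from `run` when available).
#' @param method `"dct"` (default, the reference route: one simultaneous
#'   fit) or `"butterworth"` (comparison mode: confound regression followed
#'   by a zero-phase order-2 Butterworth bandpass; requires the `signal`
#'   package; residuals are then no longer exactly orthogonal to the
#'   confounds).
#' @return Same type as `run`, with residual time series in place of data.
#' @export
regress_and_filter <- function(run, confounds, band = c(0.001, 0.1),
                               tr = NULL, method = c("dct", "butterworth")) {
  method <- match.arg(method)
  if (inherits(run, "bold_run")) {
    d <- dim(run$data)
    y <- matrix(run$data, prod(d[1:3]), d[4])
    out <- regress_and_filter(t(y), confounds, band, run$tr_seconds, method)
    run$data <- array(t(out), d)
    return(run)
  }
  if (inherits(run, "roi_run")) {
    run$roi_data <- regress_and_filter(run$roi_data, confounds, band,
                                       run$tr_seconds, method)
    return(run)
  }
  y <- as.matrix(run)
  n <- nrow(y)
  if (is.null(tr)) stopf("tr required for matrix input")
  nyq <- 1 / (2 * tr)
  if (band[1] < 0 || band[2] <= band[1] || band[2] >= nyq)
    stopf("band must satisfy 0 <= lo < hi < Nyquist (%.3f Hz)", nyq)
  if (!is.null(confounds) && nrow(confounds) != n)
    stopf("confound rows (%d) != frames (%d)", nrow(confounds), n)
  if (method == "butterworth") {
    if (!requireNamespace("signal", quietly = TRUE))
      stopf("the 'signal' package is required for method = 'butterworth'")
    X <- cbind(intercept = rep(1, n), confounds)
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
      stopf("rank-deficient nuisance design; collinear columns: %s",
            paste(bad, collapse = ", "))
    }
    res <- qr.resid(qx, y)
    bf <- signal::butter(2, pmin(pmax(band / nyq, 1e-6), 1 - 1e-6),
                         type = "pass")
    return(apply(res, 2, function(col) signal::filtfilt(bf, col)))
  }
  qb <- bandpass_design_qr(n, tr, band)
  y_t <- qr.resid(qb, y)
  if (!is.null(confounds) && ncol(confounds) > 0) {
    c_t <- qr.resid(qb, as.matrix(confounds))
    qc <- qr(c_t)
    if (qc$rank < ncol(c_t)) {
      bad <- colnames(c_t)[qc$pivot[(qc$rank + 1):ncol(c_t)]]
      stopf("rank-deficient nuisance design; collinear columns: %s",
            paste(bad, collapse = ", "))
    }
    y_t <- qr.resid(qc, y_t)
  }
  y_t
}

#' Preprocess all runs of one subject
#'
#' Runs the stage sequence on already-realigned, common-space data: framewise
#' displacement, confound extraction, nuisance regression with simultaneous
#' bandpass filtering, and censor-mask construction. Censoring is applied
#' downstream at time-series extraction, not by deleting frames here. The
#' subject is usable when the kept frames summed over runs reach
#' `min_volumes`.
#'
#' @param subject A `synthetic_subject` (voxel or ROI type), or a list with
#'   elements `runs` (list of `bold_run`), `motion` (list of matrices) and
#'   `masks`.
#' @param use_gsr Include the global-signal regressor.
#' @param fd_threshold_mm Censoring threshold (default 0.2 mm).
#' @param min_volumes Usability minimum over concatenated runs (default 200).
#' @param band Passband in Hz.
#' @param head_radius_mm Rotation-to-mm conversion radius.
#' @return A `preprocessed_subject`: `cleaned_runs`, `censor_masks`,
#'   `n_motion_free`, `usable`, `stream` ("gsr"/"nogsr"), and a per-stage
#'   `log` data.frame.
#' @export
preprocess_subject <- function(subject, use_gsr = FALSE,
                               fd_threshold_mm = 0.2, min_volumes = 200L,
                               band = c(0.001, 0.1), head_radius_mm = 50) {
  runs <- subject$runs
  motion <- subject$motion
  n_runs <- length(runs)
  cleaned <- vector("list", n_runs)
  cms <- vector("list", n_runs)
  log <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    run <- runs[[r]]
    fd <- compute_framewise_displacement(motion[[r]], head_radius_mm)
    cms[[r]] <- build_censor_mask(fd, fd_threshold_mm, min_volumes)
    conf <- if (inherits(run, "roi_run")) {
      gm <- cbind(motion[[r]],
                  wm = run$confounds_meas$wm, csf = run$confounds_meas$csf,
                  face = run$confounds_meas$face)
      colnames(gm)[1:6] <- paste0("motion_", 1:6)
      if (use_gsr) gm <- cbind(gm, global = run$confounds_meas$brain_mean)
      finish_confounds(gm)
    } else {
      extract_confounds(run, subject$masks, motion[[r]], use_gsr)
    }
    cleaned[[r]] <- tryCatch(
      regress_and_filter(run, conf, band),
      error = function(e) stopf("subject %s %s: %s",
                                run$subject_id %||% "?", run$run_id,
                                conditionMessage(e)))
    log[[r]] <- data.frame(run_id = run$run_id,
                           n_frames = length(fd),
                           n_confounds = ncol(conf),
                           n_motion_free = cms[[r]]$n_motion_free)
  }
  nmf <- sum(vapply(cms, function(x) x$n_motion_free, integer(1)))
  structure(list(cleaned_runs = cleaned, censor_masks = cms,
                 n_motion_free = nmf, usable = nmf >= min_volumes,
                 stream = if (use_gsr) "gsr" else "nogsr",
                 subject_id = runs[[1]]$subject_id,
                 log = do.call(rbind, log)),
            class = "preprocessed_subject")
}
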