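# Target ROI covariance assembly for the cohort generator.

# Full ROI x ROI target Fisher-z matrix from network-level parameters.
# Mirror-pair cells receive the base (within-network) value plus homotopic_z.
target_z_matrix <- function(atlas, within_z, between_z, homotopic_z,
                            none_z = 0.10) {
  tab <- atlas$roi_table
  nets <- tab$merged_network
  n <- nrow(tab)
  Z <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      zi <- if (nets[i] == "none" || nets[j] == "none") none_z
            else if (nets[i] == nets[j]) within_z[[nets[i]]]
            else between_z[nets[i], nets[j]]
      Z[i, j] <- Z[j, i] <- zi
    }
  }
  if (!is.null(atlas$mirror_pairs)) {
    mp <- atlas$mirror_pairs
    idx <- cbind(match(mp$left, tab$id), match(mp$right, tab$id))
    Z[idx] <- Z[idx[, 2:1, drop = FALSE]] <- Z[idx] + homotopic_z
  }
  diag(Z) <- Inf
  Z
}

#' Assemble the generating ROI covariance matrix
#'
#' Builds the symmetric positive-definite correlation matrix whose Fisher
#' transform equals the requested within-network value on within-network
#' cells, the between-network value on between-network cells, and the base
#' value plus `homotopic_z` on mirror pairs; the diagonal is 1. If the
#' assembled matrix is not positive definite it is repaired with the nearest
#' positive-definite correlation matrix (Higham projection via
#' [Matrix::nearPD()]) and the repair magnitude (max absolute cell change) is
#' recorded in the `"repair"` attribute.
#'
#' @param params A [sim_params()] object (supplies defaults for the coupling
#'   targets).
#' @param atlas Parcellation from [build_symmetric_parcellation()].
#' @param within_z,between_z,homotopic_z Optional overrides of the
#'   corresponding `params` entries.
#' @return Correlation matrix with attributes `target_z` (the assembled
#'   Fisher-z matrix) and `repair` (0 when no repair was needed).
#' @export
build_roi_covariance <- function(params, atlas,
                                 within_z = params$within_z,
                                 between_z = params$between_z,
                                 homotopic_z = params$homotopic_z,
                                 none_z = params$none_z %||% 0.10) {
  nets_in <- unique(atlas$roi_table$merged_network)
  if (!all(nets_in %in% c(params$network_labels, "none")))
    stopf("atlas contains networks absent from params$network_labels")
  nk <- length(params$network_labels)
  if (length(within_z) == 1L)
    within_z <- stats::setNames(rep(within_z, nk), params$network_labels)
  if (length(between_z) == 1L)
    between_z <- matrix(between_z, nk, nk,
                        dimnames = list(params$network_labels,
                                        params$network_labels))
  Z <- target_z_matrix(atlas, within_z, between_z, homotopic_z, none_z)
  if (!all(is.finite(Z[upper.tri(Z)])))
    stopf("coupling z-values must be finite (|r| < 1)")
  R <- tanh(Z)
  diag(R) <- 1
  repair <- 0
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(ch)) {
    fixed <- as.matrix(Matrix::nearPD(R, corr = TRUE, maxit = 200)$mat)
    repair <- max(abs(fixed - R))
    R <- fixed
  }
  dimnames(R) <- list(atlas$roi_table$name, atlas$roi_table$name)
  attr(R, "target_z") <- Z
  attr(R, "repair") <- repair
  R
}

# Subject-specific coupling targets: group deltas + between-subject jitter at
# the network-parameter level + a global IQ-dependent shift on all cells.
subject_target_params <- function(params, group_spec, iq, seed) {
  set.seed(seed)
  wz <- params$within_z
  bz <- params$between_z
  hz <- params$homotopic_z
  if (!is.null(group_spec$within_z_delta)) {
    d <- group_spec$within_z_delta
    wz[names(d)] <- wz[names(d)] + d
  }
  for (trip in group_spec$between_z_delta %||% list()) {
    bz[trip[[1]], trip[[2]]] <- bz[trip[[1]], trip[[2]]] + trip[[3]]
    bz[trip[[2]], trip[[1]]] <- bz[trip[[1]], trip[[2]]]
  }
  hz <- hz + (group_spec$homotopic_z_delta %||% 0)
  s <- params$subject_z_sd
  wz <- wz + stats::rnorm(length(wz), 0, s)
  jit <- matrix(0, nrow(bz), ncol(bz), dimnames = dimnames(bz))
  jit[upper.tri(jit)] <- stats::rnorm(sum(upper.tri(jit)), 0, s)
  bz <- bz + jit + t(jit)
  hz <- hz + stats::rnorm(1, 0, s)
  shift <- (group_spec$iq_z_slope %||% 0) * (iq - group_spec$iq_mean)
  list(within_z = wz + shift, between_z = bz + shift, homotopic_z = hz)
}
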