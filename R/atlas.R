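# Synthetic mirror-symmetric parcellation and tissue-mask geometry.

# World-coordinate affine for the synthetic grid: isotropic voxels, x = 0
# exactly between the two middle slices of the (even) first axis, y and z
# centered. Mirroring voxel index i <-> nx + 1 - i negates world x exactly.
grid_affine <- function(grid_shape, voxel_size_mm) {
  d <- voxel_size_mm
  nx <- grid_shape[1]
  aff <- diag(c(d, d, d, 1))
  aff[1, 4] <- -(nx / 2 + 0.5) * d
  aff[2, 4] <- -(grid_shape[2] + 1) / 2 * d
  aff[3, 4] <- -(grid_shape[3] + 1) / 2 * d
  aff
}

voxel_world <- function(idx, axis, affine) {
  affine[axis, axis] * idx + affine[axis, 4]
}

#' Build a mirror-symmetric block parcellation
#'
#' Places `n_rois_per_hemisphere` cubic ROI blocks in the left hemisphere
#' (negative world x) of the voxel grid and mirrors each across the
#' mid-sagittal plane, so every left ROI has a right ROI whose centroid is the
#' exact reflection (x to -x). Networks are assigned cyclically so each of the
#' eight networks has the same number of ROIs per hemisphere (exactly one when
#' `n_rois_per_hemisphere = 8`). The last six y-layers of the grid are
#' reserved for tissue-mask blocks (see [build_tissue_masks()]).
#'
#' @param params A [sim_params()] object.
#' @return A `parcellation_atlas`: list with `labels` (3D integer array, 0 =
#'   background), `affine` (4x4), `roi_table` (data.frame with id, name,
#'   hemisphere, source_network, merged_network, x, y, z centroid in world mm,
#'   n_voxels), and `mirror_pairs` (left id, right id).
#' @export
build_symmetric_parcellation <- function(params) {
  gs <- params$grid_shape
  b <- params$roi_block
  nR <- params$n_rois_per_hemisphere
  affine <- grid_affine(gs, params$voxel_size_mm)

  ny_roi <- gs[2] - 7L  # reserve tissue region (last 6 y-layers + 1 gap)
  nx_slots <- (gs[1] %/% 2L) %/% b
  ny_slots <- max(ny_roi, 0L) %/% b
  nz_slots <- gs[3] %/% b
  n_slots <- nx_slots * ny_slots * nz_slots
  if (n_slots < nR) {
    lim <- c(x = nx_slots, y = ny_slots, z = nz_slots)
    stopf(paste0("grid too small for %d ROIs per hemisphere: only %d block ",
                 "slots (limiting axis: %s with %d slots of size %d)"),
          nR, n_slots, names(which.min(lim)), min(lim), b)
  }

  slots <- expand.grid(sx = seq_len(nx_slots), sy = seq_len(ny_slots),
                       sz = seq_len(nz_slots))
  slots <- slots[seq_len(nR), , drop = FALSE]

  labels <- array(0L, gs)
  n_net <- nR - params$n_none_per_hemisphere
  nets <- c(params$network_labels[((seq_len(n_net) - 1L) %% 8L) + 1L],
            rep("none", params$n_none_per_hemisphere))
  net_idx <- stats::ave(seq_len(nR), nets, FUN = seq_along)
  tab <- vector("list", 2L * nR)
  for (j in seq_len(nR)) {
    x0 <- (slots$sx[j] - 1L) * b + 1L
    y0 <- (slots$sy[j] - 1L) * b + 1L
    z0 <- (slots$sz[j] - 1L) * b + 1L
    xl <- x0:(x0 + b - 1L)
    xr <- (gs[1] + 1L) - xl
    ys <- y0:(y0 + b - 1L)
    zs <- z0:(z0 + b - 1L)
    if (any(labels[xl, ys, zs] != 0L) || any(labels[xr, ys, zs] != 0L))
      stopf("internal error: overlapping ROI blocks")
    labels[xl, ys, zs] <- j
    labels[xr, ys, zs] <- j + nR
    cl <- c(mean(voxel_world(xl, 1, affine)), mean(voxel_world(ys, 2, affine)),
            mean(voxel_world(zs, 3, affine)))
    tab[[j]] <- data.frame(
      id = j, name = sprintf("L_%s_%d", nets[j], net_idx[j]),
      hemisphere = "L", source_network = nets[j], merged_network = nets[j],
      x = cl[1], y = cl[2], z = cl[3], n_voxels = b^3)
    tab[[j + nR]] <- data.frame(
      id = j + nR, name = sprintf("R_%s_%d", nets[j], net_idx[j]),
      hemisphere = "R", source_network = nets[j], merged_network = nets[j],
      x = -cl[1], y = cl[2], z = cl[3], n_voxels = b^3)
  }
  roi_table <- do.call(rbind, tab)
  structure(list(labels = labels, affine = affine, roi_table = roi_table,
                 mirror_pairs = data.frame(left = seq_len(nR),
                                           right = seq_len(nR) + nR),
                 network_labels = params$network_labels),
            class = "parcellation_atlas")
}

#' Build brain, white-matter, CSF and face tissue masks
#'
#' Rectangular blocks at least three voxels thick (so erosion leaves a
#' non-empty core), disjoint from each other and from the parcellation: WM and
#' CSF sit inside the brain mask in the reserved posterior y-layers; the face
#' block lies outside the brain mask. The brain mask is the union of gray
#' matter (all labeled ROI voxels), WM and CSF.
#'
#' @param params A [sim_params()] object.
#' @param atlas Parcellation from [build_symmetric_parcellation()].
#' @return List of logical 3D arrays: `brain`, `wm`, `csf`, `face`, plus the
#'   shared `affine`.
#' @export
build_tissue_masks <- function(params, atlas) {
  gs <- params$grid_shape
  blk <- function(xs, ys, zs) {
    m <- array(FALSE, gs)
    m[xs, ys, zs] <- TRUE
    m
  }
  yt <- gs[2] - 5L  # tissue region start
  if (yt < 2L || gs[3] < 3L || gs[1] < 9L)
    stopf("grid too small to place 3-voxel-thick tissue blocks")
  zs <- 1:3
  wm <- blk(1:3, yt:(yt + 2L), zs)
  csf <- blk(5:7, yt:(yt + 2L), zs)
  face <- blk((gs[1] - 3L):(gs[1] - 1L), (gs[2] - 2L):gs[2], zs)
  gm <- atlas$labels > 0L
  if (any((wm | csf | face) & gm))
    stopf("internal error: tissue blocks overlap parcellation")
  brain <- gm | wm | csf
  list(brain = brain, wm = wm, csf = csf, face = face, affine = atlas$affine)
}

#' Mapping from the 12 source networks to the 8 analysis networks
#'
#' The merge used for network-level analyses of Gordon-style parcel tables:
#' cingulo-opercular and salience merge into salience; frontoparietal and
#' cinguloparietal into frontoparietal; default and retrosplenial-temporal
#' into default; somatomotor hand and mouth into sensorimotor; auditory,
#' dorsal attention, ventral attention and visual map to themselves. Parcels
#' labeled "None" keep the label `"none"` and are excluded from network-level
#' analyses (but retained for ROI-level and homotopic analyses).
#'
#' @return Named character vector: source network -> merged network.
#' @export
gordon_merge_map <- function() {
  c(Auditory = "auditory",
    CinguloOperc = "salience", Salience = "salience",
    FrontoParietal = "frontoparietal", CinguloParietal = "frontoparietal",
    Default = "default", RetrosplenialTemporal = "default",
    DorsalAttn = "dorsal_attention", VentralAttn = "ventral_attention",
    SMhand = "sensorimotor", SMmouth = "sensorimotor",
    Visual = "visual", None = "none")
}

#' Read a Gordon-style parcel table
#'
#' Reads a tab-separated ROI table with columns `id`, `hemisphere`
#' (`L`/`R`), `network` (source network names as in [gordon_merge_map()]) and
#' centroid columns `x`, `y`, `z` in world mm, and returns a table-only
#' `parcellation_atlas` (no label volume) with the 12-to-8 network merge
#' applied. Suitable for homotopic pairing and for connectivity computed from
#' externally extracted ROI time series.
#'
#' @param path Path to the TSV file.
#' @return A `parcellation_atlas` with `labels = NULL`.
#' @export
read_parcel_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("id", "hemisphere", "network", "x", "y", "z")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stopf("parcel table missing columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$id)) stopf("parcel table ids must be unique")
  mm <- gordon_merge_map()
  unknown <- setdiff(unique(tab$network), names(mm))
  if (length(unknown))
    stopf("unknown source networks: %s", paste(unknown, collapse = ", "))
  tab$source_network <- tab$network
  tab$merged_network <- unname(mm[tab$network])
  tab$network <- NULL
  if (!("name" %in% names(tab)))
    tab$name <- sprintf("%s_%s_%d", tab$hemisphere, tab$merged_network, tab$id)
  structure(list(labels = NULL, affine = NULL, roi_table = tab,
                 mirror_pairs = NULL, network_labels = fc_networks()),
            class = "parcellation_atlas")
}
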