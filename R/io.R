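# File formats: NIfTI volumes, motion / phenotype / censor TSVs,
# connectivity bundles.

MOTION_COLUMNS <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")

#' Write a BOLD run (or any volume array) as NIfTI
#'
#' @param run A `bold_run`, or a 3D/4D numeric array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param affine 4x4 voxel-to-world affine (required for arrays).
#' @param tr_seconds Repetition time stored in the header.
#' @return `path`, invisibly.
#' @export
write_bold_nifti <- function(run, path, affine = NULL, tr_seconds = NULL) {
  if (inherits(run, "bold_run")) {
    arr <- run$data
    tr_seconds <- tr_seconds %||% run$tr_seconds
  } else arr <- run
  if (is.null(affine)) affine <- attr(arr, "affine")
  if (is.null(affine)) stopf("affine required to write NIfTI")
  img <- RNifti::asNifti(arr)
  vx <- abs(diag(affine)[1:3])
  RNifti::pixdim(img) <- if (length(dim(arr)) >= 4L)
    c(vx, tr_seconds %||% 1) else vx
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume
#'
#' @param path NIfTI file path.
#' @param subject_id,run_id Metadata attached when reading a 4D series.
#' @return For 4D input a `bold_run` (with `tr_seconds` from the header and
#'   the affine in attribute `affine`); for 3D input a plain array with the
#'   `affine` attribute.
#' @export
read_bold_nifti <- function(path, subject_id = NULL, run_id = NULL) {
  img <- RNifti::readNifti(path)
  aff <- structure(as.matrix(RNifti::xform(img)), imagedim = NULL, code = NULL)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  if (length(dim(arr)) == 4L) {
    structure(list(data = arr, tr_seconds = RNifti::pixdim(img)[4],
                   run_id = run_id %||% "run-01",
                   subject_id = subject_id %||% "subject"),
              class = "bold_run")
  } else {
    attr(arr, "affine") <- aff
    arr
  }
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Write / read a six-parameter motion TSV
#'
#' Columns `trans_x`, `trans_y`, `trans_z` in mm and `rot_x`, `rot_y`,
#' `rot_z` in radians. The reader validates the schema.
#'
#' @param motion Frames x 6 matrix.
#' @param path TSV path.
#' @return `write_motion_tsv`: the path; `read_motion_tsv`: the matrix.
#' @export
write_motion_tsv <- function(motion, path) {
  colnames(motion) <- MOTION_COLUMNS
  write_tsv(as.data.frame(motion), path)
}

#' @rdname write_motion_tsv
#' @export
read_motion_tsv <- function(path) {
  df <- read_tsv(path)
  if (!identical(names(df), MOTION_COLUMNS))
    stopf("motion TSV must have columns: %s (translations mm, rotations rad)",
          paste(MOTION_COLUMNS, collapse = ", "))
  as.matrix(df)
}

#' Write a censor mask as TSV (frame, fd_mm, keep)
#'
#' @param cm A `censor_mask`.
#' @param path TSV path.
#' @return The path, invisibly.
#' @export
write_censor_tsv <- function(cm, path) {
  write_tsv(data.frame(frame = seq_along(cm$keep),
                       fd_mm = sprintf("%.6f", cm$fd_mm),
                       keep = as.integer(cm$keep)), path)
}

#' Write a parcellation to disk (label NIfTI + ROI TSV)
#'
#' @param atlas A `parcellation_atlas` with a label volume.
#' @param dir Output directory.
#' @return Paths of the two files, invisibly.
#' @export
write_parcellation <- function(atlas, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nii <- file.path(dir, "parcellation.nii.gz")
  arr <- atlas$labels
  attr(arr, "affine") <- atlas$affine
  write_bold_nifti(arr, nii, affine = atlas$affine)
  tsv <- file.path(dir, "parcellation.tsv")
  write_tsv(atlas$roi_table, tsv)
  invisible(c(nii, tsv))
}

#' Write a subject's connectivity bundle as TSV files
#'
#' One directory per subject and stream: `zmat.tsv`, `within_mean.tsv`,
#' `between_z.tsv`, `homotopic.tsv`, `net_to_roi.tsv`.
#'
#' @param res A `connectivity_result`.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_connectivity_bundle <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(m) {
    df <- as.data.frame(round(m, 10))
    cbind(roi = rownames(m) %||% seq_len(nrow(m)), df)
  }
  write_tsv(fmt(res$zmat), file.path(dir, "zmat.tsv"))
  write_tsv(data.frame(network = names(res$within_mean),
                       within_mean_z = round(res$within_mean, 10)),
            file.path(dir, "within_mean.tsv"))
  write_tsv(fmt(res$between_z), file.path(dir, "between_z.tsv"))
  write_tsv(data.frame(left_roi = names(res$homotopic_z),
                       z = round(res$homotopic_z, 10)),
            file.path(dir, "homotopic.tsv"))
  write_tsv(res$net_to_roi, file.path(dir, "net_to_roi.tsv"))
  invisible(dir)
}

#' Write a whole synthetic subject to disk
#'
#' Per-run BOLD NIfTI and motion TSVs plus (once per output root) the
#' parcellation and tissue masks; layout mirrors a minimal BIDS-like tree.
#' Only voxel-type subjects can be written as NIfTI.
#'
#' @param subject A voxel-type `synthetic_subject`.
#' @param atlas,masks Cohort geometry.
#' @param dir Output directory.
#' @return The subject directory, invisibly.
#' @export
write_subject <- function(subject, atlas, masks, dir) {
  if (subject$type != "voxel")
    stopf("only voxel-type subjects can be written as NIfTI")
  sid <- subject$phenotype$subject_id
  sd <- file.path(dir, sid)
  dir.create(sd, showWarnings = FALSE, recursive = TRUE)
  for (r in seq_along(subject$runs)) {
    run <- subject$runs[[r]]
    write_bold_nifti(run, file.path(sd, sprintf("%s_%s_bold.nii.gz", sid,
                                                run$run_id)),
                     affine = atlas$affine)
    write_motion_tsv(subject$motion[[r]],
                     file.path(sd, sprintf("%s_%s_motion.tsv", sid,
                                           run$run_id)))
  }
  for (nm in c("brain", "wm", "csf", "face")) {
    arr <- masks[[nm]] + 0L
    write_bold_nifti(arr, file.path(dir, sprintf("mask_%s.nii.gz", nm)),
                     affine = atlas$affine)
  }
  invisible(sd)
}
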