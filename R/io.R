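# NIfTI and manifest I/O for phantom and real cohorts.

nifti_with_spacing <- function(arr, spacing) {
  img <- RNifti::asNifti(arr * 1.0)
  RNifti::pixdim(img) <- spacing
  img
}

#' Write a cohort to disk (NIfTI volumes + CSV manifest + YAML config)
#'
#' @param studies List of `dce_study` objects.
#' @param config The generating [phantom_config()] (or `NULL`).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest data frame.
#' @export
write_cohort <- function(studies, config = NULL, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(studies, function(s) {
    base <- file.path(out_dir, s$patient_id)
    paths <- c(
      pre = paste0(base, "_pre.nii.gz"),
      early = paste0(base, "_early.nii.gz"),
      delayed = paste0(base, "_delayed.nii.gz"),
      mask = paste0(base, "_mask.nii.gz")
    )
    RNifti::writeNifti(nifti_with_spacing(s$phase_pre, s$spacing), paths["pre"])
    RNifti::writeNifti(nifti_with_spacing(s$phase_early, s$spacing), paths["early"])
    RNifti::writeNifti(nifti_with_spacing(s$phase_delayed, s$spacing), paths["delayed"])
    RNifti::writeNifti(nifti_with_spacing(s$tumor_mask, s$spacing), paths["mask"])
    truth_path <- NA_character_
    if (!is.null(s$truth_habitats)) {
      truth_path <- paste0(base, "_truth.nii.gz")
      RNifti::writeNifti(nifti_with_spacing(s$truth_habitats, s$spacing), truth_path)
    }
    data.frame(patient_id = s$patient_id, her2 = s$her2,
               pre = paths[["pre"]], early = paths[["early"]],
               delayed = paths[["delayed"]], mask = paths[["mask"]],
               truth = truth_path, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  if (!is.null(config)) {
    cfg <- config
    cfg$signatures <- lapply(cfg$signatures, unclass)
    yaml::write_yaml(unclass(cfg), file.path(out_dir, "config.yaml"))
  }
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.csv` and the NIfTI volumes.
#' @return List of `dce_study` objects.
#' @export
read_cohort <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    rd <- function(p) {
      img <- RNifti::readNifti(p)
      list(arr = array(as.numeric(img), dim(img)), spacing = RNifti::pixdim(img))
    }
    pre <- rd(row$pre); early <- rd(row$early); delayed <- rd(row$delayed)
    mask <- rd(row$mask)
    truth <- NULL
    if (!is.na(row$truth) && nzchar(row$truth)) {
      t <- rd(row$truth)
      truth <- array(as.integer(round(t$arr)), dim(t$arr))
    }
    structure(list(
      patient_id = row$patient_id,
      phase_pre = pre$arr, phase_early = early$arr, phase_delayed = delayed$arr,
      tumor_mask = array(as.integer(round(mask$arr)), dim(mask$arr)),
      spacing = pre$spacing[seq_len(3)],
      her2 = row$her2, truth_habitats = truth
    ), class = "dce_study")
  })
}
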