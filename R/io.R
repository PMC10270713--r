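## NIfTI readers/writers and cohort serialization.

#' Read an aligned T1/PET volume pair plus parcellation
#'
#' Loads the two modality volumes and the integer parcellation, checking
#' that all three share one voxel grid and that the parcellation labels are
#' integral.
#'
#' @param t1_path,pet_path,parcellation_path NIfTI-1 file paths.
#' @return List with `vol_t1`, `vol_pet`, `parcellation` (plain arrays).
#' @export
read_volume_pair <- function(t1_path, pet_path, parcellation_path) {
  vols <- lapply(c(t1 = t1_path, pet = pet_path, parc = parcellation_path),
                 function(p) {
    if (!file.exists(p)) stopf("file not found: %s", p)
    arr <- tryCatch(as.array(RNifti::readNifti(p)),
                    error = function(e) stopf("not a readable NIfTI: %s", p))
    arr
  })
  shapes <- lapply(vols, dim)
  if (!identical(shapes$t1, shapes$pet) || !identical(shapes$t1, shapes$parc))
    stopf("volume geometries differ: T1 (%s), PET (%s), parcellation (%s)",
          paste(shapes$t1, collapse = "x"),
          paste(shapes$pet, collapse = "x"),
          paste(shapes$parc, collapse = "x"))
  if (!is_integerish(vols$parc))
    stopf("parcellation contains non-integer labels: %s", parcellation_path)
  list(vol_t1 = vols$t1, vol_pet = vols$pet,
       parcellation = array(as.integer(round(vols$parc)), dim(vols$parc)))
}

#' Write a volume-rendered synthetic cohort to disk
#'
#' Serializes a cohort from [generate_cohort()] (`render = "volume"`) in
#' the layout the pipeline reads back: per-subject
#' `<id>_T1.nii.gz` / `<id>_PET.nii.gz`, a shared `parcellation.nii.gz`,
#' `metadata.csv` (demographics, clinical measures, biomarker statuses,
#' file paths) and `survival.csv` (MCI follow-up time and conversion
#' event).
#'
#' @param subjects list from [generate_cohort()] with volumes.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(subjects, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(subjects[[1]]$parcellation,
                     file.path(dir, "parcellation.nii.gz"))
  meta_rows <- list()
  surv_rows <- list()
  for (s in subjects) {
    if (is.null(s$vol_t1))
      stopf("subject %s has no rendered volumes", s$subject_id)
    t1 <- paste0(s$subject_id, "_T1.nii.gz")
    pet <- paste0(s$subject_id, "_PET.nii.gz")
    RNifti::writeNifti(s$vol_t1, file.path(dir, t1))
    RNifti::writeNifti(s$vol_pet, file.path(dir, pet))
    m <- as.data.frame(s$metadata, stringsAsFactors = FALSE)
    m$t1_path <- t1
    m$pet_path <- pet
    meta_rows[[length(meta_rows) + 1L]] <- m
    if (!is.null(s$survival))
      surv_rows[[length(surv_rows) + 1L]] <- data.frame(
        subject_id = s$subject_id, time = s$survival$time,
        event = s$survival$event)
  }
  utils::write.csv(do.call(rbind, meta_rows),
                   file.path(dir, "metadata.csv"), row.names = FALSE)
  if (length(surv_rows))
    utils::write.csv(do.call(rbind, surv_rows),
                     file.path(dir, "survival.csv"), row.names = FALSE)
  invisible(dir)
}
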