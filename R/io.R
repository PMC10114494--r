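#' Write a cohort to disk
#'
#' Writes images as 8-bit grayscale PNGs plus `meta.csv` (image metadata and
#' ground truth), `subjects.csv`, and optionally `labels.csv` (long label
#' table) and `case_control.csv`.
#'
#' @param cohort A `density_cohort`.
#' @param dir Output directory (created if absent).
#' @param labels Optional label table from [assign_reader_pairs()].
#' @param case_control Optional data frame from [generate_case_control()].
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, labels = NULL, case_control = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img_dir <- file.path(dir, "images")
  dir.create(img_dir, showWarnings = FALSE)
  for (id in names(cohort$images)) {
    png::writePNG(cohort$images[[id]], file.path(img_dir, paste0(id, ".png")))
  }
  utils::write.csv(cohort$meta, file.path(dir, "meta.csv"), row.names = FALSE)
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  if (!is.null(labels)) {
    utils::write.csv(labels, file.path(dir, "labels.csv"), row.names = FALSE)
  }
  if (!is.null(case_control)) {
    utils::write.csv(case_control, file.path(dir, "case_control.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
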