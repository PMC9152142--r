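# StudyTable construction and plain-text serialization.

#' Create a StudyTable
#'
#' @param measurements long data.frame with columns `participant_id`,
#'   `group`, `variable`, `occasion`, `value`; missing entries are absent
#'   rows.
#' @param participants data.frame with `participant_id`, `group`, `age`,
#'   `sex` (`"M"`/`"F"`), `education_years`, `icv`.
#' @param latents optional data.frame of simulated latent draws.
#' @return a [StudyTable-class].
#' @export
studyTable <- function(measurements, participants, latents = data.frame()) {
  measurements <- as.data.frame(measurements)
  measurements$occasion <- as.integer(measurements$occasion)
  measurements <- measurements[!is.na(measurements$value), , drop = FALSE]
  rownames(measurements) <- NULL
  methods::new("StudyTable", measurements = measurements,
               participants = as.data.frame(participants), latents = latents)
}

#' Write / read a StudyTable as tidy CSV
#'
#' Writes `measurements.csv` (participant_id, group, variable, occasion,
#' value) and `participants.csv` into `dir`; a `# seed: <n>` comment line is
#' prepended to the measurements file when the table carries a simulation
#' seed.  `readStudyTable()` inverts the operation.
#'
#' @param table a [StudyTable-class].
#' @param dir output directory (created if needed).
#' @return `writeStudyTable()` the directory invisibly; `readStudyTable()` a
#'   [StudyTable-class].
#' @export
writeStudyTable <- function(table, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mf <- file.path(dir, "measurements.csv")
  seed <- attr(table@measurements, "seed")
  con <- file(mf, "w")
  if (!is.null(seed)) writeLines(paste0("# seed: ", seed), con)
  utils::write.csv(table@measurements, con, row.names = FALSE)
  close(con)
  utils::write.csv(table@participants, file.path(dir, "participants.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname writeStudyTable
#' @export
readStudyTable <- function(dir) {
  meas <- utils::read.csv(file.path(dir, "measurements.csv"),
                          comment.char = "#")
  part <- utils::read.csv(file.path(dir, "participants.csv"))
  studyTable(meas, part)
}

#' ROI roster and modality naming convention
#'
#' Twelve regions of interest (hippocampus, anterior and posterior cingulate
#' cortex, precentral gyrus, juxtapositional lobule cortex, inferior frontal
#' gyrus; left and right) each measured by three MRI modalities.  A measured
#' variable is named `<ROI>_<HEMI>.<MODALITY>` (e.g. `"ACC_R.VBM"`), and a
#' manifest variable in a model appends the occasion (`"ACC_R.VBM_T1"`).
#'
#' @return character vector of the 12 ROI tokens.
#' @export
roiRoster <- function() {
  as.vector(outer(c("HC", "ACC", "PCC", "PCG", "JLC", "IFG"), c("L", "R"),
                  function(a, b) paste0(a, "_", b)))
}

#' @rdname roiRoster
#' @export
modalityRoster <- function() c("VBM", "MT", "MD")

roiVariables <- function(roi) paste0(roi, ".", modalityRoster())

# validate that a StudyTable holds the variables a model needs
assertRoster <- function(table, variables) {
  have <- unique(table@measurements$variable)
  miss <- setdiff(variables, have)
  if (length(miss))
    stop("StudyTable lacks required variables: ", paste(miss, collapse = ", "))
  invisible(TRUE)
}
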