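#' Write a gait trial to a directory of plain-text files
#'
#' One directory per trial: `emg.csv` (`time_s` + seven muscle columns,
#' volts), `grf.csv` (`time_s`, `fz_n`), `breaths.csv` (`time_s`, `vo2_l_s`,
#' `vco2_l_s`) and `meta.json` (participant, condition, mass, belt speed,
#' excluded channels). Generator ground truth is not persisted; round-trips
#' reproduce what a measurement system would have recorded.
#'
#' @param trial A `gait_trial`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "gait_trial"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(trial$emg, file.path(dir, "emg.csv"))
  readr::write_csv(trial$grf, file.path(dir, "grf.csv"))
  readr::write_csv(trial$breaths, file.path(dir, "breaths.csv"))
  meta <- list(
    participant_id = trial$participant_id,
    condition = trial$condition,
    grade = trial$grade,
    crouch_rep = trial$crouch_rep,
    duration = trial$duration,
    sampling_rate = trial$sampling_rate,
    mass_kg = trial$mass,
    speed_m_s = trial$belt_speed,
    excluded_channels = as.list(trial$excluded_channels)
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' Read a gait trial from a directory
#'
#' Counterpart of [write_trial()]. The returned object has no `truth`
#' element (measured-data trials carry no generator ground truth).
#'
#' @param dir Trial directory containing `emg.csv`, `grf.csv`, `breaths.csv`
#'   and `meta.json`.
#' @return A `gait_trial`.
#' @export
read_trial <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  structure(
    list(
      participant_id = meta$participant_id,
      condition = meta$condition,
      grade = if (is.null(meta$grade)) NA_real_ else meta$grade,
      crouch_rep = if (is.null(meta$crouch_rep)) NA_character_
                   else meta$crouch_rep,
      emg = readr::read_csv(file.path(dir, "emg.csv"),
                            show_col_types = FALSE),
      grf = readr::read_csv(file.path(dir, "grf.csv"),
                            show_col_types = FALSE),
      breaths = readr::read_csv(file.path(dir, "breaths.csv"),
                                show_col_types = FALSE),
      duration = meta$duration,
      sampling_rate = meta$sampling_rate,
      belt_speed = meta$speed_m_s,
      mass = meta$mass_kg,
      excluded_channels = as.character(unlist(meta$excluded_channels)),
      truth = NULL,
      seed = NA_integer_
    ),
    class = "gait_trial"
  )
}

#' Write a cohort of trials plus a manifest
#'
#' Writes one sub-directory per trial (named `<participant>_<label>`) and a
#' `cohort.json` manifest listing participants, condition labels and
#' per-trial seeds.
#'
#' @param cohort A `gait_cohort` from [generate_cohort()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "gait_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- attr(cohort, "manifest")
  paths <- gsub("/", "_", names(cohort), fixed = TRUE)
  for (i in seq_along(cohort)) {
    write_trial(cohort[[i]], file.path(dir, paths[i]))
  }
  jsonlite::write_json(
    list(trials = cbind(manifest, path = paths)),
    file.path(dir, "cohort.json"),
    auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(dir)
}

#' Write detected stride windows to JSON
#'
#' @param strides A `stride_windows` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_strides <- function(strides, path) {
  stopifnot(inherits(strides, "stride_windows"))
  jsonlite::write_json(
    list(
      contact_indices = strides$contact_indices,
      stride_durations = strides$stride_durations,
      sampling_rate = strides$sampling_rate,
      threshold_value = strides$threshold_value
    ),
    path, digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}
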