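#' Write a recording to disk
#'
#' One CSV of samples (`sample_index`, `ch_ulnaris_mV`, `ch_radialis_mV`)
#' plus a JSON sidecar carrying the subject id, sampling rate, task markers
#' (0-based half-open sample intervals) and any metadata. The round trip
#' through [read_recording()] preserves sample values to at least 9
#' significant digits.
#'
#' @param recording An `emg_recording`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the two file paths written.
#' @export
write_recording <- function(recording, dir) {
  stopifnot(inherits(recording, "emg_recording"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv_path <- file.path(dir, paste0(recording$subject_id, ".csv"))
  json_path <- file.path(dir, paste0(recording$subject_id, ".json"))
  readr::write_csv(recording$signal, csv_path)
  sidecar <- list(
    subject_id = recording$subject_id,
    sampling_rate = recording$sampling_rate,
    markers = recording$markers,
    meta = recording$meta
  )
  jsonlite::write_json(sidecar, json_path,
    auto_unbox = TRUE, digits = NA, null = "null", na = "null"
  )
  invisible(c(csv = csv_path, json = json_path))
}

#' Read a recording written by [write_recording()]
#'
#' @param csv_path Path to the sample CSV.
#' @param json_path Path to the JSON sidecar; defaults to the CSV path with
#'   a `.json` extension.
#' @return An `emg_recording`.
#' @export
read_recording <- function(csv_path, json_path = sub("\\.csv$", ".json", csv_path)) {
  signal <- readr::read_csv(csv_path,
    col_types = readr::cols(
      sample_index = readr::col_integer(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
  sidecar <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  structure(
    list(
      subject_id = sidecar$subject_id,
      sampling_rate = sidecar$sampling_rate,
      signal = signal,
      markers = tibble::as_tibble(sidecar$markers),
      meta = sidecar$meta
    ),
    class = "emg_recording"
  )
}

#' Write a cohort of recordings
#'
#' @param cohort List of `emg_recording` objects.
#' @param dir Output directory.
#' @return Invisibly, a character vector of CSV paths.
#' @export
write_cohort <- function(cohort, dir) {
  paths <- purrr::map_chr(cohort, function(rec) {
    write_recording(rec, dir)[["csv"]]
  })
  invisible(paths)
}

#' Write processed segments in the recording dialect
#'
#' One CSV per segment (`sample_index` plus the channel columns) and a JSON
#' sidecar recording the subject, task, sampling rate, units and the
#' processing-state flags, so downstream tools can verify what has been
#' applied.
#'
#' @param segments A segment table.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the CSV paths written.
#' @export
write_segments <- function(segments, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- purrr::map_chr(seq_len(nrow(segments)), function(i) {
    stem <- sprintf("%s_task%d", segments$subject_id[i], segments$task_id[i])
    seg <- segments$data[[i]]
    out <- tibble::tibble(sample_index = seq_len(nrow(seg)) - 1L)
    csv_path <- file.path(dir, paste0(stem, ".csv"))
    readr::write_csv(dplyr::bind_cols(out, seg), csv_path)
    sidecar <- list(
      subject_id = segments$subject_id[i],
      task_id = segments$task_id[i],
      sampling_rate = segments$sampling_rate[i],
      units = segments$units[i],
      processing_state = list(
        segmented = TRUE,
        trimmed = segments$trimmed[i],
        normalized = segments$normalized[i],
        rectified = segments$rectified[i],
        filtered = segments$filtered[i]
      )
    )
    jsonlite::write_json(sidecar, file.path(dir, paste0(stem, ".json")),
      auto_unbox = TRUE, digits = NA, null = "null", na = "null"
    )
    csv_path
  })
  invisible(paths)
}

#' Read every recording in a directory
#'
#' @param dir Directory containing `<subject>.csv` / `<subject>.json` pairs.
#' @return A named list of `emg_recording` objects.
#' @export
read_cohort <- function(dir) {
  csvs <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (length(csvs) == 0) stop("no recording CSVs found in ", dir, call. = FALSE)
  recs <- purrr::map(csvs, read_recording)
  stats::setNames(recs, purrr::map_chr(recs, "subject_id"))
}
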