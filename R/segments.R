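#' Split a recording into task segments
#'
#' Slices the continuous recording at its protocol markers, one segment per
#' marker; samples that fall between markers (inter-task rest) appear in no
#' segment. Markers are 0-based half-open `[start_sample, end_sample)`
#' intervals and must be ordered and non-overlapping.
#'
#' The result is a tidy segment table: one row per task segment with the
#' channel samples nested in the `data` list-column, plus the
#' processing-state flags that the downstream verbs ([trim_baseline()],
#' [normalize_mvc()], [rectify()], [apply_lowpass()]) check and advance.
#' Flags are monotone: once set they are never unset.
#'
#' @param recording An `emg_recording`.
#' @return A tibble with columns `subject_id`, `task_id`, `sampling_rate`,
#'   `n_samples`, `data` (list of tibbles with columns `ch_ulnaris`,
#'   `ch_radialis`), `units` and logical flags `trimmed`, `normalized`,
#'   `rectified`, `filtered`.
#' @export
segment_by_task <- function(recording) {
  stopifnot(inherits(recording, "emg_recording"))
  markers <- dplyr::arrange(recording$markers, .data$start_sample)
  n_total <- nrow(recording$signal)
  if (any(markers$start_sample < 0) || any(markers$end_sample > n_total) ||
    any(markers$end_sample <= markers$start_sample)) {
    stop("markers must be non-empty intervals within the signal", call. = FALSE)
  }
  if (nrow(markers) > 1 &&
    any(markers$start_sample[-1] < markers$end_sample[-nrow(markers)])) {
    stop("protocol error: overlapping task markers", call. = FALSE)
  }
  ulnaris <- recording$signal$ch_ulnaris_mV
  radialis <- recording$signal$ch_radialis_mV
  data <- purrr::map2(markers$start_sample, markers$end_sample, function(s, e) {
    idx <- (s + 1L):e # 0-based half-open -> R indices
    tibble::tibble(ch_ulnaris = ulnaris[idx], ch_radialis = radialis[idx])
  })
  tibble::tibble(
    subject_id = recording$subject_id,
    task_id = markers$task_id,
    sampling_rate = recording$sampling_rate,
    n_samples = markers$end_sample - markers$start_sample,
    data = data,
    units = "mV",
    trimmed = FALSE,
    normalized = FALSE,
    rectified = FALSE,
    filtered = FALSE
  )
}

segment_channels <- function(seg_data) {
  names(seg_data)[startsWith(names(seg_data), "ch_")]
}

#' Trim baseline segments to a central window
#'
#' Both baseline stages (tasks 0 and 8) are trimmed to a central window of
#' `target_duration` seconds, discarding the initial and final excess in
#' equal parts; an odd excess removes the extra sample from the head. A
#' baseline already at or below the target is returned unchanged with a
#' warning. Trimming must precede normalisation.
#'
#' @param segments Segment table from [segment_by_task()]. Must contain at
#'   least one baseline row (`task_id` 0 or 8); non-baseline rows pass
#'   through untouched. Calling it on a table with no baseline rows is a
#'   contract error.
#' @param target_duration Target duration in seconds (default 180 = 3 min).
#' @param baseline_tasks Task ids treated as baselines.
#' @return The segment table with baseline rows trimmed and flagged.
#' @export
trim_baseline <- function(segments, target_duration = 180,
                          baseline_tasks = c(0L, 8L)) {
  is_base <- segments$task_id %in% baseline_tasks
  if (!any(is_base)) {
    stop("trim_baseline applies only to baseline segments (tasks ",
      paste(baseline_tasks, collapse = ", "), ")",
      call. = FALSE
    )
  }
  if (any(segments$normalized[is_base])) {
    stop("baselines must be trimmed before MVC normalisation", call. = FALSE)
  }
  for (i in which(is_base)) {
    fs <- segments$sampling_rate[i]
    target_n <- round(target_duration * fs)
    n <- segments$n_samples[i]
    if (n <= target_n) {
      warning(
        "baseline segment (task ", segments$task_id[i], ", subject ",
        segments$subject_id[i], ") is already <= ", target_duration,
        " s; returned unchanged",
        call. = FALSE
      )
    } else {
      excess <- n - target_n
      head_drop <- ceiling(excess / 2)
      segments$data[[i]] <-
        segments$data[[i]][(head_drop + 1):(head_drop + target_n), ]
      segments$n_samples[i] <- target_n
    }
    segments$trimmed[i] <- TRUE
  }
  segments
}
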