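#' Estimate the maximum voluntary contraction reference
#'
#' The MVC reference is taken, per channel, from the object-grip task
#' (task 4): the maximum of a moving-RMS (default 100 ms window) of the
#' full-wave-rectified signal. A robust alternative (99th percentile of the
#' rectified signal) is available via `estimator = "quantile"`.
#'
#' @param segments Segment table containing the unnormalized task-4 row(s)
#'   for each subject.
#' @param window Moving-RMS window length in seconds.
#' @param estimator `"moving_rms_max"` (default) or `"quantile"`.
#' @param source_task Task id supplying the MVC (default 4).
#' @return A tibble with columns `subject_id`, `channel`, `mvc_value` (mV),
#'   `source_task`, `estimator`.
#' @export
compute_mvc <- function(segments, window = 0.1,
                        estimator = c("moving_rms_max", "quantile"),
                        source_task = 4L) {
  estimator <- match.arg(estimator)
  rows <- which(segments$task_id == source_task)
  if (length(rows) == 0) {
    stop("no task-", source_task, " segment available for MVC estimation",
      call. = FALSE
    )
  }
  if (any(segments$normalized[rows])) {
    stop("MVC must be estimated on unnormalized segments", call. = FALSE)
  }
  purrr::map_dfr(rows, function(i) {
    seg <- segments$data[[i]]
    fs <- segments$sampling_rate[i]
    chans <- segment_channels(seg)
    vals <- purrr::map_dbl(chans, function(ch) {
      x <- abs(seg[[ch]])
      if (all(x == 0)) {
        stop("degenerate MVC: channel ", ch, " of subject ",
          segments$subject_id[i], " is all zero",
          call. = FALSE
        )
      }
      if (estimator == "moving_rms_max") {
        max(moving_rms(x, round(window * fs)))
      } else {
        stats::quantile(x, 0.99, names = FALSE)
      }
    })
    tibble::tibble(
      subject_id = segments$subject_id[i],
      channel = chans,
      mvc_value = vals,
      source_task = source_task,
      estimator = estimator
    )
  })
}

# Centered moving RMS over a window of w samples (w clipped to the signal
# length); computed via a C-level moving average of x^2.
moving_rms <- function(x, w) {
  w <- max(1L, min(as.integer(w), length(x)))
  ma <- stats::filter(x^2, rep(1 / w, w), sides = 2)
  sqrt(ma[!is.na(ma)])
}

#' Normalise segments by the MVC reference
#'
#' Divides each channel by that channel's MVC value for the segment's
#' subject, converting units from mV to fraction-of-MVC. Errors if the MVC
#' table does not cover the segment's subject/channels or if the segment is
#' already normalised.
#'
#' @param segments Segment table.
#' @param mvc MVC reference table from [compute_mvc()].
#' @return The segment table with normalised channels and the `normalized`
#'   flag set.
#' @export
normalize_mvc <- function(segments, mvc) {
  if (any(segments$normalized)) {
    stop("segments are already MVC-normalized", call. = FALSE)
  }
  for (i in seq_len(nrow(segments))) {
    sid <- segments$subject_id[i]
    ref <- mvc[mvc$subject_id == sid, ]
    if (nrow(ref) == 0) {
      stop("MVC reference missing for subject ", sid, call. = FALSE)
    }
    seg <- segments$data[[i]]
    for (ch in segment_channels(seg)) {
      v <- ref$mvc_value[ref$channel == ch]
      if (length(v) != 1) {
        stop("MVC reference missing channel ", ch, " for subject ", sid,
          call. = FALSE
        )
      }
      seg[[ch]] <- seg[[ch]] / v
    }
    segments$data[[i]] <- seg
  }
  segments$units <- "mvc_fraction"
  segments$normalized <- TRUE
  segments
}

#' Full-wave rectify segments
#'
#' Sample-wise absolute value on every channel. Rectification demodulates
#' burst rhythmicity of the 20--450 Hz sEMG carrier into the low-frequency
#' envelope band that the 14 Hz low-pass retains. Idempotent.
#'
#' @param segments Segment table.
#' @return The segment table with rectified channels and the `rectified`
#'   flag set.
#' @export
rectify <- function(segments) {
  if (any(segments$filtered)) {
    stop("rectification must precede low-pass filtering", call. = FALSE)
  }
  segments$data <- purrr::map(segments$data, function(seg) {
    for (ch in segment_channels(seg)) seg[[ch]] <- abs(seg[[ch]])
    seg
  })
  segments$rectified <- TRUE
  segments
}

#' Average the two normalised channels into a combined trace
#'
#' Adds a `ch_combined` column, the per-sample mean of the ulnaris and
#' radialis channels, used as the default analysis trace. Requires
#' MVC-normalised segments so the channels share units.
#'
#' @param segments Segment table (normalised).
#' @return The segment table with a `ch_combined` channel added.
#' @export
combine_channels <- function(segments) {
  if (!all(segments$normalized)) {
    stop("channels must be MVC-normalized before combining", call. = FALSE)
  }
  segments$data <- purrr::map(segments$data, function(seg) {
    seg$ch_combined <- (seg$ch_ulnaris + seg$ch_radialis) / 2
    seg
  })
  segments
}
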