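#' Clinical tremor frequency band definitions
#'
#' The five frequency groups used for tremor profiling: noise (< 3.5 Hz),
#' rest (3.5--6 Hz), action (6--9 Hz), postural (9--12 Hz, upper bound
#' inclusive) and normal (> 12 Hz). Bands are pairwise disjoint and cover
#' the whole nonnegative axis; interior boundaries are half-open at 6 and
#' 9 Hz, and 12.0 Hz itself belongs to the postural band. Only the rest,
#' action and postural bands enter the primary statistical battery; noise
#' and normal rows are retained but flagged as not analysed.
#'
#' @return A tibble with columns `band`, `lower` (Hz, inclusive), `upper`
#'   (Hz), `upper_inclusive` and `analyzed`.
#' @export
band_definitions <- function() {
  tibble::tibble(
    band = c("noise", "rest", "action", "postural", "normal"),
    lower = c(0, 3.5, 6, 9, 12),
    lower_inclusive = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    upper = c(3.5, 6, 9, 12, Inf),
    upper_inclusive = c(FALSE, FALSE, FALSE, TRUE, TRUE),
    analyzed = c(FALSE, TRUE, TRUE, TRUE, FALSE)
  )
}

#' Classify frequencies into tremor bands
#'
#' Stateless, vectorised classifier realising [band_definitions()]:
#' noise `[0, 3.5)`, rest `[3.5, 6)`, action `[6, 9)`, postural `[9, 12]`,
#' normal `(12, Inf)`.
#'
#' @param f Nonnegative frequencies in Hz.
#' @return Character vector of band names.
#' @examples
#' classify_frequency(c(5, 6, 12, 12.01))
#' @export
classify_frequency <- function(f) {
  if (any(is.na(f)) || any(f < 0)) {
    stop("frequencies must be nonnegative and non-missing", call. = FALSE)
  }
  dplyr::case_when(
    f < 3.5 ~ "noise",
    f < 6 ~ "rest",
    f < 9 ~ "action",
    f <= 12 ~ "postural",
    TRUE ~ "normal"
  )
}

#' Assemble the cohort band-observation table
#'
#' Classifies every frame observation into its frequency band and appends
#' the band name and the analysed flag. Noise- and normal-band rows are
#' kept for reporting but flagged `analyzed = FALSE` and excluded from the
#' primary statistics.
#'
#' @param observations Frame observation table from [frame_observations()]
#'   (columns `subject_id`, `task_id`, `dominant_frequency`, `magnitude`,
#'   optionally `frame_time`).
#' @return A tibble with columns `subject_id`, `task_id`, `band`,
#'   `frequency`, `magnitude`, `analyzed`.
#' @export
build_band_table <- function(observations) {
  if (nrow(observations) == 0) {
    return(tibble::tibble(
      subject_id = character(), task_id = integer(), band = character(),
      frequency = numeric(), magnitude = numeric(), analyzed = logical()
    ))
  }
  defs <- band_definitions()
  observations |>
    dplyr::mutate(band = classify_frequency(.data$dominant_frequency)) |>
    dplyr::left_join(defs[, c("band", "analyzed")], by = "band") |>
    dplyr::transmute(
      subject_id = .data$subject_id,
      task_id = .data$task_id,
      band = .data$band,
      frequency = .data$dominant_frequency,
      magnitude = .data$magnitude,
      analyzed = .data$analyzed
    )
}
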