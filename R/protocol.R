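#' Default MDS-UPDRS-aligned task protocol
#'
#' The nine-segment upper-limb protocol used throughout the package: a long
#' pre-task baseline (task 0), seven short motor tasks adapted from the
#' MDS-UPDRS Part II/III upper-limb items (tasks 1--7), and a long
#' post-baseline (task 8). Each row carries the simulation parameters that
#' the synthetic cohort generator uses to realise the task:
#'
#' * `tremor_frequency` / `tremor_depth` -- frequency (Hz) and modulation
#'   index of the rhythmic burst activity injected for that task. Finger
#'   tapping (task 3) carries a strong 5 Hz rest-band rhythm; postural
#'   holding (task 7) a mild 10 Hz component; kinetic reaching (task 5) a
#'   mild 7 Hz component.
#' * `activation_level` -- mean muscle activation as a fraction of maximum
#'   voluntary contraction (MVC). The object-grip task (task 4) is the MVC
#'   calibration source and is generated at full activation; pronation--
#'   supination (task 6) is the low, stable reference task.
#'
#' Baselines are generated at 240 s so that the 3-minute central-window
#' trimming stage operates non-trivially; motor tasks default to 12 s.
#'
#' @return A tibble with one row per task and columns `task_id` (integer,
#'   0--8), `name`, `duration` (s), `tremor_frequency` (Hz, `NA` when no
#'   rhythm is injected), `tremor_depth` (0--1) and `activation_level`
#'   (fraction of MVC, 0--1).
#' @examples
#' build_default_protocol()
#' @export
build_default_protocol <- function() {
  protocol <- tibble::tibble(
    task_id = 0:8,
    name = c(
      "baseline", "handwriting", "object_move", "finger_tapping",
      "grip", "kinetic_tremor", "pronation_supination", "postural_tremor",
      "post_baseline"
    ),
    duration = c(240, 12, 12, 12, 12, 12, 12, 12, 240),
    tremor_frequency = c(NA, NA, NA, 5.0, NA, 7.0, NA, 10.0, NA),
    tremor_depth = c(0, 0, 0, 0.8, 0, 0.3, 0, 0.4, 0),
    activation_level = c(0.03, 0.25, 0.30, 0.35, 1.00, 0.30, 0.05, 0.25, 0.05)
  )
  validate_protocol(protocol)
  protocol
}

validate_protocol <- function(protocol) {
  stopifnot(is.data.frame(protocol))
  required <- c(
    "task_id", "name", "duration", "tremor_frequency",
    "tremor_depth", "activation_level"
  )
  missing <- setdiff(required, names(protocol))
  if (length(missing) > 0) {
    stop("protocol is missing columns: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(protocol$task_id)) {
    stop("task_ids must be unique within a protocol", call. = FALSE)
  }
  if (any(protocol$duration <= 0)) {
    stop("task durations must be positive", call. = FALSE)
  }
  if (any(protocol$tremor_depth < 0 | protocol$tremor_depth > 1)) {
    stop("tremor_depth must lie in [0, 1]", call. = FALSE)
  }
  if (any(protocol$activation_level < 0 | protocol$activation_level > 1)) {
    stop("activation_level must lie in [0, 1]", call. = FALSE)
  }
  invisible(protocol)
}
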