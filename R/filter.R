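#' Design a digital Butterworth low-pass in cascaded biquad form
#'
#' Bilinear-transform design with cutoff prewarping, returned as
#' second-order sections rather than a single transfer function: at order
#' 10 with a 14 Hz cutoff on a 2048 Hz grid the expanded polynomial form is
#' numerically ill-conditioned, while the biquad cascade is stable. The
#' single-pass power gain at the cutoff is exactly 1/2 (-3.01 dB), the
#' Butterworth cutoff definition; DC gain is exactly 1 per section.
#'
#' @param sampling_rate Sampling rate in Hz.
#' @param cutoff Cutoff frequency in Hz (default 14); must be below the
#'   Nyquist frequency.
#' @param order Filter order (default 10). Odd orders add one first-order
#'   section.
#' @return An object of class `sos_filter`: a list with the section matrix
#'   `sos` (columns `b0 b1 b2 a1 a2`, denominators normalised to `a0 = 1`)
#'   and the design parameters.
#' @export
design_lowpass <- function(sampling_rate, cutoff = 14, order = 10) {
  if (cutoff <= 0 || cutoff >= sampling_rate / 2) {
    stop("cutoff must lie strictly between 0 and the Nyquist frequency",
      call. = FALSE
    )
  }
  if (order < 1) stop("order must be >= 1", call. = FALSE)
  K <- 2 * sampling_rate
  wc <- K * tan(pi * cutoff / sampling_rate) # prewarped analog cutoff
  n <- as.integer(order)
  # Analog Butterworth poles on the left half of the |s| = wc circle.
  k <- seq_len(floor(n / 2))
  theta <- pi * (2 * k + n - 1) / (2 * n)
  sections <- lapply(theta, function(th) {
    a1s <- -2 * wc * cos(th) # s^2 + a1s*s + wc^2
    d0 <- K^2 + a1s * K + wc^2
    c(
      b0 = wc^2 / d0, b1 = 2 * wc^2 / d0, b2 = wc^2 / d0,
      a1 = (-2 * K^2 + 2 * wc^2) / d0, a2 = (K^2 - a1s * K + wc^2) / d0
    )
  })
  if (n %% 2 == 1) { # real pole at s = -wc
    d0 <- K + wc
    sections <- c(sections, list(c(
      b0 = wc / d0, b1 = wc / d0, b2 = 0,
      a1 = (wc - K) / d0, a2 = 0
    )))
  }
  structure(
    list(
      sos = do.call(rbind, sections),
      family = "butterworth", kind = "lowpass",
      order = n, cutoff = cutoff, sampling_rate = sampling_rate
    ),
    class = "sos_filter"
  )
}

#' @export
print.sos_filter <- function(x, ...) {
  cat(
    "<sos_filter> order-", x$order, " ", x$family, " ", x$kind, " at ",
    x$cutoff, " Hz (fs = ", x$sampling_rate, " Hz), ",
    nrow(x$sos), " sections\n",
    sep = ""
  )
  invisible(x)
}

#' Single-pass complex frequency response of a cascaded-sections filter
#'
#' @param filt An `sos_filter`.
#' @param f Frequencies in Hz.
#' @return Complex response values `H(f)`; `Mod(.)^2` is the single-pass
#'   power gain (zero-phase application squares it).
#' @export
filter_response <- function(filt, f) {
  z <- exp(-2i * pi * f / filt$sampling_rate)
  H <- rep(1 + 0i, length(f))
  for (i in seq_len(nrow(filt$sos))) {
    s <- filt$sos[i, ]
    H <- H * (s["b0"] + s["b1"] * z + s["b2"] * z^2) /
      (1 + s["a1"] * z + s["a2"] * z^2)
  }
  unname(H)
}

sos_filter_once <- function(x, filt) {
  sos_filter_pass(x, filt$sos)
}

# Effective impulse-response length used for edge padding and the
# too-short contract: about two cutoff periods.
filter_effective_length <- function(filt) {
  ceiling(2 * filt$sampling_rate / filt$cutoff)
}

#' Zero-phase (forward-backward) filtering of one signal
#'
#' Applies the section cascade forward and backward with odd-reflection
#' edge padding, giving zero phase distortion and a squared magnitude
#' response. The output has the input's length.
#'
#' @param x Numeric signal.
#' @param filt An `sos_filter`.
#' @return Filtered numeric vector.
#' @export
filtfilt_sos <- function(x, filt) {
  n <- length(x)
  n_imp <- filter_effective_length(filt)
  if (n < 3 * n_imp) {
    stop("segment too short to filter: ", n, " samples < 3 x effective ",
      "impulse length (", 3 * n_imp, ")",
      call. = FALSE
    )
  }
  pad <- min(n - 1L, 3L * n_imp)
  head_ext <- 2 * x[1] - x[(pad + 1):2]
  tail_ext <- 2 * x[n] - x[(n - 1):(n - pad)]
  y <- c(head_ext, x, tail_ext)
  y <- sos_filter_once(y, filt)
  y <- rev(sos_filter_once(rev(y), filt))
  y[(pad + 1):(pad + n)]
}

#' Low-pass filter every channel of a segment table
#'
#' Zero-phase application of the designed Butterworth low-pass to each
#' channel; the `filtered` flag is set. Errors if the filter's design
#' sampling rate does not match a segment or a segment is shorter than
#' three effective impulse lengths.
#'
#' @param segments Segment table.
#' @param filt An `sos_filter` from [design_lowpass()]; designed on demand
#'   from `cutoff`/`order` when `NULL`.
#' @param cutoff,order Design parameters used when `filt` is `NULL`.
#' @return The segment table with filtered channels.
#' @export
apply_lowpass <- function(segments, filt = NULL, cutoff = 14, order = 10) {
  designs <- list()
  for (i in seq_len(nrow(segments))) {
    fs <- segments$sampling_rate[i]
    f <- filt
    if (is.null(f)) {
      key <- as.character(fs)
      if (is.null(designs[[key]])) {
        designs[[key]] <- design_lowpass(fs, cutoff = cutoff, order = order)
      }
      f <- designs[[key]]
    } else if (f$sampling_rate != fs) {
      stop("filter was designed for ", f$sampling_rate, " Hz but segment ",
        "has sampling rate ", fs, " Hz",
        call. = FALSE
      )
    }
    seg <- segments$data[[i]]
    for (ch in segment_channels(seg)) seg[[ch]] <- filtfilt_sos(seg[[ch]], f)
    segments$data[[i]] <- seg
  }
  segments$filtered <- TRUE
  segments
}

#' Run the full pre-processing chain on one recording
#'
#' Fixed stage order: segment by task, trim baselines to the central
#' 3 minutes, MVC-normalise (reference from task 4), full-wave rectify,
#' zero-phase low-pass at 14 Hz, then add the combined (mean) channel.
#'
#' @param recording An `emg_recording`.
#' @param target_baseline Baseline trim target in seconds.
#' @param mvc_window MVC moving-RMS window in seconds.
#' @param do_rectify Set to `FALSE` to skip rectification (for raw-envelope
#'   comparisons).
#' @param cutoff,order Low-pass design parameters.
#' @return A fully processed segment table with a `ch_combined` channel.
#' @export
preprocess_recording <- function(recording, target_baseline = 180,
                                 mvc_window = 0.1, do_rectify = TRUE,
                                 cutoff = 14, order = 10) {
  segments <- segment_by_task(recording)
  if (any(segments$task_id %in% c(0L, 8L))) {
    segments <- trim_baseline(segments, target_duration = target_baseline)
  }
  mvc <- compute_mvc(segments, window = mvc_window)
  segments <- normalize_mvc(segments, mvc)
  if (do_rectify) segments <- rectify(segments)
  segments <- apply_lowpass(segments, cutoff = cutoff, order = order)
  combine_channels(segments)
}
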