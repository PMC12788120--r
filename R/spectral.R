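#' One-sided FFT amplitude spectrum
#'
#' Amplitude scaling follows the sinusoid convention: a unit-amplitude
#' sinusoid centred on a frequency bin yields amplitude 1.0 there
#' (factor 2/N for the non-DC bins, 1/N at DC).
#'
#' @param x Numeric signal (a processed analysis trace, fraction-of-MVC
#'   units).
#' @param sampling_rate Sampling rate in Hz.
#' @return A tibble with columns `frequency` (Hz, 0 to Nyquist) and
#'   `amplitude`.
#' @export
amplitude_spectrum <- function(x, sampling_rate) {
  n <- length(x)
  if (n == 0) stop("cannot take the spectrum of an empty segment", call. = FALSE)
  X <- stats::fft(x)
  half <- floor(n / 2) + 1L
  amp <- Mod(X[seq_len(half)]) / n
  if (half > 1) amp[-1] <- 2 * amp[-1]
  tibble::tibble(
    frequency = (seq_len(half) - 1) * sampling_rate / n,
    amplitude = amp
  )
}

#' Resolve the task-adaptive STFT window specification
#'
#' The Gaussian window length adapts to the task duration: `nperseg` is the
#' smallest power of two whose frequency resolution
#' `sampling_rate / nperseg` reaches the target (default 0.25 Hz), capped
#' at the largest power of two that fits in the segment -- so the long
#' baselines get full-resolution windows while short motor tasks get the
#' longest window they can carry. The Gaussian standard deviation is
#' `nperseg / 6` samples and frames overlap by half.
#'
#' @param task_duration Segment duration in seconds.
#' @param sampling_rate Sampling rate in Hz.
#' @param target_resolution Target frequency resolution in Hz.
#' @return A list of class `stft_spec` with elements `window_family`,
#'   `nperseg`, `gaussian_sd`, `overlap_fraction`, `adaptive`.
#' @export
resolve_stft_spec <- function(task_duration, sampling_rate,
                              target_resolution = 0.25) {
  if (task_duration <= 0) stop("task_duration must be positive", call. = FALSE)
  seg_len <- floor(task_duration * sampling_rate)
  want <- 2^ceiling(log2(sampling_rate / target_resolution))
  cap <- 2^floor(log2(seg_len))
  nperseg <- max(16, min(want, cap))
  structure(
    list(
      window_family = "gaussian",
      nperseg = as.integer(nperseg),
      gaussian_sd = nperseg / 6,
      overlap_fraction = 0.5,
      adaptive = TRUE
    ),
    class = "stft_spec"
  )
}

gaussian_window <- function(n, sd) {
  i <- seq_len(n) - 1
  exp(-0.5 * ((i - (n - 1) / 2) / sd)^2)
}

#' Gaussian-window short-time Fourier transform
#'
#' Magnitude spectrogram over Gaussian-windowed frames with the overlap
#' stated in the window spec. Each frame is constant-detrended (window-
#' weighted mean removed) before windowing so that the large mean of a
#' rectified trace cannot leak into the low-frequency bins. Magnitudes use
#' the sinusoid amplitude convention (a stationary unit sinusoid gives
#' frame magnitude ~1 at its bin). The full frequency grid up to Nyquist is
#' retained; downstream observation extraction restricts to the 0--14 Hz
#' analysis range.
#'
#' @param x Numeric signal.
#' @param sampling_rate Sampling rate in Hz.
#' @param spec An `stft_spec`; resolved from the signal duration when
#'   `NULL`.
#' @return An `emg_spectrogram`: list with `times` (s, frame centres),
#'   `frequencies` (Hz), `magnitudes` (frequency x time matrix) and `spec`.
#' @export
compute_stft <- function(x, sampling_rate, spec = NULL) {
  n <- length(x)
  if (is.null(spec)) spec <- resolve_stft_spec(n / sampling_rate, sampling_rate)
  np <- spec$nperseg
  if (np > n) {
    stop("nperseg (", np, ") exceeds segment length (", n, ")", call. = FALSE)
  }
  hop <- max(1L, as.integer(round(np * (1 - spec$overlap_fraction))))
  starts <- seq(1L, n - np + 1L, by = hop)
  w <- gaussian_window(np, spec$gaussian_sd)
  frames <- matrix(x[outer(0:(np - 1L), starts, "+")], nrow = np)
  # Constant detrend per frame (weighted mean) so the rectification-induced
  # DC component cannot leak through the window into the low bins.
  mu <- colSums(frames * w) / sum(w)
  frames <- (frames - rep(mu, each = np)) * w
  S <- stats::mvfft(frames)
  half <- floor(np / 2) + 1L
  mag <- Mod(S[seq_len(half), , drop = FALSE]) / sum(w)
  if (half > 1) mag[-1, ] <- 2 * mag[-1, ]
  structure(
    list(
      times = (starts - 1 + (np - 1) / 2) / sampling_rate,
      frequencies = (seq_len(half) - 1) * sampling_rate / np,
      magnitudes = mag,
      spec = spec,
      sampling_rate = sampling_rate
    ),
    class = "emg_spectrogram"
  )
}

#' @export
print.emg_spectrogram <- function(x, ...) {
  cat(
    "<emg_spectrogram> ", length(x$frequencies), " bins x ",
    length(x$times), " frames, nperseg ", x$spec$nperseg,
    ", resolution ", signif(x$sampling_rate / x$spec$nperseg, 3), " Hz\n",
    sep = ""
  )
  invisible(x)
}

#' Extract per-frame dominant-frequency observations
#'
#' For each STFT frame, the dominant frequency is the argmax bin over the
#' (0, `fmax`] Hz analysis band, excluding DC (rectification puts a large
#' mean there that would otherwise dominate every frame). Frames without a
#' confident rhythmic component -- peak below `noise_floor_multiplier`
#' times the frame's median band magnitude -- are dropped.
#'
#' @param sg An `emg_spectrogram`.
#' @param noise_floor_multiplier Peak-to-median gate (default 3).
#' @param fmax Analysis ceiling in Hz (default 14, the filter cutoff).
#' @return A tibble with columns `frame_time` (s), `dominant_frequency`
#'   (Hz) and `magnitude`.
#' @export
extract_frame_observations <- function(sg, noise_floor_multiplier = 3,
                                       fmax = 14) {
  stopifnot(inherits(sg, "emg_spectrogram"))
  keep <- sg$frequencies > 0 & sg$frequencies <= fmax
  freqs <- sg$frequencies[keep]
  mags <- sg$magnitudes[keep, , drop = FALSE]
  obs <- purrr::map_dfr(seq_along(sg$times), function(j) {
    col <- mags[, j]
    peak <- which.max(col)
    pk <- col[peak]
    if (pk <= 0 || pk < noise_floor_multiplier * stats::median(col)) {
      return(NULL)
    }
    tibble::tibble(
      frame_time = sg$times[j],
      dominant_frequency = freqs[peak],
      magnitude = pk
    )
  })
  if (nrow(obs) == 0) {
    obs <- tibble::tibble(
      frame_time = numeric(), dominant_frequency = numeric(),
      magnitude = numeric()
    )
  }
  obs
}

#' Frame observations for every segment of a cohort
#'
#' Runs the STFT (task-adaptive window) and dominant-frequency extraction
#' on the chosen channel of each processed segment, returning one long
#' observation table.
#'
#' @param segments Processed segment table (filtered, with the analysis
#'   channel present).
#' @param channel Analysis channel (default the combined trace).
#' @param target_resolution STFT target resolution in Hz.
#' @param noise_floor_multiplier,fmax Passed to
#'   [extract_frame_observations()].
#' @return A tibble with columns `subject_id`, `task_id`, `frame_time`,
#'   `dominant_frequency`, `magnitude`.
#' @export
frame_observations <- function(segments, channel = "ch_combined",
                               target_resolution = 0.25,
                               noise_floor_multiplier = 3, fmax = 14) {
  if (!all(segments$filtered)) {
    stop("segments must be low-pass filtered before spectral analysis",
      call. = FALSE
    )
  }
  purrr::map_dfr(seq_len(nrow(segments)), function(i) {
    seg <- segments$data[[i]]
    ch <- if (channel %in% names(seg)) channel else segment_channels(seg)[1]
    fs <- segments$sampling_rate[i]
    spec <- resolve_stft_spec(nrow(seg) / fs, fs, target_resolution)
    sg <- compute_stft(seg[[ch]], fs, spec)
    obs <- extract_frame_observations(sg, noise_floor_multiplier, fmax)
    if (nrow(obs) == 0) {
      return(NULL)
    }
    dplyr::bind_cols(
      tibble::tibble(
        subject_id = segments$subject_id[i],
        task_id = segments$task_id[i]
      )[rep(1, nrow(obs)), ],
      obs
    )
  })
}
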