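#' Cohort simulation specification
#'
#' Bundles everything the synthetic sEMG generator needs: the task protocol,
#' the sampling rate, and the noise/variability parameters of the signal
#' model. Defaults describe the study conditions the analysis assumes: a
#' 2048 Hz two-channel forearm montage, modest between-subject amplitude
#' variability, sub-Hz tremor-frequency jitter, 50 Hz mains pickup and
#' broadband measurement noise.
#'
#' @param n_subjects Number of subjects to simulate (>= 1).
#' @param protocol Task protocol tibble, see [build_default_protocol()].
#' @param sampling_rate Sampling rate in Hz. Must be at least 900 Hz so the
#'   20--450 Hz sEMG carrier band can be represented (Nyquist).
#' @param subject_amp_sd Log-scale standard deviation of the per-subject
#'   lognormal amplitude factor (dimensionless).
#' @param tremor_freq_jitter_sd Standard deviation (Hz) of the per-subject
#'   shift applied to every injected tremor frequency.
#' @param mains_hum_level 50 Hz mains hum RMS as a fraction of the clean
#'   signal RMS.
#' @param noise_level White measurement-noise RMS as a fraction of the clean
#'   signal RMS.
#' @param gap_duration Un-marked inter-task rest duration in seconds;
#'   these samples are excluded from all task markers.
#' @param seed Integer seed; all cohort randomness derives from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 28,
                        protocol = build_default_protocol(),
                        sampling_rate = 2048,
                        subject_amp_sd = 0.25,
                        tremor_freq_jitter_sd = 0.3,
                        mains_hum_level = 0.02,
                        noise_level = 0.10,
                        gap_duration = 2,
                        seed = 1L) {
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  validate_protocol(protocol)
  if (sampling_rate < 900) {
    stop("sampling_rate must be >= 900 Hz to carry the 20-450 Hz sEMG band",
      call. = FALSE
    )
  }
  carrier_max <- 450
  tremor_max <- max(c(0, protocol$tremor_frequency), na.rm = TRUE)
  if (sampling_rate < 2 * max(carrier_max, tremor_max)) {
    stop("sampling_rate violates the Nyquist bound for the generated content",
      call. = FALSE
    )
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      protocol = protocol,
      sampling_rate = sampling_rate,
      subject_amp_sd = subject_amp_sd,
      tremor_freq_jitter_sd = tremor_freq_jitter_sd,
      mains_hum_level = mains_hum_level,
      noise_level = noise_level,
      gap_duration = gap_duration,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(
    "<cohort_spec> ", x$n_subjects, " subjects, ",
    nrow(x$protocol), " tasks @ ", x$sampling_rate, " Hz, seed ", x$seed, "\n",
    sep = ""
  )
  invisible(x)
}

# Band-limited unit-RMS Gaussian noise synthesised directly in the
# frequency domain: independent complex-Gaussian coefficients on the
# in-band bins of a Hermitian-symmetric spectrum, one inverse FFT, unit-RMS
# rescale. Power outside [f_lo, f_hi] is exactly zero.
band_limited_noise <- function(n, sampling_rate, f_lo, f_hi) {
  half <- floor(n / 2)
  k <- seq_len(half) # positive-frequency bins (excl. DC)
  fk <- k * sampling_rate / n
  in_band <- which(fk >= f_lo & fk <= f_hi)
  if (length(in_band) == 0) {
    return(numeric(n))
  }
  X <- complex(n)
  coef <- complex(
    real = stats::rnorm(length(in_band)),
    imaginary = stats::rnorm(length(in_band))
  )
  X[in_band + 1L] <- coef
  X[n - in_band + 1L] <- Conj(coef)
  if (n %% 2 == 0 && half %in% in_band) { # Nyquist bin must be real
    X[half + 1L] <- complex(real = Re(coef[match(half, in_band)]))
  }
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y / sqrt(mean(y^2))
}

# Slow activation drift (< f_hi Hz), synthesised on a coarse 4 Hz grid and
# linearly interpolated to the full sampling rate; approximately unit RMS.
slow_drift <- function(n, sampling_rate, f_lo = 0.02, f_hi = 0.5) {
  fs_d <- 4
  n_d <- max(32L, ceiling(n / sampling_rate * fs_d))
  d <- band_limited_noise(n_d, fs_d, f_lo, f_hi)
  stats::approx(
    x = (seq_len(n_d) - 1) / fs_d, y = d,
    xout = (seq_len(n) - 1) / sampling_rate, rule = 2
  )$y
}

# Activation envelope for one task on one channel (fraction of MVC, before
# the per-subject amplitude factor). Tremor tasks get a half-rectified
# sinusoidal burst train; non-tremor tasks a slow (< 0.5 Hz) drift.
task_envelope <- function(n, sampling_rate, activation, tremor_frequency,
                          tremor_depth, phase = 0) {
  t <- (seq_len(n) - 1) / sampling_rate
  if (!is.na(tremor_frequency) && tremor_depth > 0) {
    burst <- pmax(0, sin(2 * pi * tremor_frequency * t + phase))
    mod <- (1 - tremor_depth) + tremor_depth * burst
  } else {
    mod <- pmax(0, 1 + 0.15 * slow_drift(n, sampling_rate))
  }
  activation * mod
}

generate_task_samples <- function(spec, task, amp_scale, freq_jitter) {
  fs <- spec$sampling_rate
  n <- round(task$duration * fs)
  t <- (seq_len(n) - 1) / fs
  f_trem <- task$tremor_frequency
  if (!is.na(f_trem)) f_trem <- max(0.5, f_trem + freq_jitter)
  channels <- lapply(c(0, 0), function(phase) { # antagonists co-burst
    carrier <- band_limited_noise(n, fs, 20, 450)
    env <- task_envelope(
      n, fs, task$activation_level, f_trem, task$tremor_depth,
      phase = phase
    )
    clean <- carrier * env * amp_scale
    rms <- sqrt(mean(clean^2))
    hum <- spec$mains_hum_level * rms * sqrt(2) *
      sin(2 * pi * 50 * t + stats::runif(1, 0, 2 * pi))
    clean + hum + stats::rnorm(n, 0, spec$noise_level * rms)
  })
  list(ulnaris = channels[[1]], radialis = channels[[2]], n = n)
}

#' Generate one synthetic subject recording
#'
#' Simulates a two-channel forearm sEMG recording for the full task
#' protocol. The signal model is amplitude-modulated band-limited noise:
#' each task's carrier is zero-mean Gaussian noise confined to the
#' 20--450 Hz sEMG band, multiplied by an activation envelope. Tremor tasks
#' modulate the envelope with a half-rectified sinusoid at the (per-subject
#' jittered) tremor frequency; other tasks carry a slow (< 0.5 Hz)
#' activation drift. 50 Hz mains hum and white measurement noise are added
#' in proportion to the clean-signal RMS. The two channels share the task
#' rhythm (synchronous antagonist bursting) but carry independent carriers
#' and noise. Un-marked rest gaps separate consecutive tasks.
#'
#' Generation is bit-reproducible for a fixed `(spec, subject_id, seed)`.
#'
#' @param spec A [cohort_spec()].
#' @param subject_id Subject label, e.g. `"S01"`.
#' @param seed Integer seed for this subject's private RNG stream.
#' @return An `emg_recording`: a list with `subject_id`, `sampling_rate`,
#'   `signal` (tibble: `sample_index`, `ch_ulnaris_mV`, `ch_radialis_mV`),
#'   `markers` (tibble of 0-based half-open `[start_sample, end_sample)`
#'   task intervals) and `meta` (the realised per-subject amplitude scale
#'   and tremor-frequency jitter).
#' @export
generate_subject <- function(spec, subject_id, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(as.integer(seed), {
    amp_scale <- exp(stats::rnorm(1, 0, spec$subject_amp_sd))
    freq_jitter <- stats::rnorm(1, 0, spec$tremor_freq_jitter_sd)
    protocol <- spec$protocol
    gap_task <- list(
      duration = spec$gap_duration, activation_level = 0.03,
      tremor_frequency = NA_real_, tremor_depth = 0
    )
    pieces <- list()
    markers <- list()
    cursor <- 0L # 0-based sample cursor
    for (i in seq_len(nrow(protocol))) {
      task <- as.list(protocol[i, ])
      samp <- generate_task_samples(spec, task, amp_scale, freq_jitter)
      markers[[i]] <- tibble::tibble(
        task_id = as.integer(task$task_id),
        start_sample = cursor,
        end_sample = cursor + samp$n
      )
      pieces[[length(pieces) + 1L]] <- samp
      cursor <- cursor + samp$n
      if (i < nrow(protocol) && spec$gap_duration > 0) {
        gap <- generate_task_samples(spec, gap_task, amp_scale, freq_jitter)
        pieces[[length(pieces) + 1L]] <- gap
        cursor <- cursor + gap$n
      }
    }
    signal <- tibble::tibble(
      sample_index = seq_len(cursor) - 1L,
      ch_ulnaris_mV = unlist(lapply(pieces, `[[`, "ulnaris"), use.names = FALSE),
      ch_radialis_mV = unlist(lapply(pieces, `[[`, "radialis"), use.names = FALSE)
    )
    structure(
      list(
        subject_id = subject_id,
        sampling_rate = spec$sampling_rate,
        signal = signal,
        markers = dplyr::bind_rows(markers),
        meta = list(
          amp_scale = amp_scale, freq_jitter = freq_jitter,
          seed = as.integer(seed)
        )
      ),
      class = "emg_recording"
    )
  })
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(
    "<emg_recording> subject ", x$subject_id, ": ",
    nrow(x$signal), " samples @ ", x$sampling_rate, " Hz, ",
    nrow(x$markers), " task markers\n",
    sep = ""
  )
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' Calls [generate_subject()] once per subject with a per-subject seed
#' derived deterministically from the cohort seed as `spec$seed + i` for
#' subject index `i`, so adding subjects never perturbs existing ones.
#'
#' @param spec A [cohort_spec()].
#' @return A list of `emg_recording` objects, named by subject id.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  ids <- sprintf("S%02d", seq_len(spec$n_subjects))
  recordings <- purrr::map(seq_len(spec$n_subjects), function(i) {
    generate_subject(spec, ids[i], spec$seed + i)
  })
  stats::setNames(recordings, ids)
}
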