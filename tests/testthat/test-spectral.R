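test_that("amplitude spectrum follows the sinusoid scaling convention", {
  fs <- 1024
  n <- 2048 # 5 Hz sits exactly on a bin (resolution 0.5 Hz)
  t <- (0:(n - 1)) / fs
  sp <- amplitude_spectrum(sin(2 * pi * 5 * t), fs)
  peak <- which.max(sp$amplitude)
  expect_equal(sp$frequency[peak], 5)
  expect_equal(sp$amplitude[peak], 1.0, tolerance = 1e-9)
  expect_lt(max(sp$amplitude[-peak]), 1e-9)
  # constant maps to the DC bin only
  spc <- amplitude_spectrum(rep(2.5, 512), fs)
  expect_equal(spc$amplitude[1], 2.5)
  expect_lt(max(spc$amplitude[-1]), 1e-9)
  expect_error(amplitude_spectrum(numeric(0), fs), "empty")
})

test_that("spectrum energy matches time-domain energy (Parseval)", {
  withr::with_seed(4, x <- stats::rnorm(4097)) # odd length: no Nyquist bin
  sp <- amplitude_spectrum(x, 2048)
  n <- length(x)
  freq_energy <- n * (sp$amplitude[1]^2 + sum((sp$amplitude[-1] / 2)^2) * 2)
  expect_equal(freq_energy, sum(x^2), tolerance = 1e-6)
})

test_that("the STFT window spec adapts to task duration", {
  # 180 s at 2048 Hz: resolution target reached at nperseg 8192
  long <- resolve_stft_spec(180, 2048)
  expect_equal(long$nperseg, 8192L)
  expect_equal(long$gaussian_sd, 8192 / 6)
  expect_equal(long$overlap_fraction, 0.5)
  # 1 s at 2048 Hz: capped at the segment length
  expect_equal(resolve_stft_spec(1, 2048)$nperseg, 2048L)
  # monotone in duration
  durs <- c(0.5, 1, 2, 5, 10, 30, 60, 180, 240)
  nps <- purrr::map_int(durs, ~ resolve_stft_spec(.x, 2048)$nperseg)
  expect_true(all(diff(nps) >= 0))
  expect_error(resolve_stft_spec(0, 2048), "positive")
})

test_that("spectrogram frames locate stationary and swept tones", {
  fs <- 256
  t <- (0:(fs * 20 - 1)) / fs
  sg <- compute_stft(sin(2 * pi * 5 * t), fs)
  peaks <- sg$frequencies[apply(sg$magnitudes, 2, which.max)]
  expect_true(all(abs(peaks - 5) <= fs / sg$spec$nperseg / 2))
  # silence stays numerically silent
  sg0 <- compute_stft(numeric(fs * 20), fs)
  expect_lt(max(sg0$magnitudes), 1e-12)
  # a 3 -> 9 Hz chirp has non-decreasing frame argmax
  f0 <- 3
  k <- (9 - 3) / 20
  chirp <- sin(2 * pi * (f0 * t + k / 2 * t^2))
  sgc <- compute_stft(chirp, fs)
  keep <- sgc$frequencies <= 14
  argmax <- sgc$frequencies[keep][apply(sgc$magnitudes[keep, ], 2, which.max)]
  expect_true(all(diff(argmax) >= 0))
  # instantaneous-frequency oracle: argmax tracks f0 + k t at frame centres
  inst <- f0 + k * sgc$times
  expect_lt(max(abs(argmax - inst)), 1.0)
  expect_error(
    compute_stft(numeric(100), fs, resolve_stft_spec(20, fs)),
    "exceeds"
  )
})

test_that("spectrogram magnitudes are shift-invariant and scale linearly", {
  fs <- 256
  t <- (0:(fs * 24 - 1)) / fs
  x <- sin(2 * pi * 5 * t) + 0.3 * sin(2 * pi * 9 * t)
  spec <- resolve_stft_spec(8, fs)
  hop <- spec$nperseg / 2
  sg1 <- compute_stft(x[1:(fs * 16)], fs, spec)
  sg2 <- compute_stft(x[(hop + 1):(hop + fs * 16)], fs, spec)
  # stationary input: frames shifted by one hop coincide
  expect_equal(
    sg1$magnitudes[, -1],
    sg2$magnitudes[, -ncol(sg2$magnitudes)],
    tolerance = 1e-9
  )
  sg_double <- compute_stft(2 * x[1:(fs * 16)], fs, spec)
  expect_equal(sg_double$magnitudes, 2 * sg1$magnitudes, tolerance = 1e-12)
})

test_that("frame observations keep confident non-DC peaks below 14 Hz", {
  fs <- 256
  t <- (0:(fs * 16 - 1)) / fs
  sg <- compute_stft(sin(2 * pi * 5 * t), fs)
  obs <- extract_frame_observations(sg)
  expect_equal(nrow(obs), length(sg$times))
  expect_true(all(abs(obs$dominant_frequency - 5) <= fs / sg$spec$nperseg))
  expect_true(all(obs$dominant_frequency > 0 & obs$dominant_frequency <= 14))
  # flat spectra carry no confident rhythm: dropped
  sg_flat <- sg
  sg_flat$magnitudes[] <- 1
  expect_equal(nrow(extract_frame_observations(sg_flat)), 0)
  # silence is dropped too
  sg0 <- compute_stft(numeric(fs * 16), fs)
  expect_equal(nrow(extract_frame_observations(sg0)), 0)
})

test_that("the pipeline recovers injected task-3 rhythm in most frames", {
  hits <- purrr::map_lgl(1:20, function(s) {
    spec <- cohort_spec(
      n_subjects = 1, protocol = tremor_only_protocol(),
      seed = 100 + s
    )
    rec <- generate_subject(spec, "S01", 100 + s)
    segs <- preprocess_recording(rec)
    obs <- frame_observations(segs)
    obs3 <- obs[obs$task_id == 3, ]
    nrow(obs3) > 0 &&
      mean(obs3$dominant_frequency >= 3.5 & obs3$dominant_frequency < 6) >= 0.8
  })
  expect_gte(mean(hits), 0.9)
})
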