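test_that("segmentation copies half-open marker intervals and drops gaps", {
  spec <- cohort_spec(n_subjects = 1, protocol = tiny_protocol(), seed = 6)
  rec <- generate_subject(spec, "S01", 6)
  segs <- segment_by_task(rec)
  expect_equal(segs$task_id, 0:8)
  expect_equal(sum(segs$n_samples), sum(rec$markers$end_sample - rec$markers$start_sample))
  expect_lt(sum(segs$n_samples), nrow(rec$signal))
  # half-open arithmetic: marker (3, 1000, 3048) -> 2048 samples = 1 s
  rec2 <- rec
  rec2$markers <- tibble::tibble(
    task_id = 3L, start_sample = 1000, end_sample = 3048
  )
  one <- segment_by_task(rec2)
  expect_equal(one$n_samples, 2048)
  expect_equal(
    one$data[[1]]$ch_ulnaris,
    rec$signal$ch_ulnaris_mV[1001:3048]
  )
  # overlapping markers are a protocol error
  rec2$markers <- tibble::tibble(
    task_id = c(1L, 2L), start_sample = c(0, 500), end_sample = c(1000, 1500)
  )
  expect_error(segment_by_task(rec2), "overlap")
})

test_that("baseline trimming keeps the central window with symmetric excess", {
  fs <- 2048
  x <- seq_len(240 * fs) # values encode positions
  segs <- make_segments(x, fs = fs, task_id = 0L)
  out <- trim_baseline(segs)
  expect_equal(out$n_samples, 180 * fs)
  # 30 s removed from each end
  expect_equal(out$data[[1]]$ch_ulnaris[1], 30 * fs + 1)
  expect_equal(dplyr::last(out$data[[1]]$ch_ulnaris), 210 * fs)
  expect_true(out$trimmed)

  # already at target: unchanged with a warning
  at_target <- make_segments(seq_len(180 * fs), fs = fs, task_id = 8L)
  expect_warning(unchanged <- trim_baseline(at_target), "unchanged")
  expect_equal(unchanged$n_samples, 180 * fs)
  expect_equal(unchanged$data[[1]]$ch_ulnaris, seq_len(180 * fs))

  # odd excess: the extra sample comes off the head
  odd <- make_segments(seq_len(180 * fs + 2049), fs = fs, task_id = 0L)
  out_odd <- trim_baseline(odd)
  expect_equal(out_odd$data[[1]]$ch_ulnaris[1], 1026)
  expect_equal(dplyr::last(out_odd$data[[1]]$ch_ulnaris), 1025 + 180 * fs)

  # non-baseline tasks are a contract error
  expect_error(trim_baseline(make_segments(x, task_id = 3L)), "baseline")
})

test_that("MVC estimation matches constants, sinusoids and the sliding oracle", {
  fs <- 1000
  # constant 2 mV -> RMS 2
  const <- make_segments(rep(2, 2000), fs = fs, task_id = 4L)
  mvc <- compute_mvc(const, window = 0.1)
  expect_equal(mvc$mvc_value, c(2, 2))
  # sinusoid amplitude a, window >> period -> a/sqrt(2)
  t <- seq_len(5000) / fs
  sine <- make_segments(3 * sin(2 * pi * 100 * t), fs = fs, task_id = 4L)
  mvc_sine <- compute_mvc(sine, window = 0.5)
  expect_equal(mvc_sine$mvc_value[1], 3 / sqrt(2), tolerance = 1e-3)
  # burst signal: equals the O(n w) brute-force window maximum
  withr::with_seed(8, {
    burst <- stats::rnorm(3000) * rep(c(0.2, 1, 0.4), each = 1000)
  })
  segs <- make_segments(burst, fs = fs, task_id = 4L)
  got <- compute_mvc(segs, window = 0.05)$mvc_value[1]
  expect_equal(got, oracle_max_moving_rms(burst, 50), tolerance = 1e-12)
  # degenerate all-zero channel
  expect_error(
    compute_mvc(make_segments(rep(0, 1000), task_id = 4L)),
    "degenerate"
  )
})

test_that("MVC normalisation rescales channels and is equivariant", {
  withr::with_seed(5, {
    x <- stats::rnorm(4000)
    y <- stats::rnorm(4000) * 2
  })
  segs <- dplyr::bind_rows(
    make_segments(x, task_id = 4L, y = y),
    make_segments(x * 0.3, task_id = 1L, y = y * 0.2)
  )
  mvc <- compute_mvc(segs)
  norm <- normalize_mvc(segs, mvc)
  expect_true(all(norm$normalized))
  expect_equal(norm$units, rep("mvc_fraction", 2))
  # a sample equal to the MVC value maps to 1.0
  i <- which.max(abs(x))
  expect_equal(
    norm$data[[1]]$ch_ulnaris[i],
    x[i] / mvc$mvc_value[mvc$channel == "ch_ulnaris"]
  )
  # task-4 self-normalisation: max moving-RMS of |signal| is exactly 1
  task4 <- norm$data[[which(norm$task_id == 4L)]]
  expect_equal(
    max(tremorband:::moving_rms(abs(task4$ch_ulnaris), round(0.1 * 2048))),
    1.0,
    tolerance = 1e-12
  )
  # scaling the raw recording by c > 0 leaves normalised output unchanged
  scaled <- segs
  scaled$data <- purrr::map(scaled$data, ~ dplyr::mutate(
    .x,
    ch_ulnaris = ch_ulnaris * 7.3, ch_radialis = ch_radialis * 7.3
  ))
  norm_scaled <- normalize_mvc(scaled, compute_mvc(scaled))
  expect_equal(norm_scaled$data[[2]]$ch_ulnaris, norm$data[[2]]$ch_ulnaris,
    tolerance = 1e-12
  )
  # double normalisation and missing subjects are contract errors
  expect_error(normalize_mvc(norm, mvc), "already")
  mvc_other <- dplyr::mutate(mvc, subject_id = "ZZ")
  expect_error(normalize_mvc(segs, mvc_other), "missing for subject")
})

test_that("rectification is the idempotent sample-wise absolute value", {
  segs <- make_segments(c(-1, 2, -3), normalized = TRUE)
  rect <- rectify(segs)
  expect_equal(rect$data[[1]]$ch_ulnaris, c(1, 2, 3))
  expect_true(rect$rectified)
  again <- rectify(rect)
  expect_equal(again$data[[1]], rect$data[[1]])
  nonneg <- make_segments(c(0, 1, 2))
  expect_equal(rectify(nonneg)$data[[1]]$ch_ulnaris, c(0, 1, 2))
})

test_that("the pre-processing chain enforces its stage order", {
  x <- seq_len(240 * 2048)
  segs <- make_segments(x, task_id = 0L, normalized = TRUE)
  expect_error(trim_baseline(segs), "before")
  filtered <- make_segments(stats::rnorm(5000), filtered = TRUE)
  expect_error(rectify(filtered), "precede")
  unnorm <- make_segments(stats::rnorm(5000))
  expect_error(combine_channels(unnorm), "normalized")
})

test_that("full pre-processing leaves monotone flags and a combined trace", {
  spec <- cohort_spec(n_subjects = 1, protocol = tiny_protocol(), seed = 2)
  rec <- generate_subject(spec, "S01", 2)
  segs <- suppressWarnings(preprocess_recording(rec))
  expect_true(all(segs$normalized & segs$rectified & segs$filtered))
  expect_true(all(segs$trimmed[segs$task_id %in% c(0, 8)]))
  expect_true(all(purrr::map_lgl(segs$data, ~ "ch_combined" %in% names(.x))))
  expect_equal(segs$units, rep("mvc_fraction", 9))
})
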