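# Shared fixtures and independent oracles used across the test files.

# Reduced protocols keep the generator fast where full 4-minute baselines
# are not the point of the test.
tiny_protocol <- function() {
  proto <- build_default_protocol()
  proto$duration[proto$task_id %in% c(0L, 8L)] <- 20
  proto
}

# Just the MVC source and the tremor task: the minimal protocol on which
# the full pre-processing + spectral chain runs.
tremor_only_protocol <- function() {
  proto <- build_default_protocol()
  proto[proto$task_id %in% c(3L, 4L), ]
}

# A one-row processed-state segment table built directly from samples,
# bypassing the generator.
make_segments <- function(x, fs = 2048, task_id = 1L, subject_id = "T01",
                          normalized = FALSE, rectified = FALSE,
                          filtered = FALSE, y = x) {
  tibble::tibble(
    subject_id = subject_id,
    task_id = as.integer(task_id),
    sampling_rate = fs,
    n_samples = length(x),
    data = list(tibble::tibble(ch_ulnaris = x, ch_radialis = y)),
    units = if (normalized) "mvc_fraction" else "mV",
    trimmed = FALSE,
    normalized = normalized,
    rectified = rectified,
    filtered = filtered
  )
}

# --- independent oracles -------------------------------------------------

# O(n * w) sliding-window RMS maximum of the rectified signal.
oracle_max_moving_rms <- function(x, w) {
  x <- abs(x)
  best <- -Inf
  for (i in seq_len(length(x) - w + 1)) {
    best <- max(best, sqrt(mean(x[i:(i + w - 1)]^2)))
  }
  best
}

# Kruskal-Wallis H from the explicit mean-rank formula (tie-corrected).
oracle_kw_h <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  groups <- factor(groups)
  h <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(ri) length(ri) * mean(ri)^2)) -
    3 * (N + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Lilliefors KS distance: sup |ECDF - Phi_hat| computed point by point
# against the normal fitted by moments.
oracle_ks_d <- function(x) {
  x <- sort(x)
  n <- length(x)
  p <- pnorm((x - mean(x)) / sd(x))
  max(seq_len(n) / n - p, p - (seq_len(n) - 1) / n)
}

# Dunn pairwise columns from first principles on a pooled rank table.
oracle_dunn <- function(values, groups, gi, gj) {
  r <- rank(values)
  groups <- factor(groups)
  N <- length(values)
  ties <- table(values)
  var_core <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  mr <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  stat <- mr[[gi]] - mr[[gj]]
  se <- sqrt(var_core * (1 / ns[[gi]] + 1 / ns[[gj]]))
  k <- nlevels(groups)
  list(
    stat = stat, se = se, z = stat / se,
    sig = 2 * pnorm(-abs(stat / se)),
    adj = min(1, 2 * pnorm(-abs(stat / se)) * k * (k - 1) / 2)
  )
}

# Dominant frequency of a signal by plain periodogram argmax over
# (0, fmax], independent of the package's STFT path.
oracle_dominant_frequency <- function(x, fs, fmax = 14) {
  n <- length(x)
  x <- x - mean(x)
  a <- Mod(stats::fft(x))[seq_len(floor(n / 2) + 1)]
  f <- (seq_along(a) - 1) * fs / n
  keep <- f > 0 & f <= fmax
  f[keep][which.max(a[keep])]
}
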