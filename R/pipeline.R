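#' Build a pipeline run configuration
#'
#' Collects every knob of the end-to-end analysis -- cohort simulation (or
#' an input directory of recorded CSV/JSON pairs), pre-processing, STFT,
#' observation extraction and statistics -- into one object that
#' round-trips losslessly through JSON ([write_run_config()] /
#' [read_run_config()]). All randomness flows from the single `seed`.
#'
#' @param n_subjects Cohort size to simulate (ignored when `input_dir` is
#'   given).
#' @param seed Integer master seed.
#' @param protocol Task protocol tibble.
#' @param sampling_rate,subject_amp_sd,tremor_freq_jitter_sd,mains_hum_level,noise_level,gap_duration
#'   Cohort simulation parameters, see [cohort_spec()].
#' @param input_dir Optional directory of existing recordings to analyse
#'   instead of simulating.
#' @param target_baseline Baseline trim target (s).
#' @param do_rectify Rectify before filtering (default TRUE).
#' @param filter_cutoff,filter_order Low-pass design.
#' @param target_resolution STFT target resolution (Hz).
#' @param noise_floor_multiplier Frame peak gate.
#' @param fmax Analysis ceiling (Hz).
#' @param stats_unit `"frame"` or `"subject"` analysis unit.
#' @param alpha Reporting significance level.
#' @param output_dir Where [run_pipeline()] writes its tables and manifest.
#' @param persist_raw Also write the (large) per-subject raw recording
#'   CSVs into `output_dir/recordings`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(n_subjects = 6, seed = 1L,
                       protocol = build_default_protocol(),
                       sampling_rate = 2048,
                       subject_amp_sd = 0.25, tremor_freq_jitter_sd = 0.3,
                       mains_hum_level = 0.02, noise_level = 0.10,
                       gap_duration = 2,
                       input_dir = NULL,
                       target_baseline = 180, do_rectify = TRUE,
                       filter_cutoff = 14, filter_order = 10,
                       target_resolution = 0.25, noise_floor_multiplier = 3,
                       fmax = 14,
                       stats_unit = "frame", alpha = 0.05,
                       output_dir = tempfile("tremorband_run_"),
                       persist_raw = FALSE) {
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    stop("input_dir does not exist: ", input_dir, call. = FALSE)
  }
  cfg <- list(
    n_subjects = as.integer(n_subjects), seed = as.integer(seed),
    protocol = protocol, sampling_rate = sampling_rate,
    subject_amp_sd = subject_amp_sd,
    tremor_freq_jitter_sd = tremor_freq_jitter_sd,
    mains_hum_level = mains_hum_level, noise_level = noise_level,
    gap_duration = gap_duration,
    input_dir = input_dir,
    target_baseline = target_baseline, do_rectify = do_rectify,
    filter_cutoff = filter_cutoff, filter_order = filter_order,
    target_resolution = target_resolution,
    noise_floor_multiplier = noise_floor_multiplier, fmax = fmax,
    stats_unit = stats_unit, alpha = alpha,
    output_dir = output_dir, persist_raw = persist_raw
  )
  structure(cfg, class = "run_config")
}

#' Write / read a run configuration as JSON
#'
#' @param config A `run_config`.
#' @param path JSON file path.
#' @return `write_run_config` returns the path invisibly;
#'   `read_run_config` the restored `run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path,
    auto_unbox = TRUE, digits = NA, null = "null", na = "null"
  )
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$protocol <- tibble::as_tibble(raw$protocol)
  raw$n_subjects <- as.integer(raw$n_subjects)
  raw$seed <- as.integer(raw$seed)
  structure(raw, class = "run_config")
}

config_cohort_spec <- function(config) {
  cohort_spec(
    n_subjects = config$n_subjects, protocol = config$protocol,
    sampling_rate = config$sampling_rate,
    subject_amp_sd = config$subject_amp_sd,
    tremor_freq_jitter_sd = config$tremor_freq_jitter_sd,
    mains_hum_level = config$mains_hum_level,
    noise_level = config$noise_level,
    gap_duration = config$gap_duration,
    seed = config$seed
  )
}

with_stage <- function(stage, context, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed (", context, "): ",
      conditionMessage(e),
      call. = FALSE
    )
  })
}

#' Run the full tremor-profiling pipeline
#'
#' simulate (or ingest) -> preprocess -> spectral observation extraction ->
#' band table -> statistical battery -> persisted tables + manifest.
#' Recordings are processed one at a time and discarded, so memory stays
#' flat in the cohort size. Every output CSV is listed in the manifest with
#' its MD5 checksum; reruns with the same configuration reproduce the data
#' files bit-identically.
#'
#' @param config A [run_config()].
#' @return Invisibly, the `run_manifest` (also written to
#'   `output_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$output_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  if (is.null(config$input_dir)) {
    spec <- config_cohort_spec(config)
    ids <- sprintf("S%02d", seq_len(spec$n_subjects))
    get_recording <- function(i) {
      with_stage(
        "simulate", ids[i],
        generate_subject(spec, ids[i], spec$seed + i)
      )
    }
    n_rec <- spec$n_subjects
  } else {
    csvs <- sort(list.files(config$input_dir, "\\.csv$", full.names = TRUE))
    if (length(csvs) == 0) {
      stop("pipeline stage 'ingest' failed: no recordings in ",
        config$input_dir,
        call. = FALSE
      )
    }
    get_recording <- function(i) with_stage("ingest", csvs[i], read_recording(csvs[i]))
    n_rec <- length(csvs)
  }
  obs_list <- vector("list", n_rec)
  n_segments <- 0L
  for (i in seq_len(n_rec)) {
    rec <- get_recording(i)
    if (isTRUE(config$persist_raw)) {
      write_recording(rec, file.path(out, "recordings"))
    }
    segments <- with_stage(
      "preprocess", rec$subject_id,
      preprocess_recording(
        rec,
        target_baseline = config$target_baseline,
        do_rectify = config$do_rectify,
        cutoff = config$filter_cutoff, order = config$filter_order
      )
    )
    n_segments <- n_segments + nrow(segments)
    obs_list[[i]] <- with_stage(
      "spectral", rec$subject_id,
      frame_observations(
        segments,
        target_resolution = config$target_resolution,
        noise_floor_multiplier = config$noise_floor_multiplier,
        fmax = config$fmax
      )
    )
  }
  observations <- dplyr::bind_rows(obs_list)
  band_table <- with_stage("bands", "cohort", build_band_table(observations))
  battery <- with_stage(
    "stats", "cohort",
    run_statistical_battery(band_table,
      unit = config$stats_unit, alpha = config$alpha
    )
  )
  files <- c(
    observations = "observations.csv",
    band_table = "band_table.csv",
    normality = "normality.csv",
    omnibus = "omnibus.csv",
    pairwise = "pairwise.csv",
    pairwise_frequency_spss = "pairwise_frequency_spss.csv",
    pairwise_magnitude_spss = "pairwise_magnitude_spss.csv"
  )
  readr::write_csv(observations, file.path(out, files["observations"]))
  readr::write_csv(band_table, file.path(out, files["band_table"]))
  readr::write_csv(battery$normality, file.path(out, files["normality"]))
  readr::write_csv(battery$omnibus, file.path(out, files["omnibus"]))
  readr::write_csv(battery$pairwise, file.path(out, files["pairwise"]))
  readr::write_csv(
    spss_pairwise_table(battery, "frequency"),
    file.path(out, files["pairwise_frequency_spss"])
  )
  readr::write_csv(
    spss_pairwise_table(battery, "magnitude"),
    file.path(out, files["pairwise_magnitude_spss"])
  )
  write_run_config(config, file.path(out, "config.json"))
  paths <- file.path(out, files)
  manifest <- structure(
    list(
      config = unclass(config),
      package_version = as.character(utils::packageVersion("tremorband")),
      band_definitions = band_definitions(),
      counts = list(
        n_recordings = n_rec,
        n_segments = n_segments,
        n_observations = nrow(observations),
        n_band_rows = nrow(band_table),
        n_omnibus_tests = nrow(battery$omnibus),
        n_pairwise_rows = nrow(battery$pairwise)
      ),
      outputs = tibble::tibble(
        name = names(files),
        file = unname(files),
        md5 = unname(tools::md5sum(paths))
      ),
      timestamp = format(Sys.time(), tz = "UTC")
    ),
    class = "run_manifest"
  )
  jsonlite::write_json(unclass(manifest), file.path(out, "manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null", na = "null"
  )
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> ", x$counts$n_recordings, " recordings, ",
    x$counts$n_segments, " segments, ", x$counts$n_observations,
    " observations -> ", nrow(x$outputs), " output files\n",
    sep = ""
  )
  invisible(x)
}

#' Render figures and a summary report for a completed run
#'
#' Reads the persisted tables of a pipeline run and writes, per requested
#' band, a frequency/magnitude profile figure (PNG), plus a Markdown
#' summary embedding the two SPSS-dialect pairwise tables. Optionally
#' regenerates the cohort from the run configuration to render per
#' subject/task spectrogram images (0--14 Hz).
#'
#' @param run_dir Output directory of a completed [run_pipeline()] call
#'   (or a `run_manifest`, whose configured output directory is used).
#' @param bands Bands to plot (default all five).
#' @param spectrograms Render per subject/task spectrogram PNGs
#'   (regenerates the cohort; only available for simulated runs).
#' @return Invisibly, a character vector of files written under
#'   `run_dir/report`.
#' @export
render_reports <- function(run_dir, bands = band_definitions()$band,
                           spectrograms = FALSE) {
  if (inherits(run_dir, "run_manifest")) run_dir <- run_dir$config$output_dir
  band_path <- file.path(run_dir, "band_table.csv")
  if (!file.exists(band_path)) {
    stop("missing intermediate '", band_path,
      "': rerun run_pipeline() on this configuration first",
      call. = FALSE
    )
  }
  band_table <- readr::read_csv(band_path, show_col_types = FALSE)
  report_dir <- file.path(run_dir, "report")
  if (!dir.exists(report_dir)) dir.create(report_dir, recursive = TRUE)
  written <- character()
  for (b in intersect(bands, unique(band_table$band))) {
    fig <- plot_band_profile(band_table, band = b)
    path <- file.path(report_dir, paste0("band_", b, ".png"))
    ggplot2::ggsave(path, fig, width = 7, height = 4, dpi = 120)
    written <- c(written, path)
  }
  if (isTRUE(spectrograms)) {
    config <- read_run_config(file.path(run_dir, "config.json"))
    if (!is.null(config$input_dir)) {
      stop("spectrogram rendering requires a simulated run", call. = FALSE)
    }
    spec <- config_cohort_spec(config)
    for (i in seq_len(spec$n_subjects)) {
      sid <- sprintf("S%02d", i)
      rec <- generate_subject(spec, sid, spec$seed + i)
      segments <- preprocess_recording(rec,
        target_baseline = config$target_baseline,
        do_rectify = config$do_rectify,
        cutoff = config$filter_cutoff, order = config$filter_order
      )
      for (j in seq_len(nrow(segments))) {
        seg <- segments$data[[j]]
        fs <- segments$sampling_rate[j]
        sg <- compute_stft(seg$ch_combined, fs)
        path <- file.path(
          report_dir,
          sprintf("stft_%s_task%d.png", sid, segments$task_id[j])
        )
        ggplot2::ggsave(path, ggplot2::autoplot(sg),
          width = 6, height = 4, dpi = 120
        )
        written <- c(written, path)
      }
    }
  }
  md <- file.path(report_dir, "summary.md")
  lines <- c(
    "# Tremor band profiling run summary", "",
    paste0("Band observation rows: ", nrow(band_table)), ""
  )
  for (m in c("frequency", "magnitude")) {
    spss_path <- file.path(run_dir, paste0("pairwise_", m, "_spss.csv"))
    if (file.exists(spss_path)) {
      tab <- readr::read_csv(spss_path, show_col_types = FALSE)
      lines <- c(
        lines, paste0("## Pairwise comparisons (", m, ")"), "",
        knit_md_table(tab), ""
      )
    }
  }
  writeLines(lines, md)
  written <- c(written, md)
  invisible(written)
}

# Minimal pipe-table renderer (no knitr dependency).
knit_md_table <- function(df) {
  fmt <- function(v) {
    if (is.numeric(v)) signif(v, 4) else as.character(v)
  }
  cells <- purrr::map(df, fmt)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- purrr::map_chr(seq_len(nrow(df)), function(i) {
    paste0("| ", paste(purrr::map_chr(cells, ~ as.character(.x[i])),
      collapse = " | "
    ), " |")
  })
  c(header, sep, rows)
}
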