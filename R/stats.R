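#' Lilliefors-corrected Kolmogorov--Smirnov normality test
#'
#' One-sample KS distance of the empirical distribution from a normal with
#' mean and standard deviation estimated from the sample, with the
#' Lilliefors p-value approximation that accounts for the estimated
#' parameters (via [nortest::lillie.test()]).
#'
#' @param values Numeric sample, n >= 5, non-degenerate.
#' @return A one-row tibble: `test`, `statistic` (D), `p_value`, `n`.
#' @export
ks_normality <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 5) {
    stop("ks_normality requires at least 5 observations", call. = FALSE)
  }
  if (stats::sd(values) == 0) {
    stop("degenerate sample: zero variance", call. = FALSE)
  }
  fit <- nortest::lillie.test(values)
  tibble::tibble(
    test = "ks_lilliefors",
    statistic = unname(fit$statistic),
    p_value = unname(fit$p.value),
    n = length(values)
  )
}

#' Kruskal--Wallis omnibus test with epsilon-squared effect size
#'
#' Tie-corrected H statistic against the chi-square reference with k - 1
#' degrees of freedom (via [stats::kruskal.test()]), with the
#' epsilon-squared effect size `H (N + 1) / (N^2 - 1)` attached. A fully
#' degenerate input (all values identical) returns H = 0, p = 1.
#'
#' @param values Numeric observations.
#' @param groups Group labels, one per observation; at least 2 groups and
#'   3 observations in total.
#' @return A one-row tibble: `test`, `statistic` (H), `df`, `p_value`,
#'   `epsilon_squared`, `n`.
#' @export
kruskal_wallis <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  if (nlevels(groups) < 2) {
    stop("kruskal_wallis requires at least 2 groups", call. = FALSE)
  }
  if (length(values) < 3) {
    stop("kruskal_wallis requires at least 3 observations", call. = FALSE)
  }
  if (length(unique(values)) == 1) {
    H <- 0
    p <- 1
    df <- nlevels(groups) - 1
  } else {
    fit <- stats::kruskal.test(values, groups)
    H <- unname(fit$statistic)
    p <- fit$p.value
    df <- unname(fit$parameter)
  }
  N <- length(values)
  tibble::tibble(
    test = "kruskal_wallis",
    statistic = H,
    df = df,
    p_value = p,
    epsilon_squared = epsilon_squared(H, N),
    n = N
  )
}

#' Epsilon-squared effect size for the Kruskal--Wallis H statistic
#'
#' `epsilon^2 = H (N + 1) / (N^2 - 1)`, ranging from 0 (no separation) to
#' 1 (H at its maximum N - 1, attained when every observation is its own
#' fully ordered group).
#'
#' @param H Kruskal--Wallis H statistic.
#' @param N Total number of observations (>= 2).
#' @return The effect size.
#' @export
epsilon_squared <- function(H, N) {
  if (N < 2) stop("epsilon_squared requires N >= 2", call. = FALSE)
  H * (N + 1) / (N^2 - 1)
}

#' Dunn's pairwise comparisons after Kruskal--Wallis
#'
#' For every unordered group pair (i, j): the test statistic is the
#' difference of pooled mean ranks, the standard error is
#' `sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))` with tie term
#' `T = sum(t^3 - t)` over tied value groups, the standardised statistic
#' is their ratio, `sig` the two-sided normal p-value and `adj_sig` the
#' Bonferroni-adjusted p (multiplied by the number of pairs, capped at 1).
#' These are the columns of SPSS's pairwise-comparison output.
#'
#' @param values Numeric observations.
#' @param groups Group labels (at least 2 groups).
#' @return A tibble with one row per pair: `group_i`, `group_j`,
#'   `test_statistic`, `std_error`, `std_test_statistic`, `sig`, `adj_sig`.
#' @export
dunn_pairwise <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  k <- nlevels(groups)
  if (k < 2) {
    stop("dunn_pairwise requires at least 2 groups", call. = FALSE)
  }
  N <- length(values)
  r <- rank(values)
  mean_ranks <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties)
  var_core <- N * (N + 1) / 12 - tie_term / (12 * (N - 1))
  pairs <- utils::combn(levels(groups), 2)
  n_pairs <- ncol(pairs)
  purrr::map_dfr(seq_len(n_pairs), function(p) {
    gi <- pairs[1, p]
    gj <- pairs[2, p]
    stat <- unname(mean_ranks[gi] - mean_ranks[gj])
    se <- sqrt(var_core * (1 / ns[[gi]] + 1 / ns[[gj]]))
    z <- if (se > 0) stat / se else 0
    sig <- 2 * stats::pnorm(-abs(z))
    tibble::tibble(
      group_i = gi, group_j = gj,
      test_statistic = stat,
      std_error = se,
      std_test_statistic = z,
      sig = sig,
      adj_sig = min(1, sig * n_pairs)
    )
  })
}

#' Run the full nonparametric statistical battery on a band table
#'
#' For each analysed band (rest, action, postural by default) and each
#' measure (frequency, magnitude): a Lilliefors KS normality test per
#' task, the Kruskal--Wallis omnibus test across tasks with epsilon-squared
#' effect size, and Dunn's pairwise comparisons with Bonferroni adjustment.
#' Bands with fewer than two tasks represented are skipped with a warning.
#'
#' Two analysis units are supported: `"frame"` pools all retained STFT
#' frames across subjects (the table-level analysis the comparison tables
#' use), while `"subject"` first collapses to the per-subject median per
#' task/band/measure, giving exchangeable units for calibration-sensitive
#' inference.
#'
#' @param band_table Band observation table from [build_band_table()].
#' @param bands Bands to analyse.
#' @param measures Measures to analyse (`"frequency"`, `"magnitude"`).
#' @param unit `"frame"` (default) or `"subject"`.
#' @param alpha Reporting significance level.
#' @return An object of class `tremor_battery`: list of tibbles
#'   `normality`, `omnibus`, `pairwise` plus the settings. [tidy()] returns
#'   the pairwise table, [glance()] the omnibus table.
#' @export
run_statistical_battery <- function(band_table,
                                    bands = c("rest", "action", "postural"),
                                    measures = c("frequency", "magnitude"),
                                    unit = c("frame", "subject"),
                                    alpha = 0.05) {
  unit <- match.arg(unit)
  data <- dplyr::filter(band_table, .data$band %in% bands)
  if (unit == "subject") {
    data <- data |>
      dplyr::group_by(.data$subject_id, .data$task_id, .data$band) |>
      dplyr::summarise(
        frequency = stats::median(.data$frequency),
        magnitude = stats::median(.data$magnitude),
        .groups = "drop"
      )
  }
  normality <- list()
  omnibus <- list()
  pairwise <- list()
  for (b in bands) {
    sub <- dplyr::filter(data, .data$band == b)
    if (dplyr::n_distinct(sub$task_id) < 2) {
      warning("band '", b, "' has fewer than 2 tasks represented; skipped",
        call. = FALSE
      )
      next
    }
    for (m in measures) {
      vals <- sub[[m]]
      grps <- sub$task_id
      ks <- sub |>
        dplyr::group_by(.data$task_id) |>
        dplyr::group_map(function(g, key) {
          res <- tryCatch(ks_normality(g[[m]]), error = function(e) NULL)
          if (is.null(res)) {
            return(NULL)
          }
          dplyr::bind_cols(
            tibble::tibble(band = b, measure = m, task_id = key$task_id), res
          )
        }) |>
        dplyr::bind_rows()
      normality[[length(normality) + 1]] <- ks
      kw <- kruskal_wallis(vals, grps)
      omnibus[[length(omnibus) + 1]] <- dplyr::bind_cols(
        tibble::tibble(band = b, measure = m), kw
      )
      dn <- dunn_pairwise(vals, grps)
      pairwise[[length(pairwise) + 1]] <- dplyr::bind_cols(
        tibble::tibble(band = b, measure = m)[rep(1, nrow(dn)), ], dn
      )
    }
  }
  empty_normality <- tibble::tibble(
    band = character(), measure = character(), task_id = integer(),
    test = character(), statistic = numeric(), p_value = numeric(),
    n = integer()
  )
  empty_omnibus <- tibble::tibble(
    band = character(), measure = character(), test = character(),
    statistic = numeric(), df = numeric(), p_value = numeric(),
    epsilon_squared = numeric(), n = integer()
  )
  empty_pairwise <- tibble::tibble(
    band = character(), measure = character(), group_i = character(),
    group_j = character(), test_statistic = numeric(), std_error = numeric(),
    std_test_statistic = numeric(), sig = numeric(), adj_sig = numeric()
  )
  structure(
    list(
      normality = dplyr::bind_rows(empty_normality, dplyr::bind_rows(normality)),
      omnibus = dplyr::bind_rows(empty_omnibus, dplyr::bind_rows(omnibus)),
      pairwise = dplyr::bind_rows(empty_pairwise, dplyr::bind_rows(pairwise)),
      unit = unit,
      alpha = alpha
    ),
    class = "tremor_battery"
  )
}

#' @export
print.tremor_battery <- function(x, ...) {
  cat(
    "<tremor_battery> unit = ", x$unit, "; ",
    nrow(x$omnibus), " omnibus tests, ",
    nrow(x$pairwise), " pairwise comparisons (alpha = ", x$alpha, ")\n",
    sep = ""
  )
  if (nrow(x$omnibus) > 0) print(x$omnibus)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the pairwise comparisons of a statistical battery
#'
#' @param x A `tremor_battery`.
#' @param ... Unused.
#' @return The pairwise comparison tibble.
#' @export
tidy.tremor_battery <- function(x, ...) x$pairwise

#' One-row-per-test overview of a statistical battery
#'
#' @param x A `tremor_battery`.
#' @param ... Unused.
#' @return The omnibus Kruskal--Wallis tibble.
#' @export
glance.tremor_battery <- function(x, ...) x$omnibus

#' Format pairwise comparisons in the SPSS table dialect
#'
#' Renders the pairwise tibble for one measure with the exact column names
#' of SPSS's pairwise-comparison output: `Group`, `Sample 1-Sample 2`,
#' `Test Statistic`, `Std. Error`, `Std. Test Statistic`, `Sig.`,
#' `Adj. Sig.`.
#'
#' @param battery A `tremor_battery`.
#' @param measure `"frequency"` or `"magnitude"`.
#' @return A tibble in the SPSS column dialect.
#' @export
spss_pairwise_table <- function(battery, measure = c("frequency", "magnitude")) {
  measure <- match.arg(measure)
  pw <- dplyr::filter(battery$pairwise, .data$measure == !!measure)
  tibble::tibble(
    "Group" = tools::toTitleCase(pw$band),
    "Sample 1-Sample 2" = paste0(pw$group_i, "-", pw$group_j),
    "Test Statistic" = pw$test_statistic,
    "Std. Error" = pw$std_error,
    "Std. Test Statistic" = pw$std_test_statistic,
    "Sig." = pw$sig,
    "Adj. Sig." = pw$adj_sig
  )
}
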