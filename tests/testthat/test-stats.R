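test_that("KS normality matches the ECDF oracle and flags non-normal data", {
  # sample laid out on the fitted normal's equiprobable quantile grid
  grid <- stats::qnorm((seq_len(100) - 0.5) / 100)
  res <- ks_normality(grid)
  expect_lte(res$statistic, 0.01)
  expect_equal(res$n, 100)
  # D equals the brute-force sup|ECDF - Phi_hat|
  withr::with_seed(31, x <- stats::rexp(60))
  expect_equal(ks_normality(x)$statistic, oracle_ks_d(x), tolerance = 1e-12)
  # heavily bimodal samples are rejected (20 seeds, >= 95%)
  rejections <- purrr::map_lgl(1:20, function(s) {
    withr::with_seed(400 + s, {
      y <- c(stats::rnorm(100, -5, 0.5), stats::rnorm(100, 5, 0.5))
    })
    ks_normality(y)$p_value < 0.05
  })
  expect_gte(mean(rejections), 0.95)
  expect_error(ks_normality(rep(1, 10)), "zero variance")
  expect_error(ks_normality(1:4), "at least 5")
})

test_that("Kruskal-Wallis H matches the explicit rank oracle", {
  # one pooled 1..9 sample split into three groups, all values distinct
  values <- 1:9
  groups <- rep(c("a", "b", "c"), 3) # a: 1,4,7  b: 2,5,8  c: 3,6,9
  res <- kruskal_wallis(values, groups)
  # hand computation: mean ranks 4, 5, 6 -> H = 12/90 * 3 * (1+0+1) = 0.8
  expect_equal(res$statistic, 0.8, tolerance = 1e-12)
  expect_equal(res$statistic, oracle_kw_h(values, groups), tolerance = 1e-12)
  expect_equal(res$df, 2)
  # rank invariance under strictly increasing maps
  res_exp <- kruskal_wallis(exp(values), groups)
  expect_equal(res_exp$statistic, res$statistic, tolerance = 1e-12)
  # degenerate: all observations equal
  flat <- kruskal_wallis(rep(2, 9), groups)
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  # tie-corrected H agrees with the oracle on tied data
  withr::with_seed(9, tied <- sample(1:4, 30, replace = TRUE))
  g <- rep(1:3, each = 10)
  expect_equal(
    kruskal_wallis(tied, g)$statistic,
    oracle_kw_h(tied, g),
    tolerance = 1e-12
  )
  expect_error(kruskal_wallis(1:5, rep("a", 5)), "2 groups")
})

test_that("epsilon squared spans [0, 1] with the H (N+1) / (N^2 - 1) formula", {
  expect_equal(epsilon_squared(0, 10), 0)
  expect_equal(epsilon_squared(5, 100), 5 * 101 / 9999)
  # maximal separation: N singleton groups give H = N - 1 and epsilon = 1
  res <- kruskal_wallis(1:20, factor(1:20))
  expect_equal(res$statistic, 19, tolerance = 1e-12)
  expect_equal(res$epsilon_squared, 1, tolerance = 1e-12)
  # fully separated k = 2 groups: epsilon matches the oracle H, below 1
  sep <- kruskal_wallis(1:20, rep(c("lo", "hi"), each = 10))
  expect_equal(
    sep$epsilon_squared,
    oracle_kw_h(1:20, rep(c("lo", "hi"), each = 10)) * 21 / 399,
    tolerance = 1e-12
  )
  expect_lt(sep$epsilon_squared, 1)
  expect_error(epsilon_squared(1, 1), "N >= 2")
})

test_that("Dunn pairwise columns match the enumeration oracle", {
  # 3 groups of 4 distinct values, interleaved
  values <- c(1, 5, 9, 12, 2, 6, 10, 11, 3, 4, 7, 8)
  groups <- rep(c("g1", "g2", "g3"), each = 4)
  res <- dunn_pairwise(values, groups)
  expect_equal(nrow(res), 3)
  for (i in seq_len(nrow(res))) {
    o <- oracle_dunn(values, groups, res$group_i[i], res$group_j[i])
    expect_equal(res$test_statistic[i], o$stat, tolerance = 1e-12)
    expect_equal(res$std_error[i], o$se, tolerance = 1e-12)
    expect_equal(res$std_test_statistic[i], o$z, tolerance = 1e-12)
    expect_equal(res$sig[i], o$sig, tolerance = 1e-12)
    expect_equal(res$adj_sig[i], o$adj, tolerance = 1e-12)
  }
  # identical groups: z = 0, sig = 1
  sym <- dunn_pairwise(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(sym$std_test_statistic, 0)
  expect_equal(sym$sig, 1)
  # antisymmetry: relabelling so the pair order flips negates the statistic
  relabelled <- dplyr::recode(groups, g1 = "z1", g3 = "a3")
  res_flip <- dunn_pairwise(values, relabelled)
  orig <- res[res$group_i == "g1" & res$group_j == "g3", ]
  flip <- res_flip[res_flip$group_i == "a3" & res_flip$group_j == "z1", ]
  expect_equal(flip$test_statistic, -orig$test_statistic, tolerance = 1e-12)
  expect_equal(flip$sig, orig$sig, tolerance = 1e-12)
  expect_error(dunn_pairwise(1:3, rep("a", 3)), "2 groups")
})

test_that("the battery is deterministic with coherent pairwise columns", {
  withr::with_seed(77, {
    bt <- tibble::tibble(
      subject_id = rep(sprintf("S%02d", 1:6), each = 20),
      task_id = rep(rep(c(0L, 3L, 6L, 8L), each = 5), 6),
      band = sample(c("rest", "action", "postural"), 120, replace = TRUE),
      frequency = stats::runif(120, 3.5, 12),
      magnitude = stats::rlnorm(120, -2, 0.5),
      analyzed = TRUE
    )
  })
  bt$frequency <- pmin(pmax(bt$frequency, c(rest = 3.5, action = 6, postural = 9)[bt$band]),
    c(rest = 5.99, action = 8.99, postural = 12)[bt$band]
  )
  b1 <- run_statistical_battery(bt)
  b2 <- run_statistical_battery(bt)
  expect_identical(b1$pairwise, b2$pairwise)
  expect_identical(b1$omnibus, b2$omnibus)
  pw <- b1$pairwise
  n_pairs <- choose(4, 2)
  expect_lt(
    max(abs(pw$std_test_statistic * pw$std_error - pw$test_statistic)),
    1e-9
  )
  expect_equal(pw$adj_sig, pmin(1, pw$sig * n_pairs), tolerance = 1e-12)
  expect_true(all(pw$adj_sig >= pw$sig))
  # battery H equals the brute-force oracle on the same rows
  rest_mag <- bt[bt$band == "rest", ]
  h_battery <- b1$omnibus$statistic[b1$omnibus$band == "rest" &
    b1$omnibus$measure == "magnitude"]
  expect_equal(h_battery, oracle_kw_h(rest_mag$magnitude, rest_mag$task_id),
    tolerance = 1e-9
  )
  # tidy/glance accessors
  expect_identical(tidy(b1), b1$pairwise)
  expect_identical(glance(b1), b1$omnibus)
})

test_that("the battery restricts to represented bands and warns on thin ones", {
  bt <- tibble::tibble(
    subject_id = rep("S01", 20),
    task_id = rep(c(0L, 3L), each = 10),
    band = "rest",
    frequency = stats::runif(20, 3.5, 5.9),
    magnitude = stats::runif(20),
    analyzed = TRUE
  )
  expect_warning(
    expect_warning(res <- run_statistical_battery(bt), "action"),
    "postural"
  )
  expect_equal(unique(res$omnibus$band), "rest")
  expect_equal(unique(res$pairwise$band), "rest")
  # subject-summary unit collapses to one row per subject/task/band
  bt2 <- dplyr::mutate(bt, subject_id = rep(sprintf("S%02d", 1:4), 5))
  res2 <- suppressWarnings(run_statistical_battery(bt2, unit = "subject"))
  expect_equal(res2$omnibus$n[1], dplyr::n_distinct(bt2$subject_id, bt2$task_id))
})

test_that("SPSS-dialect tables carry the exact column names", {
  bt <- tibble::tibble(
    subject_id = "S01", task_id = rep(c(0L, 3L), each = 10),
    band = "rest", frequency = stats::runif(20, 3.5, 5.9),
    magnitude = stats::runif(20), analyzed = TRUE
  )
  batt <- suppressWarnings(run_statistical_battery(bt))
  tab <- spss_pairwise_table(batt, "magnitude")
  expect_equal(
    names(tab),
    c(
      "Group", "Sample 1-Sample 2", "Test Statistic", "Std. Error",
      "Std. Test Statistic", "Sig.", "Adj. Sig."
    )
  )
  expect_equal(tab$Group, "Rest")
  expect_equal(tab[["Sample 1-Sample 2"]], "0-3")
})
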