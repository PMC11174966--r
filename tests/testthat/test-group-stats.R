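test_that("pH grouping follows the clinical partition", {
  expect_equal(as.character(assign_ph_group(c(7.10, 7.30, 7.50))),
               c("acidosis", "normal", "alkalosis"))
  # boundary values belong to normal by default
  expect_equal(as.character(assign_ph_group(c(7.20, 7.45))), c("normal", "normal"))
  expect_equal(as.character(assign_ph_group(c(7.20, 7.45), boundary_normal = FALSE)),
               c("acidosis", "alkalosis"))
  expect_error(assign_ph_group(6.2), class = "ecgph_invalid_ph")
  expect_error(assign_ph_group(8.4), class = "ecgph_invalid_ph")
})

test_that("descriptive summaries use interpolated quartiles", {
  ds <- describe_groups(c(1, 2, 3, 4, 5, 7), c(rep("a", 5), "b"))
  tab <- ds$table
  expect_equal(tab$median[tab$group == "a"], 3)
  expect_equal(tab$iqr[tab$group == "a"], 2)  # Q1 = 2, Q3 = 4 by interpolation
  expect_equal(tab$median[tab$group == "b"], 7)
  expect_equal(tab$iqr[tab$group == "b"], 0)
  # empty group reported with n = 0
  ds2 <- describe_groups(c(1, 2), factor(c("x", "x"), levels = c("x", "y")))
  expect_equal(ds2$table$n, c(2L, 0L))
  expect_true(is.na(ds2$table$median[2]))
  # all-equal values degrade gracefully for scaled box plots
  ds3 <- describe_groups(rep(4, 6), rep(c("a", "b"), 3))
  expect_true(all(ds3$scaled == 0.5))
})

test_that("Kruskal-Wallis matches hand-derived example values", {
  labels <- rep(c("g1", "g2", "g3"), each = 3)
  expect_equal(kruskal_wallis(c(1, 2, 3, 4, 5, 6, 7, 8, 9), labels)$statistic, 7.2)
  expect_equal(kruskal_wallis(c(1, 2, 3, 4, 5, 6, 7, 8, 9), labels)$df, 2)
  expect_equal(kruskal_wallis(c(1, 6, 8, 2, 4, 9, 3, 5, 7), labels)$statistic, 0)
  expect_equal(kruskal_wallis(c(1, 4, 7, 2, 5, 8, 3, 6, 9), labels)$statistic, 0.8)
  # all-identical values: tie factor zero, H defined as 0 with p = 1
  kw0 <- kruskal_wallis(rep(5, 9), labels)
  expect_equal(kw0$statistic, 0)
  expect_equal(kw0$p.value, 1)
})

test_that("H equals the brute-force rank formula on every 3-group split of 7 values", {
  # exhaustive oracle: direct evaluation of the rank-sum formula, written
  # independently of the production implementation
  brute_h <- function(v, g) {
    r <- rank(v)
    N <- length(v)
    h <- 0
    for (lev in unique(g)) {
      ri <- r[g == lev]
      h <- h + length(ri) * (mean(ri) - (N + 1) / 2)^2
    }
    12 / (N * (N + 1)) * h  # all values distinct: no tie correction
  }
  v <- c(3, 8, 15, 1, 9, 12, 20)
  cnt <- 0
  for (code in 0:(3^7 - 1)) {
    g <- (code %/% 3^(0:6)) %% 3
    if (length(unique(g)) < 3) next
    cnt <- cnt + 1
    expect_equal(kruskal_wallis(v, as.character(g))$statistic, brute_h(v, g),
                 tolerance = 1e-12)
  }
  expect_gt(cnt, 1500)
})

test_that("chi-square p agrees with stats::kruskal.test including ties", {
  set.seed(61)
  for (k in 1:20) {
    v <- sample(1:8, 30, replace = TRUE)  # heavy ties
    g <- sample(c("a", "b", "c"), 30, replace = TRUE)
    if (length(unique(g)) < 2) next
    ref <- kruskal.test(v, factor(g))
    kw <- kruskal_wallis(v, g)
    expect_equal(kw$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(kw$p.value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("KW is invariant under strictly monotone transforms", {
  set.seed(62)
  v <- rnorm(40)
  g <- sample(c("a", "b", "c"), 40, replace = TRUE)
  base <- kruskal_wallis(v, g)$statistic
  for (f in list(function(x) exp(x), function(x) x^3, function(x) atan(x) - 5))
    expect_equal(kruskal_wallis(f(v), g)$statistic, base, tolerance = 1e-12)
})

test_that("mean ranks satisfy the rank-sum identity", {
  set.seed(63)
  v <- rnorm(50)
  g <- sample(c("a", "b", "c"), 50, replace = TRUE)
  kw <- kruskal_wallis(v, g)
  expect_equal(sum(kw$groups$n * kw$groups$mean_rank), 50 * 51 / 2)
})

test_that("Dunn-Sidak reproduces the hand-worked two-group example", {
  v <- c(1, 2, 3, 4, 5, 6)
  g <- rep(c("lo", "hi"), each = 3)
  dn <- dunn_sidak(v, g)
  expect_equal(nrow(dn), 1)
  row <- dn[dn$group_i == "lo" | dn$group_j == "lo", ]
  est <- if (row$group_i == "lo") row$estimate else -row$estimate
  expect_equal(est, -3)
  expect_equal(abs(row$z), 1.9640, tolerance = 1e-4)
  expect_equal(row$p_raw, 0.0495, tolerance = 1e-3)
  # one comparison: Sidak adjustment is the identity
  expect_equal(row$p_adj, row$p_raw, tolerance = 1e-12)
  se <- abs(row$estimate / row$z)
  expect_equal(se, 1.5275, tolerance = 1e-4)
})

test_that("identical groups give zero difference and a symmetric interval", {
  v <- c(1, 2, 3, 1, 2, 3)
  g <- rep(c("a", "b"), each = 3)
  dn <- dunn_sidak(v, g)
  expect_equal(dn$estimate, 0)
  expect_equal(dn$p_adj, 1)
  expect_equal(dn$lower, -dn$upper)
  expect_false(dn$significant)
})

test_that("decision and interval coherence is exact, and SE simplifies without ties", {
  set.seed(64)
  for (k in 1:50) {
    v <- if (k %% 2) rnorm(40) else sample(1:6, 40, replace = TRUE)
    g <- sample(c("a", "b", "c"), 40, replace = TRUE)
    dn <- dunn_sidak(v, g, alpha = 0.05)
    expect_equal(dn$significant, dn$lower > 0 | dn$upper < 0)
    expect_true(all(dn$lower <= dn$estimate & dn$estimate <= dn$upper))
  }
  # distinct values: SE reduces to sqrt(N(N+1)/12 (1/ni + 1/nj))
  v <- rnorm(30); g <- rep(c("a", "b", "c"), each = 10)
  dn <- dunn_sidak(v, g)
  expect_equal(abs(dn$estimate / dn$z)[1], sqrt(30 * 31 / 12 * (2 / 10)),
               tolerance = 1e-10)
})

test_that("feature-wise report gates the post hoc on the omnibus test", {
  cc <- cohort_config(effects = list(t_amp = c(0.4, 1, 1), tslope = c(0.4, 1, 1),
                                     qt = c(1, 1, 1)), seed = 41)
  f <- simulate_cohort_features(cc)
  rep <- run_feature_tests(f, alpha = 0.05)
  expect_s3_class(rep, "ecg_group_comparison")
  expect_setequal(names(rep$results), feature_columns())
  ta <- rep$results$t_amplitude
  expect_lt(ta$kw$p.value, 0.05)
  expect_false(is.null(ta$pairs))
  # a feature whose omnibus is not significant carries no pairs
  ns <- Filter(function(r) r$kw$p.value >= 0.05, rep$results)
  if (length(ns)) expect_true(all(vapply(ns, function(r) is.null(r$pairs), logical(1))))
  # forcing runs all pairs everywhere
  rep2 <- run_feature_tests(f, force_posthoc = TRUE)
  expect_true(all(vapply(rep2$results, function(r) nrow(r$pairs) == 3, logical(1))))
  # single-group input is refused
  expect_error(run_feature_tests(f[f$group == "normal", ]),
               class = "ecgph_insufficient_groups")
  # an all-missing feature is skipped with a warning
  f2 <- f; f2$qtc <- NA_real_
  expect_warning(rep3 <- run_feature_tests(f2), "qtc")
  expect_false("qtc" %in% names(rep3$results))
})
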