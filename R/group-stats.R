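#' Assign the pH group
#'
#' Clinical partition for neonatal acid-base status: acidosis when
#' pH < 7.20, normal for 7.20-7.45, alkalosis when pH > 7.45. The boundary
#' values 7.20 and 7.45 belong to the normal range by default
#' (`boundary_normal = FALSE` moves them to the adjacent disorder groups).
#'
#' @param ph numeric vector of pH values, within plausibility bounds
#'   `[6.5, 8.0]`.
#' @param boundary_normal logical; see above.
#' @return factor with levels `acidosis`, `normal`, `alkalosis`.
#' @examples
#' assign_ph_group(c(7.10, 7.30, 7.50))
#' @export
assign_ph_group <- function(ph, boundary_normal = TRUE) {
  if (any(!is.finite(ph)) || any(ph < 6.5 | ph > 8.0))
    ecgph_stop("pH outside plausibility bounds [6.5, 8.0]", "ecgph_invalid_ph")
  lab <- if (boundary_normal) {
    ifelse(ph < 7.20, "acidosis", ifelse(ph > 7.45, "alkalosis", "normal"))
  } else {
    ifelse(ph <= 7.20, "acidosis", ifelse(ph >= 7.45, "alkalosis", "normal"))
  }
  factor(lab, levels = c("acidosis", "normal", "alkalosis"))
}

#' Per-group descriptive statistics
#'
#' Median, interquartile range (Q3 - Q1, quartiles by linear interpolation,
#' the type-7 convention) and mean per group, plus the values rescaled to
#' `[0, 1]` across the pooled sample for symmetric box-plot display. Empty
#' groups are reported with `n = 0` and missing summaries.
#'
#' @param values numeric vector.
#' @param labels group labels (factor or character), same length.
#' @return list of class `group_summary` with `table` (data.frame: group, n,
#'   median, q1, q3, iqr, mean) and `scaled` (values mapped to `[0, 1]`).
#' @export
describe_groups <- function(values, labels) {
  labels <- as.factor(labels)
  stopifnot(length(values) == length(labels))
  rows <- lapply(levels(labels), function(g) {
    v <- values[labels == g & !is.na(values)]
    if (!length(v))
      return(data.frame(group = g, n = 0L, median = NA_real_, q1 = NA_real_,
                        q3 = NA_real_, iqr = NA_real_, mean = NA_real_))
    qs <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(group = g, n = length(v), median = qs[2], q1 = qs[1], q3 = qs[3],
               iqr = qs[3] - qs[1], mean = mean(v))
  })
  rng <- range(values, na.rm = TRUE)
  scaled <- if (diff(rng) > 0) (values - rng[1]) / diff(rng) else rep(0.5, length(values))
  structure(list(table = do.call(rbind, rows), scaled = scaled, labels = labels),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, digits = 4, ...) {
  print(format(x$table, digits = digits), row.names = FALSE)
  invisible(x)
}

# pooled midranks plus the tie sum needed by both tests
rank_info <- function(values) {
  r <- rank(values, ties.method = "average")
  t <- table(values)
  list(r = r, tie_sum = sum(t^3 - t), N = length(values))
}

#' Tie-corrected Kruskal-Wallis test
#'
#' Rank-based k-group omnibus test. Midranks are assigned over the pooled
#' sample; the statistic is
#' `H = 12 / (N (N + 1)) * sum n_i (rbar_i - (N + 1) / 2)^2` divided by the
#' tie-correction factor `1 - sum(t^3 - t) / (N^3 - N)`, referred to the
#' chi-square distribution with k - 1 degrees of freedom. When every value
#' is identical the statistic is defined as 0 with p = 1.
#'
#' @param values numeric vector.
#' @param labels group labels, same length; at least two non-empty groups
#'   and N >= 3.
#' @return object of class `kw_result`: `statistic` (H, chi-square scale),
#'   `df`, `p.value`, `groups` (data.frame label, n, mean_rank),
#'   `tie_correction`.
#' @export
kruskal_wallis <- function(values, labels) {
  keep <- !is.na(values)
  values <- values[keep]
  labels <- droplevels(as.factor(labels[keep]))
  k <- nlevels(labels)
  if (k < 2) ecgph_stop("at least 2 non-empty groups required", "ecgph_insufficient_groups")
  ri <- rank_info(values)
  if (ri$N < 3) ecgph_stop("N >= 3 required", "ecgph_insufficient_groups")
  n_i <- as.numeric(table(labels))
  rbar <- as.numeric(tapply(ri$r, labels, mean))
  N <- ri$N
  C <- 1 - ri$tie_sum / (N^3 - N)
  H0 <- 12 / (N * (N + 1)) * sum(n_i * (rbar - (N + 1) / 2)^2)
  if (C <= 0) {
    H <- 0; p <- 1
  } else {
    H <- H0 / C
    p <- pchisq(H, df = k - 1, lower.tail = FALSE)
  }
  structure(list(statistic = H, df = k - 1, p.value = p,
                 groups = data.frame(label = levels(labels), n = n_i,
                                     mean_rank = rbar),
                 tie_correction = C),
            class = "kw_result")
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: chi-square = %.4f, df = %d, p = %.4g (tie factor %.4f)\n",
              x$statistic, x$df, x$p.value, x$tie_correction))
  print(format(x$groups, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Dunn-Sidak post hoc comparisons
#'
#' For each pair of groups, compares mean ranks from the pooled ranking:
#' `z = (rbar_i - rbar_j) / SE` with
#' `SE = sqrt((N (N + 1) / 12 - sum(t^3 - t) / (12 (N - 1))) (1/n_i + 1/n_j))`.
#' Raw two-sided p-values from the standard normal are Sidak-adjusted for
#' the `m = k (k - 1) / 2` comparisons, `p_adj = 1 - (1 - p)^m`, and each
#' pair carries the simultaneous interval
#' `estimate +/- z_{1 - alpha*/2} * SE` with `alpha* = 1 - (1 - alpha)^(1/m)`.
#' By construction the interval excludes zero exactly when the adjusted p is
#' below `alpha`, matching the disjoint-interval reading of significance.
#'
#' @param values numeric vector.
#' @param labels group labels, same length.
#' @param alpha simultaneous significance level.
#' @return data.frame of class `dunn_result`: one row per pair with columns
#'   `group_i, group_j, estimate, lower, upper, z, p_raw, p_adj, significant`.
#' @export
dunn_sidak <- function(values, labels, alpha = 0.05) {
  keep <- !is.na(values)
  values <- values[keep]
  labels <- droplevels(as.factor(labels[keep]))
  k <- nlevels(labels)
  if (k < 2) ecgph_stop("at least 2 non-empty groups required", "ecgph_insufficient_groups")
  ri <- rank_info(values)
  N <- ri$N
  n_i <- as.numeric(table(labels))
  rbar <- as.numeric(tapply(ri$r, labels, mean))
  S <- N * (N + 1) / 12 - ri$tie_sum / (12 * (N - 1))
  m <- k * (k - 1) / 2
  alpha_star <- 1 - (1 - alpha)^(1 / m)
  crit <- qnorm(1 - alpha_star / 2)
  rows <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(S * (1 / n_i[i] + 1 / n_i[j]))
    est <- rbar[i] - rbar[j]
    z <- if (se > 0) est / se else 0
    p_raw <- 2 * pnorm(-abs(z))
    p_adj <- min(1, 1 - (1 - p_raw)^m)
    rows[[length(rows) + 1L]] <- data.frame(
      group_i = levels(labels)[i], group_j = levels(labels)[j],
      estimate = est, lower = est - crit * se, upper = est + crit * se,
      z = z, p_raw = p_raw, p_adj = p_adj, significant = p_adj < alpha)
  }
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  attr(out, "m") <- m
  class(out) <- c("dunn_result", "data.frame")
  out
}

#' Run the group comparison over every feature
#'
#' For each of the ten morphological features: the tie-corrected
#' Kruskal-Wallis omnibus test, followed by Dunn-Sidak pairwise comparisons
#' only when the omnibus p-value falls below `alpha` (the post hoc test
#' validates a significant omnibus result; `force_posthoc` runs all pairs
#' regardless). Features whose column is entirely missing are skipped with
#' a warning.
#'
#' @param features feature table as produced by the pipeline (must contain
#'   the [feature_columns()] and a `group` column).
#' @param alpha significance level.
#' @param force_posthoc run pairwise comparisons for every feature.
#' @return object of class `ecg_group_comparison`: per-feature list of
#'   `kw` ([kruskal_wallis()]) and `pairs` ([dunn_sidak()] or `NULL`), plus
#'   `describe` summaries, `alpha` and group sizes.
#' @export
run_feature_tests <- function(features, alpha = 0.05, force_posthoc = FALSE) {
  stopifnot("group" %in% names(features))
  labels <- droplevels(factor(features$group,
                              levels = c("acidosis", "normal", "alkalosis")))
  if (nlevels(labels) < 2)
    ecgph_stop("fewer than 2 non-empty pH groups: omnibus test not applicable",
               "ecgph_insufficient_groups")
  res <- list()
  for (f in feature_columns()) {
    if (!f %in% names(features) || all(is.na(features[[f]]))) {
      warning(sprintf("feature '%s' entirely missing; skipped", f))
      next
    }
    kw <- kruskal_wallis(features[[f]], labels)
    pairs <- if (force_posthoc || kw$p.value < alpha)
      dunn_sidak(features[[f]], labels, alpha = alpha) else NULL
    res[[f]] <- list(kw = kw, pairs = pairs,
                     describe = describe_groups(features[[f]], labels))
  }
  structure(list(results = res, alpha = alpha,
                 group_sizes = table(labels), n = nrow(features)),
            class = "ecg_group_comparison")
}

#' @export
print.ecg_group_comparison <- function(x, ...) {
  lab <- feature_labels()
  cat(sprintf("ECG feature group comparison (n = %d; %s; alpha = %g)\n\n",
              x$n, paste(sprintf("%s = %d", names(x$group_sizes), x$group_sizes),
                         collapse = ", "), x$alpha))
  cat("Kruskal-Wallis omnibus tests:\n")
  for (f in names(x$results)) {
    kw <- x$results[[f]]$kw
    cat(sprintf("  %-15s chi-square = %6.2f  p = %.4f%s\n", lab[[f]],
                kw$statistic, kw$p.value,
                if (kw$p.value < x$alpha) " *" else ""))
  }
  any_pairs <- FALSE
  for (f in names(x$results)) {
    pr <- x$results[[f]]$pairs
    if (is.null(pr)) next
    sig <- pr[pr$significant, , drop = FALSE]
    if (!nrow(sig)) next
    if (!any_pairs) { cat("\nSignificant Dunn-Sidak pairs (simultaneous intervals):\n"); any_pairs <- TRUE }
    for (r in seq_len(nrow(sig)))
      cat(sprintf("  %-15s %s vs %s: %8.3f [%8.3f, %8.3f]  p_adj = %.4f\n",
                  lab[[f]], sig$group_i[r], sig$group_j[r], sig$estimate[r],
                  sig$lower[r], sig$upper[r], sig$p_adj[r]))
  }
  invisible(x)
}

#' Serialize a group comparison as a JSON report
#'
#' Per feature: `{chi_square, df, p, tie_correction, groups: [{label, n,
#' mean_rank}], pairs: [{i, j, estimate, lower, upper, p_adj, significant}]}`.
#'
#' @param comparison an `ecg_group_comparison`.
#' @param path output JSON path.
#' @export
write_report <- function(comparison, path) {
  out <- lapply(comparison$results, function(r) {
    pairs <- if (is.null(r$pairs)) list() else
      lapply(seq_len(nrow(r$pairs)), function(i) list(
        i = r$pairs$group_i[i], j = r$pairs$group_j[i],
        estimate = r$pairs$estimate[i], lower = r$pairs$lower[i],
        upper = r$pairs$upper[i], p_adj = r$pairs$p_adj[i],
        significant = r$pairs$significant[i]))
    list(chi_square = r$kw$statistic, df = r$kw$df, p = r$kw$p.value,
         tie_correction = r$kw$tie_correction,
         groups = lapply(seq_len(nrow(r$kw$groups)), function(i) list(
           label = r$kw$groups$label[i], n = r$kw$groups$n[i],
           mean_rank = r$kw$groups$mean_rank[i])),
         pairs = pairs)
  })
  jsonlite::write_json(list(alpha = comparison$alpha, n = comparison$n,
                            features = out),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
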