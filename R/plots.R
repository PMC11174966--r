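#' Box plots of scaled features by pH group
#'
#' Displays each feature rescaled to `[0, 1]` across the pooled sample (so
#' the ten features share one axis), grouped by pH group, with the group
#' means and medians marked.
#'
#' @param features feature table with `group` column.
#' @param cols feature columns to plot.
#' @export
plot_feature_boxes <- function(features, cols = feature_columns()) {
  labs <- feature_labels()
  old <- par(mfrow = grDevices::n2mfrow(length(cols)), mar = c(2.5, 2.5, 2, 0.5),
             mgp = c(1.5, 0.5, 0))
  on.exit(par(old))
  grp <- factor(features$group, levels = c("acidosis", "normal", "alkalosis"))
  for (f in cols) {
    ds <- describe_groups(features[[f]], grp)
    boxplot(ds$scaled ~ grp, main = labs[[f]], xlab = "", ylab = "scaled",
            col = "grey90", outpch = 1, cex.main = 0.9)
    mns <- tapply(ds$scaled, grp, mean, na.rm = TRUE)
    mds <- tapply(ds$scaled, grp, median, na.rm = TRUE)
    points(seq_along(mns), mns, pch = 18, col = "darkgreen", cex = 1.2)
    points(seq_along(mds), mds, pch = 16, col = "red", cex = 0.8)
  }
  invisible(features)
}

#' Comparison-interval display for one feature
#'
#' Mean ranks per group with simultaneous comparison intervals, the
#' disjoint-interval reading of the Dunn-Sidak test: two groups differ
#' significantly when their intervals do not overlap. Per-group interval
#' half-widths are `z_crit * sqrt(S / (2 n_g))` (S the tie-corrected rank
#' variance), which reproduces the pairwise test exactly for balanced
#' groups and approximately otherwise.
#'
#' @param values numeric feature values.
#' @param labels group labels.
#' @param alpha significance level.
#' @param main plot title.
#' @export
plot_comparison_intervals <- function(values, labels, alpha = 0.05, main = "") {
  labels <- droplevels(as.factor(labels))
  k <- nlevels(labels)
  ri <- rank_info(values[!is.na(values)])
  n_i <- as.numeric(table(labels[!is.na(values)]))
  rbar <- as.numeric(tapply(ri$r, labels[!is.na(values)], mean))
  S <- ri$N * (ri$N + 1) / 12 - ri$tie_sum / (12 * (ri$N - 1))
  m <- k * (k - 1) / 2
  crit <- qnorm(1 - (1 - (1 - alpha)^(1 / m)) / 2)
  hw <- crit * sqrt(S / (2 * n_i))
  ylim <- c(0.5, k + 0.5)
  plot(rbar, seq_len(k), xlim = range(c(rbar - hw, rbar + hw)), ylim = rev(ylim),
       pch = 16, yaxt = "n", xlab = "mean rank", ylab = "", main = main)
  axis(2, at = seq_len(k), labels = levels(labels), las = 1)
  segments(rbar - hw, seq_len(k), rbar + hw, seq_len(k))
  invisible(data.frame(group = levels(labels), mean_rank = rbar,
                       lower = rbar - hw, upper = rbar + hw))
}
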