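#' Pipeline configuration
#'
#' Bundles every tunable of the analysis in one validated object. In
#' `"synthetic"` mode the embedded [cohort_config()] defines the study
#' cohort; in `"files"` mode `records` and `events` name CSV/WFDB inputs
#' (one events table per record). Every constant of the processing stages
#' (filter cascade, detector, quality gate, cycle length, T-window, alpha)
#' is exposed here so sensitivity to these choices can be explored.
#'
#' @param mode `"synthetic"` or `"files"`.
#' @param cohort a [cohort_config()] (synthetic mode).
#' @param records,events character vectors of input paths (files mode).
#' @param format input format for files mode: `"csv"` or `"wfdb"`.
#' @param channel analysis channel (1 or 2).
#' @param seg_len segment length (s).
#' @param min_seg_len minimum truncated segment length kept (s).
#' @param sides which event sides to analyse: `"following"` (default, one
#'   segment per event), `"preceding"` or `"both"`.
#' @param filter a [filter_params()].
#' @param qrs a [qrs_params()].
#' @param gate named list overriding [quality_gate()] thresholds.
#' @param M representative-cycle length (samples).
#' @param twave a [twave_params()].
#' @param alpha significance level of the group comparison.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param seed master seed; in synthetic mode it overrides `cohort$seed`.
#' @param log_level `"debug"`, `"info"` or `"warning"`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "files"),
                            cohort = cohort_config(),
                            records = NULL, events = NULL,
                            format = c("csv", "wfdb"),
                            channel = 1, seg_len = 10, min_seg_len = 8,
                            sides = c("following", "preceding", "both"),
                            filter = filter_params(), qrs = qrs_params(),
                            gate = list(), M = 256, twave = twave_params(),
                            alpha = 0.05, out_dir = NULL, seed = 1L,
                            log_level = c("info", "debug", "warning")) {
  mode <- match.arg(mode)
  sides <- match.arg(sides)
  format <- match.arg(format)
  log_level <- match.arg(log_level)
  if (seg_len <= 0) ecgph_stop("seg_len must be > 0", "ecgph_invalid_config")
  if (min_seg_len <= 0 || min_seg_len > seg_len)
    ecgph_stop("min_seg_len must be in (0, seg_len]", "ecgph_invalid_config")
  if (!channel %in% c(1, 2)) ecgph_stop("channel must be 1 or 2", "ecgph_invalid_config")
  if (alpha <= 0 || alpha >= 1) ecgph_stop("alpha must be in (0, 1)", "ecgph_invalid_config")
  if (M < 32) ecgph_stop("M must be >= 32", "ecgph_invalid_config")
  if (mode == "files" && (is.null(records) || is.null(events)))
    ecgph_stop("files mode requires 'records' and 'events' paths", "ecgph_invalid_config")
  structure(list(mode = mode, cohort = cohort, records = records,
                 events = events, format = format, channel = channel,
                 seg_len = seg_len, min_seg_len = min_seg_len, sides = sides,
                 filter = filter, qrs = qrs, gate = gate, M = M,
                 twave = twave, alpha = alpha, out_dir = out_dir,
                 seed = as.integer(seed), log_level = log_level),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Reads a flat configuration file and merges it over the defaults of
#' [pipeline_config()]; nested sections `cohort`, `filter`, `qrs`, `twave`
#' are passed to the corresponding constructors.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  args <- raw
  for (sec in c("filter", "qrs", "twave", "cohort")) {
    if (!is.null(raw[[sec]])) {
      ctor <- switch(sec, filter = filter_params, qrs = qrs_params,
                     twave = twave_params, cohort = cohort_config)
      args[[sec]] <- do.call(ctor, raw[[sec]])
    }
  }
  do.call(pipeline_config, args)
}

log_msg <- function(config, level, fmt, ...) {
  ranks <- c(debug = 1, info = 2, warning = 3)
  if (ranks[[level]] >= ranks[[config$log_level]])
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}

# run one segment through filter -> normalize -> detect -> gate -> cycle ->
# delineate -> features; returns either a feature row or a rejection reason
process_segment <- function(seg, config) {
  reject <- function(reason) list(accepted = FALSE, reason = reason, features = NULL)
  filt <- filter_segment(seg, config$filter)
  norm <- tryCatch(normalize_segment(filt), ecgph_degenerate_signal = function(e) NULL)
  if (is.null(norm)) return(reject("degenerate-signal"))
  r <- detect_r_peaks(norm, params = config$qrs)
  ann <- if (length(r) >= 2)
    tryCatch(locate_qrs_points(norm, r), ecgph_insufficient_beats = function(e) NULL)
  else NULL
  verdict <- if (is.null(ann)) quality_gate(length(r))
             else do.call(quality_gate, c(list(ann), config$gate))
  if (!verdict$accepted) return(reject(verdict$reason))
  res <- tryCatch({
    cmat <- build_cycle_matrix(norm, ann, M = config$M)
    rep_cycle <- extract_representative(cmat)
    tw <- delineate_t(rep_cycle, ann, config$twave)
    compute_features(rep_cycle, ann, tw, ph = seg$ph,
                     segment_id = paste(seg$event_id, seg$side, sep = "-"))
  }, ecgph_error = function(e) conditionMessage(e))
  if (is.character(res)) return(reject(sub(":.*", "", res)))
  list(accepted = TRUE, reason = NA_character_, features = res)
}

#' Run the full analysis pipeline
#'
#' Executes extract -> filter -> normalize -> detect -> gate -> cycle ->
#' delineate -> features -> group tests over a synthetic cohort or over
#' files, and (optionally) writes the feature TSV, the JSON statistics
#' report and a run manifest to `out_dir`. The run is fully deterministic
#' given the configuration seed.
#'
#' @param config a [pipeline_config()].
#' @return object of class `ecg_ph_analysis`: list with `features`
#'   (data.frame), `comparison` ([run_feature_tests()] result or `NULL` if
#'   fewer than two pH groups survived), `manifest` (config snapshot,
#'   per-segment dispositions, stage counts), and `config`.
#' @examples
#' cfg <- pipeline_config(cohort = cohort_config(n_acidosis = 3, n_normal = 4,
#'                                               n_alkalosis = 3), seed = 7)
#' \donttest{res <- run_pipeline(cfg)}
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$mode == "synthetic") {
    config$cohort$seed <- config$seed
    cohort <- generate_cohort(config$cohort)
    inputs <- lapply(cohort, function(r) list(record = r$record, events = r$events))
  } else {
    if (length(config$records) != length(config$events))
      ecgph_stop("records and events lists differ in length", "ecgph_invalid_config")
    inputs <- Map(function(rp, ep) list(record = read_ecg(rp, config$format),
                                        events = read_events_csv(ep)),
                  config$records, config$events)
  }
  dispositions <- list()
  feats <- list()
  n_events <- 0L
  for (inp in inputs) {
    segs <- extract_segments(inp$record, inp$events, seg_len = config$seg_len,
                             min_len = config$min_seg_len,
                             channel = config$channel, sides = config$sides)
    n_events <- n_events + nrow(inp$events)
    for (seg in segs) {
      out <- process_segment(seg, config)
      sid <- paste(seg$event_id, seg$side, sep = "-")
      dispositions[[sid]] <- list(segment_id = sid, accepted = out$accepted,
                                  reason = out$reason)
      if (out$accepted) feats[[sid]] <- out$features
      else log_msg(config, "info", "segment %s rejected: %s", sid, out$reason)
    }
  }
  n_segments <- length(dispositions)
  if (!length(feats)) {
    reasons <- table(vapply(dispositions, `[[`, character(1), "reason"))
    ecgph_stop(paste0("no segments accepted; rejection reasons: ",
                      paste(sprintf("%s = %d", names(reasons), reasons),
                            collapse = ", ")),
               "ecgph_no_accepted_segments")
  }
  features <- do.call(rbind, feats)
  rownames(features) <- NULL
  comparison <- tryCatch(run_feature_tests(features, alpha = config$alpha),
                         ecgph_insufficient_groups = function(e) {
                           log_msg(config, "warning",
                                   "group comparison skipped: %s", conditionMessage(e))
                           NULL
                         })
  manifest <- list(
    version = as.character(utils::packageVersion("ecgph")),
    mode = config$mode, seed = config$seed,
    counts = list(records = length(inputs), events = n_events,
                  segments = n_segments, accepted = length(feats),
                  rejected = n_segments - length(feats)),
    rejection_reasons = as.list(table(stats::na.omit(
      vapply(dispositions, `[[`, character(1), "reason")))),
    dispositions = unname(dispositions))
  res <- structure(list(features = features, comparison = comparison,
                        manifest = manifest, config = config),
                   class = "ecg_ph_analysis")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_features(features, file.path(config$out_dir, "features.tsv"))
    if (!is.null(comparison))
      write_report(comparison, file.path(config$out_dir, "report.json"))
    manifest_out <- c(manifest, list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
    jsonlite::write_json(manifest_out, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

#' @export
print.ecg_ph_analysis <- function(x, ...) {
  cnt <- x$manifest$counts
  cat(sprintf("<ecg_ph_analysis: %d records, %d segments (%d accepted, %d rejected)>\n",
              cnt$records, cnt$segments, cnt$accepted, cnt$rejected))
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}

#' @export
summary.ecg_ph_analysis <- function(object, ...) {
  cnt <- object$manifest$counts
  cat(sprintf("Pipeline run (seed %d, %s mode)\n", object$config$seed, object$config$mode))
  cat(sprintf("  records %d | events %d | segments %d | accepted %d | rejected %d\n",
              cnt$records, cnt$events, cnt$segments, cnt$accepted, cnt$rejected))
  if (length(object$manifest$rejection_reasons))
    cat("  rejections:", paste(sprintf("%s = %s", names(object$manifest$rejection_reasons),
                                       object$manifest$rejection_reasons), collapse = ", "), "\n")
  for (f in feature_columns()) {
    if (!f %in% names(object$features)) next
    d <- describe_groups(object$features[[f]], object$features$group)$table
    cat(sprintf("  %-18s %s\n", feature_labels()[[f]],
                paste(sprintf("%s: %.3g [%.3g]", d$group, d$median, d$iqr), collapse = "  ")))
  }
  invisible(object)
}
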