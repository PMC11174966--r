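# shared builders for synthetic fixtures (everything is generated in code)

# a clean single-segment record at a given heart rate; returns the filtered,
# normalized 10 s segment together with its ground truth
clean_segment <- function(hr = 140, seed = 1, jitter = 0.03, noise = NULL,
                          template = beat_template()) {
  cfg <- cohort_config(n_acidosis = 0, n_normal = 1, n_alkalosis = 0,
                       hr_mean = c(hr, hr, hr), hr_halfwidth = 0,
                       rr_jitter = jitter, noise = noise,
                       template = template, seed = seed)
  rec <- synthesize_record(cfg, "normal", seed = seed)
  seg <- extract_segments(rec$record, rec$events, sides = "following")[[1]]
  list(segment = normalize_segment(filter_segment(seg)),
       raw = seg, truth = rec$truth)
}

# truth R times expressed as sample indices of a following-side segment;
# beats whose QRS support (80 ms) is cut by a segment edge are excluded,
# the usual convention when benchmarking beat detectors on windows
truth_r_samples <- function(truth, segment, fs = 256) {
  rt <- truth$r_times - segment$t0
  rt <- rt[rt >= 0.08 & rt < length(segment$samples) / fs - 0.08]
  rt * fs + 1
}

# detection match at a tolerance (seconds): sensitivity / positive
# predictivity. Truth beats near segment edges were excluded up front, so an
# unmatched detection inside the same edge-guard zone is not counted as a
# false positive (it may belong to an excluded truncated beat); matched
# detections count wherever they fall.
match_detections <- function(det_idx, true_idx, fs = 256, tol = 0.010,
                             n_samples = NULL, guard = 0.08) {
  if (!length(true_idx)) return(c(se = NA, ppv = NA))
  matched <- vapply(det_idx, function(d0) any(abs(true_idx - d0) <= tol * fs),
                    logical(1))
  in_guard <- if (is.null(n_samples)) rep(FALSE, length(det_idx))
              else det_idx < guard * fs | det_idx > n_samples - guard * fs
  tp <- sum(vapply(true_idx, function(t0) any(abs(det_idx - t0) <= tol * fs),
                   logical(1)))
  fp <- sum(!matched & !in_guard)
  n_scored <- sum(matched) + fp
  c(se = tp / length(true_idx),
    ppv = if (n_scored) sum(matched) / n_scored else NA)
}
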