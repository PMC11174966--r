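#' T-wave delineation parameters
#'
#' @param search_start start of the T search window after R (s).
#' @param search_frac end of the T search window as a fraction of RRAvg.
#' @param slope_win length (s) of the sliding least-squares window used for
#'   the T-slope estimate.
#' @param baseline_win length (s) of the pre-onset window whose median
#'   defines the isoelectric baseline.
#' @param baseline_gap guard gap (s) between that window and the QRS onset,
#'   keeping the smoothed Q foot out of the baseline estimate.
#' @param limb_max maximum extent (s) of the terminal-limb slope search
#'   after the T peak.
#' @return list of class `twave_params`.
#' @export
twave_params <- function(search_start = 0.080, search_frac = 0.60,
                         slope_win = 0.040, baseline_win = 0.040,
                         baseline_gap = 0.010, limb_max = 0.150) {
  structure(list(search_start = search_start, search_frac = search_frac,
                 slope_win = slope_win, baseline_win = baseline_win,
                 baseline_gap = baseline_gap, limb_max = limb_max),
            class = "twave_params")
}

# least-squares slopes of y over every contiguous window of k samples with
# uniform spacing dt, via running sums (vectorised; x taken as 0..(k-1)*dt)
running_ls_slopes <- function(y, k, dt) {
  n <- length(y)
  if (n < k) return(numeric(0))
  j <- 0:(k - 1)
  sx <- sum(j); sxx <- sum(j^2)
  csum <- c(0, cumsum(y))
  cjsum <- c(0, cumsum(y * seq_along(y)))
  starts <- seq_len(n - k + 1)
  sy <- csum[starts + k] - csum[starts]
  # sum over window of (position-within-window)*y
  sjy <- (cjsum[starts + k] - cjsum[starts]) - (starts - 1) * sy - sy  # j is 0-based
  denom <- k * sxx - sx^2
  ((k * sjy - sx * sy) / denom) / dt
}

#' Delineate the T wave on a representative cycle
#'
#' The search window is `[R + search_start, R + search_frac * RRAvg]`. The
#' T peak is the extremum of largest absolute baseline-relative amplitude in
#' the window; the isoelectric baseline is the median over the 40 ms
#' preceding the QRS onset. T slope is the steepest slope (signed, in the
#' direction of return to baseline) among least-squares line fits over a
#' sliding 40 ms window on the terminal limb after the peak; the T end
#' follows by the tangent method, intersecting that steepest tangent with
#' the baseline. QT runs from the QRS onset (median across beats) to T end.
#'
#' @param cycle a `representative_cycle`.
#' @param ann the segment's `qrs_annotation` (source of onset timing).
#' @param params a [twave_params()].
#' @return object of class `twave_annotation`: `t_peak_idx`, `t_end_idx`,
#'   `t_amp` (mV, signed), `tslope` (mV/s, signed), `qt` (s), `baseline`
#'   (mV), `onset_rel` (s, negative), `window` (phase indices),
#'   `low_amplitude` flag.
#' @export
delineate_t <- function(cycle, ann, params = twave_params()) {
  stopifnot(inherits(cycle, "representative_cycle"))
  y <- cycle$waveform
  tt <- cycle_time(cycle)              # seconds relative to R
  dt <- cycle$rravg / cycle$M
  onset_rel <- -median(ann$beats$r - ann$beats$onset) / ann$fs
  bl_hi <- onset_rel - params$baseline_gap
  bl_idx <- which(tt >= bl_hi - params$baseline_win & tt < bl_hi)
  if (!length(bl_idx))
    ecgph_stop("no samples available for the isoelectric baseline", "ecgph_delineation_error")
  baseline <- median(y[bl_idx])
  win <- which(tt >= params$search_start & tt <= params$search_frac * cycle$rravg)
  if (length(win) < 5)
    ecgph_stop("T search window empty at this heart rate", "ecgph_delineation_error")
  rel <- y[win] - baseline
  tp <- win[which.max(abs(rel))]
  t_amp <- y[tp] - baseline
  noise_sd <- sd(y[bl_idx])
  low_amp <- is.finite(noise_sd) && abs(t_amp) < 2 * noise_sd
  # terminal limb: from the peak up to limb_max (bounds the search away from
  # the next beat's P wave at high heart rates)
  limb <- tp:min(cycle$M, tp + max(4L, round(params$limb_max / dt)))
  k <- max(4L, round(params$slope_win / dt))
  slopes <- running_ls_slopes(y[limb], k, dt)
  if (!length(slopes))
    ecgph_stop("terminal limb too short for slope estimation", "ecgph_delineation_error")
  # steepest slope returning towards baseline: most negative for upright T
  i_star <- if (t_amp >= 0) which.min(slopes) else which.max(slopes)
  tslope <- slopes[i_star]
  # tangent through the window's LS centroid intersected with the baseline
  idx <- limb[i_star:(i_star + k - 1)]
  x_bar <- mean(tt[idx]); y_bar <- mean(y[idx])
  t_end_s <- x_bar + (baseline - y_bar) / tslope
  t_end_idx <- min(cycle$M, max(tp + 1L, round((t_end_s / cycle$rravg + 0.3) * cycle$M) + 1L))
  structure(list(t_peak_idx = tp, t_end_idx = t_end_idx, t_amp = t_amp,
                 tslope = tslope, qt = t_end_s - onset_rel, baseline = baseline,
                 onset_rel = onset_rel, window = range(win),
                 low_amplitude = low_amp),
            class = "twave_annotation")
}

#' Compute the ten morphological features for one segment
#'
#' Features: `T/QRS` (T amplitude over QRS peak-to-peak, R minus the deeper
#' of the Q/S troughs), `T Amplitude` (mV, signed), `Tslope` (mV/s, signed),
#' `Tslope/T`, `Tslope/|T|`, `Tslope/sqrt(|T|)`, `HR` (bpm), `QT` (s), `QTc`
#' by Bazett's correction `QT / sqrt(RRAvg)` (s, RRAvg in s), and `RRAvg`
#' (s). A zero T amplitude leaves the ratio features missing rather than
#' infinite.
#'
#' @param cycle a `representative_cycle` (physical amplitude scale).
#' @param ann the segment's `qrs_annotation`.
#' @param tw the [delineate_t()] annotation.
#' @param ph blood pH of the source event.
#' @param segment_id identifier copied into the output row.
#' @return one-row data.frame with columns `segment_id, t_qrs, t_amplitude,
#'   tslope, tslope_t, tslope_abs_t, tslope_sqrt_abs_t, hr, qt, qtc, rravg,
#'   ph, group`.
#' @export
compute_features <- function(cycle, ann, tw, ph, segment_id = NA_character_) {
  y <- cycle$waveform
  tt <- cycle_time(cycle)
  # QRS peak-to-peak over the 80 ms neighbourhood of R: catches whichever of
  # the Q/S troughs is deeper even when smoothing moves it past the onset
  qrs_idx <- which(abs(tt) <= 0.080)
  r_val <- max(y[qrs_idx])
  trough <- min(y[qrs_idx])
  qrs_pp <- r_val - trough
  t_amp <- tw$t_amp
  ratios <- if (t_amp == 0) list(tt = NA_real_, tabs = NA_real_, tsqrt = NA_real_)
            else list(tt = tw$tslope / t_amp, tabs = tw$tslope / abs(t_amp),
                      tsqrt = tw$tslope / sqrt(abs(t_amp)))
  # one-row data.frame built directly (this runs once per segment in large
  # simulation studies, where data.frame()'s checking overhead adds up)
  structure(list(segment_id = segment_id,
                 t_qrs = if (qrs_pp > 0) t_amp / qrs_pp else NA_real_,
                 t_amplitude = t_amp, tslope = tw$tslope,
                 tslope_t = ratios$tt, tslope_abs_t = ratios$tabs,
                 tslope_sqrt_abs_t = ratios$tsqrt,
                 hr = ann$hr, qt = tw$qt, qtc = tw$qt / sqrt(ann$rravg),
                 rravg = ann$rravg, ph = ph,
                 group = as.character(assign_ph_group(ph))),
            class = "data.frame", row.names = 1L)
}

#' Feature columns of the analysis
#' @return character vector of the ten feature column names, in report order.
#' @export
feature_columns <- function() {
  c("t_qrs", "t_amplitude", "tslope", "tslope_t", "tslope_abs_t",
    "tslope_sqrt_abs_t", "hr", "qt", "qtc", "rravg")
}

#' Human-readable feature labels
#' @return named character vector mapping column names to display labels.
#' @export
feature_labels <- function() {
  c(t_qrs = "T/QRS", t_amplitude = "T Amplitude", tslope = "Tslope",
    tslope_t = "Tslope/T", tslope_abs_t = "Tslope/|T|",
    tslope_sqrt_abs_t = "Tslope/sqrt|T|", hr = "HR", qt = "QT", qtc = "QTc",
    rravg = "RRAvg")
}
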