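#' Gaussian-sum beat template
#'
#' A single ECG beat is modelled as the sum of five Gaussian bumps (P, Q, R,
#' S, T) on a flat baseline. Each wave has an amplitude (mV), a centre offset
#' from the R peak (s) and a width (the Gaussian standard deviation, s). The
#' model is deliberately simple: T-wave amplitude, steepest T slope and the
#' tangent-method T end all have closed forms, giving analytic ground truth
#' for parameter-recovery testing.
#'
#' Defaults are conventional neonatal values: R = 1 mV, T = 0.25 mV,
#' tangent-method T end at 0.25 s after R so QT is close to 0.28 s. Signal
#' amplitudes from chest leads are uncalibrated in practice, so all
#' amplitude-ratio features downstream are scale invariant.
#'
#' @param p,q,r,s,t numeric triplets `c(amplitude_mv, center_s, width_s)`;
#'   centres are offsets from the R peak (R centre is always 0).
#' @param baseline baseline level (mV).
#' @return object of class `beat_template`: a list with a `waves` matrix
#'   (rows p,q,r,s,t; columns amp, center, width) and `baseline`.
#' @examples
#' tmpl <- beat_template()
#' beat <- generate_beat(tmpl, rr = 0.5, fs = 256)
#' @export
beat_template <- function(p = c(0.10, -0.100, 0.015),
                          q = c(-0.15, -0.020, 0.010),
                          r = c(1.00, 0.000, 0.010),
                          s = c(-0.20, 0.020, 0.010),
                          t = c(0.25, 0.170, 0.040),
                          baseline = 0) {
  waves <- rbind(p = p, q = q, r = r, s = s, t = t)
  colnames(waves) <- c("amp", "center", "width")
  tmpl <- structure(list(waves = waves, baseline = baseline),
                    class = "beat_template")
  validate_beat_template(tmpl)
  tmpl
}

validate_beat_template <- function(tmpl) {
  w <- tmpl$waves
  if (any(w[, "width"] <= 0))
    ecgph_stop("wave widths must be > 0", "ecgph_invalid_template")
  if (w["r", "amp"] <= 0)
    ecgph_stop("R amplitude must be > 0", "ecgph_invalid_template")
  if (w["r", "center"] != 0)
    ecgph_stop("R centre must be 0 (waves are R-relative)", "ecgph_invalid_template")
  ctr <- w[, "center"]
  nz <- w[, "amp"] != 0  # a zero-amplitude wave's centre is irrelevant
  ord <- ctr[c("p", "q", "r", "s", "t")]
  ok <- ord["p"] < ord["q"] && ord["q"] < 0 && 0 < ord["s"] && ord["s"] < ord["t"]
  if (any(nz[c("p", "q", "s", "t")]) && !ok)
    ecgph_stop("wave centres must be ordered P < Q < R = 0 < S < T",
               "ecgph_invalid_template")
  invisible(tmpl)
}

# continuous-time clean beat (and derivative), vectorised over t (seconds from R)
beat_value <- function(tmpl, t_rel) {
  w <- tmpl$waves
  out <- rep(tmpl$baseline, length(t_rel))
  for (i in seq_len(nrow(w))) {
    if (w[i, "amp"] == 0) next
    out <- out + w[i, "amp"] * exp(-(t_rel - w[i, "center"])^2 / (2 * w[i, "width"]^2))
  }
  out
}

beat_deriv <- function(tmpl, t_rel) {
  w <- tmpl$waves
  out <- numeric(length(t_rel))
  for (i in seq_len(nrow(w))) {
    if (w[i, "amp"] == 0) next
    d <- t_rel - w[i, "center"]
    out <- out - w[i, "amp"] * d / w[i, "width"]^2 * exp(-d^2 / (2 * w[i, "width"]^2))
  }
  out
}

#' Sample one beat cycle from a template
#'
#' Samples the Gaussian-sum beat over one cycle of length `rr`, spanning
#' `[-0.3 rr, 0.7 rr)` around the R peak (the same 30/70 split used when
#' beats are period-normalized downstream). The sample grid is aligned so
#' the R centre falls exactly on a sample.
#'
#' @param tmpl a [beat_template()].
#' @param rr cycle length (s), at least 0.25.
#' @param fs sampling rate (Hz), at least 128.
#' @return numeric vector of `round(rr * fs)` samples with attributes
#'   `r_index` (sample of the R centre), `truth` (see [beat_truth()]).
#' @export
generate_beat <- function(tmpl, rr, fs) {
  if (rr < 0.25) ecgph_stop("rr must be >= 0.25 s", "ecgph_invalid_config")
  if (fs < 128) ecgph_stop("fs must be >= 128 Hz", "ecgph_invalid_config")
  wt <- tmpl$waves["t", ]
  if (wt["amp"] != 0 && wt["center"] + 3 * wt["width"] > rr)
    ecgph_stop("T wave extends beyond the cycle (center + 3 widths > rr): degenerate morphology",
               "ecgph_degenerate_morphology")
  n <- round(rr * fs)
  r_index <- round(0.3 * rr * fs) + 1L
  t_rel <- (seq_len(n) - r_index) / fs
  x <- beat_value(tmpl, t_rel)
  structure(x, r_index = r_index, truth = beat_truth(tmpl))
}

#' Analytic ground truth of a beat template
#'
#' Closed-form morphological truth for a clean Gaussian-sum beat:
#' T amplitude is the T Gaussian amplitude; the steepest slope of the T
#' wave's terminal limb is `-amp * exp(-1/2) / width` (signed, negative for
#' an upright T); the tangent-method T end is exactly `center + 2 width`.
#' QRS onset uses the same tangent rule the delineator applies (steepest
#' R-upslope tangent intersected with the isoelectric baseline), evaluated
#' on a dense grid of the analytic waveform, and QT is T end minus onset.
#'
#' @param tmpl a [beat_template()].
#' @return list with `t_amp`, `tslope`, `t_peak`, `t_end`, `qrs_onset`, `qt`.
#' @export
beat_truth <- function(tmpl) {
  w <- tmpl$waves
  t_amp <- unname(w["t", "amp"])
  tslope <- -t_amp * exp(-0.5) / w["t", "width"]
  t_end <- unname(w["t", "center"] + 2 * w["t", "width"])
  onset <- qrs_onset_true(tmpl)
  list(t_amp = t_amp, tslope = unname(tslope),
       t_peak = unname(w["t", "center"]), t_end = t_end,
       qrs_onset = onset, qt = t_end - onset)
}

# QRS onset of the clean continuous beat by the tangent method: the tangent
# at the steepest point of the R upslope, intersected with the isoelectric
# baseline. For a pure Gaussian R this is exactly center - 2 width and, like
# the T-end tangent, it is unmoved by amplitude scaling and nearly unmoved by
# symmetric (zero-phase) smoothing.
qrs_onset_true <- function(tmpl, resolution = 1e-4) {
  grid <- seq(-0.08, 0, by = resolution)
  d <- beat_deriv(tmpl, grid)
  i <- which.max(d)
  x0 <- beat_value(tmpl, grid[i]) - tmpl$baseline
  unname(grid[i] - x0 / d[i])
}
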