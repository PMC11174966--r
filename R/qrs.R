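#' Pan-Tompkins detector parameters
#'
#' Constants of the QRS detector. Defaults follow common Pan-Tompkins /
#' Hamilton-Tompkins practice: 5-15 Hz band-pass emphasis, 150 ms
#' moving-window integration, 200 ms refractory period, exponential
#' signal/noise level tracking with a 1.66 x RR search-back for missed
#' beats. All thresholds are relative to the tracked levels, which makes
#' detection invariant to positive rescaling of the input.
#'
#' @param band band-pass emphasis corners (Hz).
#' @param integration_win moving-window integration length (s).
#' @param refractory minimum inter-beat distance (s).
#' @param searchback_factor missed-beat search-back multiple of the running
#'   RR average.
#' @param refine_win half-width (s) of the window in which a detection is
#'   refined to the local maximum of the input waveform.
#' @return list of class `qrs_params`.
#' @export
qrs_params <- function(band = c(5, 15), integration_win = 0.150,
                       refractory = 0.200, searchback_factor = 1.66,
                       refine_win = 0.080) {
  structure(list(band = band, integration_win = integration_win,
                 refractory = refractory, searchback_factor = searchback_factor,
                 refine_win = refine_win), class = "qrs_params")
}

# zero-phase 5-15 Hz emphasis, cached per fs
bandpass_emphasis <- function(x, fs, band) {
  key <- paste("bp", fs, band[1], band[2], sep = ",")
  if (is.null(.filter_cache[[key]]))
    .filter_cache[[key]] <- signal::butter(2, band / (fs / 2), type = "pass")
  filtfilt_fb(.filter_cache[[key]], x)
}

#' Detect R peaks (Pan-Tompkins style)
#'
#' Stages: zero-phase 5-15 Hz band-pass, centred five-point derivative,
#' squaring (the nonlinear transform emphasising QRS energy), centred
#' moving-window integration, then peak classification with dual adaptive
#' thresholds, a refractory period, and RR-based search-back for missed
#' beats. Each accepted detection is refined to the local maximum of the
#' input waveform within `refine_win`.
#'
#' @param segment an [ecg_segment] or numeric vector.
#' @param fs sampling rate (needed for a bare vector).
#' @param params a [qrs_params()].
#' @return integer vector of R-peak sample indices (possibly empty).
#' @export
detect_r_peaks <- function(segment, fs = NULL, params = qrs_params()) {
  x <- if (inherits(segment, "ecg_segment")) segment$samples else as.numeric(segment)
  if (inherits(segment, "ecg_segment")) fs <- segment$fs
  if (is.null(fs)) ecgph_stop("fs required", "ecgph_invalid_config")
  n <- length(x)
  if (n < fs) return(integer(0))
  if (max(x) - min(x) == 0) return(integer(0))

  bp <- bandpass_emphasis(x, fs, params$band)
  # centred five-point derivative
  d <- numeric(n)
  d[3:(n - 2)] <- (-bp[1:(n - 4)] - 2 * bp[2:(n - 3)] +
                     2 * bp[4:(n - 1)] + bp[5:n]) / 8
  sq <- d^2
  nw <- max(3L, round(params$integration_win * fs))
  if (nw %% 2 == 0) nw <- nw + 1L
  # centred moving average via cumulative sums (edges taper to zero)
  half <- (nw - 1L) %/% 2L
  cs <- cumsum(c(numeric(half + 1L), sq, numeric(half)))
  mwi <- (cs[(nw + 1L):(n + nw)] - cs[1:n]) / nw

  # candidate peaks: local maxima of the integrated signal
  pk <- which(diff(sign(diff(mwi))) < 0) + 1L
  pk <- pk[mwi[pk] > 0]
  if (!length(pk)) return(integer(0))

  init <- seq_len(min(n, round(2 * fs)))
  spki <- 0.5 * max(mwi[init])
  npki <- 0.5 * mean(mwi[init])
  refr <- round(params$refractory * fs)
  qrs <- integer(0)
  rr_buf <- numeric(0)
  for (i in seq_along(pk)) {
    p <- pk[i]
    v <- mwi[p]
    thr1 <- npki + 0.25 * (spki - npki)
    if (v >= thr1 && (!length(qrs) || p - qrs[length(qrs)] > refr)) {
      if (length(qrs)) rr_buf <- c(rr_buf, p - qrs[length(qrs)])
      if (length(rr_buf) > 8) rr_buf <- tail(rr_buf, 8)
      qrs <- c(qrs, p)
      spki <- 0.125 * v + 0.875 * spki
    } else {
      npki <- 0.125 * v + 0.875 * npki
    }
    # search-back: a long gap since the last QRS suggests a missed beat
    if (length(qrs) && length(rr_buf) >= 2) {
      gap_limit <- params$searchback_factor * mean(rr_buf)
      if (p - qrs[length(qrs)] > gap_limit) {
        thr2 <- 0.5 * (npki + 0.25 * (spki - npki))
        inwin <- pk[pk > qrs[length(qrs)] + refr & pk < p]
        inwin <- inwin[mwi[inwin] >= thr2]
        if (length(inwin)) {
          best <- inwin[which.max(mwi[inwin])]
          qrs <- sort(c(qrs, best))
          spki <- 0.25 * mwi[best] + 0.75 * spki
        }
      }
    }
  }
  if (!length(qrs)) return(integer(0))

  # refine to the local maximum of the input waveform
  w <- round(params$refine_win * fs)
  refined <- vapply(qrs, function(p) {
    lo <- max(1L, p - w); hi <- min(n, p + w)
    as.integer(lo + which.max(x[lo:hi]) - 1L)
  }, integer(1))
  refined <- sort(unique(refined))
  # collapse refinements that landed on the same maximum within refractory
  if (length(refined) > 1) {
    keep <- c(TRUE, diff(refined) > refr)
    refined <- refined[keep]
  }
  refined
}

#' Locate Q, R, S and QRS onset/offset for each beat
#'
#' For every detected R peak: Q is the waveform minimum between QRS onset
#' and R, S the minimum between R and QRS offset. Onset and offset are
#' located by the tangent method: the tangent at the steepest point of the
#' R upslope (respectively the steepest post-S return limb), intersected
#' with the isoelectric baseline taken as the median over the window 80 to
#' 55 ms before R. The tangent rule is insensitive to amplitude scaling and
#' to the symmetric smoothing of the zero-phase filter cascade, which is
#' why it is preferred over a raw derivative threshold here and reused for
#' the T end. RR intervals, their mean (RRAvg) and HR = 60 / RRAvg are
#' derived from the R series.
#'
#' @param segment an [ecg_segment] or numeric vector.
#' @param r_peaks integer vector of R indices (at least 2).
#' @param fs sampling rate (needed for a bare vector).
#' @return object of class `qrs_annotation`: list with `beats` (data.frame
#'   `beat, onset, q, r, s, offset`, sample indices), `rr` (s), `rravg` (s),
#'   `hr` (bpm), `fs`.
#' @export
locate_qrs_points <- function(segment, r_peaks, fs = NULL) {
  x <- if (inherits(segment, "ecg_segment")) segment$samples else as.numeric(segment)
  if (inherits(segment, "ecg_segment")) fs <- segment$fs
  if (length(r_peaks) < 2)
    ecgph_stop("at least 2 R peaks are required", "ecgph_insufficient_beats")
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
  w80 <- round(0.080 * fs)
  w55 <- round(0.055 * fs)
  rows <- matrix(NA_integer_, nrow = length(r_peaks), ncol = 5,
                 dimnames = list(NULL, c("onset", "q", "r", "s", "offset")))
  for (b in seq_along(r_peaks)) {
    r <- r_peaks[b]
    lo <- max(1L, r - w80); hi <- min(n, r + w80)
    if (r - lo < 3 || hi - r < 3) next
    baseline <- median(x[lo:max(lo + 1L, r - w55)])
    # onset: tangent at the steepest R upslope, intersected with the baseline
    pre <- lo:r
    a1 <- pre[which.max(d[pre])]
    onset <- if (d[a1] > 0)
      as.integer(round(a1 + (baseline - x[a1]) * fs / d[a1])) else lo
    onset <- max(lo, min(onset, r - 3L))
    # offset: tangent at the steepest post-S return limb
    post <- (r + 1L):hi
    a2 <- post[which.max(d[post])]
    offset <- if (d[a2] > 0)
      as.integer(round(a2 + (baseline - x[a2]) * fs / d[a2])) else hi
    offset <- min(hi, max(offset, r + 3L))
    # troughs inside the tangent-bounded complex
    q_i <- onset + which.min(x[(onset + 1L):(r - 1L)])
    s_i <- r + which.min(x[(r + 1L):(offset - 1L)])
    if (!(onset < q_i && q_i < r && r < s_i && s_i < offset)) next
    rows[b, ] <- c(onset, q_i, r, s_i, offset)
  }
  rows <- rows[!is.na(rows[, "r"]), , drop = FALSE]
  if (nrow(rows) < 2)
    ecgph_stop("fewer than 2 delineable beats", "ecgph_insufficient_beats")
  beats <- data.frame(beat = seq_len(nrow(rows)), rows)
  rr <- diff(r_peaks) / fs
  rravg <- mean(rr)
  structure(list(beats = beats, rr = rr, rravg = rravg, hr = 60 / rravg, fs = fs),
            class = "qrs_annotation")
}

#' @export
print.qrs_annotation <- function(x, ...) {
  cat(sprintf("<qrs_annotation: %d beats, RRAvg %.3f s, HR %.1f bpm>\n",
              nrow(x$beats), x$rravg, x$hr))
  invisible(x)
}

#' Segment quality gate
#'
#' Rejects a segment whose beat series suggests failed detection or missing
#' cycles. Rules, in order: fewer than `min_beats` beats; implied HR outside
#' `hr_range`; any RR exceeding `rr_gap_ratio` times the median RR (a missed
#' cycle); RR coefficient of variation above `rr_cv_max`. The verdict names
#' the rule that fired.
#'
#' @param ann a [locate_qrs_points()] annotation, or `NULL` / a bare count
#'   of detections when annotation was impossible.
#' @param min_beats minimum beats per segment.
#' @param hr_range admissible HR interval (bpm).
#' @param rr_gap_ratio missed-cycle threshold on RR / median RR.
#' @param rr_cv_max maximum RR coefficient of variation.
#' @return list of class `quality_verdict` with `accepted` and `reason`.
#' @export
quality_gate <- function(ann, min_beats = 6, hr_range = c(60, 250),
                         rr_gap_ratio = 1.8, rr_cv_max = 0.25) {
  n_beats <- if (inherits(ann, "qrs_annotation")) nrow(ann$beats)
             else if (is.numeric(ann)) as.integer(ann)
             else 0L
  verdict <- function(accepted, reason = NA_character_)
    structure(list(accepted = accepted, reason = reason), class = "quality_verdict")
  if (n_beats < min_beats) return(verdict(FALSE, "beat-count"))
  if (ann$hr < hr_range[1] || ann$hr > hr_range[2]) return(verdict(FALSE, "hr-range"))
  if (any(ann$rr > rr_gap_ratio * median(ann$rr))) return(verdict(FALSE, "missed-cycle"))
  if (sd(ann$rr) / mean(ann$rr) > rr_cv_max) return(verdict(FALSE, "rr-variability"))
  verdict(TRUE)
}

#' @export
print.quality_verdict <- function(x, ...) {
  cat(if (x$accepted) "accepted\n" else sprintf("rejected (%s)\n", x$reason))
  invisible(x)
}

#' Export a QRS annotation as CSV
#'
#' One row per beat with 0-based sample indices, columns
#' `beat,onset,q,r,s,offset`.
#'
#' @param ann a `qrs_annotation`.
#' @param path output file.
#' @export
write_annotation <- function(ann, path) {
  b <- ann$beats
  b[, c("onset", "q", "r", "s", "offset")] <-
    b[, c("onset", "q", "r", "s", "offset")] - 1L
  write.csv(b, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
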