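#' ECG segment adjacent to a blood-gas event
#'
#' One-channel excerpt tied to a blood-gas sampling event and its pH value.
#' Constructed by [extract_segments()]; carries normalization metadata once
#' [normalize_segment()] has been applied so physical amplitudes stay
#' recoverable.
#'
#' @param samples numeric vector (mV, or normalized units).
#' @param fs sampling rate (Hz).
#' @param ph blood pH attached to the source event (plausibility 6.5-8.0).
#' @param side `"preceding"` or `"following"` the event.
#' @param event_id identifier of the source event.
#' @param t0 record time (s) of the first sample.
#' @param norm `NULL`, or `list(offset, scale)` after normalization.
#' @return object of class `ecg_segment`.
#' @export
ecg_segment <- function(samples, fs, ph, side = c("following", "preceding"),
                        event_id = NULL, t0 = 0, norm = NULL) {
  side <- match.arg(side)
  if (!is.numeric(samples) || !length(samples))
    ecgph_stop("segment samples must be a non-empty numeric vector", "ecgph_invalid_segment")
  if (!is.na(ph) && (ph < 6.5 || ph > 8.0))
    ecgph_stop(sprintf("pH %.3f outside plausibility bounds [6.5, 8.0]", ph),
               "ecgph_invalid_ph")
  structure(list(samples = as.numeric(samples), fs = fs, ph = ph, side = side,
                 event_id = event_id, t0 = t0, norm = norm),
            class = "ecg_segment")
}

#' @export
print.ecg_segment <- function(x, ...) {
  cat(sprintf("<ecg_segment %s (%s): %.1f s at %g Hz, pH %.2f%s>\n",
              x$event_id %||% "?", x$side, length(x$samples) / x$fs, x$fs, x$ph,
              if (is.null(x$norm)) "" else ", normalized"))
  invisible(x)
}

#' Extract event-adjacent segments from a record
#'
#' For every blood-gas event, cuts up to two segments of `seg_len` seconds:
#' one immediately preceding (`[t - seg_len, t)`) and one immediately
#' following (`[t, t + seg_len)`) the sampling time, the windows where the
#' ECG is temporally closest to the blood draw. Segments truncated by the
#' record edges are kept if at least `min_len` seconds survive, otherwise
#' dropped; events outside the record span are skipped with a warning.
#'
#' @param record an [ecg_record].
#' @param events data.frame with columns `time_s` and `ph`.
#' @param seg_len segment length (s).
#' @param min_len minimum accepted truncated length (s).
#' @param channel channel to extract (default 1).
#' @param sides which sides to cut: `"both"`, `"preceding"` or `"following"`.
#' @return list of [ecg_segment] objects.
#' @export
extract_segments <- function(record, events, seg_len = 10, min_len = 8,
                             channel = 1, sides = c("both", "preceding", "following")) {
  stopifnot(inherits(record, "ecg_record"))
  sides <- match.arg(sides)
  if (seg_len <= 0) ecgph_stop("seg_len must be > 0", "ecgph_invalid_config")
  if (!all(c("time_s", "ph") %in% names(events)))
    ecgph_stop("events table must have columns time_s and ph", "ecgph_parse_error")
  n <- nrow(record$samples)
  t_end <- record$start + n / record$fs
  segs <- list()
  for (i in seq_len(nrow(events))) {
    ev_t <- events$time_s[i]
    ev_ph <- events$ph[i]
    ev_id <- sprintf("%s-ev%d", record$id %||% "rec", i)
    if (ev_t < record$start || ev_t > t_end) {
      warning(sprintf("event %d at t = %.2f s outside record span [%.2f, %.2f]; skipped",
                      i, ev_t, record$start, t_end))
      next
    }
    for (side in c("preceding", "following")) {
      if (sides != "both" && side != sides) next
      win <- if (side == "preceding") c(ev_t - seg_len, ev_t) else c(ev_t, ev_t + seg_len)
      lo <- max(win[1], record$start)
      hi <- min(win[2], t_end)
      if (hi - lo < min_len) next
      i0 <- floor((lo - record$start) * record$fs) + 1L
      i1 <- i0 + round((hi - lo) * record$fs) - 1L
      i1 <- min(i1, n)
      segs[[length(segs) + 1L]] <-
        ecg_segment(record$samples[i0:i1, channel], fs = record$fs, ph = ev_ph,
                    side = side, event_id = ev_id,
                    t0 = record$start + (i0 - 1L) / record$fs)
    }
  }
  segs
}

#' Filtering parameters of the preprocessing cascade
#'
#' @param hp_cutoff high-pass cutoff (Hz) removing baseline wander.
#' @param lp_cutoff low-pass cutoff (Hz) removing high-frequency noise.
#' @param notch_freq mains frequency (Hz).
#' @param notch_q notch quality factor (bandwidth = freq / Q).
#' @param order Butterworth order for high- and low-pass.
#' @param sg_order,sg_window Savitzky-Golay polynomial order and window
#'   length (samples, odd).
#' @return list of class `filter_params`.
#' @export
filter_params <- function(hp_cutoff = 0.5, lp_cutoff = 100, notch_freq = 50,
                          notch_q = 30, order = 4, sg_order = 3, sg_window = 15) {
  structure(list(hp_cutoff = hp_cutoff, lp_cutoff = lp_cutoff,
                 notch_freq = notch_freq, notch_q = notch_q, order = order,
                 sg_order = sg_order, sg_window = sg_window),
            class = "filter_params")
}

# Zero-phase (forward-backward) ARMA filtering with reflective edge padding.
# Equivalent to signal::filtfilt away from the edges but avoids its ts-object
# overhead, which matters when thousands of segments are processed.
filtfilt_fb <- function(flt, x) {
  b <- flt$b; a <- flt$a
  one_pass <- function(z) {
    nb <- length(b)
    y <- stats::filter(c(numeric(nb - 1), z), b, method = "convolution", sides = 1)
    y <- as.numeric(y)[nb:(nb + length(z) - 1)]
    if (length(a) > 1) y <- as.numeric(stats::filter(y, -a[-1], method = "recursive"))
    y
  }
  npad <- 3 * (max(length(a), length(b)) - 1)
  n <- length(x)
  # filter about the signal mean and restore it through the filter's DC gain:
  # a high-pass then kills a constant input exactly instead of leaving a
  # slowly decaying start-up transient (its slowest pole rings for seconds)
  mu <- mean(x)
  g0 <- (sum(b) / sum(a))^2  # DC gain of the forward-backward pass
  x <- x - mu
  xp <- c(2 * x[1] - x[(npad + 1):2], x, 2 * x[n] - x[(n - 1):(n - npad)])
  y <- one_pass(xp)
  y <- rev(one_pass(rev(y)))
  y[(npad + 1):(npad + n)] + mu * g0
}

# Butterworth designs are fs-dependent; cache per (fs, params)
.filter_cache <- new.env(parent = emptyenv())
cascade_filters <- function(fs, fp) {
  key <- paste(c(fs, unlist(fp)), collapse = ",")
  if (is.null(.filter_cache[[key]])) {
    nyq <- fs / 2
    bw <- fp$notch_freq / fp$notch_q
    .filter_cache[[key]] <- list(
      hp = signal::butter(fp$order, fp$hp_cutoff / nyq, type = "high"),
      lp = signal::butter(fp$order, fp$lp_cutoff / nyq, type = "low"),
      notch = signal::butter(2, c(fp$notch_freq - bw / 2, fp$notch_freq + bw / 2) / nyq,
                             type = "stop"))
  }
  .filter_cache[[key]]
}

#' Apply the preprocessing filter cascade
#'
#' In order: 0.5 Hz high-pass Butterworth (baseline wander), 100 Hz low-pass
#' Butterworth (EMG and acquisition noise), 50 Hz notch (power-line
#' interference), then Savitzky-Golay smoothing. The IIR stages are applied
#' forward-backward (zero phase) and the Savitzky-Golay stage is a symmetric
#' FIR, so fiducial points are not displaced -- essential because QT and
#' other timing features are measured downstream.
#'
#' @param segment an [ecg_segment] (or plain numeric vector with `fs`).
#' @param params a [filter_params()].
#' @param fs sampling rate, only needed when `segment` is a bare vector.
#' @return the filtered segment (same class and length as the input).
#' @export
filter_segment <- function(segment, params = filter_params(), fs = NULL) {
  bare <- !inherits(segment, "ecg_segment")
  x <- if (bare) as.numeric(segment) else segment$samples
  fs <- if (bare) fs else segment$fs
  if (is.null(fs)) ecgph_stop("fs required for a bare vector", "ecgph_invalid_config")
  if (fs <= 2 * params$lp_cutoff)
    ecgph_stop(sprintf("fs = %g Hz must exceed twice the low-pass cutoff (%g Hz)",
                       fs, params$lp_cutoff), "ecgph_invalid_config")
  flt <- cascade_filters(fs, params)
  y <- filtfilt_fb(flt$hp, x)
  y <- filtfilt_fb(flt$lp, y)
  y <- filtfilt_fb(flt$notch, y)
  y <- signal::sgolayfilt(y, p = params$sg_order, n = params$sg_window)
  if (bare) return(y)
  segment$samples <- y
  segment
}

#' Min-max normalize a segment to [0, 1]
#'
#' Maps the samples to the unit interval and stores the offset and scale in
#' the segment metadata so physical amplitudes remain recoverable (see
#' [denormalize_segment()]). Idempotent: normalizing an already-unit-range
#' segment changes nothing. Any positive affine transform of the input
#' yields the identical normalized output.
#'
#' @param segment an [ecg_segment].
#' @return the normalized segment with `norm = list(offset, scale)`.
#' @export
normalize_segment <- function(segment) {
  stopifnot(inherits(segment, "ecg_segment"))
  rng <- range(segment$samples)
  scale <- rng[2] - rng[1]
  if (scale == 0)
    ecgph_stop("constant signal cannot be normalized", "ecgph_degenerate_signal")
  prev <- segment$norm
  segment$samples <- (segment$samples - rng[1]) / scale
  # compose with any previous normalization so offset/scale always map back to mV
  if (is.null(prev)) {
    segment$norm <- list(offset = rng[1], scale = scale)
  } else {
    segment$norm <- list(offset = prev$offset + prev$scale * rng[1],
                         scale = prev$scale * scale)
  }
  segment
}

#' Undo min-max normalization
#'
#' @param segment a normalized [ecg_segment].
#' @return the segment on the physical (mV) scale.
#' @export
denormalize_segment <- function(segment) {
  if (is.null(segment$norm)) return(segment)
  segment$samples <- segment$samples * segment$norm$scale + segment$norm$offset
  segment$norm <- NULL
  segment
}

# physical-scale samples without mutating the segment
physical_samples <- function(segment) {
  if (is.null(segment$norm)) segment$samples
  else segment$samples * segment$norm$scale + segment$norm$offset
}
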