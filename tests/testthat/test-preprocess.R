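fs <- 256

test_that("segment extraction cuts both event-adjacent windows", {
  rec <- ecg_record(matrix(rnorm(120 * fs), ncol = 1), fs = fs)
  events <- data.frame(time_s = 60, ph = 7.3)
  segs <- extract_segments(rec, events)
  expect_length(segs, 2)
  expect_setequal(vapply(segs, `[[`, character(1), "side"),
                  c("preceding", "following"))
  expect_true(all(vapply(segs, function(s) length(s$samples), numeric(1)) == 2560))
  expect_true(all(vapply(segs, `[[`, numeric(1), "ph") == 7.3))
  # window positions: [t-10, t) and [t, t+10)
  pre <- segs[[which(vapply(segs, `[[`, character(1), "side") == "preceding")]]
  expect_equal(pre$t0, 50)
})

test_that("edge events keep only the feasible side; short remnants are dropped", {
  rec <- ecg_record(matrix(rnorm(30 * fs), ncol = 1), fs = fs)
  segs <- extract_segments(rec, data.frame(time_s = 5, ph = 7.3))
  expect_length(segs, 1)
  expect_equal(segs[[1]]$side, "following")
  # 9 s available before the event: truncated preceding segment is kept (>= 8 s)
  segs2 <- extract_segments(rec, data.frame(time_s = 9, ph = 7.3))
  sides <- vapply(segs2, `[[`, character(1), "side")
  expect_setequal(sides, c("preceding", "following"))
  pre <- segs2[[which(sides == "preceding")]]
  expect_equal(length(pre$samples) / fs, 9, tolerance = 1e-6)
  # out-of-span event: skipped with a warning, not fatal
  expect_warning(segs3 <- extract_segments(rec, data.frame(time_s = 99, ph = 7.3)),
                 "outside record span")
  expect_length(segs3, 0)
})

test_that("segment count equals the sum of feasible sides over records", {
  n_segs <- 0
  for (k in 1:5) {
    rec <- ecg_record(matrix(rnorm(40 * fs), ncol = 1), fs = fs)
    ev <- data.frame(time_s = c(3, 20, 38), ph = c(7.1, 7.3, 7.5))
    feasible <- sum(c(3, 20, 38) >= 8, 40 - c(3, 20, 38) >= 8)
    n_segs <- n_segs + length(extract_segments(rec, ev))
    expect_length(extract_segments(rec, ev), feasible)
  }
  expect_equal(n_segs, 5 * 4)
})

test_that("filter cascade removes DC, mains and drift but passes the QRS band", {
  tt <- (0:(10 * fs - 1)) / fs
  mid <- (2 * fs):(8 * fs)
  rms <- function(x) sqrt(mean(x^2))
  # DC: removed almost entirely
  dc <- filter_segment(rep(2, 10 * fs), fs = fs)
  expect_lt(max(abs(dc[mid])) / 2, 1e-6)
  # 50 Hz tone: >= 30 dB down
  x50 <- sin(2 * pi * 50 * tt)
  expect_lt(rms(filter_segment(x50, fs = fs)[mid]) / rms(x50[mid]), 0.03)
  # 10 Hz tone (QRS band): <= 1 dB loss
  x10 <- sin(2 * pi * 10 * tt)
  expect_gt(rms(filter_segment(x10, fs = fs)[mid]) / rms(x10[mid]), 0.9)
  # 0.25 Hz baseline wander: strongly attenuated
  xbw <- sin(2 * pi * 0.25 * tt)
  expect_lt(rms(filter_segment(xbw, fs = fs)[mid]) / rms(xbw[mid]), 0.2)
})

test_that("cascade attenuations agree with the analytic frequency response", {
  # independent oracle: |H| of the designed filters evaluated analytically,
  # squared for the forward-backward pass, times the Savitzky-Golay FIR gain
  fp <- filter_params()
  flt <- ecgph:::cascade_filters(fs, fp)
  gain <- function(flt_obj, f) {
    w <- 2 * pi * f / fs
    h <- sum(flt_obj$b * exp(-1i * w * (seq_along(flt_obj$b) - 1))) /
      sum(flt_obj$a * exp(-1i * w * (seq_along(flt_obj$a) - 1)))
    Mod(h)^2  # filtfilt applies the magnitude twice
  }
  sg <- signal::sgolay(p = fp$sg_order, n = fp$sg_window)[(fp$sg_window + 1) / 2, ]
  sg_gain <- function(f) Mod(sum(sg * exp(-1i * 2 * pi * f *
                                            (-(fp$sg_window - 1) / 2):((fp$sg_window - 1) / 2) / fs)))
  for (f in c(10, 50)) {
    analytic <- gain(flt$hp, f) * gain(flt$lp, f) * gain(flt$notch, f) * sg_gain(f)
    tt <- (0:(10 * fs - 1)) / fs
    mid <- (2 * fs):(8 * fs)
    x <- sin(2 * pi * f * tt)
    measured <- sqrt(mean(filter_segment(x, fs = fs)[mid]^2)) / sqrt(mean(x[mid]^2))
    expect_equal(measured, analytic, tolerance = 0.02)
  }
})

test_that("cascade is linear and keeps its output length", {
  set.seed(42)
  x <- rnorm(2560); y <- rnorm(2560)
  fx <- filter_segment(x, fs = fs)
  fy <- filter_segment(y, fs = fs)
  fxy <- filter_segment(x + y, fs = fs)
  expect_equal(fxy, fx + fy, tolerance = 1e-6)
  expect_length(fx, 2560)
  expect_error(filter_segment(x, fs = 180), class = "ecgph_invalid_config")
})

test_that("zero-phase contract: R peaks move at most one sample", {
  cs <- clean_segment(hr = 130, seed = 8)
  raw <- cs$raw$samples
  filt <- filter_segment(cs$raw)$samples
  true_r <- truth_r_samples(cs$truth, cs$raw)
  for (r0 in round(true_r[3:10])) {
    win <- (r0 - 10):(r0 + 10)
    expect_lte(abs(which.max(raw[win]) - which.max(filt[win])), 1)
  }
})

test_that("min-max normalization is exact, idempotent and affine-invariant", {
  seg <- ecg_segment(c(-1, 0, 1), fs = 3, ph = 7.3)
  nrm <- normalize_segment(seg)
  expect_equal(nrm$samples, c(0, 0.5, 1))
  expect_equal(nrm$norm$offset, -1)
  expect_equal(nrm$norm$scale, 2)
  # idempotence
  again <- normalize_segment(nrm)
  expect_equal(again$samples, nrm$samples)
  expect_equal(again$norm, nrm$norm)
  # round trip to physical units
  expect_equal(denormalize_segment(nrm)$samples, seg$samples)
  # any positive affine map yields the identical normalized trace
  set.seed(7)
  x <- rnorm(100)
  base <- normalize_segment(ecg_segment(x, fs = 10, ph = 7.3))$samples
  for (k in 1:20) {
    a <- runif(1, 0.1, 10); b <- runif(1, -5, 5)
    tr <- normalize_segment(ecg_segment(a * x + b, fs = 10, ph = 7.3))$samples
    expect_equal(tr, base, tolerance = 1e-12)
  }
  expect_error(normalize_segment(ecg_segment(rep(1, 10), fs = 10, ph = 7.3)),
               class = "ecgph_degenerate_signal")
})
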