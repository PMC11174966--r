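# run one clean segment through the full measurement chain
measure_segment <- function(hr = 140, seed = 1, template = beat_template()) {
  cs <- clean_segment(hr = hr, seed = seed, template = template)
  ann <- locate_qrs_points(cs$segment, detect_r_peaks(cs$segment))
  rc <- extract_representative(build_cycle_matrix(cs$segment, ann))
  tw <- delineate_t(rc, ann)
  list(ann = ann, rc = rc, tw = tw, truth = cs$truth,
       fv = compute_features(rc, ann, tw, ph = cs$truth$ph, segment_id = "seg"))
}

test_that("T peak, amplitude and slope recover the Gaussian ground truth", {
  m <- measure_segment(hr = 130, seed = 3)
  tmpl <- m$truth$template
  expect_equal(m$tw$t_amp, m$truth$t_amp[1], tolerance = 0.05)
  tt <- ecgph:::cycle_time(m$rc)
  expect_lt(abs(tt[m$tw$t_peak_idx] - tmpl$waves["t", "center"]), 0.010)
  expect_equal(m$tw$tslope, m$truth$tslope[1], tolerance = 0.10)
})

test_that("an inverted T flips the amplitude and slope signs", {
  tmpl_inv <- beat_template(t = c(-0.25, 0.17, 0.04))
  up <- measure_segment(hr = 130, seed = 3)
  dn <- measure_segment(hr = 130, seed = 3, template = tmpl_inv)
  expect_gt(up$tw$t_amp, 0)
  expect_lt(dn$tw$t_amp, 0)
  expect_lt(up$tw$tslope, 0)
  expect_gt(dn$tw$tslope, 0)
  # the sign convention's footprint: Tslope/T is invariant under inversion,
  # Tslope/|T| flips
  expect_equal(dn$fv$tslope_t, up$fv$tslope_t, tolerance = 0.15)
  expect_lt(dn$fv$tslope_abs_t * up$fv$tslope_abs_t, 0)
})

test_that("feature formulas follow their definitions", {
  m <- measure_segment(hr = 140, seed = 6)
  fv <- m$fv
  expect_equal(fv$qtc, fv$qt / sqrt(fv$rravg))
  expect_equal(fv$hr, 60 / fv$rravg)
  expect_equal(fv$tslope_t, fv$tslope / fv$t_amplitude)
  expect_equal(fv$tslope_abs_t, fv$tslope / abs(fv$t_amplitude))
  expect_equal(fv$tslope_sqrt_abs_t, fv$tslope / sqrt(abs(fv$t_amplitude)))
  # Bazett reference points
  expect_equal(0.28 / sqrt(1), 0.28)
  expect_equal(0.28 / sqrt(0.444), 0.4202, tolerance = 1e-4)
  # T/QRS with known amplitudes: 0.25 / 1.25 = 0.2
  expect_equal(0.25 / 1.25, 0.2)
  expect_named(fv, c("segment_id", "t_qrs", "t_amplitude", "tslope", "tslope_t",
                     "tslope_abs_t", "tslope_sqrt_abs_t", "hr", "qt", "qtc",
                     "rravg", "ph", "group"))
})

test_that("ratio features are missing, not infinite, for a vanished T", {
  m <- measure_segment(hr = 140, seed = 6)
  tw0 <- m$tw
  tw0$t_amp <- 0
  fv <- compute_features(m$rc, m$ann, tw0, ph = 7.3)
  expect_true(is.na(fv$tslope_t))
  expect_true(is.na(fv$tslope_abs_t))
  expect_true(is.na(fv$tslope_sqrt_abs_t))
  expect_false(is.na(fv$qt))
})

test_that("amplitude-ratio features are scale invariant, amplitudes scale", {
  cs <- clean_segment(hr = 130, seed = 12)
  ann <- locate_qrs_points(cs$segment, detect_r_peaks(cs$segment))
  measure <- function(gain) {
    seg <- cs$segment
    seg$samples <- seg$samples  # normalized trace
    seg$norm$scale <- seg$norm$scale * gain
    seg$norm$offset <- seg$norm$offset * gain
    rc <- extract_representative(build_cycle_matrix(seg, ann))
    tw <- delineate_t(rc, ann)
    compute_features(rc, ann, tw, ph = 7.3)
  }
  base <- measure(1)
  for (a in c(0.5, 3)) {
    fv <- measure(a)
    for (col in c("t_qrs", "tslope_t", "tslope_abs_t", "hr", "qt", "qtc", "rravg"))
      expect_equal(fv[[col]], base[[col]], tolerance = 1e-9, label = col)
    expect_equal(fv$t_amplitude, a * base$t_amplitude, tolerance = 1e-9)
    expect_equal(fv$tslope, a * base$tslope, tolerance = 1e-9)
    expect_equal(fv$tslope_sqrt_abs_t, sqrt(a) * base$tslope_sqrt_abs_t,
                 tolerance = 1e-9)
  }
})

test_that("time dilation scales HR, QT, RRAvg and QTc as expected", {
  # resampling the record by c dilates time: HR -> HR/c, QT/RRAvg -> c *,
  # QTc -> sqrt(c) *; emulate by generating at a proportionally lower HR and
  # a dilated template
  c_fac <- 1.25
  base <- measure_segment(hr = 140, seed = 31)
  tmpl <- beat_template()
  tmpl_d <- beat_template(p = tmpl$waves["p", ] * c(1, c_fac, c_fac),
                          q = tmpl$waves["q", ] * c(1, c_fac, c_fac),
                          r = c(1, 0, tmpl$waves["r", "width"] * c_fac),
                          s = tmpl$waves["s", ] * c(1, c_fac, c_fac),
                          t = tmpl$waves["t", ] * c(1, c_fac, c_fac))
  dil <- measure_segment(hr = 140 / c_fac, seed = 31, template = tmpl_d)
  expect_equal(dil$fv$hr, base$fv$hr / c_fac, tolerance = 0.02)
  expect_equal(dil$fv$rravg, base$fv$rravg * c_fac, tolerance = 0.02)
  expect_equal(dil$fv$qt, base$fv$qt * c_fac, tolerance = 0.05)
  expect_equal(dil$fv$qtc, base$fv$qtc * sqrt(c_fac), tolerance = 0.05)
})

test_that("parameter recovery holds across a clean cohort", {
  errs <- t(sapply(1:15, function(k) {
    m <- measure_segment(hr = 120 + 3 * k, seed = 400 + k)
    c(hr = abs(m$ann$hr - m$truth$hr),
      qt = abs(m$tw$qt - m$truth$qt[1]),
      ta = abs(m$tw$t_amp / m$truth$t_amp[1] - 1),
      ts = abs(m$tw$tslope / m$truth$tslope[1] - 1))
  }))
  expect_lte(median(errs[, "hr"]), 1)
  expect_lte(median(errs[, "qt"]), 0.010)
  expect_lte(median(errs[, "ta"]), 0.05)
  expect_lte(median(errs[, "ts"]), 0.10)
})
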