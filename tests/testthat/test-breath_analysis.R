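test_that("paced flow segments into the programmed breaths", {
  fl <- generate_flow(default_breathing_program()$CR6, duration = 120,
                      fs = 100, vt_cv = 0, noise_sd = 0)
  br <- segment_breaths(fl)
  expect_equal(nrow(br), 12L)
  expect_true(all(abs(br$ti - 5) < 0.05))
  expect_true(all(abs(br$te - 5) < 0.05))
  # detected period sum bounded by epoch duration
  expect_lte(sum(br$ti + br$te), 120)
  expect_gte(sum(br$ti + br$te), 120 - 2 * 10)
  # volumes conserve mass per breath
  expect_true(all(abs(br$vt_insp - br$vt_exp) / br$vt_insp < 0.05))
})

test_that("hysteresis keeps the breath count stable under noise", {
  set.seed(2)
  fl <- generate_flow(default_breathing_program()$CR6, duration = 120,
                      fs = 100, vt_cv = 0, noise_sd = 0.01)
  expect_equal(nrow(segment_breaths(fl)), 12L)
})

test_that("degenerate flows raise the insufficient-breaths error", {
  expect_error(segment_breaths(flow_signal(rep(0, 1200), 100)),
               "insufficient breaths")
  one <- generate_flow(default_breathing_program()$CR6, duration = 10,
                       fs = 100, vt_cv = 0, noise_sd = 0)
  expect_error(segment_breaths(one), "insufficient breaths")
})

test_that("pattern indices follow their defining arithmetic", {
  br <- data.frame(t_start = c(0, 10, 20), ti = 5, te = 5,
                   vt_insp = 1.7, vt_exp = 1.7)
  p <- pattern_indices(br)
  expect_equal(p$rr_breath, 6.0)
  expect_equal(p$v_minute, 10.2)
  expect_equal(p$ti_frac, 0.5)
  expect_equal(p$vo2, 0.046 * 10.2)
  br2 <- data.frame(t_start = c(0, 4), ti = 2, te = 2,
                    vt_insp = 0.89, vt_exp = 0.89)
  expect_equal(pattern_indices(br2)$vt_over_ti, 0.445)
  expect_error(pattern_indices(br[0, ]), "at least 2 breaths")
})

test_that("the uptake/ventilation ratio reproduces the reference medians", {
  # constant-fraction model: uptake at the reference CR6 / CR15 ventilations
  expect_equal(vo2_from_ventilation(11.050, 0.046), 0.508, tolerance = 0.002)
  expect_equal(vo2_from_ventilation(13.740, 0.046), 0.632, tolerance = 0.002)
})

test_that("ventilation event series carries expiratory mean flow in L/min", {
  br <- data.frame(t_start = c(0, 10, 20), ti = 5, te = 5,
                   vt_insp = 1.7, vt_exp = 1.7)
  vs <- ventilation_series(br)
  expect_equal(vs$value, rep(20.4, 3))
  # alternating volumes: series variance equals the two-point variance
  br2 <- data.frame(t_start = seq(0, 90, by = 10), ti = 5, te = 5,
                    vt_insp = rep(c(1.5, 1.9), 5),
                    vt_exp = rep(c(1.5, 1.9), 5))
  vs2 <- ventilation_series(br2)
  expect_equal(stats::var(vs2$value),
               stats::var(60 * rep(c(1.5, 1.9), 5) / 5))
  expect_error(ventilation_series(br[1, ]), "at least 2 breaths")
})

test_that("ventilation waveform keeps the per-breath level as its envelope", {
  br <- data.frame(t_start = seq(0, 110, by = 10), ti = 5, te = 5,
                   vt_insp = 1.7, vt_exp = 1.7)
  w <- ventilation_waveform(br, fs = 4)
  # per-breath mean of the raised-cosine shape equals 60*vt_exp/te;
  # detrending removes that constant level, so the residual mean is ~0
  expect_lt(abs(mean(w$y)), 1e-9)
  # the waveform's spectral line sits at the breathing frequency (0.1 Hz)
  p <- band_powers(w)
  expect_gt(p$lfn, 90)
})

test_that("the uptake fraction is constant across epochs", {
  rec <- generate_subject(sim_config(seed = 31))$record
  fr <- vapply(c("SR", "CR6", "CR15"), function(lab) {
    br <- segment_breaths(slice_epoch(rec, lab)$flow)
    p <- pattern_indices(br)
    p$vo2 / p$v_minute
  }, numeric(1))
  expect_equal(unname(fr), rep(0.046, 3), tolerance = 1e-12)
})
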