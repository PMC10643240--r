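test_that("paced flow programs emit exact breath counts and per-breath volumes", {
  fl <- generate_flow(default_breathing_program()$CR6, duration = 120,
                      fs = 100, vt_cv = 0, noise_sd = 0)
  br <- attr(fl, "breaths")
  expect_equal(nrow(br), 12L)
  # integral of the positive lobe equals V_T within 1% per breath
  t <- (seq_along(fl$samples) - 1L) / fl$fs
  for (k in seq_len(nrow(br))) {
    idx <- t >= br$t_start[k] & t < br$t_start[k] + br$ti[k]
    expect_equal(sum(fl$samples[idx]) / fl$fs, 1.7, tolerance = 0.01)
  }
  # mass conservation over the whole record
  expect_lt(abs(mean(fl$samples)), 0.01)
})

test_that("noiseless paced flow is periodic at the programmed period", {
  fl <- generate_flow(default_breathing_program()$CR15, duration = 120,
                      fs = 100, vt_cv = 0, noise_sd = 0)
  x <- fl$samples
  lag <- 4 * 100                      # 2 s in + 2 s out = 4.0 s
  expect_equal(x[seq_len(length(x) - lag)], x[-seq_len(lag)],
               tolerance = 1e-10)
  expect_error(
    generate_flow(list(type = "paced", ti = 2, te = 2, vt = 0.9),
                  duration = 120, fs = 4),
    "sampling rate too low")
})

test_that("spontaneous breathing rate is calibrated (Monte-Carlo)", {
  set.seed(1)
  rates <- replicate(100, {
    fl <- generate_flow(default_breathing_program()$SR, duration = 120,
                        fs = 100, vt_cv = 0.07, noise_sd = 0.01)
    br <- segment_breaths(fl)
    60 / mean(br$ti + br$te)
  })
  se <- stats::sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - 14.2), 2 * se)
})

test_that("unmodulated IPFM emits perfectly regular beats", {
  cfg <- sim_config(seed = 1, mean_rr = 1000, rsa_gain = 0, lf_amp_rr = 0,
                    lf_amp_sbp = 0, lf_amp_dbp = 0, resp_sbp_amp = 0,
                    resp_dbp_amp = 0, baroreflex_gain = 0, rr_noise_sd = 0,
                    sbp_noise_sd = 0, dbp_noise_sd = 0,
                    epoch_rr_scale = c(SR = 1, CR6 = 1, CR15 = 1))
  seg <- segment_markers(0, 120, "SR")
  flow <- flow_signal(rep(0, 120 * 100), 100)
  set.seed(1)
  gb <- generate_beats(cfg, flow, seg)
  expect_true(nrow(gb$beats) %in% c(119L, 120L))
  expect_true(all(abs(gb$beats$rr - 1000) < 1e-6))
})

test_that("RSA under CR6 produces an RR spectral peak at 0.10 Hz", {
  cfg <- sim_config(seed = 21, lf_amp_rr = 0, lf_amp_sbp = 0,
                    baroreflex_gain = 0)
  rec <- generate_subject(cfg)$record
  ep <- slice_epoch(rec, "CR6")
  ser <- resample_events(ep$beats$time, ep$beats$rr)
  sp <- crmaneuver:::welch_psd(ser$y, ser$fs)
  pk <- sp$freq[which.max(sp$psd)]
  expect_lt(abs(pk - 0.10), 0.01)
})

test_that("injected ectopics are exactly the beats the detector flags", {
  out <- generate_subject(sim_config(seed = 3, n_ectopics = 2L))
  b <- detect_ectopics(out$record$beats)
  expect_identical(which(b$ectopic), as.integer(out$truth$ectopic_affected))
  expect_length(out$truth$ectopic_beats, 2L)
  # every injected beat deviates > 20% from its local median
  rr <- out$record$beats$rr
  for (j in out$truth$ectopic_beats) {
    med <- stats::median(rr[(j - 5):(j + 5)])
    expect_gt(abs(rr[j] - med) / med, 0.20)
  }
})

test_that("cohorts are deterministic given a seed and differ across seeds", {
  a <- generate_cohort(3, sim_config(seed = 9))
  b <- generate_cohort(3, sim_config(seed = 9))
  for (i in 1:3) {
    expect_identical(as.data.frame(a$records[[i]]$beats),
                     as.data.frame(b$records[[i]]$beats))
    expect_identical(a$records[[i]]$flow$samples, b$records[[i]]$flow$samples)
  }
  c <- generate_cohort(3, sim_config(seed = 10))
  expect_false(identical(a$records[[1]]$beats$rr, c$records[[1]]$beats$rr))
})

test_that("zero dispersion collapses the cohort to identical subjects", {
  coh <- generate_cohort(3, sim_config(seed = 5, dispersion_cv = 0))
  for (i in 2:3) {
    expect_equal(as.data.frame(coh$records[[i]]$beats),
                 as.data.frame(coh$records[[1]]$beats))
  }
})

test_that("paced cohort hits the programmed CR6 rate under zero jitter", {
  cfg <- sim_config(seed = 8, vt_cv = 0, flow_noise_sd = 0)
  coh <- generate_cohort(5, cfg)
  rates <- vapply(coh$records, function(r) {
    br <- segment_breaths(slice_epoch(r, "CR6")$flow)
    60 / mean(br$ti + br$te)
  }, numeric(1))
  expect_equal(stats::median(rates), 6.0, tolerance = 0.01)
})
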