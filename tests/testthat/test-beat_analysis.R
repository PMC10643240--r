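test_that("the running-median rule flags deviant intervals and only those", {
  b <- make_regular_beats(60, 1000)
  expect_equal(attr(detect_ectopics(b), "n_ectopic"), 0L)
  rr <- rep(1000, 60); rr[30] <- 600           # 40% deviation > 20% rule
  times <- cumsum(rr / 1000)
  b2 <- beat_series(times, rr, rep(120, 60), rep(80, 60))
  f <- detect_ectopics(b2)
  expect_identical(which(f$ectopic), 30L)
  cb <- clean_beats(f)
  expect_false(any(cb$time %in% times[30:31]))  # beat + following interval
  expect_error(detect_ectopics(make_regular_beats(5)), "too few beats")
})

test_that("the exclusion gate mirrors the study design", {
  rec <- make_tiny_record()
  expect_true(exclusion_gate(rec)$keep)
  ns <- make_tiny_record(sinus_rhythm = FALSE)
  g <- exclusion_gate(ns)
  expect_false(g$keep)
  expect_equal(g$reason, "non-sinus rhythm")
  # an ectopic only inside the CR6 window names that epoch
  rr <- rep(1000, 358); rr[180] <- 600; rr[181] <- 1400
  beats <- beat_series(cumsum(rr / 1000), rr, rep(120, 358), rep(80, 358))
  g2 <- exclusion_gate(make_tiny_record(beats = beats))
  expect_false(g2$keep)
  expect_equal(g2$reason, "extrasystole at CR6")
  expect_equal(g2$epoch, "CR6")
})

test_that("time-domain indices match closed forms", {
  expect_error(time_domain(rep(1000, 5)), "too few")
  z <- time_domain(rep(1000, 50))
  expect_equal(c(z$sdann, z$rmssd, z$pnn50), c(0, 0, 0))
  alt <- time_domain(rep(c(950, 1050), 30))
  expect_equal(alt$rmssd, 100)
  expect_equal(alt$pnn50, 100)
  # sampling-theory oracle: SD of Gaussian RR
  set.seed(3)
  rr <- stats::rnorm(1000, 900, 60)
  se_sd <- 60 / sqrt(2 * (1000 - 1))
  expect_lt(abs(time_domain(rr)$sdann - 60), 3 * se_sd)
  # shift invariance: adding a constant leaves rmssd/pnn50 unchanged
  sh <- time_domain(rr + 200)
  expect_equal(sh$rmssd, time_domain(rr)$rmssd)
  expect_equal(sh$pnn50, time_domain(rr)$pnn50)
})

test_that("Baevsky indices follow the histogram construction", {
  rr <- rep(c(1010, 1020, 1030), 20)           # all inside bin [1000, 1050)
  g <- baevsky(rr)
  expect_equal(g$mo, 1.025)
  expect_equal(g$amo, 100)
  expect_equal(g$mxdmn, 0.02)
  expect_equal(g$si, g$amo / (2 * g$mo * g$mxdmn))
  expect_equal(g$abi, g$amo / g$mxdmn)
  expect_equal(g$srai, g$amo / g$mo)
  expect_equal(g$ari, 1 / (g$mo * g$mxdmn))
  # degenerate range
  d <- baevsky(rep(1000, 40))
  expect_true(is.na(d$si) && is.na(d$abi))
  expect_error(baevsky(rep(1000, 10)), "too few")
})

test_that("uniform RR matches the analytic histogram expectation", {
  set.seed(6)
  rr <- stats::runif(4000, 800, 1200)
  g <- baevsky(rr)
  expect_equal(g$amo, 12.5, tolerance = 0.15)      # 50 / 400 ms
  expect_equal(g$mxdmn, 0.4, tolerance = 0.01)
})

test_that("the stress index increases monotonically as dispersion narrows", {
  set.seed(11)
  z <- stats::rnorm(300)
  si <- vapply(c(100, 60, 30), function(s) baevsky(900 + s * z)$si,
               numeric(1))
  expect_true(all(diff(si) > 0))
  # mode shifts with a constant RR offset
  expect_gt(baevsky(900 + 30 * z + 200)$mo, baevsky(900 + 30 * z)$mo)
})

test_that("ECG summary applies Bazett per beat and passes options through", {
  b <- make_regular_beats(40, 1000, qt = 0.40)
  e <- ecg_summary(b)
  expect_equal(e$hr, 60)
  expect_equal(e$qtc, 0.400)
  no_qt <- ecg_summary(make_regular_beats(40, 1000))
  expect_true(is.na(no_qt$qtc))
  # generator round trip: qtc_true recovered within 1%
  out <- generate_subject(sim_config(seed = 13))
  ep <- slice_epoch(out$record, "SR")
  qtc <- ecg_summary(detect_ectopics(ep$beats))$qtc
  expect_lt(abs(qtc - out$truth$qtc) / out$truth$qtc, 0.01)
})
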