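#' Simulation configuration for the synthetic cardiorespiratory cohort
#'
#' Defaults emulate the stated world of the maneuver protocol in a healthy
#' young male athlete cohort: spontaneous breathing near 14.2 min^-1, paced
#' epochs at 6 min^-1 (5 s in / 5 s out) and 15 min^-1 (2 s in / 2 s out),
#' mean RR ~880 ms (HR ~68 min^-1), finger pressure ~112/67 mmHg, stroke
#' volume ~66 cm^3, QTc ~0.41 s, spectral baroreflex gain ~14 ms mmHg^-1.
#'
#' @param seed integer RNG seed, or `NA` to use the caller's RNG stream.
#' @param epoch_s epoch duration, s.
#' @param flow_fs airflow sampling rate, Hz.
#' @param mean_rr mean RR interval, ms (must lie in (300, 2000)).
#' @param rsa_gain respiratory sinus arrhythmia modulation depth, ms of RR per
#'   unit of normalized flow (flow / max|flow| per epoch).
#' @param lf_amp_rr intrinsic 0.1 Hz (Mayer-wave) RR modulation amplitude, ms.
#' @param baroreflex_gain beat-lagged SBP-to-RR coupling, ms mmHg^-1.
#' @param sbp_mean,dbp_mean mean finger pressures, mmHg.
#' @param resp_sbp_amp,resp_dbp_amp respiratory pressure oscillation
#'   amplitudes, mmHg per unit normalized flow.
#' @param lf_amp_sbp,lf_amp_dbp intrinsic 0.1 Hz (Mayer-wave) pressure
#'   oscillation amplitudes, mmHg; these feed back into RR through the
#'   baroreflex coupling.
#' @param sv_mean,esv_mean,sv_resp_amp stroke/end-systolic volume model, cm^3.
#' @param qtc_true generated Bazett-corrected QT, s.
#' @param st_mean mean ST level, n.u.
#' @param epoch_rr_scale named per-epoch multipliers on the mean RR interval
#'   (chronotropic maneuver response: heart rate rises under paced breathing,
#'   most under the faster 15 min^-1 program, reflecting mild hyperventilation
#'   and increased venous return).
#' @param breathing_program named list of per-epoch programs (`SR`, `CR6`,
#'   `CR15`); paced programs give `ti`, `te`, `vt`; the spontaneous program
#'   gives `rate_mean` (min^-1), `rate_cv`, `vt`, `ti_frac`.
#' @param vt_cv breath-to-breath tidal-volume coefficient of variation
#'   (log-normal), present even under paced breathing.
#' @param vo2_fraction oxygen uptake as a fixed fraction of minute ventilation.
#' @param flow_noise_sd,sbp_noise_sd,dbp_noise_sd,rr_noise_sd,qt_noise_sd,sv_noise_sd,esv_noise_sd,st_noise_sd
#'   per-channel additive noise SDs (L s^-1, mmHg, ms, s, cm^3, n.u.).
#' @param ectopic_rate probability per beat of injecting a premature beat
#'   (0.6 x local RR) with compensatory pause (1.4 x local RR).
#' @param n_ectopics force an exact number of injected ectopics (overrides
#'   `ectopic_rate` when not `NA`).
#' @param dispersion_cv between-subject coefficient of variation applied to
#'   the physiological parameters when generating a cohort.
#' @param weight_mean,weight_sd,height_mean,height_sd cohort anthropometrics.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = NA_integer_, epoch_s = 120, flow_fs = 100,
                       mean_rr = 880, rsa_gain = 35, lf_amp_rr = 15,
                       baroreflex_gain = 14,
                       sbp_mean = 112.5, dbp_mean = 67,
                       resp_sbp_amp = 2.5, resp_dbp_amp = 1.2,
                       lf_amp_sbp = 1.8, lf_amp_dbp = 1.0,
                       sv_mean = 66, esv_mean = 30, sv_resp_amp = 3,
                       qtc_true = 0.410, st_mean = 0.09,
                       epoch_rr_scale = c(SR = 1, CR6 = 0.946, CR15 = 0.874),
                       breathing_program = default_breathing_program(),
                       vt_cv = 0.07, vo2_fraction = 0.046,
                       flow_noise_sd = 0.01, sbp_noise_sd = 1.5,
                       dbp_noise_sd = 1.0, rr_noise_sd = 6,
                       qt_noise_sd = 0.002, sv_noise_sd = 1,
                       esv_noise_sd = 1, st_noise_sd = 0.01,
                       ectopic_rate = 0, n_ectopics = NA_integer_,
                       dispersion_cv = 0.08,
                       weight_mean = 73, weight_sd = 8,
                       height_mean = 178, height_sd = 6) {
  cfg <- as.list(environment())
  if (!(mean_rr > 300 && mean_rr < 2000)) {
    stop("mean_rr must lie in (300, 2000) ms")
  }
  amps <- c(rsa_gain, lf_amp_rr, resp_sbp_amp, resp_dbp_amp, sv_resp_amp)
  if (any(amps < 0)) stop("modulation amplitudes must be >= 0")
  if ((rsa_gain + lf_amp_rr) / mean_rr >= 0.8) {
    stop("combined RR modulation depth too large for a positive heart rate")
  }
  structure(cfg, class = "sim_config")
}

#' Default per-epoch breathing programs
#'
#' SR: spontaneous, rate 14.2 min^-1 (10% CV breath to breath), tidal volume
#' 0.57 L, inspiratory duty cycle 0.41. CR6: paced 5 s / 5 s, 1.70 L.
#' CR15: paced 2 s / 2 s, 0.89 L. Volumes and rates sit at the cohort medians
#' reported for this maneuver in young male athletes.
#'
#' @return named list of programs.
#' @export
default_breathing_program <- function() {
  list(
    SR   = list(type = "spontaneous", rate_mean = 14.2, rate_cv = 0.10,
                vt = 0.57, ti_frac = 0.41),
    CR6  = list(type = "paced", ti = 5, te = 5, vt = 1.70),
    CR15 = list(type = "paced", ti = 2, te = 2, vt = 0.89)
  )
}

# log-normal multiplier with unit mean and coefficient of variation cv
ln_mult <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdl <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdl^2 / 2, sdl))
}

#' Generate a paced or spontaneous airflow signal
#'
#' Each breath is a half-sine inspiratory lobe of duration `ti` and area
#' `+vt`, followed by a half-sine expiratory lobe of duration `te` and area
#' `-vt`. Under the spontaneous program, breath-to-breath rate and tidal
#' volume are jittered log-normally; paced programs keep exact timing but
#' retain tidal-volume jitter `vt_cv`. Band-limited noise is added.
#'
#' @param program one entry of [default_breathing_program()].
#' @param duration signal duration, s.
#' @param fs sampling rate, Hz.
#' @param vt_cv breath-to-breath tidal-volume CV (log-normal).
#' @param noise_sd additive band-limited noise SD, L s^-1.
#' @return a [flow_signal()] with attribute `breaths`: the generating breath
#'   table (`t_start`, `ti`, `te`, `vt`).
#' @export
generate_flow <- function(program, duration, fs, vt_cv = 0, noise_sd = 0) {
  paced <- identical(program$type, "paced")
  if (paced) {
    ti <- program$ti; te <- program$te
    if (fs * min(ti, te) < 10) {
      stop("sampling rate too low for the breathing program ",
           "(< 10 samples per phase)")
    }
    nb <- ceiling(duration / (ti + te))
    ti <- rep(ti, nb); te <- rep(te, nb)
  } else {
    nb <- ceiling(duration / (60 / program$rate_mean)) + 10L
    # jitter the breath period (unit-mean log-normal) so that the detected
    # rate 60/mean(ti+te) stays centred on rate_mean
    ttot <- (60 / program$rate_mean) * ln_mult(nb, program$rate_cv)
    ti <- program$ti_frac * ttot; te <- (1 - program$ti_frac) * ttot
    if (fs * min(ti, te) < 10) {
      stop("sampling rate too low for the breathing program ",
           "(< 10 samples per phase)")
    }
  }
  vt <- program$vt * ln_mult(length(ti), vt_cv)
  t_start <- cumsum(c(0, (ti + te)[-length(ti)]))
  keep <- t_start + ti + te <= duration + 1e-9
  ti <- ti[keep]; te <- te[keep]; vt <- vt[keep]; t_start <- t_start[keep]

  n <- round(duration * fs)
  t <- (seq_len(n) - 1L) / fs
  x <- numeric(n)
  for (k in seq_along(t_start)) {
    i0 <- t_start[k]; i1 <- i0 + ti[k]; i2 <- i1 + te[k]
    ins <- which(t >= i0 & t < i1)
    exs <- which(t >= i1 & t < i2)
    x[ins] <- (pi * vt[k] / (2 * ti[k])) * sin(pi * (t[ins] - i0) / ti[k])
    x[exs] <- -(pi * vt[k] / (2 * te[k])) * sin(pi * (t[exs] - i1) / te[k])
  }
  if (noise_sd > 0) {
    w <- stats::rnorm(n)
    k <- max(3L, round(fs / 4))          # ~2 Hz moving-average low-pass
    sm <- stats::filter(w, rep(1 / k, k), sides = 2)
    sm[is.na(sm)] <- 0
    sm <- sm - mean(sm)
    if (stats::sd(sm) > 0) x <- x + noise_sd * as.numeric(sm) / stats::sd(sm)
  }
  fl <- flow_signal(x, fs, check_mean = FALSE)
  attr(fl, "breaths") <- data.frame(t_start = t_start, ti = ti, te = te,
                                    vt = vt)
  fl
}

# evaluate per-epoch normalized flow (flow / max|flow| within each window)
normalize_flow_by_epoch <- function(samples, fs, segments) {
  t <- (seq_along(samples) - 1L) / fs
  out <- numeric(length(samples))
  for (i in seq_len(nrow(segments))) {
    idx <- t >= segments$start[i] & t < segments$end[i]
    m <- max(abs(samples[idx]))
    out[idx] <- if (m > 0) samples[idx] / m else 0
  }
  out
}

#' Generate a beat series by integral pulse frequency modulation
#'
#' Beats fire when the running integral of the instantaneous rate
#' `m(t) = (1/RR0) * (1 + a_resp * flow_norm(t) + a_lf * sin(2 pi 0.1 t + phi))`
#' crosses successive integers (`a_resp = rsa_gain/RR0`,
#' `a_lf = lf_amp_rr/RR0`). Per-beat SBP/DBP follow the respiratory
#' oscillation at the beat time; RR is then additionally perturbed by the
#' beat-lagged baroreflex term `G * (SBP_prev - sbp_mean)` and white noise,
#' and beat times are rebuilt as the cumulative sum of the final intervals.
#' Optional ectopics replace a beat's RR with 0.6 x its local value followed
#' by a 1.4 x compensatory pause (total timing preserved).
#'
#' @param config a [sim_config()].
#' @param flow a [flow_signal()] spanning the whole record.
#' @param segments [segment_markers()] (used to normalize flow per epoch).
#' @param lf_phase phase of the intrinsic 0.1 Hz modulation, radians.
#' @return list with `beats` (a [beat_series()]) and `truth` (ground-truth
#'   list: injected ectopic indices, affected beat indices, their epochs, and
#'   the generating parameters).
#' @export
generate_beats <- function(config, flow, segments,
                           lf_phase = stats::runif(1, 0, 2 * pi)) {
  fs <- flow$fs
  t <- (seq_along(flow$samples) - 1L) / fs
  fn <- normalize_flow_by_epoch(flow$samples, fs, segments)
  rr0 <- config$mean_rr / 1000
  a_resp <- config$rsa_gain / config$mean_rr
  a_lf <- config$lf_amp_rr / config$mean_rr
  scale_t <- rep(1, length(t))
  for (i in seq_len(nrow(segments))) {
    sc <- config$epoch_rr_scale[segments$label[i]]
    if (!is.na(sc)) {
      scale_t[t >= segments$start[i] & t < segments$end[i]] <- sc
    }
  }
  m <- (1 / (rr0 * scale_t)) *
    (1 + a_resp * fn + a_lf * sin(2 * pi * 0.1 * t + lf_phase))
  m <- pmax(m, 0.2 / rr0)
  M <- cumsum(m) / fs
  nb <- floor(max(M))
  if (nb < 2L) stop("record too short for beat generation")
  # M[i] integrates m over (0, i/fs]: interpolate on the right-edge grid
  tb <- stats::approx(M, seq_along(m) / fs, xout = seq_len(nb))$y
  raw_rr <- diff(c(0, tb)) * 1000

  fn_at <- stats::approx(t, fn, xout = tb, rule = 2)$y
  mayer_phase <- stats::runif(1, 0, 2 * pi)
  mayer <- sin(2 * pi * 0.1 * tb + mayer_phase)
  # the physiological pressure wave; white measurement noise is added on top
  # and is never seen by the baroreflex (baroreceptors low-pass their input)
  sbp_wave <- config$resp_sbp_amp * fn_at + config$lf_amp_sbp * mayer
  sbp <- config$sbp_mean + sbp_wave + stats::rnorm(nb, 0, config$sbp_noise_sd)
  dbp <- config$dbp_mean + config$resp_dbp_amp * fn_at +
    config$lf_amp_dbp * mayer + stats::rnorm(nb, 0, config$dbp_noise_sd)
  dbp <- pmin(dbp, sbp - 20)
  sbp_wave_prev <- c(0, sbp_wave[-nb])
  rr <- raw_rr + config$baroreflex_gain * sbp_wave_prev +
    stats::rnorm(nb, 0, config$rr_noise_sd)
  rr <- pmax(rr, 250)

  # ectopic injection: premature beat + compensatory pause
  if (!is.na(config$n_ectopics)) {
    n_e <- config$n_ectopics
  } else if (config$ectopic_rate > 0) {
    n_e <- stats::rbinom(1, nb, config$ectopic_rate)
  } else n_e <- 0L
  ect <- integer(0)
  if (n_e > 0) {
    # keep clear of record edges and epoch boundaries (>= 8 s margin)
    margin <- 8
    ok <- rep(TRUE, nb)
    ok[c(seq_len(6L), seq.int(nb - 6L, nb))] <- FALSE
    for (edge in c(segments$start, segments$end)) {
      ok[abs(tb - edge) < margin] <- FALSE
    }
    cand <- which(ok)
    while (length(ect) < n_e && length(cand) > 0L) {
      j <- cand[sample.int(length(cand), 1L)]
      ect <- c(ect, j)
      cand <- setdiff(cand, (j - 12L):(j + 12L))
    }
    ect <- sort(ect)
    for (j in ect) {
      local <- rr[j]
      rr[j] <- 0.6 * local
      rr[j + 1L] <- 1.4 * local
    }
  }
  time <- cumsum(rr) / 1000
  keep <- time < max(segments$end)
  idx_keep <- which(keep)
  rr <- rr[keep]; time <- time[keep]; sbp <- sbp[keep]; dbp <- dbp[keep]
  fn_at <- fn_at[keep]
  nb <- length(rr)
  ect <- ect[ect %in% idx_keep]

  qt <- config$qtc_true * sqrt(rr / 1000) +
    stats::rnorm(nb, 0, config$qt_noise_sd)
  st <- config$st_mean + stats::rnorm(nb, 0, config$st_noise_sd)
  sv <- config$sv_mean + config$sv_resp_amp * fn_at +
    stats::rnorm(nb, 0, config$sv_noise_sd)
  esv <- config$esv_mean + stats::rnorm(nb, 0, config$esv_noise_sd)

  beats <- beat_series(time, rr, sbp, dbp, qt = qt, st = st,
                       sv = sv, edv = sv + esv, esv = esv)
  affected <- sort(unique(c(ect, ect + 1L)))
  affected <- affected[affected <= nb]
  epoch_of <- function(i) {
    s <- segments
    s$label[time[i] >= s$start & time[i] < s$end][1]
  }
  truth <- list(
    qtc = config$qtc_true,
    baroreflex_gain = config$baroreflex_gain,
    rsa_gain = config$rsa_gain, lf_amp_rr = config$lf_amp_rr,
    true_hf_rr = config$rsa_gain^2 / 2,
    true_lf_rr = config$lf_amp_rr^2 / 2,
    ectopic_beats = ect,
    ectopic_affected = affected,
    ectopic_epochs = if (length(ect)) vapply(ect, epoch_of, character(1))
                     else character(0)
  )
  list(beats = beats, truth = truth)
}

#' Simulate one subject record
#'
#' Generates the three-epoch airflow channel from the configured breathing
#' programs, drives the IPFM beat generator over the full record, and wraps
#' everything as a [subject_record()] with ground truth.
#'
#' @param config a [sim_config()]; if `config$seed` is not `NA` the RNG is
#'   seeded here, otherwise the caller's stream is used.
#' @param subject_id identifier for the emitted record.
#' @return list with `record` (a [subject_record()]) and `truth` (ground-truth
#'   list; also includes the per-epoch generating breath tables).
#' @export
generate_subject <- function(config, subject_id = "sim-001") {
  if (!is.na(config$seed)) set.seed(config$seed)
  prog <- config$breathing_program
  labels <- names(prog)
  seg <- segment_markers(
    start = config$epoch_s * (seq_along(labels) - 1L),
    end = config$epoch_s * seq_along(labels),
    label = labels)
  flows <- lapply(prog, generate_flow, duration = config$epoch_s,
                  fs = config$flow_fs, vt_cv = config$vt_cv,
                  noise_sd = config$flow_noise_sd)
  samples <- unlist(lapply(flows, `[[`, "samples"), use.names = FALSE)
  flow <- flow_signal(samples, config$flow_fs, check_mean = FALSE)
  gb <- generate_beats(config, flow, seg)
  wt <- config$weight_mean; ht <- config$height_mean
  rec <- subject_record(subject_id, gb$beats, flow, seg,
                        weight_kg = wt, height_cm = ht, sinus_rhythm = TRUE)
  truth <- gb$truth
  truth$breath_tables <- lapply(flows, attr, "breaths")
  truth$programs <- prog
  truth$vo2_fraction <- config$vo2_fraction
  list(record = rec, truth = truth)
}

#' Simulate a cohort of subject records
#'
#' Per-subject physiological parameters are drawn once (log-normal dispersion
#' with CV `config$dispersion_cv`; anthropometrics Gaussian), then each
#' subject's three epochs are simulated under the per-epoch breathing
#' programs. Fully deterministic given `seed`.
#'
#' @param n number of subjects (>= 1).
#' @param config a [sim_config()]; `config$seed` seeds the single RNG stream.
#' @return list with `records` (list of [subject_record()]) and `truths`
#'   (parallel list of ground-truth lists).
#' @export
generate_cohort <- function(n, config = sim_config()) {
  stopifnot(n >= 1)
  if (!is.na(config$seed)) set.seed(config$seed)
  cv <- config$dispersion_cv
  # zero dispersion means a fully homogeneous cohort: every subject is the
  # same stochastic realization (same sub-seed, same anthropometrics)
  seeds <- sample.int(2147483646L, n, replace = TRUE)
  if (cv == 0) seeds[] <- seeds[1L]
  records <- vector("list", n)
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    ci <- config
    ci$seed <- seeds[i]
    ci$mean_rr <- min(1990, max(310, config$mean_rr * ln_mult(1, cv)))
    ci$rsa_gain <- config$rsa_gain * ln_mult(1, cv)
    ci$lf_amp_rr <- config$lf_amp_rr * ln_mult(1, cv)
    ci$baroreflex_gain <- config$baroreflex_gain * ln_mult(1, cv)
    ci$sbp_mean <- config$sbp_mean * ln_mult(1, cv / 2)
    ci$dbp_mean <- min(ci$sbp_mean - 25, config$dbp_mean * ln_mult(1, cv / 2))
    ci$resp_sbp_amp <- config$resp_sbp_amp * ln_mult(1, cv)
    ci$resp_dbp_amp <- config$resp_dbp_amp * ln_mult(1, cv)
    ci$lf_amp_sbp <- config$lf_amp_sbp * ln_mult(1, cv)
    ci$lf_amp_dbp <- config$lf_amp_dbp * ln_mult(1, cv)
    ci$sv_mean <- config$sv_mean * ln_mult(1, cv)
    ci$esv_mean <- config$esv_mean * ln_mult(1, cv)
    ci$qtc_true <- config$qtc_true * ln_mult(1, cv / 4)
    if (cv > 0) {
      ci$weight_mean <- stats::rnorm(1, config$weight_mean, config$weight_sd)
      ci$height_mean <- stats::rnorm(1, config$height_mean, config$height_sd)
    }
    for (ep in names(ci$breathing_program)) {
      ci$breathing_program[[ep]]$vt <-
        ci$breathing_program[[ep]]$vt * ln_mult(1, cv)
    }
    if (!is.null(ci$breathing_program$SR$rate_mean)) {
      ci$breathing_program$SR$rate_mean <-
        config$breathing_program$SR$rate_mean * ln_mult(1, cv)
    }
    out <- generate_subject(ci, subject_id = sprintf("sim-%03d", i))
    out$truth$config <- ci
    records[[i]] <- out$record
    truths[[i]] <- out$truth
  }
  list(records = records, truths = truths)
}
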