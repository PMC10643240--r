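# zero-phase FIR low-pass (windowed sinc), used before breath segmentation
lowpass_fir <- function(x, fs, cutoff) {
  if (cutoff >= fs / 2) return(x)
  half <- max(10L, round(2 * fs / cutoff))
  k <- (-half):half
  h <- 2 * cutoff / fs * sinc(2 * cutoff * k / fs)
  h <- h * (0.54 + 0.46 * cos(pi * k / half))   # Hamming taper
  h <- h / sum(h)
  n <- length(x)
  xp <- c(rep(x[1], half), x, rep(x[n], half))  # edge padding
  y <- stats::filter(xp, h, sides = 2)
  as.numeric(y[(half + 1L):(half + n)])
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Segment an airflow signal into breaths
#'
#' Breath onsets are negative-to-positive zero crossings of the low-pass
#' filtered flow, debounced by a hysteresis band of +/- `hysteresis` L s^-1.
#' Candidate breaths failing the minimum-duration or minimum-volume rules are
#' merged into their preceding neighbour. Inspired volume is the integral of
#' positive flow, expired volume the negative of the integral of negative
#' flow, within each breath window.
#'
#' @param flow a [flow_signal()].
#' @param lowpass_hz filter cutoff, Hz.
#' @param hysteresis zero-crossing hysteresis band, L s^-1.
#' @param min_duration minimum inspiratory/expiratory phase duration, s.
#' @param min_volume minimum inspired volume, L.
#' @return `data.frame` with one row per breath: `t_start`, `ti`, `te`,
#'   `vt_insp`, `vt_exp` (times relative to the start of `flow`).
#' @export
segment_breaths <- function(flow, lowpass_hz = 2, hysteresis = 0.02,
                            min_duration = 0.5, min_volume = 0.05) {
  fs <- flow$fs
  x <- flow$samples
  s <- lowpass_fir(x, fs, lowpass_hz)
  state <- ifelse(s > hysteresis, 1L, ifelse(s < -hysteresis, -1L, 0L))
  # propagate last non-zero state through the hysteresis band
  nz <- state != 0L
  idx <- cumsum(nz)
  filled <- ifelse(idx == 0L, 0L, state[nz][pmax(idx, 1L)])
  starts <- which(diff(filled) == 2L & filled[-1L] == 1L) + 1L
  # record starting in inspiration: count its onset as a breath start
  nz_idx <- which(nz)
  if (length(nz_idx) && state[nz_idx[1L]] == 1L &&
      (!length(starts) || nz_idx[1L] < starts[1L])) {
    starts <- c(nz_idx[1L], starts)
  }
  # close the final breath at the end of the expiratory run that follows the
  # last inspiration; stray noise excursions in a trailing quiescent segment
  # must not be absorbed into the final expiration
  if (length(starts)) {
    segi <- starts[length(starts)]:length(s)
    pos1 <- which(state[segi] == 1L)[1L]
    negs <- which(state[segi] == -1L)
    if (!is.na(pos1)) negs <- negs[negs > pos1]
    if (length(negs)) {
      gap <- max(2L, round(0.25 * fs))    # tolerate brief flicker to 0-state
      brk <- which(diff(negs) > gap)
      run_end <- negs[if (length(brk)) brk[1L] else length(negs)]
      close_at <- segi[1L] + run_end - 1L
      # bridge the short gap from the hysteresis exit to the adjacent zero
      # crossing; the cap stops the walk from eating slightly-negative noise
      cap <- close_at + round(0.2 * fs)
      while (close_at < length(s) && close_at < cap &&
             s[close_at + 1L] < 0) {
        close_at <- close_at + 1L
      }
      if (close_at + 1L > starts[length(starts)]) {
        starts <- c(starts, close_at + 1L)
      }
    }
  }
  if (length(starts) < 2L) stop("insufficient breaths in flow signal")
  # hysteresis only debounces; refine each onset back to the zero crossing
  # so phase durations are unbiased
  starts <- vapply(starts, function(j) {
    cap <- j - round(0.2 * fs)
    while (j > 1L && j > cap && s[j - 1L] > 0) j <- j - 1L
    j
  }, integer(1))
  starts <- unique(starts)

  build <- function(starts) {
    nb <- length(starts) - 1L
    out <- data.frame(t_start = numeric(nb), ti = numeric(nb),
                      te = numeric(nb), vt_insp = numeric(nb),
                      vt_exp = numeric(nb))
    for (k in seq_len(nb)) {
      i0 <- starts[k]; i1 <- starts[k + 1L] - 1L
      seg <- i0:i1
      # expiration = first -1 state after the inspiratory +1 state (the
      # refined onset may still sit on the tail of the previous expiration)
      pos1 <- which(filled[seg] == 1L)[1L]
      neg <- which(filled[seg] == -1L)
      if (!is.na(pos1)) neg <- neg[neg > pos1]
      exp_start <- if (length(neg)) seg[neg[1L]] else i1
      cap <- exp_start - round(0.2 * fs)
      while (exp_start > i0 && exp_start > cap && s[exp_start - 1L] < 0) {
        exp_start <- exp_start - 1L     # back to the downward zero crossing
      }
      out$t_start[k] <- (i0 - 1L) / fs
      out$ti[k] <- (exp_start - i0) / fs
      out$te[k] <- (i1 - exp_start + 1L) / fs
      out$vt_insp[k] <- sum(pmax(x[seg], 0)) / fs
      out$vt_exp[k] <- -sum(pmin(x[seg], 0)) / fs
    }
    out
  }
  # merge sub-threshold candidates into the preceding breath
  repeat {
    br <- build(starts)
    bad <- which(br$ti < min_duration | br$te < min_duration |
                   br$vt_insp < min_volume)
    bad <- bad[bad > 1L]
    if (!length(bad)) break
    starts <- starts[-bad[1L]]
    if (length(starts) < 2L) stop("insufficient breaths in flow signal")
  }
  if (nrow(br) > 1L && (br$ti[1L] < min_duration || br$te[1L] < min_duration ||
                        br$vt_insp[1L] < min_volume)) {
    br <- br[-1L, , drop = FALSE]
    rownames(br) <- NULL
  }
  if (nrow(br) < 2L) stop("insufficient breaths in flow signal")
  br
}

#' Breathing-pattern indices for one epoch
#'
#' Means over detected breaths: inspiratory/expiratory times `ti`/`te` (s),
#' tidal volume `vt` (L, inspiratory lobe), mean inspiratory and expiratory
#' flows `vt/ti` and `vt/te` (L s^-1), inspiratory duty cycle
#' `ti/(ti + te)`, breathing rate `60/(ti + te)` (min^-1), minute ventilation
#' `vt x rate` (L min^-1), and oxygen uptake as the fixed fraction
#' `vo2_fraction` of minute ventilation (a flow-only sensor cannot measure
#' gas concentrations; the default 0.046 reproduces the constant uptake to
#' ventilation ratio of the reference cohort).
#'
#' @param breaths output of [segment_breaths()].
#' @param vo2_fraction dimensionless uptake/ventilation ratio.
#' @return named list of class `breath_pattern`.
#' @export
pattern_indices <- function(breaths, vo2_fraction = 0.046) {
  if (is.null(breaths) || nrow(breaths) < 2L) {
    stop("breathing-pattern indices need at least 2 breaths")
  }
  ti <- mean(breaths$ti); te <- mean(breaths$te)
  vt <- mean(breaths$vt_insp)
  rr_breath <- 60 / (ti + te)
  v_minute <- vt * rr_breath
  structure(list(
    ti = ti, te = te, vt = vt,
    vt_over_ti = vt / ti, vt_over_te = vt / te,
    ti_frac = ti / (ti + te),
    rr_breath = rr_breath,
    v_minute = v_minute,
    vo2 = vo2_fraction * v_minute
  ), class = "breath_pattern")
}

#' Oxygen uptake from minute ventilation
#'
#' The fixed-fraction model used throughout the package:
#' `vo2 = vo2_fraction * v_minute`.
#'
#' @param v_minute minute ventilation, L min^-1.
#' @param vo2_fraction dimensionless ratio (default 0.046).
#' @return oxygen uptake, L min^-1.
#' @export
vo2_from_ventilation <- function(v_minute, vo2_fraction = 0.046) {
  vo2_fraction * v_minute
}

#' Breath-wise ventilation event series
#'
#' One value per breath: the expiratory mean flow `60 * vt_exp / te` in
#' L min^-1, stamped at the breath start. This is the event series whose
#' band powers carry units (L min^-1)^2.
#'
#' @param breaths output of [segment_breaths()].
#' @return `data.frame` with `time` (s) and `value` (L min^-1).
#' @export
ventilation_series <- function(breaths) {
  if (is.null(breaths) || nrow(breaths) < 2L) {
    stop("ventilation series needs at least 2 breaths")
  }
  data.frame(time = breaths$t_start, value = 60 * breaths$vt_exp / breaths$te)
}

#' Uniformly sampled ventilation waveform for spectral analysis
#'
#' Builds a waveform whose within-breath shape is the raised cosine
#' `1 - cos(2 pi (t - t_k) / T_k)` scaled so that its mean over breath `k`
#' equals that breath's expiratory mean flow `60 * vt_exp / te` (L min^-1).
#' The breath-wise ventilation level is therefore the waveform's envelope,
#' while the waveform itself carries a spectral line at the instantaneous
#' breathing frequency — which is what makes the ventilation spectrum
#' resonant with the paced rate (LF-dominant at 6 min^-1, HF-dominant at
#' 15 min^-1). A flat, per-breath constant series sampled once per breath
#' could not represent those lines: its Nyquist frequency is half the
#' breathing rate.
#'
#' @param breaths output of [segment_breaths()].
#' @param fs output sampling rate, Hz.
#' @return uniform series (list `y`, `fs`, `t0`) with mean and linear trend
#'   removed, ready for [band_powers()].
#' @export
ventilation_waveform <- function(breaths, fs = 4) {
  if (is.null(breaths) || nrow(breaths) < 2L) {
    stop("ventilation waveform needs at least 2 breaths")
  }
  t0 <- breaths$t_start[1L]
  t_end <- breaths$t_start[nrow(breaths)] +
    breaths$ti[nrow(breaths)] + breaths$te[nrow(breaths)]
  t <- seq(t0, t_end, by = 1 / fs)
  y <- numeric(length(t))
  for (k in seq_len(nrow(breaths))) {
    tk <- breaths$t_start[k]
    Tk <- breaths$ti[k] + breaths$te[k]
    level <- 60 * breaths$vt_exp[k] / breaths$te[k]
    idx <- t >= tk & t < tk + Tk
    y[idx] <- level * (1 - cos(2 * pi * (t[idx] - tk) / Tk))
  }
  detrend_series(y, fs, t0)
}
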