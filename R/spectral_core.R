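#' Default spectral band scheme
#'
#' Contiguous half-open bands: VLF `(0, 0.04]`, LF `(0.04, 0.15]`,
#' HF `(0.15, 0.4]` Hz; total power integrates up to 0.4 Hz. Applied
#' identically to RR (ms^2), SBP/DBP (mmHg^2) and ventilation
#' ((L min^-1)^2) series.
#'
#' @param vlf_hi,lf_hi,hf_hi upper band edges, Hz.
#' @return list of class `band_scheme`.
#' @export
band_scheme <- function(vlf_hi = 0.04, lf_hi = 0.15, hf_hi = 0.4) {
  if (!(0 < vlf_hi && vlf_hi < lf_hi && lf_hi < hf_hi)) {
    stop("band edges must satisfy 0 < vlf_hi < lf_hi < hf_hi")
  }
  structure(list(vlf_hi = vlf_hi, lf_hi = lf_hi, hf_hi = hf_hi),
            class = "band_scheme")
}

# uniform series container; mean and linear trend removed
detrend_series <- function(y, fs, t0 = 0) {
  n <- length(y)
  tt <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, tt), y)
  structure(list(y = as.numeric(fit$residuals), fs = fs, t0 = t0),
            class = "uniform_series")
}

#' Resample an event series onto a uniform grid
#'
#' Cubic (natural spline) interpolation of a beat- or breath-stamped event
#' series onto a uniform grid at `fs` over `[first, last]` event time, with
#' linear fallback when fewer than 4 points would remain, followed by mean
#' and linear-trend removal. This is the standard preparation of RR / SBP /
#' DBP beat series for Fourier analysis.
#'
#' @param time event times, s.
#' @param value event values.
#' @param fs output sampling rate, Hz (default 4).
#' @param min_span minimum span of the events, s.
#' @return uniform series (list `y`, `fs`, `t0`).
#' @export
resample_events <- function(time, value, fs = 4, min_span = 30) {
  ok <- !is.na(time) & !is.na(value)
  time <- time[ok]; value <- value[ok]
  if (length(time) < 4L) stop("too few events to resample (need >= 4)")
  if (diff(range(time)) < min_span) {
    stop("event span too short to resample (need >= ", min_span, " s)")
  }
  o <- order(time)
  time <- time[o]; value <- value[o]
  grid <- seq(time[1L], time[length(time)], by = 1 / fs)
  y <- stats::spline(time, value, xout = grid, method = "natural")$y
  detrend_series(y, fs, t0 = time[1L])
}

# Welch power spectral density, one-sided, Hann taper.
# Normalized so that sum(psd) * df equals the (windowed-corrected) variance.
welch_psd <- function(y, fs, segment_s = 64, overlap = 0.5) {
  n <- length(y)
  L <- min(n, round(segment_s * fs))
  L <- max(L - L %% 2L, 8L)
  step <- max(1L, floor(L * (1 - overlap)))
  starts <- seq(1L, n - L + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))   # Hann
  u <- sum(w^2)
  nf <- L %/% 2L
  acc <- numeric(nf + 1L)
  for (s in starts) {
    seg <- y[s:(s + L - 1L)]
    seg <- seg - mean(seg)
    X <- stats::fft(seg * w)
    p <- Mod(X[seq_len(nf + 1L)])^2 / (fs * u)
    p[2:nf] <- 2 * p[2:nf]                 # fold negative frequencies
    acc <- acc + p
  }
  list(freq = (0:nf) * fs / L, psd = acc / length(starts))
}

#' Band powers of a uniform series
#'
#' Power spectral density by Welch's method (Hann taper, 64-s segments, 50%
#' overlap by default), integrated over the half-open bands of `scheme`.
#' Derived fields (normalized units, LF/HF, centralization index) are filled
#' via [normalize_and_ratios()]. Deterministic: identical input gives
#' identical output.
#'
#' @param series a uniform series from [resample_events()] or
#'   [ventilation_waveform()], or a numeric vector (then `fs` is required).
#' @param fs sampling rate, Hz (taken from `series` when it is a list).
#' @param scheme a [band_scheme()].
#' @param segment_s Welch segment length, s; reduce for short series, or set
#'   to the series duration for a plain periodogram.
#' @param overlap fractional segment overlap.
#' @return list of class `spectral_indices`: `tp`, `vlf`, `lf`, `hf` (signal
#'   units squared) plus `lfn`, `hfn`, `lfhf`, `ic`.
#' @export
band_powers <- function(series, fs = NULL, scheme = band_scheme(),
                        segment_s = 64, overlap = 0.5) {
  if (is.list(series)) {
    fs <- series$fs
    y <- series$y
  } else y <- as.numeric(series)
  if (is.null(fs)) stop("fs is required when series is a plain vector")
  if (length(y) < 64L) stop("series too short for spectral analysis")
  if (all(y == 0)) {
    return(normalize_and_ratios(spectral_indices(0, 0, 0, 0)))
  }
  sp <- welch_psd(y, fs, segment_s = segment_s, overlap = overlap)
  df <- sp$freq[2L] - sp$freq[1L]
  bp <- function(lo, hi) sum(sp$psd[sp$freq > lo & sp$freq <= hi]) * df
  p <- spectral_indices(
    tp = bp(0, scheme$hf_hi),
    vlf = bp(0, scheme$vlf_hi),
    lf = bp(scheme$vlf_hi, scheme$lf_hi),
    hf = bp(scheme$lf_hi, scheme$hf_hi))
  normalize_and_ratios(p)
}

#' Spectral index bundle constructor
#'
#' @param tp,vlf,lf,hf band powers (signal units squared), all >= 0.
#' @return list of class `spectral_indices` with derived fields unset.
#' @export
spectral_indices <- function(tp, vlf, lf, hf) {
  if (any(c(tp, vlf, lf, hf) < 0)) stop("band powers must be >= 0")
  structure(list(tp = tp, vlf = vlf, lf = lf, hf = hf,
                 lfn = NA_real_, hfn = NA_real_,
                 lfhf = NA_real_, ic = NA_real_),
            class = "spectral_indices")
}

#' Fill normalized units, balance ratio and centralization index
#'
#' `lfn = lf/(tp - vlf) x 100`, `hfn = hf/(tp - vlf) x 100` (so that
#' `lfn + hfn = 100` whenever `tp = vlf + lf + hf`), `lfhf = lf/hf`,
#' `ic = (lf + vlf)/hf`. Ratio fields are `NA` ("absent") when `hf = 0`;
#' normalized units are `NA` when `tp = vlf`.
#'
#' @param powers a [spectral_indices()] with the four band powers set.
#' @return the same object with derived fields filled.
#' @export
normalize_and_ratios <- function(powers) {
  if (powers$tp < powers$vlf) stop("tp < vlf is not a valid power bundle")
  denom <- powers$tp - powers$vlf
  powers$lfn <- if (denom > 0) 100 * powers$lf / denom else NA_real_
  powers$hfn <- if (denom > 0) 100 * powers$hf / denom else NA_real_
  if (powers$hf > 0) {
    powers$lfhf <- powers$lf / powers$hf
    powers$ic <- (powers$lf + powers$vlf) / powers$hf
  } else {
    powers$lfhf <- NA_real_
    powers$ic <- NA_real_
  }
  powers
}

#' Spectral baroreflex sensitivity (alpha coefficient)
#'
#' `br_lf = sqrt(LF_RR / LF_SBP)` and `br_hf = sqrt(HF_RR / HF_SBP)`, in
#' ms mmHg^-1: the square-root form is the one consistent with the printed
#' units of the index. Returns `NA` fields with a warning when an SBP band
#' power is zero.
#'
#' @param rr_spectrum [spectral_indices()] of the RR series (ms^2).
#' @param sbp_spectrum [spectral_indices()] of the SBP series (mmHg^2).
#' @return list of class `baroreflex`: `br_lf`, `br_hf` (ms mmHg^-1).
#' @export
baroreflex_alpha <- function(rr_spectrum, sbp_spectrum) {
  safe <- function(num, den, band) {
    if (is.na(den) || den <= 0) {
      warning("zero SBP ", band, " power: baroreflex alpha absent")
      return(NA_real_)
    }
    sqrt(num / den)
  }
  structure(list(
    br_lf = safe(rr_spectrum$lf, sbp_spectrum$lf, "LF"),
    br_hf = safe(rr_spectrum$hf, sbp_spectrum$hf, "HF")
  ), class = "baroreflex")
}
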