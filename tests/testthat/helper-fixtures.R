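# fixtures built in code: no binary data ships with the package

# regular beat table: n beats at constant RR (ms), constant pressures
make_regular_beats <- function(n, rr_ms = 1000, sbp = 120, dbp = 80,
                               qt = NULL, ...) {
  time <- cumsum(rep(rr_ms / 1000, n))
  beat_series(time = time, rr = rep(rr_ms, n), sbp = rep(sbp, n),
              dbp = rep(dbp, n), qt = if (!is.null(qt)) rep(qt, n), ...)
}

# minimal three-epoch record with regular beats and a paced CR6-style flow
make_tiny_record <- function(rr_ms = 1000, duration = 360, fs = 20,
                             sinus_rhythm = TRUE, beats = NULL) {
  n <- floor(duration / (rr_ms / 1000)) - 1L
  if (is.null(beats)) beats <- make_regular_beats(n, rr_ms)
  t <- (seq_len(duration * fs) - 1L) / fs
  flow <- flow_signal(0.5 * sin(2 * pi * t / 10), fs)
  seg <- segment_markers(duration * (0:2) / 3, duration * (1:3) / 3)
  subject_record("tiny", beats, flow, seg,
                 weight_kg = 73, height_cm = 178,
                 sinus_rhythm = sinus_rhythm)
}

# uniform series wrapper for direct spectral tests
make_series <- function(y, fs = 4) {
  structure(list(y = y - mean(y), fs = fs, t0 = 0),
            class = "uniform_series")
}

# independent oracle: exact two-sided signed-rank p by enumerating all 2^n
# sign patterns (usable for n <= ~12)
brute_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1), function(k) {
    s <- as.integer(intToBits(k))[1:n]
    sum(r[s == 1])
  }, numeric(1))
  min(1, 2 * min(mean(ws <= w), mean(ws >= w)))
}
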