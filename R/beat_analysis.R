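#' Flag ectopic beats by a running-median rule
#'
#' Beat `i` is flagged when its RR interval deviates from the median RR of the
#' `window`-beat neighbourhood centred on `i` (truncated at record edges) by
#' more than `threshold` times that median. Downstream index computations
#' exclude flagged beats and the immediately following interval (see
#' [clean_beats()]).
#'
#' @param beats a [beat_series()].
#' @param threshold fractional deviation (default 0.20).
#' @param window neighbourhood size in beats (odd, default 11).
#' @return `beats` with the `ectopic` column filled; attribute `n_ectopic`
#'   carries the flag count.
#' @export
detect_ectopics <- function(beats, threshold = 0.20, window = 11L) {
  n <- nrow(beats)
  if (n < window) stop("too few beats for ectopic detection (need >= ",
                       window, ")")
  rr <- beats$rr
  half <- window %/% 2L
  flag <- logical(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    med <- stats::median(rr[lo:hi], na.rm = TRUE)
    flag[i] <- !is.na(rr[i]) && abs(rr[i] - med) > threshold * med
  }
  beats$ectopic <- flag
  attr(beats, "n_ectopic") <- sum(flag)
  beats
}

#' Keep only clean sinus intervals
#'
#' Removes flagged beats and invalidates the interval immediately following a
#' flagged beat (its RR is bounded by an ectopic beat time), as well as
#' intervals with missing RR.
#'
#' @param beats a [beat_series()] after [detect_ectopics()].
#' @return `data.frame` with `time` and `rr` of the retained intervals.
#' @export
clean_beats <- function(beats) {
  drop <- beats$ectopic | c(FALSE, beats$ectopic[-nrow(beats)])
  keep <- !drop & !is.na(beats$rr)
  data.frame(time = beats$time[keep], rr = beats$rr[keep])
}

#' Record-level exclusion rule
#'
#' A record is excluded from cohort analysis when any epoch contains at least
#' one ectopic flag, or when the record is annotated as non-sinus rhythm. The
#' reason names the rule and (for extrasystoles) the first offending epoch.
#'
#' @param record a [subject_record()].
#' @param threshold,window forwarded to [detect_ectopics()].
#' @return list with `keep` (logical), `reason` (`NA` when kept), `epoch`
#'   (first epoch with a flag, else `NA`) and `n_ectopic` per epoch.
#' @export
exclusion_gate <- function(record, threshold = 0.20, window = 11L) {
  if (!record$sinus_rhythm) {
    return(list(keep = FALSE, reason = "non-sinus rhythm",
                epoch = NA_character_, n_ectopic = NULL))
  }
  labels <- record$segments$label
  counts <- stats::setNames(integer(length(labels)), labels)
  for (lab in labels) {
    ep <- slice_epoch(record, lab)
    if (nrow(ep$beats) >= window) {
      b <- detect_ectopics(ep$beats, threshold = threshold, window = window)
      counts[lab] <- attr(b, "n_ectopic")
    }
  }
  bad <- names(counts)[counts > 0]
  if (length(bad)) {
    list(keep = FALSE,
         reason = paste0("extrasystole at ", bad[1]),
         epoch = bad[1], n_ectopic = counts)
  } else {
    list(keep = TRUE, reason = NA_character_, epoch = NA_character_,
         n_ectopic = counts)
  }
}

#' Time-domain heart-rate variability indices
#'
#' `sdann` is the standard deviation of all NN intervals within the epoch
#' (the conventional 5-min sub-averaged SDANN is impossible on 2-min epochs;
#' the label follows the source methodology and `sdnn` is returned as an
#' alias). `rmssd` is the root mean square of successive differences;
#' `pnn50` the percentage of successive pairs differing by more than 50 ms.
#'
#' @param rr clean NN intervals, ms (vector or [clean_beats()] output).
#' @return list of class `hrv_time_domain`: `sdann`, `sdnn`, `rmssd`, `pnn50`.
#' @export
time_domain <- function(rr) {
  if (is.data.frame(rr)) rr <- rr$rr
  rr <- rr[!is.na(rr)]
  if (length(rr) < 10L) stop("too few clean intervals for time-domain HRV")
  d <- diff(rr)
  structure(list(
    sdann = stats::sd(rr),
    sdnn = stats::sd(rr),
    rmssd = sqrt(mean(d^2)),
    pnn50 = 100 * mean(abs(d) > 50)
  ), class = "hrv_time_domain")
}

#' Baevsky geometric heart-rhythm indices
#'
#' RR intervals are histogrammed into fixed `bin_ms` bins anchored at 0 ms.
#' Mode `mo` is the centre of the tallest bin (s; ties broken toward the
#' shorter RR), mode amplitude `amo` the percentage of intervals in it, and
#' `mxdmn` the RR range (s). Derived: stress index
#' `si = amo / (2 mo mxdmn)`, autonomic balance `abi = amo / mxdmn`,
#' subcortical regulation adequacy `srai = amo / mo`, autonomic regulation
#' `ari = 1 / (mo mxdmn)` (all c.u.). Indices with `mxdmn` in the denominator
#' are `NA` when the range is zero.
#'
#' @param rr clean NN intervals, ms (vector or [clean_beats()] output).
#' @param bin_ms histogram bin width, ms.
#' @return list of class `baevsky_indices`.
#' @export
baevsky <- function(rr, bin_ms = 50) {
  if (is.data.frame(rr)) rr <- rr$rr
  rr <- rr[!is.na(rr)]
  if (length(rr) < 30L) stop("too few intervals for geometric analysis")
  bin <- floor(rr / bin_ms)
  tab <- table(bin)
  top <- names(tab)[tab == max(tab)]
  modal <- min(as.numeric(top))          # tie -> lower-RR bin
  mo <- (modal * bin_ms + bin_ms / 2) / 1000
  amo <- 100 * max(tab) / length(rr)
  mxdmn <- (max(rr) - min(rr)) / 1000
  has_rng <- mxdmn > 0
  structure(list(
    mo = mo, amo = amo, mxdmn = mxdmn,
    si = if (has_rng) amo / (2 * mo * mxdmn) else NA_real_,
    abi = if (has_rng) amo / mxdmn else NA_real_,
    srai = amo / mo,
    ari = if (has_rng) 1 / (mo * mxdmn) else NA_real_
  ), class = "baevsky_indices")
}

#' Per-epoch ECG interval summary
#'
#' Heart rate `hr = 60000 / mean(RR ms)`; Bazett-corrected QT computed per
#' beat (`qt / sqrt(rr s)`) then averaged; QT and ST pass through as epoch
#' means when annotated, `NA` otherwise (never 0).
#'
#' @param beats a [beat_series()] (clean intervals are selected internally
#'   from the `ectopic` flags).
#' @return list of class `ecg_intervals`: `hr`, `qt`, `qtc`, `st`.
#' @export
ecg_summary <- function(beats) {
  cb <- clean_beats(beats)
  keep <- beats$time %in% cb$time
  rr <- beats$rr[keep]; qt <- beats$qt[keep]; st <- beats$st[keep]
  hr <- 60000 / mean(rr, na.rm = TRUE)
  qtc <- if (all(is.na(qt))) NA_real_ else {
    mean(qt / sqrt(rr / 1000), na.rm = TRUE)
  }
  structure(list(
    hr = hr,
    qt = if (all(is.na(qt))) NA_real_ else mean(qt, na.rm = TRUE),
    qtc = qtc,
    st = if (all(is.na(st))) NA_real_ else mean(st, na.rm = TRUE)
  ), class = "ecg_intervals")
}
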