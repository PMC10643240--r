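#' Beat-to-beat series constructor
#'
#' Builds the per-beat table of a combined cardiorespiratory record: beat time
#' (s from record start), RR interval (ms, the interval *ending* at this beat),
#' per-beat systolic and diastolic finger pressure (mmHg) and optional per-beat
#' annotations: QT interval (s), ST level (n.u.) and the stroke-volume triplet
#' SV/EDV/ESV (cm^3) from an external hemodynamic estimator.
#'
#' @param time numeric, beat times in seconds, strictly increasing.
#' @param rr numeric, RR intervals in ms; `NA` allowed for the first beat of a
#'   sliced epoch whose initiating beat falls outside the window.
#' @param sbp,dbp numeric, per-beat systolic/diastolic pressure in mmHg.
#' @param qt,st,sv,edv,esv optional per-beat annotations; `NULL` means absent.
#' @param validate logical, run [validate_beats()] on the result.
#' @return a `data.frame` of class `beat_series` with one row per beat and an
#'   `ectopic` logical column (filled by [detect_ectopics()], `FALSE` here).
#' @export
beat_series <- function(time, rr, sbp, dbp, qt = NULL, st = NULL,
                        sv = NULL, edv = NULL, esv = NULL, validate = TRUE) {
  n <- length(time)
  opt <- function(x) if (is.null(x)) rep(NA_real_, n) else as.numeric(x)
  beats <- data.frame(
    time = as.numeric(time), rr = as.numeric(rr),
    sbp = as.numeric(sbp), dbp = as.numeric(dbp),
    qt = opt(qt), st = opt(st),
    sv = opt(sv), edv = opt(edv), esv = opt(esv),
    ectopic = logical(n)
  )
  class(beats) <- c("beat_series", "data.frame")
  if (validate) validate_beats(beats)
  beats
}

#' Validate a beat series
#'
#' Checks the invariants of a [beat_series()]: strictly increasing beat times,
#' positive RR, `sbp > dbp > 0`, and agreement between successive time
#' differences and RR/1000 within `tol_s`.
#'
#' @param beats a `beat_series`.
#' @param tol_s tolerance (s) for the time-difference/RR consistency check.
#' @return `beats`, invisibly; errors describe the first offending index.
#' @export
validate_beats <- function(beats, tol_s = 1e-3) {
  dt <- diff(beats$time)
  if (any(dt <= 0)) {
    stop("beat times not strictly increasing; first offending index: ",
         which(dt <= 0)[1] + 1L)
  }
  ok <- !is.na(beats$rr)
  if (any(beats$rr[ok] <= 0)) {
    stop("non-positive RR at index ", which(ok & beats$rr <= 0)[1])
  }
  bad_bp <- which(!(beats$sbp > beats$dbp & beats$dbp > 0))
  if (length(bad_bp)) stop("sbp > dbp > 0 violated at index ", bad_bp[1])
  if (nrow(beats) > 1L) {
    rr_s <- beats$rr[-1L] / 1000
    chk <- which(!is.na(rr_s) & abs(dt - rr_s) > tol_s)
    if (length(chk)) {
      stop("time difference and rr/1000 disagree by > ", tol_s,
           " s at index ", chk[1] + 1L)
    }
  }
  invisible(beats)
}

#' Respiratory airflow signal
#'
#' @param samples numeric airflow samples, L s^-1, inhalation positive.
#' @param fs sampling rate, Hz; must exceed 1 Hz (twice the 0.4 Hz analysis
#'   ceiling with margin), default recordings use 100 Hz.
#' @param check_mean logical; verify volume conservation (mean approximately
#'   zero) — applies to full records, not cropped epochs.
#' @param mean_tol tolerance on the mean, L s^-1.
#' @return object of class `flow_signal`: list with `samples` and `fs`.
#' @export
flow_signal <- function(samples, fs, check_mean = TRUE, mean_tol = 0.05) {
  if (!is.numeric(fs) || length(fs) != 1L || fs < 1) {
    stop("flow sampling rate must be a single value >= 1 Hz")
  }
  if (!all(is.finite(samples))) stop("flow samples must be finite")
  if (check_mean && abs(mean(samples)) > mean_tol) {
    stop("flow does not conserve volume: |mean| = ",
         signif(abs(mean(samples)), 3), " L/s exceeds ", mean_tol)
  }
  structure(list(samples = as.numeric(samples), fs = fs),
            class = "flow_signal")
}

#' Segment markers for the three maneuver epochs
#'
#' Half-open windows `[start, end)` in seconds labelled `SR` (spontaneous),
#' `CR6` (paced 6 min^-1) and `CR15` (paced 15 min^-1), in that order.
#'
#' @param start,end numeric vectors of window bounds (s).
#' @param label character vector of labels; must be unique.
#' @return `data.frame` of class `segment_markers`.
#' @export
segment_markers <- function(start = c(0, 120, 240),
                            end = c(120, 240, 360),
                            label = c("SR", "CR6", "CR15")) {
  if (anyDuplicated(label)) stop("segment labels must be unique")
  if (any(end <= start)) stop("segment windows must satisfy start < end")
  if (length(start) > 1L && any(start[-1L] < end[-length(end)])) {
    stop("segment windows must be non-overlapping and ordered")
  }
  structure(data.frame(label = label, start = as.numeric(start),
                       end = as.numeric(end)),
            class = c("segment_markers", "data.frame"))
}

#' Combined cardiorespiratory subject record
#'
#' The pipeline's unit of input: a beat table, a respiratory airflow channel,
#' segment markers delimiting the three maneuver epochs, and anthropometrics.
#'
#' @param subject_id character identifier.
#' @param beats a [beat_series()].
#' @param flow a [flow_signal()].
#' @param segments a [segment_markers()] table.
#' @param weight_kg,height_cm anthropometrics.
#' @param sinus_rhythm logical flag from annotation; non-sinus records are
#'   rejected by [exclusion_gate()].
#' @param validate logical, run validity checks.
#' @return object of class `subject_record`.
#' @export
subject_record <- function(subject_id, beats, flow, segments,
                           weight_kg, height_cm, sinus_rhythm = TRUE,
                           validate = TRUE) {
  rec <- structure(
    list(subject_id = as.character(subject_id), beats = beats, flow = flow,
         segments = segments, weight_kg = as.numeric(weight_kg),
         height_cm = as.numeric(height_cm),
         sinus_rhythm = isTRUE(sinus_rhythm)),
    class = "subject_record")
  if (validate) {
    validate_beats(beats)
    dur <- length(flow$samples) / flow$fs
    if (any(segments$end > dur + 1 / flow$fs + 1e-9)) {
      stop("segment windows extend beyond the flow record duration")
    }
  }
  rec
}

#' @export
print.subject_record <- function(x, ...) {
  cat("<subject_record> ", x$subject_id, "\n",
      "  beats: ", nrow(x$beats), "  flow: ",
      length(x$flow$samples), " samples @ ", x$flow$fs, " Hz\n",
      "  segments: ",
      paste(sprintf("%s [%g,%g)", x$segments$label, x$segments$start,
                    x$segments$end), collapse = ", "), "\n",
      "  weight ", x$weight_kg, " kg, height ", x$height_cm,
      " cm, sinus rhythm: ", x$sinus_rhythm, "\n", sep = "")
  invisible(x)
}

fmt_num <- function(x) {
  ifelse(is.na(x), "", formatC(x, digits = 10, format = "g"))
}

#' Write a subject record to a directory
#'
#' On-disk representation is one directory per subject: `beats.csv` (header
#' `time_s,rr_ms,sbp_mmHg,dbp_mmHg,qt_s,st_nu[,sv_cm3,edv_cm3,esv_cm3]`, empty
#' cell = absent; the stroke-volume columns are written only when annotated),
#' `flow.txt` (single column of samples), `flow.json` (`{"fs_hz": ...}`) and
#' `meta.json` (id, anthropometrics, sinus flag, segment windows).
#' [read_record()] inverts it field-by-field; writing the re-read record again
#' is byte-identical.
#'
#' @param record a [subject_record()].
#' @param path directory to create/fill.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create record directory: ", path)
  b <- record$beats
  cols <- c(time_s = "time", rr_ms = "rr", sbp_mmHg = "sbp", dbp_mmHg = "dbp",
            qt_s = "qt", st_nu = "st")
  hemo <- c(sv_cm3 = "sv", edv_cm3 = "edv", esv_cm3 = "esv")
  keep <- vapply(hemo, function(f) any(!is.na(b[[f]])), logical(1))
  cols <- c(cols, hemo[keep])
  out <- vapply(cols, function(f) fmt_num(b[[f]]), character(nrow(b)))
  if (nrow(b) == 1L) out <- matrix(out, nrow = 1L, dimnames = list(NULL, names(cols)))
  lines <- c(paste(names(cols), collapse = ","),
             apply(out, 1L, paste, collapse = ","))
  writeLines(lines, file.path(path, "beats.csv"))
  writeLines(fmt_num(record$flow$samples), file.path(path, "flow.txt"))
  writeLines(jsonlite::toJSON(list(fs_hz = record$flow$fs), auto_unbox = TRUE,
                              digits = NA),
             file.path(path, "flow.json"))
  meta <- list(
    subject_id = record$subject_id,
    weight_kg = record$weight_kg, height_cm = record$height_cm,
    sinus_rhythm = record$sinus_rhythm,
    segments = lapply(seq_len(nrow(record$segments)), function(i) {
      list(label = record$segments$label[i],
           start = record$segments$start[i], end = record$segments$end[i])
    }))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             file.path(path, "meta.json"))
  invisible(path)
}

#' Read a subject record from a directory
#'
#' Inverse of [write_record()]. All invariants are re-checked on load and
#' units are normalized to the package's canonical ones (s, ms, mmHg, L s^-1).
#'
#' @param path record directory.
#' @param validate logical, run validity checks.
#' @return a [subject_record()].
#' @export
read_record <- function(path, validate = TRUE) {
  need <- c("beats.csv", "flow.txt", "flow.json", "meta.json")
  for (f in need) {
    if (!file.exists(file.path(path, f))) {
      stop("record at ", path, " is missing channel file: ", f)
    }
  }
  b <- utils::read.csv(file.path(path, "beats.csv"),
                       colClasses = "numeric", check.names = FALSE)
  get <- function(nm) if (nm %in% names(b)) b[[nm]] else NULL
  flow_js <- jsonlite::fromJSON(file.path(path, "flow.json"))
  flow <- flow_signal(as.numeric(readLines(file.path(path, "flow.txt"))),
                      fs = flow_js$fs_hz, check_mean = FALSE)
  meta <- jsonlite::fromJSON(file.path(path, "meta.json"),
                             simplifyDataFrame = TRUE)
  seg <- segment_markers(start = meta$segments$start, end = meta$segments$end,
                         label = meta$segments$label)
  beats <- beat_series(b$time_s, b$rr_ms, b$sbp_mmHg, b$dbp_mmHg,
                       qt = get("qt_s"), st = get("st_nu"),
                       sv = get("sv_cm3"), edv = get("edv_cm3"),
                       esv = get("esv_cm3"), validate = validate)
  subject_record(meta$subject_id, beats, flow, seg,
                 weight_kg = meta$weight_kg, height_cm = meta$height_cm,
                 sinus_rhythm = meta$sinus_rhythm, validate = validate)
}

#' Restrict a record to one maneuver epoch
#'
#' Beats with `time` in the half-open window `[start, end)` are kept. The RR
#' interval of the first kept beat is retained only when the beat initiating
#' it (at `time - rr/1000`) also lies inside the window, so epoch statistics
#' never mix boundary-crossing intervals. Flow is cropped to the window.
#'
#' @param record a [subject_record()].
#' @param label one of the record's segment labels (`"SR"`, `"CR6"`, `"CR15"`).
#' @return a `subject_record` restricted to the window, with a single segment
#'   marker and beat times kept on the original time base.
#' @export
slice_epoch <- function(record, label) {
  seg <- record$segments
  i <- match(label, seg$label)
  if (is.na(i)) stop("no segment labelled '", label, "' in record")
  lo <- seg$start[i]; hi <- seg$end[i]
  b <- record$beats
  keep <- b$time >= lo & b$time < hi
  b <- b[keep, , drop = FALSE]
  if (nrow(b) > 0L && !is.na(b$rr[1L]) && (b$time[1L] - b$rr[1L] / 1000) < lo) {
    b$rr[1L] <- NA_real_
  }
  rownames(b) <- NULL
  class(b) <- c("beat_series", "data.frame")
  fs <- record$flow$fs
  idx0 <- floor(lo * fs)               # samples at times idx/fs in [lo, hi)
  idx1 <- ceiling(hi * fs) - 1L
  idx1 <- min(idx1, length(record$flow$samples) - 1L)
  flow <- flow_signal(record$flow$samples[(idx0 + 1L):(idx1 + 1L)], fs,
                      check_mean = FALSE)
  subject_record(record$subject_id, b, flow,
                 segment_markers(lo, hi, label),
                 weight_kg = record$weight_kg, height_cm = record$height_cm,
                 sinus_rhythm = record$sinus_rhythm, validate = FALSE)
}
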