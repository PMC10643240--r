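#' Analysis configuration
#'
#' Collects the tunable parameters of every pipeline stage with their
#' defaults: 4 Hz cubic resampling and Welch estimation with 64-s Hann
#' segments at 50% overlap; the 0.04 / 0.15 / 0.4 Hz band edges; the 11-beat
#' 20% running-median ectopic rule; the breath segmenter thresholds; the
#' ventilation-to-uptake fraction; and the body-surface-area formula.
#'
#' @param fs_hz resampling rate for beat/breath event series, Hz.
#' @param welch_segment_s,welch_overlap Welch estimator parameters.
#' @param bands a [band_scheme()].
#' @param ectopic_threshold,ectopic_window running-median detector parameters.
#' @param breath_lowpass_hz,breath_hysteresis,breath_min_duration,breath_min_volume
#'   breath segmenter parameters.
#' @param vo2_fraction ventilation-to-uptake ratio.
#' @param bsa_formula `"dubois"` or `"mosteller"`.
#' @param baevsky_bin_ms histogram bin width for the geometric indices, ms.
#' @return list of class `crm_config`.
#' @export
crm_config <- function(fs_hz = 4, welch_segment_s = 64, welch_overlap = 0.5,
                       bands = band_scheme(),
                       ectopic_threshold = 0.20, ectopic_window = 11L,
                       breath_lowpass_hz = 2, breath_hysteresis = 0.02,
                       breath_min_duration = 0.5, breath_min_volume = 0.05,
                       vo2_fraction = 0.046, bsa_formula = "dubois",
                       baevsky_bin_ms = 50) {
  structure(as.list(environment()), class = "crm_config")
}

# canonical flat index names: one column of the per-epoch output tables
flat_index_names <- function() {
  c("HR", "QTc", "ST",
    "TP", "VLF", "LF", "LFn", "HF", "HFn", "LFHF", "IC_HR",
    "ABI", "SRAI", "ARI", "SI", "SDANN", "RMSSD", "pNN50",
    "TP_SBP", "VLF_SBP", "LF_SBP", "LF_SBPn", "HF_SBP", "HF_SBPn",
    "LFHF_SBP", "IC_SBP",
    "TP_DBP", "VLF_DBP", "LF_DBP", "LF_DBPn", "HF_DBP", "HF_DBPn",
    "LFHF_DBP", "IC_DBP",
    "SBPf", "DBPf", "PBPf", "BR_LF", "BR_HF",
    "TP_R", "VLF_R", "LF_R", "LF_Rn", "HF_R", "HF_Rn", "LFHF_R", "IC_R",
    "Ti", "Te", "VT", "VT_TI", "VT_TE", "Ti_frac", "RR", "V", "VO2",
    "EDV", "ESV", "SV", "CO", "CI", "GPVR", "SI_stroke", "VSI", "HI")
}

flatten_epoch <- function(e) {
  sp <- function(s, suffix = "") {
    out <- c(s$tp, s$vlf, s$lf, s$lfn, s$hf, s$hfn, s$lfhf, s$ic)
    names(out) <- paste0(c("TP", "VLF", "LF", "LFn", "HF", "HFn", "LFHF",
                           "IC"), suffix)
    out
  }
  v <- c(HR = e$ecg$hr, QTc = e$ecg$qtc, ST = e$ecg$st,
         sp(e$hrv_spec)[c("TP", "VLF", "LF", "LFn", "HF", "HFn", "LFHF")],
         IC_HR = e$hrv_spec$ic,
         ABI = e$baevsky$abi, SRAI = e$baevsky$srai, ARI = e$baevsky$ari,
         SI = e$baevsky$si, SDANN = e$hrv_time$sdann,
         RMSSD = e$hrv_time$rmssd, pNN50 = e$hrv_time$pnn50,
         TP_SBP = e$sbp_spec$tp, VLF_SBP = e$sbp_spec$vlf,
         LF_SBP = e$sbp_spec$lf, LF_SBPn = e$sbp_spec$lfn,
         HF_SBP = e$sbp_spec$hf, HF_SBPn = e$sbp_spec$hfn,
         LFHF_SBP = e$sbp_spec$lfhf, IC_SBP = e$sbp_spec$ic,
         TP_DBP = e$dbp_spec$tp, VLF_DBP = e$dbp_spec$vlf,
         LF_DBP = e$dbp_spec$lf, LF_DBPn = e$dbp_spec$lfn,
         HF_DBP = e$dbp_spec$hf, HF_DBPn = e$dbp_spec$hfn,
         LFHF_DBP = e$dbp_spec$lfhf, IC_DBP = e$dbp_spec$ic,
         SBPf = e$bp$sbpf, DBPf = e$bp$dbpf, PBPf = e$bp$pbpf,
         BR_LF = e$baroreflex$br_lf, BR_HF = e$baroreflex$br_hf,
         TP_R = e$vrv$tp, VLF_R = e$vrv$vlf, LF_R = e$vrv$lf,
         LF_Rn = e$vrv$lfn, HF_R = e$vrv$hf, HF_Rn = e$vrv$hfn,
         LFHF_R = e$vrv$lfhf, IC_R = e$vrv$ic,
         Ti = e$pattern$ti, Te = e$pattern$te, VT = e$pattern$vt,
         VT_TI = e$pattern$vt_over_ti, VT_TE = e$pattern$vt_over_te,
         Ti_frac = e$pattern$ti_frac, RR = e$pattern$rr_breath,
         V = e$pattern$v_minute, VO2 = e$pattern$vo2,
         EDV = e$hemo$edv, ESV = e$hemo$esv, SV = e$hemo$sv,
         CO = e$hemo$co, CI = e$hemo$ci, GPVR = e$hemo$gpvr,
         SI_stroke = e$hemo$stroke_index,
         VSI = e$sync$vsi, HI = e$sync$hi)
  v[flat_index_names()]
}

#' Compute the full index bundle for one maneuver epoch
#'
#' Runs breath segmentation, the ventilation spectrum, ectopic flagging, the
#' RR / SBP / DBP spectra, time-domain and geometric HRV, the ECG summary,
#' blood-pressure and hemodynamic summaries, the baroreflex alpha and the
#' synchronization indices on one epoch of a record.
#'
#' @param record a [subject_record()] (full record).
#' @param label epoch label to analyze.
#' @param config a [crm_config()].
#' @return list of class `epoch_indices` with the sub-structures and a
#'   `flat` named vector (one column of the per-epoch output tables).
#' @export
epoch_indices <- function(record, label, config = crm_config()) {
  ep <- slice_epoch(record, label)
  beats <- detect_ectopics(ep$beats, threshold = config$ectopic_threshold,
                           window = config$ectopic_window)
  cb <- clean_beats(beats)
  breaths <- segment_breaths(ep$flow, lowpass_hz = config$breath_lowpass_hz,
                             hysteresis = config$breath_hysteresis,
                             min_duration = config$breath_min_duration,
                             min_volume = config$breath_min_volume)
  pattern <- pattern_indices(breaths, vo2_fraction = config$vo2_fraction)
  vrv <- band_powers(ventilation_waveform(breaths, fs = config$fs_hz),
                     scheme = config$bands,
                     segment_s = config$welch_segment_s,
                     overlap = config$welch_overlap)
  bspec <- function(time, value) {
    band_powers(resample_events(time, value, fs = config$fs_hz),
                scheme = config$bands, segment_s = config$welch_segment_s,
                overlap = config$welch_overlap)
  }
  hrv_spec <- bspec(cb$time, cb$rr)
  ok <- !beats$ectopic
  sbp_spec <- bspec(beats$time[ok], beats$sbp[ok])
  dbp_spec <- bspec(beats$time[ok], beats$dbp[ok])
  hrv_time <- time_domain(cb$rr)
  baev <- baevsky(cb$rr, bin_ms = config$baevsky_bin_ms)
  ecg <- ecg_summary(beats)
  bp <- bp_summary(beats[ok, , drop = FALSE])
  br <- baroreflex_alpha(hrv_spec, sbp_spec)
  bsa <- body_surface_area(record$weight_kg, record$height_cm,
                           formula = config$bsa_formula)
  hemo <- hemodynamic_indices(beats[ok, , drop = FALSE], bp, ecg$hr, bsa)
  sync <- sync_indices(ecg$hr, pattern$rr_breath, hemo$co, pattern$v_minute)
  e <- structure(list(
    label = label, pattern = pattern, vrv = vrv, hrv_spec = hrv_spec,
    hrv_time = hrv_time, baevsky = baev, ecg = ecg,
    sbp_spec = sbp_spec, dbp_spec = dbp_spec, bp = bp, baroreflex = br,
    hemo = hemo, sync = sync), class = "epoch_indices")
  e$flat <- flatten_epoch(e)
  e
}

#' Load the shipped reference increment limits
#'
#' The packaged table of per-index Q1/Q3 increment limits for both contrasts
#' (SR to CR6, SR to CR15) with the tail class each side maps to. Derived
#' from a reference cohort of 183 healthy male athletes; classifying input
#' from other populations emits a provenance warning in
#' [classify_reactivity()].
#'
#' @param path optional path to a user limits file with the same columns
#'   (`index,contrast,median,q1,q3,low_tail_class,high_tail_class`; `median`
#'   optional).
#' @return `data.frame` of class `reference_limits`.
#' @export
reference_limits <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "reference_limits.csv",
                        package = "crmaneuver")
  }
  lim <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("index", "contrast", "q1", "q3", "low_tail_class",
            "high_tail_class")
  if (!all(need %in% names(lim))) {
    stop("limits file must have columns: ", paste(need, collapse = ", "))
  }
  if (any(lim$q1 > lim$q3)) stop("limits must satisfy q1 <= q3")
  structure(lim, class = c("reference_limits", "data.frame"))
}

#' Classify per-index increments against reference limits
#'
#' For each index and contrast: `delta < q1` maps to the low-tail class,
#' `delta > q3` to the high-tail class, and boundary values classify
#' `"expected"` (closed interval). Indices absent from the limits table, or
#' with missing deltas, classify `"not_evaluated"`. The classification is a
#' total deterministic function of (delta, limits).
#'
#' @param deltas `data.frame` with columns `index`, `delta_cr6`, `delta_cr15`.
#' @param limits a [reference_limits()] table.
#' @param athlete logical; `FALSE` warns that the shipped limits derive from
#'   a male-athlete reference cohort.
#' @return `deltas` with `class_cr6` and `class_cr15` columns filled.
#' @export
classify_reactivity <- function(deltas, limits = reference_limits(),
                                athlete = TRUE) {
  if (!athlete) {
    warning("shipped reference limits derive from a cohort of male ",
            "athletes; interpret non-athlete classifications with care")
  }
  one <- function(idx, delta, contrast) {
    row <- limits[limits$index == idx & limits$contrast == contrast, ]
    if (nrow(row) == 0L || is.na(delta)) return("not_evaluated")
    if (delta < row$q1[1]) row$low_tail_class[1]
    else if (delta > row$q3[1]) row$high_tail_class[1]
    else "expected"
  }
  deltas$class_cr6 <- vapply(seq_len(nrow(deltas)), function(i) {
    one(deltas$index[i], deltas$delta_cr6[i], "CR6")
  }, character(1))
  deltas$class_cr15 <- vapply(seq_len(nrow(deltas)), function(i) {
    one(deltas$index[i], deltas$delta_cr15[i], "CR15")
  }, character(1))
  deltas
}

#' Analyze one subject over the three maneuver epochs
#'
#' Applies the exclusion gate, computes the per-epoch index bundles, the
#' delta increments (`CR6 - SR` and `CR15 - SR` for every scalar index) and
#' their reactivity classes.
#'
#' @param record a [subject_record()].
#' @param config a [crm_config()].
#' @param limits a [reference_limits()] table (or `NULL` to skip
#'   classification).
#' @return list of class `subject_analysis`: `status` (`"ok"`/`"excluded"`),
#'   `reason`, `epochs` (named list of [epoch_indices()]), `flat` (matrix,
#'   epochs x indices) and `increments` (classified delta table). Excluded
#'   records return a structured refusal, not an error.
#' @export
analyze_subject <- function(record, config = crm_config(),
                            limits = reference_limits()) {
  gate <- exclusion_gate(record, threshold = config$ectopic_threshold,
                         window = config$ectopic_window)
  if (!gate$keep) {
    return(structure(list(subject_id = record$subject_id,
                          status = "excluded", reason = gate$reason,
                          epoch = gate$epoch, epochs = NULL, flat = NULL,
                          increments = NULL),
                     class = "subject_analysis"))
  }
  labels <- record$segments$label
  epochs <- lapply(labels, function(lab) epoch_indices(record, lab, config))
  names(epochs) <- labels
  flat <- do.call(rbind, lapply(epochs, `[[`, "flat"))
  rownames(flat) <- labels
  inc <- data.frame(index = colnames(flat),
                    delta_cr6 = flat["CR6", ] - flat["SR", ],
                    delta_cr15 = flat["CR15", ] - flat["SR", ],
                    row.names = NULL)
  if (!is.null(limits)) inc <- classify_reactivity(inc, limits)
  structure(list(subject_id = record$subject_id, status = "ok",
                 reason = NA_character_, epoch = NA_character_,
                 epochs = epochs, flat = flat, increments = inc),
            class = "subject_analysis")
}

# type-7 quartile summary formatted like the reference tables
med_iqr <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, type = 7,
                       names = FALSE)
  c(q1 = q[1], median = q[2], q3 = q[3])
}

#' Cohort analysis with paired Wilcoxon tests
#'
#' Applies the exclusion gate to every record (counts reported), analyzes the
#' kept subjects, summarizes each index per epoch as median (Q1; Q3), runs
#' the Wilcoxon matched-pairs signed-rank test on the three epoch contrasts,
#' and exports the empirical Q1/Q3 of the per-subject increments in the
#' [reference_limits()] format so a user cohort can define its own limits.
#'
#' @param records list of [subject_record()].
#' @param config a [crm_config()].
#' @param limits a [reference_limits()] table for per-subject classification.
#' @return list of class `cohort_summary`: `n_total`, `n_excluded`,
#'   `exclusions` (id/reason/epoch), `summary` (index x epoch medians and
#'   quartiles), `tests` (per index and contrast: W, p), `empirical_limits`,
#'   and `subjects` (per-subject analyses).
#' @export
cohort_analysis <- function(records, config = crm_config(),
                            limits = reference_limits()) {
  analyses <- lapply(records, analyze_subject, config = config,
                     limits = limits)
  excluded <- Filter(function(a) a$status == "excluded", analyses)
  kept <- Filter(function(a) a$status == "ok", analyses)
  if (length(kept) == 0L) stop("all subjects excluded: no cohort to analyze")
  idx <- flat_index_names()
  arr <- simplify2array(lapply(kept, `[[`, "flat"))
  if (length(dim(arr)) == 2L) {
    arr <- array(arr, dim = c(dim(arr), 1L),
                 dimnames = c(dimnames(arr), list(NULL)))
  }
  labels <- rownames(kept[[1]]$flat)

  rows <- list(); tests <- list()
  contrasts <- list(c("SR", "CR6"), c("SR", "CR15"), c("CR6", "CR15"))
  for (j in seq_along(idx)) {
    for (lab in labels) {
      v <- arr[lab, j, ]
      q <- med_iqr(v)
      rows[[length(rows) + 1L]] <- data.frame(
        index = idx[j], epoch = lab, median = q["median"], q1 = q["q1"],
        q3 = q["q3"],
        formatted = sprintf("%.5g (%.5g; %.5g)", q["median"], q["q1"],
                            q["q3"]))
    }
    for (ct in contrasts) {
      a <- arr[ct[1], j, ]; b <- arr[ct[2], j, ]
      ok <- !is.na(a) & !is.na(b)
      wt <- if (sum(ok) >= 6) wilcoxon_signed_rank(b[ok], a[ok]) else
        list(statistic = NA_real_, p_value = NA_real_, evaluable = FALSE)
      tests[[length(tests) + 1L]] <- data.frame(
        index = idx[j], contrast = paste(ct, collapse = "-"),
        statistic = wt$statistic, p_value = wt$p_value,
        evaluable = wt$evaluable)
    }
  }
  summary_df <- do.call(rbind, rows); rownames(summary_df) <- NULL
  tests_df <- do.call(rbind, tests); rownames(tests_df) <- NULL

  emp <- list()
  for (ct in c("CR6", "CR15")) {
    col <- if (ct == "CR6") "delta_cr6" else "delta_cr15"
    for (j in seq_along(idx)) {
      d <- vapply(kept, function(a) {
        a$increments[[col]][a$increments$index == idx[j]]
      }, numeric(1))
      q <- med_iqr(d)
      emp[[length(emp) + 1L]] <- data.frame(
        index = idx[j], contrast = ct, median = q["median"], q1 = q["q1"],
        q3 = q["q3"], low_tail_class = "reduced",
        high_tail_class = "increased")
    }
  }
  emp_df <- do.call(rbind, emp); rownames(emp_df) <- NULL
  class(emp_df) <- c("reference_limits", "data.frame")

  structure(list(
    n_total = length(records), n_kept = length(kept),
    n_excluded = length(excluded),
    exclusions = data.frame(
      subject_id = vapply(excluded, `[[`, character(1), "subject_id"),
      reason = vapply(excluded, `[[`, character(1), "reason"),
      epoch = vapply(excluded, `[[`, character(1), "epoch")),
    summary = summary_df, tests = tests_df, empirical_limits = emp_df,
    subjects = analyses), class = "cohort_summary")
}
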