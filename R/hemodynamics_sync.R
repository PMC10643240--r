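#' Body surface area
#'
#' DuBois (`0.007184 W^0.425 H^0.725`, default) or Mosteller
#' (`sqrt(W H / 3600)`), with weight in kg and height in cm.
#'
#' @param weight_kg,height_cm anthropometrics, both > 0.
#' @param formula `"dubois"` or `"mosteller"`.
#' @return body surface area, m^2.
#' @export
body_surface_area <- function(weight_kg, height_cm,
                              formula = c("dubois", "mosteller")) {
  formula <- match.arg(formula)
  if (any(weight_kg <= 0) || any(height_cm <= 0)) {
    stop("weight and height must be positive")
  }
  switch(formula,
         dubois = 0.007184 * weight_kg^0.425 * height_cm^0.725,
         mosteller = sqrt(weight_kg * height_cm / 3600))
}

#' Per-epoch blood-pressure summary
#'
#' Epoch means of per-beat systolic and diastolic finger pressure and of the
#' per-beat pulse pressure `sbp - dbp`. Pulse pressure is averaged per beat,
#' not taken as the difference of the two means, so out-of-phase systolic and
#' diastolic oscillations are summarized correctly.
#'
#' @param beats a [beat_series()].
#' @return list of class `bp_summary`: `sbpf`, `dbpf`, `pbpf` (mmHg).
#' @export
bp_summary <- function(beats) {
  structure(list(
    sbpf = mean(beats$sbp, na.rm = TRUE),
    dbpf = mean(beats$dbp, na.rm = TRUE),
    pbpf = mean(beats$sbp - beats$dbp, na.rm = TRUE)
  ), class = "bp_summary")
}

#' Derived systemic-hemodynamics indices
#'
#' Epoch means of the per-beat chamber-volume annotations, then:
#' cardiac output `co = sv x hr / 1000` (dm^3 min^-1), cardiac index
#' `ci = co / bsa`, stroke index `sv / bsa` (cm^3 m^-2), mean arterial
#' pressure `map = dbpf + (sbpf - dbpf)/3`, and peripheral resistance
#' `gpvr = 80 x map / co` (dyn s cm^-5; 80 is the conventional
#' mmHg min dm^-3 conversion constant).
#'
#' @param beats a [beat_series()] with `sv` (and optionally `edv`/`esv`)
#'   annotations.
#' @param bp a [bp_summary()].
#' @param hr heart rate, min^-1.
#' @param bsa body surface area, m^2.
#' @return list of class `hemodynamics`.
#' @export
hemodynamic_indices <- function(beats, bp, hr, bsa) {
  if (all(is.na(beats$sv))) stop("stroke-volume annotations are absent")
  sv <- mean(beats$sv, na.rm = TRUE)
  edv <- if (all(is.na(beats$edv))) NA_real_ else mean(beats$edv, na.rm = TRUE)
  esv <- if (all(is.na(beats$esv))) NA_real_ else mean(beats$esv, na.rm = TRUE)
  co <- sv * hr / 1000
  map <- bp$dbpf + (bp$sbpf - bp$dbpf) / 3
  structure(list(
    edv = edv, esv = esv, sv = sv, co = co,
    ci = co / bsa, stroke_index = sv / bsa,
    map = map,
    gpvr = if (co > 0) 80 * map / co else NA_real_,
    bsa = bsa
  ), class = "hemodynamics")
}

#' Cardiorespiratory synchronization indices
#'
#' Hildebrandt (rate synchronization) index `hi = hr / rr_breath`
#' (dimensionless) and volume synchronization index `vsi = co / v_minute`
#' (dm^3 L^-1).
#'
#' @param hr heart rate, min^-1.
#' @param rr_breath breathing rate, min^-1 (> 0).
#' @param co cardiac output, dm^3 min^-1.
#' @param v_minute minute ventilation, L min^-1 (> 0).
#' @return list of class `sync_indices`: `hi`, `vsi`.
#' @export
sync_indices <- function(hr, rr_breath, co, v_minute) {
  if (rr_breath <= 0 || v_minute <= 0) {
    stop("breathing rate and minute ventilation must be positive")
  }
  structure(list(hi = hr / rr_breath, vsi = co / v_minute),
            class = "sync_indices")
}
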