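#' Analyte and urine constants
#'
#' Molar masses of the two acrolein mercapturic-acid biomarkers and the
#' density used to convert urine weight to volume. The defaults are computed
#' from the molecular formulas with IUPAC atomic weights
#' (C 12.011, H 1.008, N 14.007, O 15.999, S 32.06):
#' 3-HPMA (N-acetyl-S-(3-hydroxypropyl)-L-cysteine, C8H15NO4S) 221.271 g/mol,
#' CEMA (N-acetyl-S-(carboxyethyl)-L-cysteine, C8H13NO5S) 235.254 g/mol.
#' Urine density defaults to 1 kg/L.
#'
#' @param mw_hpma,mw_cema Molar masses in g/mol.
#' @param urine_density Urine density in kg/L.
#' @return A list of class `analyte_constants`.
#' @export
analyte_constants <- function(mw_hpma = 221.271, mw_cema = 235.254,
                              urine_density = 1.0) {
  stopifnot(mw_hpma > 0, mw_cema > 0, urine_density > 0)
  structure(list(mw_hpma = mw_hpma, mw_cema = mw_cema,
                 urine_density = urine_density),
            class = "analyte_constants")
}

#' Urine volume from weight
#'
#' @param urine_weight_g Urine weight in grams (non-negative).
#' @param density Urine density in kg/L (default 1).
#' @return Volume in litres.
#' @examples
#' interval_volume(500) # 0.5 L
#' @export
interval_volume <- function(urine_weight_g, density = 1.0) {
  if (any(!is.finite(urine_weight_g) | urine_weight_g < 0)) {
    stop("urine_weight_g must be non-negative", call. = FALSE)
  }
  stopifnot(density > 0)
  (urine_weight_g / 1000) / density
}

#' Excreted amount of an analyte over a collection interval
#'
#' Converts a concentration in ng/mL and a collection volume to micromoles:
#' total ng = conc x volume in mL; umol = ng / 1000 / molar mass.
#'
#' @param conc_ng_ml Concentration in ng/mL.
#' @param volume_l Collection volume in litres.
#' @param mw_g_mol Molar mass in g/mol (> 0).
#' @return Amount in micromoles.
#' @examples
#' interval_amount(100, 0.5, 221.271) # ~0.226 umol
#' @export
interval_amount <- function(conc_ng_ml, volume_l, mw_g_mol) {
  if (any(mw_g_mol <= 0) || any(!is.finite(mw_g_mol))) {
    stop("molar mass must be positive", call. = FALSE)
  }
  if (any(conc_ng_ml < 0) || any(volume_l < 0)) {
    stop("concentration and volume must be non-negative", call. = FALSE)
  }
  conc_ng_ml * (volume_l * 1000) / mw_g_mol / 1000
}

#' Collection-window specification
#'
#' Defines how timestamps map to study days and overnight windows. A study
#' day runs from `day_start` to `day_start` of the next calendar day (the
#' study began at 08:00 on day 1); the overnight window runs from
#' `night_start` in the evening of a study day to `night_end` the next
#' morning. All windows are half-open `[start, end)`.
#'
#' @param day_start Clock time ("HH:MM") at which a study day begins.
#' @param night_start,night_end Clock times bounding the overnight window.
#' @param origin Optional POSIXct giving `day_start` on study day 1; when
#'   NULL it is inferred as the last `day_start` boundary at or before the
#'   earliest interval start.
#' @return A list of class `window_spec`.
#' @export
window_spec <- function(day_start = "08:00", night_start = "20:00",
                        night_end = "08:00", origin = NULL) {
  structure(list(day_start = parse_clock(day_start),
                 night_start = parse_clock(night_start),
                 night_end = parse_clock(night_end),
                 origin = origin),
            class = "window_spec")
}

parse_clock <- function(x) {
  if (is.numeric(x)) return(x)
  parts <- as.numeric(strsplit(x, ":", fixed = TRUE)[[1]])
  parts[1] + parts[2] / 60
}

# day-1 boundary (day_start on the first study day) for a set of intervals
infer_origin <- function(start, spec) {
  if (!is.null(spec$origin)) return(as.POSIXct(spec$origin, tz = "UTC"))
  t0 <- min(start)
  midnight <- as.POSIXct(format(t0, "%Y-%m-%d"), tz = "UTC")
  cand <- midnight + spec$day_start * 3600
  if (cand > t0) cand <- cand - 86400
  cand
}

validate_intervals <- function(intervals) {
  require_columns(intervals,
                  c("participant", "start", "end", "urine_weight_g",
                    "conc_hpma_ng_ml", "conc_cema_ng_ml"), "urine table")
  intervals$start <- as.POSIXct(intervals$start, tz = "UTC")
  intervals$end <- as.POSIXct(intervals$end, tz = "UTC")
  if (any(intervals$end <= intervals$start)) {
    stop("interval end must be after start", call. = FALSE)
  }
  overlaps <- intervals |>
    dplyr::arrange(.data$participant, .data$start) |>
    dplyr::group_by(.data$participant) |>
    dplyr::filter(dplyr::row_number() > 1 &
                    .data$start < dplyr::lag(.data$end)) |>
    dplyr::ungroup()
  if (nrow(overlaps) > 0) {
    stop("overlapping urine intervals for participant(s): ",
         paste(unique(overlaps$participant), collapse = ", "), call. = FALSE)
  }
  intervals
}

# per-interval analyte amounts in umol
interval_amounts <- function(intervals, constants) {
  vol <- interval_volume(intervals$urine_weight_g, constants$urine_density)
  intervals |>
    dplyr::mutate(
      volume_l = vol,
      hpma_umol = interval_amount(.data$conc_hpma_ng_ml, vol, constants$mw_hpma),
      cema_umol = interval_amount(.data$conc_cema_ng_ml, vol, constants$mw_cema))
}

# Credit interval amounts to a repeating daily window [offset_h, offset_h + len_h)
# after each day boundary, pro-rated by the fraction of interval duration
# falling inside each window occurrence ("prorate") or assigned whole to the
# window containing the interval midpoint ("whole").
credit_windows <- function(x, origin, offset_h, len_h, method) {
  dur <- as.numeric(difftime(x$end, x$start, units = "hours"))
  rel_start <- as.numeric(difftime(x$start, origin, units = "hours"))
  rel_end <- rel_start + dur
  if (method == "whole") {
    mid <- (rel_start + rel_end) / 2
    win <- floor((mid - offset_h) / 24) + 1
    inside <- (mid - offset_h) %% 24 < len_h
    out <- x[inside, , drop = FALSE]
    out$window_day <- win[inside]
    out$credit <- 1
    out$overlap_h <- dur[inside]
    return(out)
  }
  # candidate window occurrences each interval can touch
  d0 <- floor((rel_start - offset_h) / 24)
  d1 <- floor((rel_end - offset_h) / 24)
  reps <- pmax(d1 - d0 + 1L, 1L)
  idx <- rep(seq_len(nrow(x)), reps)
  day <- unlist(lapply(seq_len(nrow(x)), function(i) seq(d0[i], d1[i])))
  w_start <- offset_h + day * 24
  w_end <- w_start + len_h
  overlap <- pmax(0, pmin(rel_end[idx], w_end) - pmax(rel_start[idx], w_start))
  keep <- overlap > 0
  out <- x[idx[keep], , drop = FALSE]
  out$window_day <- day[keep] + 1L
  out$overlap_h <- overlap[keep]
  out$credit <- overlap[keep] / dur[idx[keep]]
  out
}

#' Daily biomarker excretion per participant
#'
#' Converts interval concentrations to amounts and aggregates them into
#' study days (running `day_start` to `day_start`). By default an interval
#' spanning a day boundary is pro-rated by the fraction of its duration on
#' each side, which assumes uniform excretion within the interval and makes
#' the aggregation conserve total amounts; `method = "whole"` instead
#' assigns each interval to the day containing its midpoint.
#'
#' @param intervals Data frame with columns `participant`, `start`, `end`
#'   (POSIXct or ISO-8601 strings), `urine_weight_g`, `conc_hpma_ng_ml`,
#'   `conc_cema_ng_ml`.
#' @param spec A [window_spec()].
#' @param constants An [analyte_constants()].
#' @param method "prorate" (default) or "whole".
#' @param n_days When given, the output grid is completed to all
#'   participant x day combinations for days `1..n_days`; days with no
#'   coverage get zero amounts and `missing = TRUE`.
#' @return Tibble: `participant`, `study_day`, `hpma_umol`, `cema_umol`,
#'   `sum_umol`, `coverage_h`, `missing`.
#' @export
daily_excretion <- function(intervals, spec = window_spec(),
                            constants = analyte_constants(),
                            method = c("prorate", "whole"), n_days = NULL) {
  method <- match.arg(method)
  x <- validate_intervals(intervals)
  x <- interval_amounts(x, constants)
  origin <- infer_origin(x$start, spec)
  credited <- credit_windows(x, origin, offset_h = 0, len_h = 24,
                             method = method)
  out <- credited |>
    dplyr::group_by(.data$participant, study_day = .data$window_day) |>
    dplyr::summarise(
      hpma_umol = sum(.data$hpma_umol * .data$credit),
      cema_umol = sum(.data$cema_umol * .data$credit),
      coverage_h = sum(.data$overlap_h),
      .groups = "drop")
  if (!is.null(n_days)) {
    out <- out |>
      tidyr::complete(participant = unique(x$participant),
                      study_day = seq_len(n_days),
                      fill = list(hpma_umol = 0, cema_umol = 0,
                                  coverage_h = 0)) |>
      dplyr::filter(.data$study_day >= 1, .data$study_day <= n_days)
  }
  out |>
    dplyr::mutate(sum_umol = .data$hpma_umol + .data$cema_umol,
                  missing = .data$coverage_h == 0) |>
    dplyr::select("participant", "study_day", "hpma_umol", "cema_umol",
                  "sum_umol", "coverage_h", "missing") |>
    dplyr::arrange(.data$participant, .data$study_day)
}

#' Overnight biomarker excretion per participant-night
#'
#' Accumulates interval amounts falling inside the overnight window
#' (`night_start` to `night_end`, default 20:00-08:00), pro-rated by overlap
#' as in [daily_excretion()]. Each night is keyed by the study day of its
#' evening, so the night credited to day 3 follows day 3's dinner.
#'
#' @inheritParams daily_excretion
#' @return Tibble: `participant`, `study_day` (evening's day), `hpma_umol`,
#'   `cema_umol`, `sum_umol`, `coverage_h`, `missing`.
#' @export
overnight_excretion <- function(intervals, spec = window_spec(),
                                constants = analyte_constants(),
                                method = c("prorate", "whole"),
                                n_days = NULL) {
  method <- match.arg(method)
  x <- validate_intervals(intervals)
  x <- interval_amounts(x, constants)
  origin <- infer_origin(x$start, spec)
  offset <- (spec$night_start - spec$day_start) %% 24
  len <- (spec$night_end - spec$night_start) %% 24
  credited <- credit_windows(x, origin, offset_h = offset, len_h = len,
                             method = method)
  out <- credited |>
    dplyr::group_by(.data$participant, study_day = .data$window_day) |>
    dplyr::summarise(
      hpma_umol = sum(.data$hpma_umol * .data$credit),
      cema_umol = sum(.data$cema_umol * .data$credit),
      coverage_h = sum(.data$overlap_h),
      .groups = "drop")
  if (!is.null(n_days)) {
    out <- out |>
      tidyr::complete(participant = unique(x$participant),
                      study_day = seq_len(n_days),
                      fill = list(hpma_umol = 0, cema_umol = 0,
                                  coverage_h = 0)) |>
      dplyr::filter(.data$study_day >= 1, .data$study_day <= n_days)
  }
  out |>
    dplyr::mutate(sum_umol = .data$hpma_umol + .data$cema_umol,
                  missing = .data$coverage_h == 0) |>
    dplyr::select("participant", "study_day", "hpma_umol", "cema_umol",
                  "sum_umol", "coverage_h", "missing") |>
    dplyr::arrange(.data$participant, .data$study_day)
}

#' CEMA / 3-HPMA ratio
#'
#' Ratio of the two biomarker amounts for a participant-day. Undefined
#' (returned as NA with a message) when the 3-HPMA amount is not positive;
#' such records are excluded from ratio summaries.
#'
#' @param cema_umol,hpma_umol Amounts in micromoles (vectorised).
#' @return Numeric vector of ratios with NA where undefined.
#' @export
daily_ratio <- function(cema_umol, hpma_umol) {
  undefined <- !is.finite(hpma_umol) | hpma_umol <= 0
  if (any(undefined)) {
    message(sum(undefined),
            " record(s) with non-positive 3-HPMA excluded from ratios")
  }
  ifelse(undefined, NA_real_, cema_umol / hpma_umol)
}

#' Read a urine interval table from CSV
#'
#' Expected columns: `participant`, `start`, `end` (ISO-8601),
#' `urine_weight_g`, `conc_hpma_ng_ml`, `conc_cema_ng_ml`.
#'
#' @param path Path to a CSV file.
#' @return A tibble with parsed POSIXct timestamps (UTC).
#' @export
read_urine <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  validate_intervals(x)
}
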