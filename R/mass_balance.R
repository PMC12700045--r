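#' Mass-balance model parameters
#'
#' Physiological and chemical constants of the intestinal acrolein
#' mass-balance model. Small-intestinal lipolysis hydrolyses about 95% of
#' dietary triglyceride to glycerol and free fatty acids and the released
#' glycerol is absorbed, so the glycerol available to the colonic microbiota
#' is modelled as the unhydrolysed fraction (1 - `hydrolysis_eff`) of
#' intake. Oral dosing studies indicate about 20% of an acrolein dose is
#' excreted in urine as 3-HPMA, which is inverted to back-calculate
#' intestinal acrolein from urinary 3-HPMA.
#'
#' @param mw_glycerol,mw_acrolein Molar masses in g/mol.
#' @param hydrolysis_eff Fraction of dietary triglyceride hydrolysed (and
#'   its glycerol absorbed) in the small intestine, in `[0, 1]`.
#' @param hpma_excretion_frac Fraction of an acrolein dose excreted as
#'   urinary 3-HPMA, in `(0, 1]`.
#' @param denominator_mode Glycerol pool used for mol% conversion:
#'   `"colonic"` (glycerol reaching the colon, default) or `"intake"`
#'   (total dietary glycerol).
#' @return A list of class `mass_balance_params`.
#' @export
mass_balance_params <- function(mw_glycerol = 92.09, mw_acrolein = 56.06,
                                hydrolysis_eff = 0.95,
                                hpma_excretion_frac = 0.20,
                                denominator_mode = c("colonic", "intake")) {
  denominator_mode <- match.arg(denominator_mode)
  stopifnot(mw_glycerol > 0, mw_acrolein > 0,
            hydrolysis_eff >= 0, hydrolysis_eff <= 1)
  if (hpma_excretion_frac <= 0 || hpma_excretion_frac > 1) {
    stop("hpma_excretion_frac must be in (0, 1]", call. = FALSE)
  }
  structure(list(mw_glycerol = mw_glycerol, mw_acrolein = mw_acrolein,
                 hydrolysis_eff = hydrolysis_eff,
                 hpma_excretion_frac = hpma_excretion_frac,
                 denominator_mode = denominator_mode),
            class = "mass_balance_params")
}

#' Convert grams of glycerol to millimoles
#'
#' @param glycerol_g Mass in grams (non-negative).
#' @param mw_glycerol Molar mass in g/mol (default 92.09).
#' @return Millimoles.
#' @export
glycerol_g_to_mmol <- function(glycerol_g, mw_glycerol = 92.09) {
  if (any(mw_glycerol <= 0)) stop("mw_glycerol must be positive", call. = FALSE)
  if (any(glycerol_g < 0)) stop("glycerol_g must be non-negative", call. = FALSE)
  glycerol_g / mw_glycerol * 1000
}

#' Glycerol reaching the colon
#'
#' The unhydrolysed fraction of dietary triglyceride-bound glycerol assumed
#' to escape small-intestinal absorption: at the default 95% hydrolysis
#' efficiency, a 0.44 g glycerol dinner delivers 0.24 mmol to the colon and
#' a 1.26 g dinner 0.68 mmol.
#'
#' @param glycerol_g Dietary glycerol in grams.
#' @param params A [mass_balance_params()].
#' @return Millimoles of glycerol reaching the colon (full precision; round
#'   to 2 decimals for reporting).
#' @export
colonic_glycerol <- function(glycerol_g, params = mass_balance_params()) {
  stopifnot(inherits(params, "mass_balance_params"))
  (1 - params$hydrolysis_eff) *
    glycerol_g_to_mmol(glycerol_g, params$mw_glycerol)
}

#' Back-calculate intestinal acrolein from urinary 3-HPMA
#'
#' Inverts the excretion fraction: intestinal acrolein = urinary 3-HPMA /
#' `hpma_excretion_frac`.
#'
#' @param hpma_umol Urinary 3-HPMA in micromoles.
#' @param params A [mass_balance_params()].
#' @return Intestinal acrolein in micromoles.
#' @export
acrolein_from_hpma <- function(hpma_umol, params = mass_balance_params()) {
  stopifnot(inherits(params, "mass_balance_params"))
  if (any(hpma_umol < 0)) stop("hpma_umol must be non-negative", call. = FALSE)
  hpma_umol / params$hpma_excretion_frac
}

#' Mole-percent of a glycerol pool converted to acrolein
#'
#' @param acrolein_umol Acrolein in micromoles.
#' @param glycerol_pool_mmol Glycerol pool in millimoles (> 0); typically
#'   the colonic delivery from [colonic_glycerol()] or total intake,
#'   depending on the `denominator_mode` of the model.
#' @return mol% converted; NA with a message for a non-positive pool.
#' @export
molpct_converted <- function(acrolein_umol, glycerol_pool_mmol) {
  if (any(acrolein_umol < 0)) {
    stop("acrolein_umol must be non-negative", call. = FALSE)
  }
  undefined <- !is.finite(glycerol_pool_mmol) | glycerol_pool_mmol <= 0
  if (any(undefined)) {
    message(sum(undefined), " record(s) with non-positive glycerol pool; ",
            "mol% undefined")
  }
  ifelse(undefined, NA_real_,
         100 * acrolein_umol / (glycerol_pool_mmol * 1000))
}

#' Acrolein intake from coffee
#'
#' Amount of acrolein in a volume of coffee at a given concentration.
#'
#' @param conc_ug_ml Acrolein concentration in ug/mL.
#' @param volume_ml Coffee volume in mL.
#' @param mw_acrolein Molar mass in g/mol (default 56.06).
#' @return Micromoles of acrolein.
#' @export
coffee_acrolein <- function(conc_ug_ml, volume_ml, mw_acrolein = 56.06) {
  if (any(mw_acrolein <= 0)) stop("mw_acrolein must be positive", call. = FALSE)
  if (any(conc_ug_ml < 0) || any(volume_ml < 0)) {
    stop("concentration and volume must be non-negative", call. = FALSE)
  }
  conc_ug_ml * volume_ml / mw_acrolein
}

#' Exposure-class acrolein estimates
#'
#' Runs the full estimation chain for each dinner-exposure class: median
#' overnight 3-HPMA -> intestinal acrolein; dinner glycerol range ->
#' colonic glycerol range; acrolein / glycerol pool -> mol% converted.
#'
#' @param overnight Output of [overnight_excretion()].
#' @param day_glycerol Output of [diet_glycerol()].
#' @param attribution An [attribution_config()].
#' @param params A [mass_balance_params()].
#' @return Tibble with one row per exposure class ("low", "high"):
#'   median overnight 3-HPMA, estimated intestinal acrolein, dinner glycerol
#'   range, colonic glycerol range, and mol% converted range.
#' @export
acrolein_estimates <- function(overnight, day_glycerol,
                               attribution = default_attribution(),
                               params = mass_balance_params()) {
  stopifnot(inherits(params, "mass_balance_params"))
  on <- overnight |>
    dplyr::filter(!.data$missing) |>
    dplyr::mutate(class = attribute_exposure(.data$study_day, attribution)) |>
    dplyr::filter(.data$class %in% c("low", "high"))
  dinners <- day_glycerol |>
    dplyr::filter(.data$slot == "dinner") |>
    dplyr::mutate(class = attribute_exposure(.data$study_day, attribution)) |>
    dplyr::filter(.data$class %in% c("low", "high"))
  on |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(median_hpma_umol = stats::median(.data$hpma_umol),
                     .groups = "drop") |>
    dplyr::left_join(
      dinners |>
        dplyr::group_by(.data$class) |>
        dplyr::summarise(dinner_glycerol_min_g = min(.data$glycerol_g),
                         dinner_glycerol_max_g = max(.data$glycerol_g),
                         .groups = "drop"),
      by = "class") |>
    dplyr::mutate(
      acrolein_umol = acrolein_from_hpma(.data$median_hpma_umol, params),
      colonic_min_mmol = colonic_glycerol(.data$dinner_glycerol_min_g, params),
      colonic_max_mmol = colonic_glycerol(.data$dinner_glycerol_max_g, params),
      pool_min_mmol = switch(params$denominator_mode,
        colonic = .data$colonic_min_mmol,
        intake = glycerol_g_to_mmol(.data$dinner_glycerol_min_g,
                                    params$mw_glycerol)),
      pool_max_mmol = switch(params$denominator_mode,
        colonic = .data$colonic_max_mmol,
        intake = glycerol_g_to_mmol(.data$dinner_glycerol_max_g,
                                    params$mw_glycerol)),
      molpct_min = molpct_converted(.data$acrolein_umol, .data$pool_max_mmol),
      molpct_max = molpct_converted(.data$acrolein_umol, .data$pool_min_mmol)) |>
    dplyr::arrange(dplyr::desc(.data$class))
}
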