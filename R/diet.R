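#' Glycerol content of a single food item
#'
#' Estimates the triglyceride-bound glycerol in a food item from its fat
#' content. Dietary fat is assumed to be essentially all triglyceride, so the
#' glycerol backbone is a fixed mass fraction of the fat, expressed as a
#' per-item correction factor that accounts for the fatty-acid chain lengths
#' of that food. The default factor used by the bundled synthetic menu,
#' 0.1040, is the glycerol/triolein molar-mass ratio (92.09 / 885.45).
#'
#' @param fat_g Fat per serving in grams. Vectorised; must be non-negative.
#' @param correction_factor Glycerol-per-fat mass fraction in `[0, 1]`.
#' @param item Optional item name(s) used in validation messages.
#' @return Grams of glycerol, same length as `fat_g`.
#' @examples
#' item_glycerol(10, 0.104)
#' @export
item_glycerol <- function(fat_g, correction_factor, item = NULL) {
  bad_fat <- which(!is.finite(fat_g) | fat_g < 0)
  if (length(bad_fat) > 0) {
    stop("negative or non-finite fat_g for item(s): ",
         item_label(item, bad_fat), call. = FALSE)
  }
  bad_cf <- which(!is.finite(correction_factor) |
                    correction_factor < 0 | correction_factor > 1)
  if (length(bad_cf) > 0) {
    stop("correction_factor outside [0, 1] for item(s): ",
         item_label(item, bad_cf), call. = FALSE)
  }
  fat_g * correction_factor
}

item_label <- function(item, idx) {
  if (is.null(item)) paste(idx, collapse = ", ")
  else paste(item[pmin(idx, length(item))], collapse = ", ")
}

#' Glycerol content of a meal
#'
#' Sums [item_glycerol()] over the food items of one meal. An empty meal has
#' zero glycerol.
#'
#' @param items Data frame with columns `fat_g` and `correction_factor`
#'   (optionally `item` for error messages).
#' @return Grams of glycerol (length-1 numeric).
#' @export
meal_glycerol <- function(items) {
  stopifnot(is.data.frame(items))
  if (nrow(items) == 0) return(0)
  require_columns(items, c("fat_g", "correction_factor"), "meal items")
  sum(item_glycerol(items$fat_g, items$correction_factor, items$item))
}

#' Per-slot glycerol profile of one study day
#'
#' Aggregates the food items of a single participant-group day into per-slot
#' glycerol, the percentage each slot contributes to the day, and the daily
#' total. Percentages are undefined (NA) for an all-zero day.
#'
#' @param day_items Data frame with columns `group`, `study_day`, `slot`,
#'   `fat_g`, `correction_factor` for exactly one group and day.
#' @return A tibble with one row per meal slot: `group`, `study_day`, `slot`,
#'   `glycerol_g`, `pct_of_day`, `day_total_g`.
#' @export
day_profile <- function(day_items) {
  require_columns(day_items, c("group", "study_day", "slot", "fat_g",
                               "correction_factor"), "diet table")
  if (length(unique(day_items$study_day)) > 1 ||
      length(unique(day_items$group)) > 1) {
    stop("day_profile() expects a single group and study day; got groups {",
         paste(unique(day_items$group), collapse = ", "), "}, days {",
         paste(unique(day_items$study_day), collapse = ", "), "}",
         call. = FALSE)
  }
  check_slots(day_items$slot)
  day_items$glycerol_g <- item_glycerol(
    day_items$fat_g, day_items$correction_factor,
    if ("item" %in% names(day_items)) day_items$item else NULL)
  out <- day_items |>
    dplyr::group_by(.data$group, .data$study_day, .data$slot) |>
    dplyr::summarise(glycerol_g = sum(.data$glycerol_g), .groups = "drop")
  total <- sum(out$glycerol_g)
  out$pct_of_day <- if (total > 0) 100 * out$glycerol_g / total else NA_real_
  out$day_total_g <- total
  tibble::as_tibble(out)
}

MEAL_SLOTS <- c("breakfast", "lunch", "dinner", "snack")

check_slots <- function(slot) {
  bad <- setdiff(unique(slot), MEAL_SLOTS)
  if (length(bad) > 0) {
    stop("unknown meal slot(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(MEAL_SLOTS, collapse = "/"), ")", call. = FALSE)
  }
  invisible(slot)
}

#' Day-level glycerol for a whole diet table
#'
#' Convenience wrapper applying [day_profile()] to every group x day of a
#' diet table.
#'
#' @param diet Data frame with columns `group`, `study_day`, `slot`, `item`,
#'   `fat_g`, `correction_factor`.
#' @return Tibble with one row per group x day x slot (see [day_profile()]).
#' @export
diet_glycerol <- function(diet) {
  require_columns(diet, c("group", "study_day", "slot", "fat_g",
                          "correction_factor"), "diet table")
  diet |>
    dplyr::group_by(.data$group, .data$study_day) |>
    dplyr::group_modify(~ day_profile(dplyr::mutate(.x,
                                                    group = .y$group,
                                                    study_day = .y$study_day)) |>
                          dplyr::select(-"group", -"study_day")) |>
    dplyr::ungroup() |>
    tibble::as_tibble()
}

#' Dinner-exposure attribution configuration
#'
#' Study days are attributed to a dinner glycerol class: "high" dinners,
#' "low" dinners, or "excluded" (days whose urine was pooled over 24 h and
#' cannot resolve an overnight window). The defaults are high `{3,4,7,8}`,
#' low `{1,2,5,6,9}` and excluded `{10,11}`. The three sets must be disjoint
#' and together cover days 1 to `n_days`.
#'
#' @param high,low,excluded Integer vectors of study days.
#' @param n_days Number of study days the sets must cover.
#' @return A list of class `attribution_config`.
#' @export
attribution_config <- function(high = c(3, 4, 7, 8),
                               low = c(1, 2, 5, 6, 9),
                               excluded = c(10, 11),
                               n_days = 11) {
  all_days <- sort(c(high, low, excluded))
  if (anyDuplicated(all_days)) {
    stop("attribution day sets overlap: day(s) ",
         paste(unique(all_days[duplicated(all_days)]), collapse = ", "),
         call. = FALSE)
  }
  if (!setequal(all_days, seq_len(n_days))) {
    stop("attribution day sets must partition days 1..", n_days,
         "; got {", paste(all_days, collapse = ", "), "}", call. = FALSE)
  }
  structure(list(high = as.integer(high), low = as.integer(low),
                 excluded = as.integer(excluded), n_days = as.integer(n_days)),
            class = "attribution_config")
}

#' @rdname attribution_config
#' @export
default_attribution <- function() attribution_config()

#' Attribute study days to dinner-exposure classes
#'
#' Deterministic lookup of each study day's dinner class under an
#' [attribution_config()].
#'
#' @param study_day Integer vector of study days.
#' @param config An [attribution_config()].
#' @return Character vector in `{"high", "low", "excluded"}`.
#' @export
attribute_exposure <- function(study_day, config = default_attribution()) {
  stopifnot(inherits(config, "attribution_config"))
  out <- rep(NA_character_, length(study_day))
  out[study_day %in% config$high] <- "high"
  out[study_day %in% config$low] <- "low"
  out[study_day %in% config$excluded] <- "excluded"
  if (anyNA(out)) {
    stop("study day(s) not covered by attribution config: ",
         paste(unique(study_day[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Threshold-based attribution from observed dinner glycerol
#'
#' For datasets without a predefined day grouping, classifies days by whether
#' the dinner glycerol meets a threshold. The default 1.5 g sits between the
#' study's low-dinner maximum (1.26 g) and high-dinner minimum (2.1 g).
#'
#' @param day_glycerol Output of [diet_glycerol()] (needs rows with
#'   `slot == "dinner"`).
#' @param threshold Grams of dinner glycerol at or above which a day is "high".
#' @param excluded Days to force into the "excluded" class.
#' @return An [attribution_config()] derived from the data.
#' @export
attribution_from_dinner <- function(day_glycerol, threshold = 1.5,
                                    excluded = c(10, 11)) {
  dinners <- day_glycerol |>
    dplyr::filter(.data$slot == "dinner") |>
    dplyr::group_by(.data$study_day) |>
    dplyr::summarise(glycerol_g = max(.data$glycerol_g), .groups = "drop")
  n_days <- max(dinners$study_day)
  keep <- !(dinners$study_day %in% excluded)
  high <- dinners$study_day[keep & dinners$glycerol_g >= threshold]
  low <- dinners$study_day[keep & dinners$glycerol_g < threshold]
  attribution_config(high = high, low = low, excluded = excluded,
                     n_days = n_days)
}

#' Read a diet table from CSV
#'
#' Expected columns: `group`, `study_day`, `slot`, `item`, `fat_g`,
#' `correction_factor`.
#'
#' @param path Path to a CSV file.
#' @return A tibble.
#' @export
read_diet <- function(path) {
  diet <- readr::read_csv(path, show_col_types = FALSE)
  require_columns(diet, c("group", "study_day", "slot", "item", "fat_g",
                          "correction_factor"), path)
  diet
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(what, " is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(df)
}
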