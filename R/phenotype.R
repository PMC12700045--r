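#' Mercapturic-acid phenotype classification rule
#'
#' A participant is labelled "CEMA" when CEMA exceeds 3-HPMA on more than
#' `majority_threshold` of valid study days, or (when the median override is
#' enabled) when the participant's median daily CEMA exceeds the median
#' daily 3-HPMA. Both comparisons are strict, so ties fall through to
#' `tie_label`; the default tie label is "HPMA" because 3-HPMA is usually
#' the dominant urinary mercapturic acid of acrolein.
#'
#' @param majority_threshold Fraction of days that must show CEMA > 3-HPMA
#'   (exclusive), in `(0, 1]`. Default 0.5.
#' @param use_median_override Whether the median clause may also trigger the
#'   CEMA label. Default TRUE.
#' @param tie_label Label when neither clause fires. Default "HPMA".
#' @return A list of class `classifier_rule`.
#' @export
classifier_rule <- function(majority_threshold = 0.5,
                            use_median_override = TRUE,
                            tie_label = "HPMA") {
  if (majority_threshold <= 0 || majority_threshold > 1) {
    stop("majority_threshold must be in (0, 1]", call. = FALSE)
  }
  stopifnot(tie_label %in% c("HPMA", "CEMA"))
  structure(list(majority_threshold = majority_threshold,
                 use_median_override = use_median_override,
                 tie_label = tie_label),
            class = "classifier_rule")
}

#' Classify one participant's mercapturic-acid phenotype
#'
#' Applies the day-majority / median-override rule to a participant's daily
#' excretion records. Days with a missing flag or a missing analyte are
#' dropped; fewer than 3 valid days makes the participant unclassifiable
#' (label NA). The call records the evidence used (day counts and medians)
#' and flags participants for whom the two clauses disagree (majority of
#' 3-HPMA days but higher CEMA median), whom the disjunction labels CEMA.
#'
#' @param daily Data frame with columns `hpma_umol` and `cema_umol`
#'   (optionally `missing`) for a single participant.
#' @param rule A [classifier_rule()].
#' @return One-row tibble: `label`, `n_days`, `n_days_cema_gt_hpma`,
#'   `median_cema_umol`, `median_hpma_umol`, `clause_conflict`.
#' @export
classify_participant <- function(daily, rule = classifier_rule()) {
  stopifnot(inherits(rule, "classifier_rule"))
  valid <- is.finite(daily$hpma_umol) & is.finite(daily$cema_umol)
  if ("missing" %in% names(daily)) valid <- valid & !daily$missing
  d <- daily[valid, , drop = FALSE]
  n <- nrow(d)
  if (n < 3) {
    return(tibble::tibble(label = NA_character_, n_days = n,
                          n_days_cema_gt_hpma = NA_integer_,
                          median_cema_umol = NA_real_,
                          median_hpma_umol = NA_real_,
                          clause_conflict = NA))
  }
  n_gt <- sum(d$cema_umol > d$hpma_umol)
  med_c <- stats::median(d$cema_umol)
  med_h <- stats::median(d$hpma_umol)
  majority <- (n_gt / n) > rule$majority_threshold
  override <- rule$use_median_override && (med_c > med_h)
  label <- if (majority || override) "CEMA" else rule$tie_label
  tibble::tibble(label = label, n_days = n, n_days_cema_gt_hpma = n_gt,
                 median_cema_umol = med_c, median_hpma_umol = med_h,
                 clause_conflict = !majority && override)
}

#' Classify every participant in a daily excretion table
#'
#' @param daily Output of [daily_excretion()] (multiple participants).
#' @param rule A [classifier_rule()].
#' @return Tibble with one row per participant (see
#'   [classify_participant()]).
#' @export
classify_cohort <- function(daily, rule = classifier_rule()) {
  require_columns(daily, c("participant", "hpma_umol", "cema_umol"),
                  "daily excretion table")
  daily |>
    dplyr::group_by(.data$participant) |>
    dplyr::group_modify(~ classify_participant(.x, rule)) |>
    dplyr::ungroup()
}

#' Phenotype counts over a cohort
#'
#' @param calls Output of [classify_cohort()]; unclassifiable participants
#'   (label NA) are excluded from the counts.
#' @return Tibble with columns `label` and `n`.
#' @export
cohort_phenotype_counts <- function(calls) {
  classified <- calls |> dplyr::filter(!is.na(.data$label))
  if (nrow(classified) == 0) {
    stop("no classifiable participants", call. = FALSE)
  }
  classified |> dplyr::count(.data$label, name = "n")
}

#' Compare overnight excretion after high- vs low-glycerol dinners
#'
#' Two-sided Mann-Whitney U test per analyte (3-HPMA, CEMA and their sum),
#' with participant-nights as the units of comparison. Nights on excluded
#' days are dropped.
#'
#' @param overnight Output of [overnight_excretion()].
#' @param attribution An [attribution_config()].
#' @param analytes Columns of `overnight` to compare.
#' @return Tibble with one row per analyte: group sizes, group medians,
#'   the U statistic of the high group, and the two-sided p-value.
#' @export
compare_exposure_groups <- function(overnight,
                                    attribution = default_attribution(),
                                    analytes = c("hpma_umol", "cema_umol",
                                                 "sum_umol")) {
  require_columns(overnight, c("study_day", analytes), "overnight table")
  x <- overnight
  if ("missing" %in% names(x)) x <- x[!x$missing, , drop = FALSE]
  x$class <- attribute_exposure(x$study_day, attribution)
  x <- x[x$class %in% c("high", "low"), , drop = FALSE]
  if (sum(x$class == "high") == 0 || sum(x$class == "low") == 0) {
    stop("empty exposure group under attribution config (high days: ",
         paste(attribution$high, collapse = ","), "; low days: ",
         paste(attribution$low, collapse = ","), ")", call. = FALSE)
  }
  dplyr::bind_rows(lapply(analytes, function(a) {
    hi <- x[[a]][x$class == "high"]
    lo <- x[[a]][x$class == "low"]
    wt <- stats::wilcox.test(hi, lo, alternative = "two.sided")
    tibble::tibble(analyte = a, group_a = "high", group_b = "low",
                   n_a = length(hi), n_b = length(lo),
                   median_a = stats::median(hi), median_b = stats::median(lo),
                   u_statistic = unname(wt$statistic), p_value = wt$p.value)
  }))
}

#' Omnibus study-day effect on daily excretion
#'
#' Kruskal-Wallis test across study days, followed by pairwise two-sided
#' Wilcoxon rank-sum tests with Bonferroni correction.
#'
#' @param daily Output of [daily_excretion()].
#' @param value Column to compare across days (default `"sum_umol"`).
#' @return List with `kruskal` (a `htest`), `pairwise` (tibble of
#'   Bonferroni-adjusted pairwise p-values) and `n_groups`.
#' @export
day_effect <- function(daily, value = "sum_umol") {
  require_columns(daily, c("study_day", value), "daily excretion table")
  x <- daily
  if ("missing" %in% names(x)) x <- x[!x$missing, , drop = FALSE]
  sizes <- table(x$study_day)
  if (sum(sizes >= 2) < 2) {
    stop("day_effect() needs at least 2 study days with >= 2 values each",
         call. = FALSE)
  }
  day <- factor(x$study_day)
  kw <- stats::kruskal.test(x[[value]], day)
  pw <- stats::pairwise.wilcox.test(x[[value]], day,
                                    p.adjust.method = "bonferroni",
                                    exact = FALSE)
  pairs <- as.data.frame(as.table(pw$p.value), stringsAsFactors = FALSE)
  names(pairs) <- c("day_a", "day_b", "p_adj")
  pairs <- tibble::as_tibble(pairs[!is.na(pairs$p_adj), ])
  list(kruskal = kw, pairwise = pairs, n_groups = nlevels(day))
}
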