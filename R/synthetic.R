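#' Synthetic cohort configuration
#'
#' Parameters of the seeded synthetic cohort generator. The defaults emulate
#' an 11-day controlled-diet intervention in 20 participants (10 male,
#' 10 female) with four repeating menu schedules, high-glycerol dinners on
#' the days of schedules 3 and 4, a 14:6 split between 3-HPMA and CEMA
#' mercapturic-acid phenotypes, daily biomarker excretion in the
#' 0.11-1.82 umol (CEMA) and 0.20-1.90 umol (3-HPMA) ranges, a pooled
#' median daily CEMA/3-HPMA ratio near 0.73, fecal glycerol between 0.2 and
#' 19.4 umol/g, and nine pdu-positive taxa detected in at least five species
#' per donor.
#'
#' Daily biomarker excretion follows a log-normal model with a
#' participant-level random intercept: participant i's daily 3-HPMA is
#' `hpma_daily_median * exp(b_i + e_id)` with `b_i ~ N(0, sdlog_participant)`
#' and `e_id ~ N(0, sdlog_day)`; daily CEMA is the 3-HPMA amount times a
#' participant ratio centred at `ratio_hpma_pheno` or `ratio_cema_pheno`
#' according to the latent phenotype (SD `sdlog_ratio` on the log scale),
#' with an independent day effect. The overnight portion of a day's
#' excretion (half, by collection duration) is multiplied by
#' `overnight_effect` after high-glycerol dinners. Interval concentrations
#' carry multiplicative measurement noise with coefficient of variation
#' `noise_cv`.
#'
#' @param n_participants Cohort size (first half male, second half female).
#' @param n_days Study days.
#' @param seed Integer seed; the same config and seed reproduce the cohort
#'   exactly.
#' @param n_hpma_phenotype Number of participants assigned the 3-HPMA
#'   phenotype; labels are fixed in this proportion (not sampled) and
#'   shuffled across participant ids.
#' @param schedules List of day sets sharing a menu; must partition
#'   `1..n_days`.
#' @param high_schedules Indices of schedules whose dinners are
#'   high-glycerol.
#' @param attribution [attribution_config()] used by downstream comparisons.
#' @param correction_factor Glycerol-per-fat mass fraction of the synthetic
#'   menu (default 0.1040, the glycerol/triolein molar-mass ratio).
#' @param dinner_low_range,dinner_high_range Dinner glycerol ranges in grams.
#' @param dinner_threshold_g Dinner glycerol at or above which the overnight
#'   uplift applies.
#' @param hpma_daily_median Median daily 3-HPMA excretion in umol.
#' @param sdlog_participant,sdlog_day,sdlog_ratio Log-scale SDs of the
#'   participant intercept, the day effect, and the participant ratio.
#' @param ratio_hpma_pheno,ratio_cema_pheno CEMA/3-HPMA ratio centres of
#'   the two phenotypes.
#' @param overnight_effect Multiplicative uplift of overnight excretion
#'   after high-glycerol dinners (1 = no effect).
#' @param noise_cv Coefficient of variation of interval measurement noise.
#' @param start_date Calendar date of study day 1 (day starts 08:00).
#' @param n_genomes,n_pdu_positive Size of the genome table and number of
#'   pdu-positive taxa in it.
#' @param n_fecal_donors Number of participants donating fecal samples.
#' @param detect_p_core,detect_p_variable Per-donor detection probabilities
#'   of the core (5) and variable (4) pdu-positive taxa.
#' @param fecal_glycerol_range,fecal_glycerol_meanlog,fecal_glycerol_sdlog
#'   Truncated log-normal model of fecal glycerol in umol/g.
#' @param scfa_medians Named vector of median fecal acetate, propionate and
#'   butyrate in umol/g.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 20,
                          n_days = 11,
                          seed = 42,
                          n_hpma_phenotype = 14,
                          schedules = list(c(1, 5, 9), c(2, 6, 10),
                                           c(3, 7, 11), c(4, 8)),
                          high_schedules = c(3, 4),
                          attribution = default_attribution(),
                          correction_factor = 0.1040,
                          dinner_low_range = c(0.44, 1.26),
                          dinner_high_range = c(2.1, 3.4),
                          dinner_threshold_g = 1.5,
                          hpma_daily_median = 0.58,
                          sdlog_participant = 0.05,
                          sdlog_day = 0.30,
                          sdlog_ratio = 0.05,
                          ratio_hpma_pheno = 0.586,
                          ratio_cema_pheno = 1.45,
                          overnight_effect = 1.5,
                          noise_cv = 0.10,
                          start_date = "2021-06-01",
                          n_genomes = 399,
                          n_pdu_positive = 9,
                          n_fecal_donors = 19,
                          detect_p_core = 0.99,
                          detect_p_variable = 0.55,
                          fecal_glycerol_range = c(0.2, 19.4),
                          fecal_glycerol_meanlog = log(1.5),
                          fecal_glycerol_sdlog = 1.0,
                          scfa_medians = c(acetate = 55, propionate = 6.9,
                                           butyrate = 14.7)) {
  days <- sort(unlist(schedules))
  if (!setequal(days, seq_len(n_days)) || anyDuplicated(days)) {
    stop("menu schedules must partition days 1..", n_days, call. = FALSE)
  }
  stopifnot(n_hpma_phenotype >= 0, n_hpma_phenotype <= n_participants,
            dinner_low_range[1] < dinner_low_range[2],
            dinner_high_range[1] < dinner_high_range[2],
            dinner_low_range[2] <= dinner_high_range[1],
            overnight_effect > 0, noise_cv >= 0,
            n_pdu_positive <= n_genomes)
  cfg <- as.list(environment())
  structure(cfg, class = "cohort_config")
}

participant_ids <- function(config) {
  sprintf("P%02d", seq_len(config$n_participants))
}

participant_groups <- function(config) {
  n <- config$n_participants
  rep(c("male", "female"), c(ceiling(n / 2), floor(n / 2)))
}

# lognormal multiplier with unit mean and given cv
cv_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  exp(stats::rnorm(n, -s2 / 2, sqrt(s2)))
}

#' Generate the standardized menu
#'
#' Builds an 11-day, four-slot menu per participant group following the
#' repeating schedule structure: days sharing a schedule receive identical
#' meals. Dinners of the high schedules fall in `dinner_high_range`, the
#' rest in `dinner_low_range`; on low-dinner days lunch carries 49-55% of
#' the day's glycerol. Item fat is derived from the slot glycerol target
#' through the menu correction factor.
#'
#' @param config A [cohort_config()].
#' @return Tibble with columns `group`, `study_day`, `slot`, `item`,
#'   `fat_g`, `correction_factor`.
#' @export
generate_menu <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  foods <- list(
    breakfast = c("yogurt with fruit", "muesli with nuts", "whole milk"),
    lunch = c("boiled beef", "potatoes with butter", "cream sauce"),
    dinner = c("pasta with cheese", "vegetables in oil", "boiled chicken"),
    snack = c("fruit curd", "biscuit"))
  withr::with_seed(config$seed + 101L, {
    rows <- list()
    for (group in c("male", "female")) {
      scale <- if (group == "male") 1 else 0.92
      for (s in seq_along(config$schedules)) {
        is_high <- s %in% config$high_schedules
        # male dinners sit in the upper part of the configured range,
        # female in the lower, mirroring the ~300 kcal menu difference
        sub_range <- function(rng) {
          if (group == "male") rng[1] + c(0.4, 1) * diff(rng)
          else rng[1] + c(0, 0.6) * diff(rng)
        }
        if (is_high) {
          rng <- sub_range(config$dinner_high_range)
          dinner <- stats::runif(1, rng[1], rng[2])
          lunch <- stats::runif(1, 1.4, 1.9) * scale
          breakfast <- stats::runif(1, 0.5, 0.8) * scale
          snack <- stats::runif(1, 0.3, 0.5) * scale
        } else {
          rng <- sub_range(config$dinner_low_range)
          dinner <- stats::runif(1, rng[1], rng[2])
          total <- stats::runif(1, 4.2, 5.0) * scale
          lunch <- stats::runif(1, 0.49, 0.55) * total
          rest <- max(total - lunch - dinner, 0.5)
          breakfast <- 0.62 * rest
          snack <- 0.38 * rest
        }
        slot_g <- c(breakfast = breakfast, lunch = lunch, dinner = dinner,
                    snack = snack)
        for (slot_name in names(slot_g)) {
          items <- foods[[slot_name]]
          w <- stats::runif(length(items), 0.5, 1.5)
          w <- w / sum(w)
          rows[[length(rows) + 1]] <- tibble::tibble(
            group = group,
            schedule = s,
            slot = slot_name,
            item = items,
            glycerol_g = slot_g[[slot_name]] * w)
        }
      }
    }
    menu <- dplyr::bind_rows(rows)
  })
  schedule_days <- tibble::tibble(
    schedule = rep(seq_along(config$schedules),
                   lengths(config$schedules)),
    study_day = unlist(config$schedules))
  menu |>
    dplyr::inner_join(schedule_days, by = "schedule",
                      relationship = "many-to-many") |>
    dplyr::mutate(fat_g = .data$glycerol_g / config$correction_factor,
                  correction_factor = config$correction_factor) |>
    dplyr::select("group", "study_day", "slot", "item", "fat_g",
                  "correction_factor") |>
    dplyr::arrange(.data$group, .data$study_day,
                   match(.data$slot, MEAL_SLOTS), .data$item)
}

#' Generate urine collection intervals with latent truth
#'
#' Simulates per-participant-day biomarker excretion under the log-normal
#' model of [cohort_config()], distributes it over the collection scheme
#' (08:00-14:00, 14:00-20:00 and an overnight 20:00-08:00 interval on most
#' days; a single 24-h collection on the last two days), applies the
#' overnight uplift after high-glycerol dinners, and converts amounts to
#' concentrations through simulated urine weights at 1 kg/L. Interval
#' concentrations carry multiplicative measurement noise.
#'
#' @param config A [cohort_config()].
#' @param menu Output of [generate_menu()]; used to find each group's
#'   high-glycerol dinner days via `dinner_threshold_g`. When NULL the
#'   high days are taken from the high schedules.
#' @return List with `intervals` (urine interval table) and `truth`
#'   (latent per participant-day phenotype, true daily and overnight
#'   amounts before measurement noise).
#' @export
generate_urine <- function(config = cohort_config(), menu = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  ids <- participant_ids(config)
  groups <- participant_groups(config)
  n <- config$n_participants
  nd <- config$n_days
  high_days_of <- function(group) {
    if (is.null(menu)) {
      sort(unlist(config$schedules[config$high_schedules]))
    } else {
      dg <- diet_glycerol(menu[menu$group == group, ])
      dd <- dg[dg$slot == "dinner", ]
      agg <- tapply(dd$glycerol_g, dd$study_day, sum)
      as.integer(names(agg)[agg >= config$dinner_threshold_g])
    }
  }
  high_by_group <- lapply(stats::setNames(nm = unique(groups)), high_days_of)

  withr::with_seed(config$seed + 202L, {
    pheno <- rep(c("HPMA", "CEMA"),
                 c(config$n_hpma_phenotype, n - config$n_hpma_phenotype))
    pheno <- pheno[sample.int(n)]
    b <- stats::rnorm(n, 0, config$sdlog_participant)
    rho_centre <- ifelse(pheno == "HPMA", config$ratio_hpma_pheno,
                         config$ratio_cema_pheno)
    rho <- rho_centre * exp(stats::rnorm(n, 0, config$sdlog_ratio))

    grid <- tidyr::expand_grid(p = seq_len(n), study_day = seq_len(nd))
    m <- nrow(grid)
    e_h <- exp(stats::rnorm(m, 0, config$sdlog_day))
    e_c <- exp(stats::rnorm(m, 0, config$sdlog_day))
    base_h <- config$hpma_daily_median * exp(b[grid$p]) * e_h
    base_c <- base_h / e_h * rho[grid$p] * e_c
    is_high <- mapply(function(p, d) d %in% high_by_group[[groups[p]]],
                      grid$p, grid$study_day)
    uplift <- ifelse(is_high, config$overnight_effect, 1)

    truth <- tibble::tibble(
      participant = ids[grid$p],
      group = groups[grid$p],
      study_day = grid$study_day,
      phenotype = pheno[grid$p],
      dinner_class = ifelse(is_high, "high", "low"),
      overnight_hpma_umol = base_h * 0.5 * uplift,
      overnight_cema_umol = base_c * 0.5 * uplift,
      hpma_umol = base_h * 0.5 + overnight_hpma_umol,
      cema_umol = base_c * 0.5 + overnight_cema_umol)

    # portion-level amounts: morning / afternoon / overnight
    portions <- tidyr::expand_grid(row = seq_len(m),
                                   portion = c("morning", "afternoon",
                                               "night"))
    w <- ifelse(portions$portion == "night", 0.5 * uplift[portions$row],
                0.25)
    portions$hpma <- base_h[portions$row] * w
    portions$cema <- base_c[portions$row] * w
    portions$participant <- ids[grid$p[portions$row]]
    portions$study_day <- grid$study_day[portions$row]

    day0 <- as.POSIXct(paste(config$start_date, "08:00:00"), tz = "UTC")
    pooled <- portions$study_day >= nd - 1 # 24-h collections, last two days
    start_h <- c(morning = 0, afternoon = 6, night = 12, day = 0)
    intervals <- portions |>
      dplyr::mutate(portion = ifelse(pooled, "day", .data$portion)) |>
      dplyr::group_by(.data$participant, .data$study_day, .data$portion) |>
      dplyr::summarise(hpma = sum(.data$hpma), cema = sum(.data$cema),
                       .groups = "drop") |>
      dplyr::mutate(
        offset_h = ifelse(.data$portion == "day", 0,
                          start_h[.data$portion]),
        dur_h = dplyr::case_when(.data$portion == "day" ~ 24,
                                 .data$portion == "night" ~ 12,
                                 TRUE ~ 6),
        start = day0 + ((.data$study_day - 1) * 24 + .data$offset_h) * 3600,
        end = .data$start + .data$dur_h * 3600)
    k <- nrow(intervals)
    weight_mean <- c(`6` = 450, `12` = 800, `24` = 1600)
    intervals$urine_weight_g <-
      weight_mean[as.character(intervals$dur_h)] * cv_noise(k, 0.20)
    vol_ml <- intervals$urine_weight_g # 1 kg/L
    const <- analyte_constants()
    intervals$conc_hpma_ng_ml <- intervals$hpma * const$mw_hpma * 1000 /
      vol_ml * cv_noise(k, config$noise_cv)
    intervals$conc_cema_ng_ml <- intervals$cema * const$mw_cema * 1000 /
      vol_ml * cv_noise(k, config$noise_cv)
  })
  list(
    intervals = intervals |>
      dplyr::select("participant", "start", "end", "urine_weight_g",
                    "conc_hpma_ng_ml", "conc_cema_ng_ml") |>
      dplyr::arrange(.data$participant, .data$start),
    truth = truth |> dplyr::arrange(.data$participant, .data$study_day))
}

#' Generate synthetic community tables
#'
#' Produces a pdu gene presence/absence matrix with `n_pdu_positive`
#' positive taxa in a background of negatives, a per-sample qPCR-style
#' absolute abundance table in which one taxon dominates the pduC signal,
#' fecal SCFA profiles with acetate-dominant composition, and fecal
#' glycerol drawn from a truncated log-normal inside the configured range.
#' Taxon names are synthetic labels modelled on known intestinal glycerol
#' transformers.
#'
#' @param config A [cohort_config()].
#' @return List with `pdu_genes`, `qpcr`, `scfa`, `fecal_glycerol` tibbles.
#' @export
generate_microbiome <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  positive_taxa <- c(
    "Anaerobutyricum_hallii", "Anaerobutyricum_soehngenii",
    "Blautia_obeum", "Blautia_sp900066335", "Blautia_ammoniilytica",
    "Mediterraneibacter_gnavus", "Mediterraneibacter_glycyrrhizinilytica",
    "Flavonifractor_plautii", "Propionibacterium_freudenreichii")
  stopifnot(config$n_pdu_positive <= length(positive_taxa))
  positive_taxa <- positive_taxa[seq_len(config$n_pdu_positive)]
  n_core <- min(5L, length(positive_taxa))
  core <- positive_taxa[seq_len(n_core)]
  dominant <- positive_taxa[1]
  background <- sprintf("rMAG_%03d", seq_len(config$n_genomes -
                                               config$n_pdu_positive))
  withr::with_seed(config$seed + 303L, {
    # presence/absence: most positives carry all three subunit genes
    np <- length(positive_taxa)
    pduC <- rep(TRUE, np)
    pduD <- c(rep(TRUE, max(np - 2, 0)), rep(FALSE, min(2, np)))
    pduE <- c(rep(TRUE, max(np - 3, 0)), rep(FALSE, min(3, np)))
    pdu_genes <- tibble::tibble(
      genome_id = c(positive_taxa, background),
      pduC = c(pduC, rep(FALSE, length(background))),
      pduD = c(pduD, rep(FALSE, length(background))),
      pduE = c(pduE, rep(FALSE, length(background))))

    donors <- sprintf("D%02d", seq_len(config$n_fecal_donors))
    n_samples <- pmax(3L, pmin(config$n_days,
                               stats::rbinom(length(donors), config$n_days,
                                             0.8)))
    samples <- dplyr::bind_rows(lapply(seq_along(donors), function(i) {
      tibble::tibble(donor = donors[i],
                     study_day = sort(sample.int(config$n_days,
                                                 n_samples[i])))
    }))
    samples$sample <- paste(samples$donor, sprintf("d%02d",
                                                   samples$study_day),
                            sep = "_")

    detect_p <- ifelse(positive_taxa %in% core, config$detect_p_core,
                       config$detect_p_variable)
    donor_taxon <- tidyr::expand_grid(donor = donors, taxon = positive_taxa)
    donor_taxon$present <- stats::rbinom(nrow(donor_taxon), 1,
                                         detect_p[match(donor_taxon$taxon,
                                                        positive_taxa)]) == 1

    qpcr <- samples |>
      dplyr::select("sample", "donor") |>
      tidyr::expand_grid(taxon = positive_taxa) |>
      dplyr::left_join(donor_taxon, by = c("donor", "taxon"))
    lod <- 1e5
    mu <- ifelse(qpcr$taxon == dominant, log(2e9), log(3e6))
    sdl <- ifelse(qpcr$taxon == dominant, 0.4, 0.7)
    qpcr$copies_per_g <- ifelse(
      qpcr$present, exp(stats::rnorm(nrow(qpcr), mu, sdl)), 0)
    qpcr$lod <- lod
    qpcr <- qpcr |> dplyr::select("sample", "donor", "taxon",
                                  "copies_per_g", "lod")

    meds <- config$scfa_medians
    ns <- nrow(samples)
    scfa <- tibble::tibble(
      sample = samples$sample,
      donor = samples$donor,
      study_day = samples$study_day,
      acetate = meds[["acetate"]] * exp(stats::rnorm(ns, 0, 0.30)),
      propionate = meds[["propionate"]] * exp(stats::rnorm(ns, 0, 0.45)),
      butyrate = meds[["butyrate"]] * exp(stats::rnorm(ns, 0, 0.35)))

    rng <- config$fecal_glycerol_range
    p_lo <- stats::plnorm(rng[1], config$fecal_glycerol_meanlog,
                          config$fecal_glycerol_sdlog)
    p_hi <- stats::plnorm(rng[2], config$fecal_glycerol_meanlog,
                          config$fecal_glycerol_sdlog)
    fecal_glycerol <- tibble::tibble(
      sample = samples$sample,
      donor = samples$donor,
      study_day = samples$study_day,
      glycerol_umol_g = stats::qlnorm(
        stats::runif(ns, p_lo, p_hi),
        config$fecal_glycerol_meanlog, config$fecal_glycerol_sdlog))
  })
  list(pdu_genes = pdu_genes, qpcr = qpcr, scfa = scfa,
       fecal_glycerol = fecal_glycerol)
}

#' Simulate a full synthetic cohort
#'
#' Runs [generate_menu()], [generate_urine()] and [generate_microbiome()]
#' under one configuration and optionally writes the tables as CSV files
#' (`diet.csv`, `urine.csv`, `urine_truth.csv`, `pdu_genes.csv`,
#' `qpcr.csv`, `scfa.csv`, `fecal_glycerol.csv`).
#'
#' @param config A [cohort_config()].
#' @param outdir Optional directory for the CSV files (created if needed).
#' @return (Invisibly) a list with `menu`, `urine` (intervals + truth) and
#'   `microbiome`.
#' @export
simulate_cohort <- function(config = cohort_config(), outdir = NULL) {
  menu <- generate_menu(config)
  urine <- generate_urine(config, menu)
  micro <- generate_microbiome(config)
  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    readr::write_csv(menu, file.path(outdir, "diet.csv"))
    readr::write_csv(urine$intervals, file.path(outdir, "urine.csv"))
    readr::write_csv(urine$truth, file.path(outdir, "urine_truth.csv"))
    readr::write_csv(micro$pdu_genes, file.path(outdir, "pdu_genes.csv"))
    readr::write_csv(micro$qpcr, file.path(outdir, "qpcr.csv"))
    readr::write_csv(micro$scfa, file.path(outdir, "scfa.csv"))
    readr::write_csv(micro$fecal_glycerol,
                     file.path(outdir, "fecal_glycerol.csv"))
  }
  invisible(list(menu = menu, urine = urine, microbiome = micro))
}
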