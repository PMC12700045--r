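test_that("urine volume and interval amounts convert units correctly", {
  expect_equal(interval_volume(500), 0.5)
  expect_equal(interval_volume(0), 0)
  expect_equal(interval_volume(1234), 1.234)
  expect_error(interval_volume(-1), "non-negative")

  expect_equal(interval_amount(0, 1, 200), 0)
  # arithmetic oracle: ng total / 1000 / mw
  expect_equal(interval_amount(100, 0.5, 221.271),
               100 * 500 / 221.271 / 1000, tolerance = 1e-12)
  expect_equal(round(interval_amount(100, 0.5, 221.27), 4), 0.2260)
  expect_equal(interval_amount(50, 1.0, 200), 0.25)
  expect_error(interval_amount(10, 1, 0), "positive")
})

test_that("biomarker molar masses match their molecular formulas", {
  # 3-HPMA C8H15NO4S, CEMA C8H13NO5S
  w <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, S = 32.06)
  hpma <- 8 * w["C"] + 15 * w["H"] + w["N"] + 4 * w["O"] + w["S"]
  cema <- 8 * w["C"] + 13 * w["H"] + w["N"] + 5 * w["O"] + w["S"]
  const <- analyte_constants()
  expect_equal(const$mw_hpma, unname(hpma), tolerance = 1e-9)
  expect_equal(const$mw_cema, unname(cema), tolerance = 1e-9)
})

test_that("daily excretion sums, splits at day boundaries, flags gaps", {
  iv <- dplyr::bind_rows(
    interval_row("P1", "2021-06-01 09:00:00", "2021-06-01 12:00:00",
                 hpma_umol = 0.1),
    interval_row("P1", "2021-06-01 13:00:00", "2021-06-01 18:00:00",
                 hpma_umol = 0.2))
  d <- daily_excretion(iv, constants = toy_constants())
  expect_equal(d$hpma_umol, 0.3, tolerance = 1e-12)

  # interval straddling the 08:00 day boundary: 6 of 12 h on each side
  straddle <- interval_row("P1", "2021-06-02 02:00:00",
                           "2021-06-02 14:00:00", hpma_umol = 0.3)
  iv2 <- dplyr::bind_rows(
    interval_row("P1", "2021-06-01 08:00:00", "2021-06-01 10:00:00",
                 hpma_umol = 0.05),
    straddle)
  d2 <- daily_excretion(iv2, constants = toy_constants())
  expect_equal(d2$hpma_umol[d2$study_day == 1], 0.05 + 0.15,
               tolerance = 1e-9)
  expect_equal(d2$hpma_umol[d2$study_day == 2], 0.15, tolerance = 1e-9)

  # days without any interval are flagged missing when the grid is completed
  d3 <- daily_excretion(iv, constants = toy_constants(), n_days = 3)
  expect_true(all(d3$missing[d3$study_day %in% 2:3]))
  expect_equal(d3$hpma_umol[d3$study_day == 2], 0)

  # whole-interval assignment puts the straddling interval on one day
  d4 <- daily_excretion(iv2, constants = toy_constants(), method = "whole")
  expect_equal(d4$hpma_umol[d4$study_day == 1], 0.05, tolerance = 1e-9)
  expect_equal(d4$hpma_umol[d4$study_day == 2], 0.3, tolerance = 1e-9)

  overlapping <- dplyr::bind_rows(
    interval_row("P7", "2021-06-01 09:00:00", "2021-06-01 12:00:00"),
    interval_row("P7", "2021-06-01 11:00:00", "2021-06-01 13:00:00"))
  expect_error(daily_excretion(overlapping), "P7")
})

test_that("overnight window credits overlap fractions keyed to the evening", {
  full <- interval_row("P1", "2021-06-01 20:00:00", "2021-06-02 08:00:00",
                       cema_umol = 0.4)
  o <- overnight_excretion(full, constants = toy_constants())
  expect_equal(o$cema_umol, 0.4, tolerance = 1e-12)
  expect_equal(o$study_day, 1) # the night after day 1's dinner

  partial <- interval_row("P1", "2021-06-01 18:00:00",
                          "2021-06-01 22:00:00", cema_umol = 0.4)
  o2 <- overnight_excretion(partial, constants = toy_constants())
  expect_equal(o2$cema_umol, 0.2, tolerance = 1e-9) # 2 of 4 h inside

  day_only <- interval_row("P1", "2021-06-01 09:00:00",
                           "2021-06-01 12:00:00", cema_umol = 0.4)
  o3 <- overnight_excretion(day_only, constants = toy_constants(),
                            n_days = 1)
  expect_true(all(o3$missing))
  expect_equal(o3$cema_umol, 0)
})

test_that("pro-rating conserves amounts over the daily partition", {
  withr::with_seed(11, {
    for (rep in 1:10) {
      rows <- list()
      for (p in c("A", "B")) {
        t <- as.POSIXct("2021-06-01 08:00:00", tz = "UTC")
        while (t < as.POSIXct("2021-06-05 08:00:00", tz = "UTC")) {
          dur <- sample(1:24, 1) * 3600
          rows[[length(rows) + 1]] <- interval_row(
            p, t, t + dur, hpma_umol = runif(1, 0, 1),
            cema_umol = runif(1, 0, 1))
          t <- t + dur + sample(0:3, 1) * 3600 # gaps allowed
        }
      }
      iv <- dplyr::bind_rows(rows)
      amt <- interval_amount(iv$conc_hpma_ng_ml,
                             interval_volume(iv$urine_weight_g), 200) +
        interval_amount(iv$conc_cema_ng_ml,
                        interval_volume(iv$urine_weight_g), 200)
      d <- daily_excretion(iv, constants = toy_constants())
      expect_equal(sum(d$sum_umol), sum(amt), tolerance = 1e-9)
    }
  })
})

test_that("pro-rating is invariant to splitting intervals", {
  one <- interval_row("P1", "2021-06-01 22:00:00", "2021-06-02 10:00:00",
                      hpma_umol = 0.6, cema_umol = 0.3)
  # same excretion split into three abutting sub-intervals with amounts
  # proportional to duration (identical concentrations)
  split <- dplyr::bind_rows(
    interval_row("P1", "2021-06-01 22:00:00", "2021-06-02 02:00:00",
                 hpma_umol = 0.2, cema_umol = 0.1),
    interval_row("P1", "2021-06-02 02:00:00", "2021-06-02 06:00:00",
                 hpma_umol = 0.2, cema_umol = 0.1),
    interval_row("P1", "2021-06-02 06:00:00", "2021-06-02 10:00:00",
                 hpma_umol = 0.2, cema_umol = 0.1))
  for (f in list(daily_excretion, overnight_excretion)) {
    a <- f(split, constants = toy_constants())
    b <- f(one, constants = toy_constants())
    merged <- dplyr::full_join(a, b, by = c("participant", "study_day"))
    expect_equal(merged$hpma_umol.x, merged$hpma_umol.y, tolerance = 1e-9)
    expect_equal(merged$cema_umol.x, merged$cema_umol.y, tolerance = 1e-9)
  }
})

test_that("daily ratio excludes non-positive 3-HPMA with a note", {
  expect_equal(daily_ratio(0.5, 1.0), 0.5)
  expect_equal(daily_ratio(1.0, 1.0), 1.0)
  expect_equal(daily_ratio(0.73, 1.0), 0.73)
  expect_message(r <- daily_ratio(c(0.5, 0.2), c(1.0, 0)), "excluded")
  expect_true(is.na(r[2]))
  expect_equal(r[1], 0.5)
})
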