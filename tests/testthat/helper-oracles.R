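# Independent oracles used across the suite.

# Exact two-sided Mann-Whitney p-value by enumeration of all group
# assignments of the pooled observed values (no ties assumed).
exact_mwu_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  m <- length(y)
  r <- rank(pooled)
  combos <- utils::combn(n + m, n)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  if (u_obs > n * m / 2) {
    p <- 2 * mean(u_all >= u_obs)
  } else {
    p <- 2 * mean(u_all <= u_obs)
  }
  min(p, 1)
}

# Literal evaluation of the phenotype rule's two clauses.
brute_classify <- function(cema, hpma, majority_threshold = 0.5,
                           use_median_override = TRUE, tie_label = "HPMA") {
  n_gt <- 0L
  for (i in seq_along(cema)) if (cema[i] > hpma[i]) n_gt <- n_gt + 1L
  clause_majority <- (n_gt / length(cema)) > majority_threshold
  med <- function(v) {
    v <- sort(v)
    k <- length(v)
    if (k %% 2 == 1) v[(k + 1) / 2] else (v[k / 2] + v[k / 2 + 1]) / 2
  }
  clause_median <- use_median_override && (med(cema) > med(hpma))
  if (clause_majority || clause_median) "CEMA" else tie_label
}

# Build a urine interval row with a prescribed analyte amount (in umol)
# using mw 200 g/mol and 1 L of urine, so conc ng/mL = amount * 200.
interval_row <- function(participant, start, end, hpma_umol = 0,
                         cema_umol = 0, weight_g = 1000) {
  tibble::tibble(
    participant = participant,
    start = as.POSIXct(start, tz = "UTC"),
    end = as.POSIXct(end, tz = "UTC"),
    urine_weight_g = weight_g,
    conc_hpma_ng_ml = hpma_umol * 200 * 1000 / weight_g,
    conc_cema_ng_ml = cema_umol * 200 * 1000 / weight_g)
}

# Constants making interval_row amounts exact: both molar masses 200.
toy_constants <- function() analyte_constants(mw_hpma = 200, mw_cema = 200)
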