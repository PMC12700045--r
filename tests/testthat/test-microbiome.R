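toy_matrix <- function() {
  tibble::tibble(
    genome_id = paste0("g", 1:10),
    pduC = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
             FALSE),
    pduD = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
             FALSE),
    pduE = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
             FALSE))
}

test_that("pdu positivity counts genomes with required subunit genes", {
  res <- pdu_positive(toy_matrix())
  expect_equal(res$n_positive, 2)
  expect_equal(res$percent_positive, 20.0)
  expect_setequal(res$positive_ids, c("g1", "g2"))

  # mode all: a genome with pduC only is not positive
  res_all <- pdu_positive(toy_matrix(), mode = "all")
  expect_identical(res_all$positive_ids, "g1")

  # full-precision percentage at the study scale
  big <- tibble::tibble(genome_id = paste0("g", 1:399),
                        pduC = c(rep(TRUE, 9), rep(FALSE, 390)),
                        pduD = FALSE, pduE = FALSE)
  expect_equal(pdu_positive(big)$percent_positive, 100 * 9 / 399,
               tolerance = 1e-12)
  expect_equal(round(pdu_positive(big)$percent_positive, 2), 2.26)

  expect_error(pdu_positive(toy_matrix(), required_genes = c("pduC", "pduX")),
               "pduX")
  dup <- toy_matrix()
  dup$genome_id[2] <- "g1"
  expect_error(pdu_positive(dup), "duplicate")
})

test_that("mode-all positives are a subset of mode-any positives", {
  withr::with_seed(31, {
    for (i in 1:20) {
      m <- tibble::tibble(genome_id = paste0("g", 1:15),
                          pduC = runif(15) < 0.4,
                          pduD = runif(15) < 0.4,
                          pduE = runif(15) < 0.4)
      any_ids <- pdu_positive(m, mode = "any")$positive_ids
      all_ids <- pdu_positive(m, mode = "all")$positive_ids
      expect_true(all(all_ids %in% any_ids))
    }
  })
})

test_that("per-donor species counts summarise detection above LOD", {
  det <- tibble::tibble(
    donor = c(rep("d1", 9), rep("d2", 2)),
    taxon = c(paste0("t", 1:9), "t1", "t2"),
    copies_per_g = c(rep(1e6, 3), rep(0, 6), 1e6, 1e6),
    lod = 1e5)
  res <- per_donor_pdu_species(paste0("t", 1:9), det)
  expect_equal(res$per_donor$n_species[res$per_donor$donor == "d1"], 3)
  expect_equal(res$per_donor$n_species[res$per_donor$donor == "d2"], 2)

  counts <- tibble::tibble(
    donor = rep(c("a", "b", "c", "d"), times = c(5, 7, 7, 9)),
    taxon = c(paste0("t", 1:5), paste0("t", 1:7), paste0("t", 1:7),
              paste0("t", 1:9)),
    detected = TRUE)
  res2 <- per_donor_pdu_species(paste0("t", 1:9), counts)
  expect_equal(res2$cohort_median, 7)
  expect_equal(res2$cohort_min, 5)

  expect_error(per_donor_pdu_species("t1", counts[0, ]), "empty")
})

test_that("taxon shares normalise per sample with LOD/2 substitution", {
  ab <- tibble::tibble(sample = "s1", taxon = c("A", "B", "C"),
                       copies_per_g = c(930, 50, 20), lod = 1)
  sh <- taxon_share(ab)
  expect_equal(sh$share[sh$taxon == "A"], 0.93, tolerance = 1e-12)
  expect_equal(sum(sh$share), 1, tolerance = 1e-9)

  single <- tibble::tibble(sample = "s1", taxon = "A",
                           copies_per_g = 5, lod = 1)
  expect_equal(taxon_share(single)$share, 1)

  cens <- tibble::tibble(sample = "s1", taxon = c("A", "B"),
                         copies_per_g = c(2, 100), lod = 10)
  sh2 <- taxon_share(cens, lod_substitute = "half")
  expect_equal(sh2$share[sh2$taxon == "B"], 100 / 105, tolerance = 1e-9)
  expect_true(sh2$below_lod[sh2$taxon == "A"])

  all_cens <- tibble::tibble(sample = "s1", taxon = c("A", "B"),
                             copies_per_g = c(1, 2), lod = 10)
  expect_message(sh3 <- taxon_share(all_cens), "below LOD")
  expect_true(all(is.na(sh3$share)))
})

test_that("prevalence reports occurrence above threshold and medians", {
  ab <- tibble::tibble(sample = paste0("s", 1:20), taxon = "A",
                       value = c(rep(0.01, 19), 0))
  res <- prevalence(ab)
  expect_equal(res$occurrence_pct, 95.0)

  zero <- tibble::tibble(sample = paste0("s", 1:4), taxon = "A", value = 0)
  res0 <- prevalence(zero)
  expect_equal(res0$occurrence_pct, 0)
  expect_equal(res0$median_value, 0)

  four <- tibble::tibble(sample = paste0("s", 1:4), taxon = "A",
                         value = c(0, 0, 1, 3))
  res4 <- prevalence(four, threshold = 0)
  expect_equal(res4$occurrence_pct, 50)
  expect_equal(res4$median_value, 0.5)

  # monotone nonincreasing in the threshold
  withr::with_seed(32, {
    ab2 <- tibble::tibble(sample = paste0("s", 1:30), taxon = "A",
                          value = rexp(30))
    occ <- sapply(c(0, 0.2, 0.5, 1, 2),
                  function(th) prevalence(ab2, th)$occurrence_pct)
    expect_true(all(diff(occ) <= 0))
  })
  expect_error(prevalence(four[0, ]), "empty")
})

test_that("SCFA proportions normalise to 100% with ratio handling", {
  # normalising the study's printed medians (medians of ratios need not
  # equal ratios of medians, so this is arithmetic, not a cohort claim)
  x <- tibble::tibble(sample = "s1", acetate = 68.6, propionate = 8.6,
                      butyrate = 18.4)
  pr <- scfa_proportions(x)
  expect_equal(pr$acetate_pct, 100 * 68.6 / 95.6, tolerance = 1e-9)
  expect_equal(round(pr$acetate_pct, 2), 71.76)
  expect_equal(round(pr$but_prop_ratio, 2), 2.14)

  sym <- tibble::tibble(sample = "s", acetate = 1, propionate = 1,
                        butyrate = 1)
  prs <- scfa_proportions(sym)
  expect_equal(prs$acetate_pct, 100 / 3, tolerance = 1e-9)
  expect_equal(prs$but_prop_ratio, 1)

  deg <- tibble::tibble(sample = "s", acetate = 10, propionate = 0,
                        butyrate = 0)
  prd <- scfa_proportions(deg)
  expect_equal(prd$acetate_pct, 100)
  expect_true(is.na(prd$but_prop_ratio))

  zero <- tibble::tibble(sample = "s0", acetate = 0, propionate = 0,
                         butyrate = 0)
  expect_message(prz <- scfa_proportions(zero), "flagged")
  expect_true(prz$undefined)
  expect_true(is.na(prz$acetate_pct))
})

test_that("share and proportion outputs normalise within 1e-6", {
  withr::with_seed(33, {
    for (i in 1:10) {
      ns <- 5
      ab <- tidyr::expand_grid(sample = paste0("s", 1:ns),
                               taxon = paste0("t", 1:8))
      ab$copies_per_g <- rlnorm(nrow(ab), log(1e6), 2)
      ab$lod <- 1e3
      sh <- taxon_share(ab)
      sums <- tapply(sh$share, sh$sample, sum)
      expect_true(all(abs(sums - 1) < 1e-6))

      sc <- tibble::tibble(sample = paste0("s", 1:ns),
                           acetate = rlnorm(ns, log(50), 0.4),
                           propionate = rlnorm(ns, log(7), 0.4),
                           butyrate = rlnorm(ns, log(15), 0.4))
      pr <- scfa_proportions(sc)
      tot <- pr$acetate_pct + pr$propionate_pct + pr$butyrate_pct
      expect_true(all(abs(tot - 100) < 1e-6))
    }
  })
})

test_that("log10 reporting censors below-LOD values", {
  res <- log10_abundance(c(1e8, 0, 1e10), lod = 1e5)
  expect_equal(res$log10_copies, c(8, NA, 10))
  expect_identical(res$below_lod, c(FALSE, TRUE, FALSE))
})
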