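# glycacro

Dietary glycerol and urinary acrolein biomarker analysis for
controlled-diet intervention studies.

## What this package is for

Gut bacteria carrying the glycerol/diol dehydratase (*pdu*) operon can
transform colonic glycerol into acrolein, a highly reactive aldehyde that
the body conjugates with glutathione and excretes in urine as two
mercapturic acids: **3-HPMA** (N-acetyl-S-(3-hydroxypropyl)-L-cysteine)
and **CEMA** (N-acetyl-S-(carboxyethyl)-L-cysteine). `glycacro` is for
researchers running (or re-analysing) diet interventions who need to
connect what participants ate to what they excreted:

* per-item / per-meal / per-day **dietary glycerol** from food fat
  content (`item_glycerol()`, `diet_glycerol()`), with high/low
  dinner-exposure attribution;
* **timed urine collections** converted to excreted amounts and
  aggregated into study days and overnight (20:00–08:00) windows with a
  conservation-preserving pro-rating rule (`daily_excretion()`,
  `overnight_excretion()`);
* a **mass-balance model** back-calculating intestinal acrolein
  (`colonic_glycerol()`, `acrolein_from_hpma()`, `molpct_converted()`);
* rule-based **mercapturic-acid phenotyping** and nonparametric
  exposure-group comparisons (`classify_cohort()`,
  `compare_exposure_groups()`);
* summaries of ***pdu* functional potential** and fecal SCFA profiles
  from community tables (`pdu_positive()`, `scfa_proportions()`);
* a seeded **synthetic cohort generator** (`simulate_cohort()`) so the
  whole pipeline is testable end to end without any study data.

## The model in brief

For a meal with fat mass $F$ (g) and glycerol correction factor $c$
(default 0.1040, the glycerol/triolein molar-mass ratio), dietary
glycerol is $G = cF$. With small-intestinal hydrolysis efficiency
$h = 0.95$, the glycerol reaching the colon is

$$G_{colon} = (1-h)\,\frac{G}{92.09}\times 1000 \quad \text{[mmol]}.$$

With an acrolein-to-3-HPMA urinary excretion fraction $f = 0.20$,
intestinal acrolein is back-calculated from overnight urinary 3-HPMA as
$A = \mathrm{HPMA}/f$ (µmol), and the fraction of the colonic pool
converted is $100\,A/(1000\,G_{colon})$ mol%.

Participants are phenotyped **CEMA** when CEMA exceeds 3-HPMA on more
than half their study days *or* their median daily CEMA exceeds their
median daily 3-HPMA (strict inequalities; ties fall to **HPMA**).

## Worked example

```r
library(glycacro)

cohort <- simulate_cohort(cohort_config(seed = 42))
daily  <- daily_excretion(cohort$urine$intervals, n_days = 11)

cohort_phenotype_counts(classify_cohort(daily))
#> # A tibble: 2 × 2
#>   label     n
#>   <chr> <int>
#> 1 CEMA      6
#> 2 HPMA     14

ratios <- daily_ratio(daily$cema_umol, daily$hpma_umol)
median(ratios, na.rm = TRUE)
#> [1] 0.695

on <- overnight_excretion(cohort$urine$intervals, n_days = 11)
compare_exposure_groups(on)
#> # A tibble: 3 × 9
#>   analyte   group_a group_b   n_a   n_b median_a median_b u_statistic  p_value
#> 1 hpma_umol high    low        80   100    0.475    0.292        6307 3.14e-11
#> 2 cema_umol high    low        80   100    0.290    0.211        5720 7.42e- 7
#> 3 sum_umol  high    low        80   100    0.786    0.544        6602 6.93e-14
```

The cohort splits into 14 participants with a persistent 3-HPMA phenotype
and 6 with a CEMA phenotype; the pooled median daily CEMA/3-HPMA ratio is
about 0.7; and overnight excretion of both biomarkers is significantly
higher after high-glycerol dinners (days 3, 4, 7, 8) than after
low-glycerol dinners — the signature of intestinal glycerol-to-acrolein
conversion the mass-balance module then quantifies:

```r
mass_balance_params()             # h = 0.95, f = 0.20, MW 92.09 / 56.06
round(colonic_glycerol(0.44), 2)  # 0.24 mmol reaches the colon
round(acrolein_from_hpma(0.26), 2) # 1.30 umol intestinal acrolein
```

`run_pipeline(run_config(...))` chains every stage over CSV inputs and
writes per-stage tables plus a `report.json` capturing all parameters
used.

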