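---
title: "From dietary glycerol to urinary acrolein biomarkers: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From dietary glycerol to urinary acrolein biomarkers: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycacro)
```

## The scientific problem

Dietary fat is almost entirely triglyceride, so every meal delivers a
glycerol backbone bound to fatty acids. Most of it is hydrolysed and
absorbed in the small intestine, but the unabsorbed remainder reaches the
colon, where bacteria carrying the cobalamin-dependent glycerol/diol
dehydratase (the *pdu* operon, with *pduCDE* encoding the catalytic
subunits) can dehydrate glycerol to 3-hydroxypropanal, which spontaneously
yields acrolein — a highly reactive, toxic aldehyde. Acrolein is detoxified
through glutathione conjugation and excreted in urine as two mercapturic
acids: 3-HPMA (the reduced metabolite) and CEMA (the oxidised one).

`glycacro` implements the quantitative chain that connects these layers in
a controlled-diet intervention:

1. **diet**: per-item, per-meal and per-day glycerol from food fat content;
2. **urine**: timed urine collections converted to excreted biomarker
   amounts, aggregated into study days and overnight windows;
3. **mass balance**: back-calculation of intestinal acrolein and of the
   glycerol fraction converted;
4. **phenotypes and comparisons**: rule-based participant phenotyping and
   nonparametric exposure-group tests;
5. **community tables**: *pdu* functional-potential and SCFA summaries;
6. **synthetic cohort**: a seeded generator reproducing the cohort's
   statistical structure so that everything above is testable without
   study data.

## Diet model

Glycerol per food item is `fat_g * correction_factor`, where the
correction factor is the glycerol-per-fat mass fraction of that item. The
factor depends on fatty-acid chain length; published per-food factors are
not bundled, so the synthetic menu uses a single chemically motivated
default, the glycerol/triolein molar-mass ratio 92.09 / 885.45 = 0.1040.
Users supply their own per-item factors as a column of the diet table.

The menu follows the intervention's structure: four meal slots per day and
four repeating schedules covering the 11 study days as {1,5,9}, {2,6,10},
{3,7,11}, {4,8}. Dinner-exposure attribution is a configured lookup —
high-glycerol dinners on days {3,4,7,8}, low on {1,2,5,6,9}, and days
{10,11} excluded because their urine was pooled over 24 h. For new
datasets, `attribution_from_dinner()` classifies days by a dinner glycerol
threshold (default 1.5 g, between the low-dinner maximum 1.26 g and
high-dinner minimum 2.1 g of the emulated menu).

## Urine processing

Urine volume is weight / density at 1 kg/L. Amounts are
`conc [ng/mL] x volume [mL] / MW / 1000` µmol. The biomarker molar masses
are computed from the molecular formulas (3-HPMA C8H15NO4S = 221.271
g/mol; CEMA C8H13NO5S = 235.254 g/mol) and are configurable.

A study day runs 08:00 to 08:00; the overnight window runs 20:00 to 08:00
and is keyed to the study day of its evening, so that each night follows
one dinner. Collections are half-open intervals of 1–24 h that need not
align with window boundaries. The default assignment rule **pro-rates** an
interval's amount by the fraction of its duration inside each window. This
assumes uniform excretion within a collection; it is the only rule that
conserves total excreted amounts under any window partition, which makes
daily sums robust to how collections were scheduled. Whole-interval
assignment (by interval midpoint) is available as `method = "whole"` for
sensitivity analysis, since real excretion after an evening meal is not
uniform in time.

## Mass-balance model

With hydrolysis efficiency `h` (default 0.95), colonic glycerol delivery
from a meal containing `G` grams of glycerol is `(1 - h) * G / 92.09 * 1000`
mmol: the unhydrolysed fraction of intake. At the defaults this maps the
emulated low-dinner extremes 0.44 g and 1.26 g to 0.24 and 0.68 mmol.

Intestinal acrolein is back-calculated from urinary 3-HPMA by inverting
the excretion fraction `f` (default 0.20, from oral dosing studies):
`acrolein = 3-HPMA / f`. The mol% of a glycerol pool converted is
`100 * acrolein [µmol] / (pool [mmol] * 1000)`. The pool defaults to the
**colonic** delivery; total intake is available via
`denominator_mode = "intake"`. We default to colonic because conversion
happens in the colon and only colonic glycerol is available to *pdu*
carriers; the printed-report convention is full-precision computation with
half-even rounding to 2 decimals at presentation.

## Phenotype classification

The persistent mercapturic-acid phenotype rule is a disjunction of two
clauses evaluated on a participant's valid study days (both analytes
present; at least 3 days required):

* **majority**: CEMA > 3-HPMA on strictly more than half the days;
* **median override**: median daily CEMA > median daily 3-HPMA.

Either clause labels the participant CEMA; otherwise the label is HPMA.
Ties fall to HPMA because 3-HPMA is usually the dominant urinary
mercapturic acid of acrolein; the tie label and threshold are
configurable. The two clauses can genuinely disagree (a majority of
3-HPMA days together with a higher CEMA median, when win margins are
uneven); the disjunction labels such participants CEMA and flags them
(`clause_conflict`) for review rather than deciding silently.

Exposure-group comparisons use the two-sided Mann–Whitney U test on
participant-nights (not participant means), matching per-sample overnight
boxplots; day effects use Kruskal–Wallis with pairwise Wilcoxon tests
under Bonferroni correction. All tests are the standard `stats` routines;
an exact-enumeration Mann–Whitney oracle in the test suite checks the
small-sample behaviour independently.

## The synthetic cohort generator

The generator reproduces the statistical structure the analysis assumes —
it is a simulation of the study design, not of human physiology.

* **Cohort**: 20 participants (10 male, 10 female), 11 days, phenotype
  labels fixed at exactly 14 HPMA : 6 CEMA (deterministic proportions
  after a seeded shuffle, so integration tests see the exact split).
* **Menu**: schedule-repeating, dinners in [0.44, 1.26] g (low) and
  [2.1, 3.4] g (high), lunch carrying 49–55% of glycerol on low days;
  male menus sit in the upper part of each range, female in the lower.
* **Biomarkers**: daily 3-HPMA for participant *i* on day *d* is
  `0.58 * exp(b_i + e_id)` µmol with `b_i ~ N(0, 0.05²)` and
  `e_id ~ N(0, 0.30²)`; daily CEMA is 3-HPMA times a participant-level
  ratio centred at 0.586 (HPMA phenotype) or 1.45 (CEMA phenotype) with
  log-SD 0.05 and an independent day effect. These values were calibrated
  once, by simulation, so that (i) the pooled median daily CEMA/3-HPMA
  ratio is 0.73, (ii) pooled daily amounts stay inside the target ranges
  (CEMA 0.11–1.82, 3-HPMA 0.20–1.90 µmol/day) for ≥99% of
  participant-days, and (iii) the classifier recovers the latent labels
  essentially always at the default separation.
* **Collections**: three intervals per day (08–14, 14–20, 20–08) on days
  1–9 and a single 24-h collection on days 10–11, mirroring the emulated
  sampling scheme. Half of a day's excretion (by duration) falls in the
  overnight portion, which is multiplied by the `overnight_effect` uplift
  (default 1.5) after high-glycerol dinners. Concentrations derive from
  simulated urine weights (1 kg/L) and carry multiplicative lognormal
  measurement noise with CV 0.10.
* **Community tables**: 9 *pdu*-positive taxa (labels modelled on known
  intestinal glycerol transformers; the tables are synthetic) in a
  background of 390 negative genomes; 5 "core" taxa detected per donor
  with probability 0.99 and 4 variable ones with 0.55, giving per-donor
  species counts of at least 5 with a cohort median near 7; one taxon
  dominates the pduC copy signal (>90%); fecal glycerol is a truncated
  lognormal on [0.2, 19.4] µmol/g; SCFA are acetate-dominant lognormals.

What the generator does **not** emulate: pharmacokinetics of acrolein
(absorption, conjugation kinetics, the excretion-time profile within a
night), diet–microbiome feedback, correlation between a participant's
*pdu* carriage and their biomarker levels, below-LOD censoring of urine
concentrations, or missing collections. Passing tests therefore
demonstrate that the pipeline's arithmetic, aggregation rules and
statistical procedures behave as specified — not that the biological model
generating real data has these parameters.

### A note on the overnight null comparison

Under a unit uplift (`overnight_effect = 1`) high and low nights are
identically distributed, but nights are clustered within participants and
the persistent phenotype ratio is itself a participant-level effect.
Rank tests applied to clustered observations that appear in both groups
are *conservative*, so the empirical size of the CEMA and CEMA+3-HPMA
comparisons falls below the nominal α; only the 3-HPMA comparison, whose
participant-level variance component is small, attains near-nominal size.
The test suite therefore checks size ≈ α on 3-HPMA and
non-anticonservativeness (size ≤ α + 0.02) on the other analytes. This is
a property of the test applied at the participant-night level, not a bug
in the generator; a mixed-effects or within-participant analysis would
restore exact size but is outside the scope of the emulated analysis.

## Numerical choices and degenerate inputs

* Pro-rating conserves amounts to well below 1e-9 µmol; additivity of the
  diet aggregation holds to 1e-9 g.
* Percentages (day profiles, SCFA proportions, taxon shares) are reported
  as NA, with a message, when their denominator is zero — never silently
  0 or `Inf`; ratio denominators (3-HPMA, propionate) behave the same.
* Below-LOD qPCR values are substituted with LOD/2 for share computation
  and treated as absent for occurrence counting, the standard censoring
  convention; absolute abundances are reported on the log10 scale with
  below-LOD flagged rather than log(0).
* Strict inequalities throughout the phenotype rule make label changes
  under exact ties impossible; the tie label is explicit configuration.
* All generator randomness flows through a single integer seed;
  sub-generators use fixed offsets of it, and identical configurations
  produce byte-identical CSV output.

## Problem sizes used by the test suite

The suite exercises the default cohort size (20 participants × 11 days,
580 collection intervals): single-cohort checks at fixed seeds, latent
phenotype recovery over 100 cohorts, overnight-comparison size over 500
null cohorts and power over 100 cohorts, and exact-enumeration
Mann–Whitney checks for group sizes up to 8 (≤ 12 870 assignments). These
sizes keep each property estimate's Monte-Carlo error small relative to
the asserted bands.

## Known limitations

* Per-food correction factors are study-specific inputs; the bundled
  default (0.1040) is a single-value stand-in, so absolute daily glycerol
  from the synthetic menu should not be read as nutritional ground truth.
* The excretion fraction (0.20) comes from oral dosing in rats; the
  back-calculated intestinal acrolein inherits that assumption linearly.
* The mol% conversion depends on the chosen glycerol pool; per-participant
  variation in hydrolysis efficiency is not modelled.
* Phenotype calls on short series (3–5 days) rest on few comparisons and
  should be read together with the reported evidence columns.
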