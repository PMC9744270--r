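---
title: "Methods: algorithmic screening for atypical diabetes"
author: "adscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: algorithmic screening for atypical diabetes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adscreen)
```

## The screening problem

Atypical diabetes — here, the insulin-sufficient non-metabolic (ISNM)
phenotype — is rare enough (on the order of one in ten thousand biobank
participants) that finding cases by reviewing every diabetes chart is
infeasible. The package implements a screening funnel: a **base
algorithm** that removes patients whose records carry evidence of typical
type 2 diabetes or another known cause, six **branch algorithms** that
remove likely type 1 diabetes by different clinical signals, and a
deterministic **chart-classification rule engine** that plays the role of
the final expert review. The funnel trades recall for review burden: its
purpose is a candidate list small enough to verify, not an exhaustive
census.

## Base algorithm

Input is the set of patients flagged by an external ML T2D phenotype
algorithm (`ml_t2d`); the package never recomputes that flag. Six
exclusion criteria are evaluated as independent predicates over each
patient's full longitudinal record, with per-criterion attrition
accounting:

| criterion | rule | default |
|---|---|---|
| `metabolic_hdl` | any HDL **strictly below** the floor | 50 mg/dL |
| `metabolic_tg` | any triglycerides **strictly above** the ceiling | 150 mg/dL |
| `metabolic_bmi` | any BMI **strictly above** the ceiling | 30 kg/m² |
| `engagement` | fewer than `min_bmi_count` BMI records ≤ `bmi_normal_ceiling` | 3 records, ≤ 30 kg/m² |
| `cf` | any diagnosis code with a cystic-fibrosis prefix | ICD-9 `277.0`, ICD-10 `E84` |
| `antibody` | any positive GAD65/IA2/ZnT8 result | full panel |

Conventions worth making explicit:

* **Strict comparisons.** The rules are worded "ever less than" / "ever
  greater than", so boundary values (HDL exactly 50, TG exactly 150, BMI
  exactly 30) survive.
* **Missing labs pass.** A patient with no HDL or TG on record is not
  excluded by the metabolic criteria — absence of evidence is not
  evidence of metabolic disease. Data sufficiency is enforced only by the
  engagement criterion, whose stated purpose is reliable longitudinal
  contact, not weight status; accordingly "normal BMI" defaults to
  ≤ 30 kg/m² (the > 30 exclusion already removes obese-range records). A
  stricter normal-weight reading (18.5–24.9) is available through
  `bmi_normal_floor`/`bmi_normal_ceiling`.
* **Joint predicate with per-criterion tags.** Whether the source flow
  applied the criteria sequentially or jointly is not recoverable; the
  package evaluates them jointly and tags every criterion a patient
  trips, which subsumes both readings (a sequential attrition view is
  also derived, in the fixed criterion order above).

## Branch algorithms

The six branches are evaluated **independently over the same base-kept
set** — they are alternative rule-outs, not a chain — and their union,
with a per-branch membership matrix, is the candidate set. Two subset
laws follow from the definitions and are enforced by property tests:
branch 3 ⊆ branch 4 (a T2D-specific agent implies "T2D-specific or
metformin"), and branch 5 ⊆ branch 6 given the flag-exclusivity
invariant (a patient cannot be simultaneously ruled out and confidently
called T1D).

Open choices, resolved as follows:

* **Branch 1 panel completeness.** "Documented negative antibody
  testing" defaults to *at least one* negative result with no positives;
  `require_full_panel = TRUE` demands all three antibodies.
* **Drug-class era.** GLP-1 RA and SGLT2i became common outside T2D
  after early 2020; an optional `cutoff_date` ignores later exposures.
  The default is no cutoff, matching records extracted before that era.
* **Medication vocabulary.** Drug names resolve through a shipped
  name → class table; unknown names map to class `other` with a warning,
  never an error, so one exotic prescription cannot abort a run.

## Chart classification

`summarize_case()` condenses a record into the fields a reviewer would
extract: value ranges, the count of distinct non-insulin diabetes drug
classes (prescriptions are not counted twice; steroids and non-diabetes
drugs never count), derived antibody status (`positive` dominates, then
`negative_documented`, else `untested`), chart facts, and the
observation span. Undocumented facts are `NA` and are semantically
distinct from documented absence — the NMI category depends on this.

`classify_diabetes_type()` applies an ordered, first-match-wins rule
list (the exact review flow is not fully recoverable from its published
description, so the order is an explicit, documented approximation, and
the rule list is data — users can reorder or edit it):

1. positive MODY genetic test → MODY;
2. antibody-positive with youth onset (< 20 y) and insulin dependence
   from onset → typical T1D;
3. antibody-positive otherwise → LADA/autoimmune;
4. pancreatic disease before diagnosis → pancreatic-secondary;
5. chronic steroid exposure **at diagnosis** → steroid-induced (current
   steroid use alone does not fire the rule);
6. metabolic features at diagnosis → typical T2D;
7. youth onset + insulin from onset + low C-peptide → typical T1D;
8. MODY suspicion (diagnosis < 35 y **and** multigenerational family
   history) without genetic testing → NMI;
9. required information missing → NMI, listing the gaps;
10. default → AD.

The required-information set (rule 9) is a documented choice: antibody
**or** C-peptide testing, age at diagnosis, and BMI or metabolic
features at diagnosis. `NA` never fires a named-form rule, so removing
documentation can move a case from AD to NMI but never to a named form —
a monotonicity property the test suite checks.

### Subtype rules

`classify_ad_subtype()` applies KPD, then MARD, else ISNM
(see `subtype_config()`):

* **KPD** requires a documented adult ketosis history, non-positive
  antibody status, and no long-term insulin (preserved β-cell function).
* **MARD** requires onset strictly after 60 (the clinical "soft cutoff"
  is implemented strictly: a case diagnosed exactly at 60 is ISNM, which
  is the reading consistent with the packaged roster), every recorded
  HbA1c strictly below 8 % (64 mmol/mol), at most two non-insulin
  agents, no insulin, and at least five years of observed course.
* Ages recorded as "X or earlier" classify at X, flagged as upper bounds
  in the output.

**Observation span** is measured as the difference in calendar years
between the first and last dated record. EHR diagnosis dates are
commonly documented at year resolution, and a day-resolution span makes
"N years apart" equal 4.999 years, which would misread courses observed
over exactly the five-year MARD boundary; the year convention is exact
at such boundaries and is used everywhere (generator, fixture,
summaries).

## The packaged case roster

`table2_case_specs()` ships a transcription of the 16 published
confirmed-atypical cases (sex, ages, BMI/HbA1c ranges, regimen, family
history), plus the adult-ketosis indicator documented in the narrative
for case 1 only. Facts the table does not state were filled with the
least informative values consistent with a confirmed review: antibody
status `negative_documented` (all cases passed an antibody-aware
review), C-peptide tested only for the explicitly β-cell-positive case,
MODY testing `untested`, no pancreatic disease or steroid exposure at
diagnosis, BMI at diagnosis at the range midpoint. The published
subtype label rides along as a held-out column for validation; no
classifier reads it. `plant_cases()` materialises these specifications
as full records whose derived summaries equal the specification, which
is how the roster is embedded in synthetic haystacks.

## Synthetic cohort generator

`generate_cohort()` draws patients from latent archetypes (nondiabetic,
typical T2D, typical T1D, LADA, MODY-like, and three atypical forms)
and materialises longitudinal labs, BMI, medications, antibody tests,
chart facts and phenotype flags. Defaults mirror the published cohort
composition: 6.22 % latent typical T2D, 0.63 % typical T1D, atypical
cases at 16/114,975 split 1:7:8 (KPD:MARD:ISNM), plus 0.2 % LADA and
0.1 % MODY-like as confounder mass. `ad_prevalence` exists because at
the realistic rate a 10,000-patient simulation contains about one
atypical case; studies of the funnel itself raise it for power.

Design points:

* **Lab values are i.i.d. draws** around archetype means. The filters
  read only extrema and counts, so temporal autocorrelation would add
  complexity without changing any decision.
* **Constructive guarantee.** Atypical archetypes are truncated into the
  base-passing region (HDL ≥ 51, TG ≤ 148, BMI ≤ 29.4 with ≥ 3 records,
  no CF, no positive antibody) and receive favorable flags (`ml_t2d`
  TRUE — the screened population is by definition what the T2D flag
  captured — high-PPV T1D FALSE, rule-out TRUE). Every atypical patient
  therefore survives the base algorithm and reaches the candidate union;
  the test suite checks this exhaustively per generated cohort.
* **Flag-noise algebra.** For a flag with sensitivity *s* and PPV *p*
  against latent truth of prevalence π, the false-positive rate that
  reproduces *p* is *s*π(1−*p*)/(*p*(1−π)). The T1D rule-out with NPV
  *v* and coverage *q* (fraction of non-T1D patients ruled out) requires
  P(ruled out | T1D) = *q*(1−π)(1−*v*)/(*v*π), which must not exceed
  1 − *s* for the two flags to stay mutually exclusive. At π = 0.63 %
  an NPV as low as 0.99 is only attainable for limited coverage — hence
  the default *q* = 0.12; infeasible configurations are rejected with
  the algebra in the error message. Rates are calibrated against the
  *realized* archetype counts of each cohort, so that conditional on the
  truth table the flag errors are purely binomial at the stated
  operating points. The high-PPV flag's sensitivity is not published for
  its operating point; the 0.78 of the sibling algorithm is the default.
* **Chart-fact missingness** is injected independently per field at a
  default rate of 0.13, chosen once to place the NMI fraction of
  classified candidates near the published one-in-eight share under the
  default classifier.
* **Determinism.** The seed is mandatory; identical configurations
  produce identical cohorts, and the caller's RNG state is restored.

What the generator does **not** emulate: real lab trajectories
(autocorrelation, treatment response), realistic ICD vocabularies beyond
the CF codes the filter reads, correlated chart-fact missingness, or
informative antibody-testing patterns (who gets tested is independent of
latent type within an archetype). Passing tests on this test bed
therefore demonstrate the *logic* of the funnel — exclusion boundaries,
set algebra, accounting, calibration of flag noise — not its clinical
operating characteristics on real records.

## Polygenic scoring

Scores are plain dosage-weight dot products. Missing dosages contribute
the variant's cohort-mean dosage by default (standard scoring
behaviour; `missing = "zero"` is available). The T2D global extended
score is reported after a linear shift anchoring the minimum at exactly
0; the shift preserves ranks and is idempotent. Centiles count the
fraction of the reference strictly below the score, rounded to an
integer: ties do not count as "below", so a score at the reference
maximum of an *n*-value reference gets round(100(*n*−1)/*n*), and 100
requires strictly exceeding every reference value. Variant QC applies
call-rate, MAF, Hardy–Weinberg (exact conditional test on hard-called
genotypes — robust at small *n*, where the chi-square test is not) and
case/control differential-missingness filters; the published pipeline
names these filters without thresholds, so the defaults (0.05, 0.01,
1e-6, 0.02) are conventional GWAS values surfaced in
`variant_qc_config()`. Ancestry restriction is honoured as a filter on
caller-supplied metadata; the package does not infer ancestry. Phasing,
imputation and posterior weight estimation are out of scope — published
weights are inputs.

## Statistics

* **Median/IQR** uses linear interpolation at positions 1 + (*n*−1)*p*
  (quantile type 7) — the convention under which the roster's age
  summaries reproduce exactly; it is fixed, not configurable, to keep
  reports comparable.
* **Wilcoxon rank-sum**: midrank ties; normal approximation with
  tie-corrected variance and a 0.5 continuity correction; exact mode
  computes the conditional rank-sum distribution by a shift-algorithm
  convolution (midranks doubled to an integer support) and doubles the
  smaller tail, capped at 1. `mode = "auto"` switches to exact at pooled
  *n* ≤ 12.
* **Kruskal–Wallis** delegates to `stats::kruskal.test` (tie-corrected
  H, χ² reference with *k*−1 df); fully tied input returns H = 0, p = 1
  rather than the 0/0 the textbook formula produces.
* **Categorical variables** are routed to the rank test on
  integer-coded categories, as is conventional in this literature even
  though a contingency test is the textbook choice;
  `categorical_test = "fisher"` provides the alternative. No
  multiple-testing correction is applied by default (`p_adjust` exposes
  one), matching the descriptive use of these tables.

## Problem sizes used in validation

The shipped test suite exercises the oracle-equivalence checks at
10,000 synthetic patients, the structural-invariant sweeps over 1,000
small random cohorts, flag calibration at 20,000 patients, and
planted-recovery runs at 3,000 patients with boosted atypical
prevalence — sizes at which multinomial sampling error is small
relative to the tolerances being checked while the full suite stays
fast enough to run routinely.

## Known limitations

* The chart-classification engine is a deterministic approximation of a
  consensus expert review; it cannot reproduce judgement on facts the
  summary does not carry, and its rule order, required-information set
  and youth-onset cutoff are documented choices, not published ones.
* The roster transcription fills undocumented fields with least-informative
  defaults (above); cases 9 and 10 carry upper-bound diagnosis ages and
  are classified at the bound.
* The funnel's published single-number yields depend on a private
  source population and are not recomputable here; the package validates
  against the in-roster reproductions and property/oracle suites
  instead.
* Branch yields are reported as exact fractions; note that the published
  "48.2 %" for 13/27 rounds from 48.148… and prints as 48.1 at one
  decimal in this package's reports.
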