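---
title: "Candidate-gene SNP analysis: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Candidate-gene SNP analysis: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snptrait)
library(dplyr)
```

snptrait implements the three statistical stages of a classical
candidate-gene association study in poultry or livestock: per-marker
diversity statistics, fixed-effects genotype–trait association with
significance-letter displays, and qPCR relative-expression analysis. This
vignette explains the models behind each stage, the conventions the
package adopts where the field's practice is ambiguous, and what the
bundled synthetic-cohort generator does and does not emulate.

## Marker diversity and Hardy–Weinberg testing

For a biallelic locus with allele frequencies $p_i$ estimated by direct
allele counting, the package computes

* expected (average) heterozygosity $H = 1 - \sum_i p_i^2$,
* polymorphism information content
  $\mathrm{PIC} = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2$,
* effective allele number $N_e = 1 / \sum_i p_i^2$.

All three are written over $n$ alleles, so a multi-allelic extension
needs no interface change, but the tabulation layer accepts biallelic
loci only. PIC classes follow the usual thresholds: below 0.25 lowly
polymorphic, 0.25–0.5 moderately, above 0.5 highly.

`hwe_test()` is a plain $\chi^2$ goodness-of-fit of the three observed
genotype-class counts against $N(p^2,\,2pq,\,q^2)$, with every class in
the sum even when its observed count is zero. Two degrees-of-freedom
conventions are offered because published candidate-gene tables are not
consistent about them:

* `df_mode = "paper"` (default) uses **df = 2**, treating all three
  class proportions as free. This is what reproduces the p-values of the
  summary tables this package was validated against.
* `df_mode = "standard"` uses the conventional **df = 1** (three
  classes minus one constraint minus one estimated allele frequency).

df = 2 is statistically conservative: under exact equilibrium its
rejection rate at $\alpha = 0.05$ falls below the nominal level, while
df = 1 is calibrated. The test suite verifies both behaviours by
simulation (2,000 cohorts of 176 individuals at $p = 0.25$). A locus
with an absent allele is flagged `monomorphic` and assigned
$\chi^2 = 0$, $p = 1$ rather than dividing by a zero expectation.

### Rounding policy

Every statistic is computed at full double precision; rounding exists
only in the report-rendering layer (`render_diversity_report()`,
`render_association_report()`), which rounds **half away from zero**
(`round_half_up()`) — frequencies, $p$, $H$, PIC and $N_e$ to three
decimals, $\chi^2$ to two, means and SDs to two. Published tables of
this kind occasionally mix conventions (statistics recomputed from
already-rounded frequencies); keeping computation and display separate
means such quirks can never contaminate downstream numbers. Two cells of
the reference table are known casualties of that mixing and are
documented rather than chased: one locus's H/PIC pair (printed values
arise only from pre-rounded frequencies) and one p-value that no
consistent convention reproduces.

```{r table2}
counts <- genotype_counts(
  locus = c("g.57337C>A", "g.64757T>G", "g.97213G>A", "g.220985G>A"),
  n_hom_ref = c(111, 21, 159, 158),
  n_het = c(47, 50, 17, 18),
  n_hom_alt = c(18, 105, 0, 0),
  allele_ref = c("C", "T", "G", "G"),
  allele_alt = c("A", "G", "A", "A")
)
render_diversity_report(counts)
```

## Genotype–trait association

Each trait–locus pair is analysed with the unbalanced two-factor
fixed-effects model

$$Y_{ijk} = \mu + G_j + S_k + e_{ijk},$$

where $G_j$ is the genotype class, $S_k$ the sex, and no interaction is
included. Decisions embedded in `fit_trait_model()`:

* **Estimation** is ordinary least squares on complete cases
  (trait, genotype and sex all present; missingness is handled per
  locus, so different loci may analyse slightly different subsets).
* **The genotype test** is the partial ("each term last", Type III) F
  for genotype given sex. With no interaction term this equals the
  classical SPSS GLM default and, in balanced designs, the ordinary
  two-way ANOVA F — both identities are tested against `car::Anova()`
  and `stats::anova()`.
* **Reference levels**: sex F (female), genotype the first level of the
  canonical order hom-ref, het, hom-alt.
* A factor left with a single level, or an aliased design, raises a
  degenerate-design error naming the factor rather than silently
  dropping terms.

### Pairwise comparisons and letters

`pairwise_genotype_comparisons()` builds model-adjusted genotype
contrasts with standard errors from the pooled residual mean square.
The default multiplicity treatment is **Fisher's LSD** (unadjusted
pairwise t), with Tukey HSD (studentized range) and Bonferroni
selectable. LSD was chosen as default because the reference tables'
letter patterns are most readily produced by unadjusted pairwise tests
and the software they came from does not state its procedure; users
wanting family-wise control should pass `method = "tukey"`.

`compact_letter_display()` converts the comparisons to letters by
insert-and-absorb: start with one letter column containing every group;
for each significant pair, split every column containing both members;
absorb columns that became subsets; assign letters to columns ordered so
that `a` seeds at the group with the highest **observed** mean (ties
broken by canonical genotype order). The defining invariant — two groups
share a letter iff their comparison is non-significant at $\alpha$ — is
property-tested on 500 random p-matrices. Letters are generated at two
levels: lower-case at $\alpha = 0.05$ and upper-case at
$\alpha = 0.01$, the dual-alpha convention of animal-science tables.

The rendered summary deliberately mixes conventions the way the field's
tables do: **means and SDs are raw group statistics** (not model-adjusted
means), while the **letters come from model-based comparisons**. The SD
column in such tables describes raw dispersion; the letters answer the
adjusted question.

```{r assoc}
cohort <- simulate_cohort(heying_cohort_spec(), seed = 42)
associate_traits(cohort$genotypes, cohort$traits,
                 trait_cols = "live_weight") |>
  render_association_report() |>
  select(locus, genotype, n, display, genotype_p)
```

## Relative expression (2^-ddCt)

`delta_ct()` averages technical replicates **on the Ct scale** first,
then forms $\Delta Ct = Ct_{target} - Ct_{reference}$ per sample.
`relative_expression()` subtracts the **mean** $\Delta Ct$ of the
calibrator group (expression "relative to the average of control"), so
the calibrator's mean $\Delta\Delta Ct$ is 0 and its geometric-mean fold
change is 1. No amplification-efficiency correction is applied: the
method is the plain Livak $2^{-\Delta\Delta Ct}$.

Group comparisons default to the **pooled-variance Student t-test on
the $\Delta Ct$ scale**. The scale choice matters: $\Delta Ct$ is
approximately normal where fold changes are log-normal, and p-values on
the $\Delta Ct$ scale are invariant to which group is the calibrator
(an invariance the tests verify). Comparing fold changes directly
(`scale = "fold"`) and Welch's correction (`var_equal = FALSE`) are
available. Significance marks follow the usual figure legend: `*` for
$p<0.05$, `**` for $p<0.01$.

## The synthetic cohort generator

Raw data for studies of this design are rarely deposited, so the
package ships a generator whose defaults mirror the motivating study's
conditions and whose ground truth makes every stage testable:

* **Cohort shape**: 176 birds, 133 female / 43 male — the sex imbalance
  is part of the design, since it is what makes Type III testing
  non-trivial.
* **Genotypes**: four biallelic loci at allele-frequency pairs
  0.236/0.764, 0.261/0.739, 0.952/0.048, 0.949/0.051. Hardy–Weinberg
  departure is a single inbreeding coefficient $f$ per locus
  (heterozygote frequency $2pq(1-f)$); the preset uses $f = 0.26$ at
  the two loci whose published $\chi^2$ implies a heterozygote deficit
  (the value implied by their observed/expected heterozygosity ratio)
  and $f = 0$ at the two loci consistent with equilibrium. The slight
  heterozygote *excess* at the latter two ($\hat f \approx -0.05$) is
  not emulated: $f$ is restricted to $[0,1]$ and their departure is not
  statistically distinguishable from zero at $N = 176$.
* **Traits**: six representative phenotypes at published gram scales
  (e.g. live weight $\mu \approx 1430$ g, $\sigma \approx 240$ g), with
  additive genotype effects on the first locus chosen to qualitatively
  reproduce the published letter patterns (the het and hom-alt classes
  roughly 80–100 g above hom-ref for live weight) and a rooster–hen
  effect of 230–250 g. True effect sizes are unknowable without the raw
  data; these are calibrated to pattern, not to printed means.
* **Ct tables**: reference-gene Ct $\sim N(\mu_{ref}, \sigma_{ct}^2)$
  and target Ct offset by $-\log_2(\text{fold})$, making recovered
  fold changes unbiased on the log2 scale.

What the generator does **not** emulate: pedigree/relatedness structure,
genotype-by-sex interaction, linkage between loci, longitudinal
correlation between repeated weights, non-Gaussian residuals, and
genotyping error. Passing tests on synthetic cohorts therefore
demonstrate correctness of the estimators under the stated model, not
robustness to those real-data features.

Generation is deterministic: the same spec and seed reproduce the
tables byte-identically (`withr::with_seed`, leaving the caller's RNG
untouched).

## Problem sizes used in the test suite

Simulation-based checks run at the sizes that make their statistical
guarantees sharp while staying quick: 1,000 random spectra for the PIC
brute-force oracle, 500 random p-matrices for the letter invariant,
100 random small designs for the OLS oracle, 500 replicates of the
176-bird cohort for effect-recovery bias, 1,000 replicates for the
null-uniformity KS check, and 2,000 replicates each for the HWE and
t-test type-I-error calibrations. Monte-Carlo assertions use 3–3.5
standard-error bands.

## Known limitations

* Only biallelic loci are tabulated; the diversity formulas themselves
  are $n$-allele general.
* No exact (permutation) Hardy–Weinberg test and no continuity
  correction; at the cohort sizes targeted the plain $\chi^2$ is what
  reference tables use.
* The association module fits each trait independently; repeated
  weekly weights are treated as separate traits, not as a longitudinal
  model.
* LSD letters control only per-comparison error; with three genotype
  classes the inflation is modest, but Tukey is one flag away.
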