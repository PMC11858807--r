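---
title: "Methods: kinanthropometric profiling of an orienteering cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinanthropometric profiling of an orienteering cohort}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinanthro)
```

kinanthro implements the full computational pipeline of a cross-sectional
kinanthropometry study of athletes grouped by sex and competitive ranking
(elite vs non-elite): body composition derived from ISAK anthropometry,
Heath-Carter somatotyping with somatochart dispersion statistics,
nutrition-knowledge (A-NSKQ) and physical-activity (IPAQ-SF) questionnaire
scoring, a factorial inference layer, and a seeded synthetic-cohort
generator so that every stage can be exercised without access to the
original athlete records, which are not publicly deposited.

## Body composition

The derivation chain starts from 26 ISAK measurements per athlete (4 basic,
9 skinfolds in mm, 9 girths in cm, 4 breadths in cm). BMI is mass/stature².
Body density comes from sex-specific skinfold regressions, converted to
percent body fat, with bone mass from stature and breadths and skeletal
muscle mass from the circumference model of Lee and colleagues:

$$\mathrm{SMM} = \mathrm{Ht} \cdot (0.00744\,\mathrm{CAG}^2 +
0.00088\,\mathrm{CTG}^2 + 0.00441\,\mathrm{CCG}^2) + 2.4\,\mathrm{sex} -
0.048\,\mathrm{age} + \mathrm{race} + 7.8$$

with Ht in metres and CAG/CTG/CCG the arm, thigh and calf girths corrected
by $\pi \times$ skinfold (cm). The ethnicity term defaults to 0 because the
study population's composition is not modelled.

**The equation registry.** The density, fat-conversion and bone-mass steps
are deliberately pluggable (`register_equation()`, keyed by string id).
Published skinfold equations differ between laboratories, and the study
this pipeline reconstructs cites its density and bone-mass sources without
printing the formulas. The shipped defaults are a linear male-athlete
7-skinfold density, a log-linear female-athlete 4-skinfold density, the
Siri conversion (495/BD − 450) and a von Döbeln-type bone-mass form,
3.02·(h²·wrist·femur·400)^0.712. On the elite-male group-mean skinfolds
these defaults give ≈9.0 %BF where the study's descriptive table prints
8.4: the defaults are therefore *provisional*, the %BF/BD/bone-mass table
cells are excluded from numeric validation, and swapping in a confirmed
equation requires no code change. Muscle mass, by contrast, reproduces both
printed elite group means (30.5 and 22.1 kg) exactly at 1 dp, which pins
down the Lee chain including the π-correction convention.

Skinfolds are stored in mm (the ISAK convention) and converted to cm inside
the girth corrections. Validation is warn-not-fail within broad physiologic
ranges (stature 100–230 cm, skinfolds 1–80 mm): athlete populations include
extreme but valid values, so only impossible values (non-positive, girth
smaller than its correction) reject a record. Derived values are carried at
full precision; 1-dp rounding — the presentation convention of these
tables — happens only at serialisation (`write_report(round = 1)`).

## Heath-Carter somatotype

Endomorphy uses the cubic in the height-corrected sum of triceps,
subscapular and supraspinale skinfolds (factor 170.18/stature, the standard
proportional correction; kept on by default because it reproduces the
published elite-male endomorphy of 2.1). Mesomorphy is the linear form in
humerus and femur breadths, corrected flexed-arm and calf girths (girth −
skinfold/10) and stature. Ectomorphy is piecewise in the height-weight
ratio HWR = stature/mass^(1/3), with the upper branch applied *inclusively*
at HWR ≥ 40.75 — the two branches disagree there (1.249 vs 1.237), so the
boundary convention is covered by an explicit test. All components floor at
0.1.

Somatotypes project onto the somatochart as X = ecto − endo,
Y = 2·meso − (endo + ecto). Dispersion uses two distances: SDD =
√(3ΔX² + ΔY²) in chart Y-units (the √3 makes steps along the two chart
axes commensurate on the triangular grid) and SAD, the plain Euclidean
distance in 3-D component space; SDM and SAM are their means over
individuals, by default around the group-mean somatotype. Both are exposed
in pairwise and per-group list form, because published tables sometimes
print a single elite-vs-non-elite distance per sex and sometimes the
within-group means. Note that distances recomputed from *rounded* printed
group means differ from values computed on raw data (e.g. a male
elite/non-elite SDD of 2.96 from 1-dp means where 3.1 was printed); the
package treats such checks as bound checks, not equalities.

**Classification.** The 13-category labels operate on 1-dp rounded
components, the resolution at which the rules are stated. Precedence:
central (no pairwise difference > 1.0) first — this ordering is required
for a somatotype like (3.3, 3.5, 3.0), which is central although mesomorphy
is nominally dominant; then the edge categories ("endomorph-mesomorph"
etc., named in chart order) when the top two are within 0.5 and exceed the
third, which also resolves exact ties deterministically; otherwise the
strictly dominant component gives "balanced X" or "Y-ic X".

## Questionnaire scoring

**A-NSKQ.** 35 multiple-choice items, 11 general (GNK) and 24 sports
nutrition (SNK); scores are percent correct per section and overall, so
TNK = (11·GNK% + 24·SNK%)/35 identically — a weighting the published group
means satisfy exactly at 1 dp, which is used as an acceptance check.
Unanswered items count as incorrect (the denominator is fixed by the
instrument). The items themselves are copyrighted, so the package ships a
synthetic placeholder key and takes the licensed key as an argument. Band
boundaries are published as integers (0–49, 50–65, 66–75, 76–100); they are
implemented as the half-open partition [0,50), [50,66), [66,76), [76,100]
so that non-integer scores are covered without gaps or overlaps.

**IPAQ-SF.** Cleaning first: domains under 10 min/day are re-coded to zero,
and records whose summed daily activity minutes exceed 960 (16 h) are
flagged as outliers and excluded from categorisation. The outlier rule is
applied to the *daily* sum across the three domains, matching the "16 h per
day" gloss of the guideline; the official 180-min/day per-domain truncation
exists behind `truncate_180` but defaults off because the reconstructed
protocol does not mention it. MET-minutes use the standard weights (walking
3.3, moderate 4.0, vigorous 8.0; domain score = weight × days × min/day),
and the low/moderate/high categories follow the official criteria.
kcal/week uses the IPAQ convention MET-min × kg/60; the study prints
kcal/week without a formula, so the convention used is recorded in the
report metadata.

## Inference layer

Each variable passes a normality gate: a Kolmogorov-Smirnov test with
sample-estimated parameters, which requires the Lilliefors correction —
the naive KS p-value would be strongly anticonservative. The null
distribution is simulated (default 400 replicates, seeded, default seed
20230714; the caller's RNG state is restored), and the statistic itself is
test-verified against an independent Lilliefors implementation. Normal
variables get a two-way Type-III ANOVA under sum-to-zero contrasts (the
convention under which Type-III sums of squares are standard; they matter
because the four cells are unbalanced); partial eta-squared is
SS_effect/(SS_effect + SS_error), labelled small/medium/large at
0.01/0.06/0.14. Non-normal variables get the aligned rank transform: for
each effect the response is stripped of all *other* estimated effects
(unweighted cell-mean estimates), mid-ranked, and the full factorial run on
the ranks, reading off only the aligned effect. The Type-III sums of
squares are verified in tests against a brute-force full-vs-reduced model
comparison, and both engines hold their nominal Type-I error (0.05 ± 0.02
over 1000 seeded null replicates at 15 observations per cell). The gate is
automatic but can be pinned per variable (`method_override`), since
reproducing a specific published table can hinge on a borderline gate.

When the sex×ranking interaction is significant at 0.05, Welch
(unequal-variance) pairwise t-tests over the four cells are attached with
the Bonferroni correction min(1, m·p); Welch because the groups are
unbalanced and heteroscedastic in practice. Pearson correlations are
computed per sex on pairwise complete cases with |r| labels at
0.10/0.30/0.50.

Design utilities: the Cochran sample size n₀ = z²p(1−p)/m² with
finite-population correction (population 2500, z = 1.96, p = 0.8, ±10%
gives the study's 61), and omnibus power via the noncentral F
(λ = f²N; f = 0.4, α = 0.05, 4 groups, N = 58 gives 0.691, the "0.7
achieved"). Exact power is returned and rounding left to the caller,
because per-group rounding conventions differ between software (the
study's a priori 18/group; some tools return 19).

## Synthetic cohort generator

The generator's defaults *are* the study conditions: four groups of
13/17/10/18 athletes with every printed raw-variable mean and SD as
generating parameters. Only raw inputs are generated — BMI, somatotype,
MET scores are always derived downstream, so tests exercise the real
arithmetic rather than a circular shortcut.

Anthropometrics follow a three-factor latent model (frame size, adiposity,
muscularity) rather than a full 26×26 covariance: the descriptive table
gives no covariances, and three interpretable knobs (loadings fixed per
variable; frame-adiposity and frame-muscularity correlations as spec
parameters, defaults 0.3/0.4) produce realistic structure — skinfolds
correlate ≈0.64 with each other, near zero with muscularity girths. Each
variable maps its athlete's standard-normal latent score through the
inverse CDF of a truncated normal whose location is solved (by root
finding) so the truncated mean equals the configured mean. This is
distributionally identical to resampling-to-bounds (never clipping, which
distorts means) and keeps group means exact under truncation; SDs shrink
slightly for heavily truncated variables, which is accepted.

Parameters the table does not print get documented defaults chosen once:
sex-specific bone breadth means (e.g. humerus 7.0/6.3 cm M/F, SDs 0.3–0.5
cm, consistent with the printed mesomorphy range); activity-diary day
counts of 3.5/3.5/5.0 d/wk (vigorous/moderate/walking, SD 1.5, rounded to
whole days as the instrument reports) with minutes/day means solved per
group so the implied MET-min/week mean equals the printed one; A-NSKQ items
as independent Bernoulli draws at the printed section percentages /100.
Within-group distributions are assumed normal (only M ± SD are published).

What the generator does *not* emulate: cross-domain covariances (e.g.
between adiposity and nutrition knowledge, so the published correlation
table is out of reach by design), item-level difficulty structure,
measurement error of repeated passes, or skewed anthropometric
distributions. Passing recovery tests therefore demonstrates pipeline
correctness, not distributional fidelity to real athletes.

Generation is bit-reproducible from (specs, seed) and leaves the caller's
RNG state untouched.

## Problem sizes and numerical choices

The test suite verifies parameter recovery at 5,000 athletes per group
(tolerance 2% relative on raw-variable means, 2 percentage points on
knowledge scores — comfortably above the ≈1.2% Monte-Carlo standard error
of the noisiest variables) and Type-I error calibration over 1,000 null
replicates at 15 per cell; both finish in well under two minutes on a
single core. Monte-Carlo normality p-values use 400 replicates by default
(resolution ≈0.0025, ample for a 0.05 gate). Ties in ranking are handled
by mid-ranks; degenerate inputs (constant samples, empty cells, singleton
groups, zero-variance variables) raise informative errors rather than
propagating NaN.

## Known limitations

* The shipped density/bone-mass equations are provisional stand-ins for
  the study's uncited formulas; %BF and bone-mass descriptive cells are
  not validated against the published table until those are confirmed.
* The ART implementation targets the 2×2 (sex × ranking) factorial the
  pipeline needs; higher-way designs are out of scope.
* Published dispersion values computed on raw data cannot be reproduced
  exactly from rounded printed means; bound checks are used instead.
* No multiple-testing control is applied across variables (matching the
  reconstructed protocol), and mixed/longitudinal models are out of scope.
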