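---
title: "Methods: scoring, central reading and reliability estimation in semacd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, central reading and reliability estimation in semacd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semacd)
```

## The indices

SEMA-CD grades two bowel regions on a 0–4 ordinal scale (0 endoscopic
remission, 4 severe disease): the terminal ileum, and the colon as a whole
graded by its most severe segment. The reader also ticks which of the four
colonic segments (ascending, transverse, descending, rectum) show any active
disease. The total is

$$\mathrm{SEMA\text{-}CD} \;=\; g_\mathrm{ileum} \;+\; g_\mathrm{colon}
\times k,\qquad k = \#\{\text{involved colonic segments}\},$$

which ranges 0–20. Two conventions matter at the edges. Ileocecal-valve
strictures are folded into the ileum grade upstream of the calculator, so
`sema_total()` needs no special case. A non-intubated ileum without stricture
is *not assessed*: the total is then the colon component alone, flagged
`partial = TRUE`, and the flag propagates into every downstream table. We
permit severity classification of partial totals (the alternative — dropping
such videos — discards information the reading workflow in fact produces),
but the flag keeps them auditable. Validation enforces the coupling
$g_\mathrm{colon} = 0 \iff k = 0$: a positive colon grade is by definition
the grade of the worst involved segment, so at least one segment must be
ticked, and a zero colon grade with ticked segments is contradictory.

The comparator SES-CD is taken as its usual concrete form: five segments
(ileum, right/transverse/left colon, rectum), four items each (ulcer size,
ulcerated surface, affected surface, narrowing; each 0–3), summed over
assessed segments with no renormalization for missing segments — no
renormalization rule is established for this index, and complete-case
handling downstream makes one unnecessary.

### Severity bands

The candidate SEMA-CD cutoffs are integer bands (0; 1; 2–4; 5–9; ≥10).
Final scores, however, are medians of two reads and can be half-integers, so
the bands are realized as half-open real intervals
$[0,1)$, $[1,2)$, $[2,5)$, $[5,10)$, $[10,20]$. On integers this reproduces
the printed partition exactly; on half-integers it is a total, deterministic
rule (for example 4.5 is mild, 9.5 moderate). SES-CD bands are the standard
integer partition 0–2 / 3–6 / 7–15 / ≥16.

## The central-reading workflow

Each video receives two blinded primary reads. Readers rotate over the
unordered pairs of the pool round-robin, so with 4 readers the 6 pairs are
loaded within one video of each other; the within-pair order is randomized.
The adjudication trigger is *strictly* more than 5 points of disagreement —
the margin is phrased as a maximum allowed difference, so a difference of
exactly 5 does not trigger. The final score is the median of available reads:
the mean of two concordant reads, or the middle order statistic of three,
which makes it robust to a single outlying read. Re-reads (round-half-up of
15% of videos, reassigned to one of the original readers with a gap of at
least 14 days; the generator draws 22–35 days) serve intra-rater analysis
only and never enter the final score. When one primary read is partial and
the other is not, the trigger compares the totals as recorded and a
data-quality warning is raised — comparing recorded totals is the only total
rule available without imputing the unassessed region.

## Reliability estimators

**Spearman correlation.** Average-rank ρ with a Fisher-z interval using the
Bonett–Wright standard error $\sqrt{(1+\rho^2/2)/(n-3)}$; the
Fieller–Hartley–Pearson $\sqrt{1.06/(n-3)}$ is available via
`se_method = "fieller"`. The interval degenerates to a point at $|\rho| = 1$
(the z transform is unbounded there). Fewer than 4 complete pairs, or a
constant vector, is an error rather than an `NA`: both indicate a degenerate
analysis the caller should see. ρ ≥ 0.6 is flagged as meeting the
pre-specified meaningfulness threshold.

**ICC.** Reader pairs rotate, so a crossed reader-by-video design does not
exist and the appropriate agreement model is one-way random effects with the
video as the only random effect: $\mathrm{ICC}(1) = \sigma^2_b/(\sigma^2_b +
\sigma^2_w)$, truncated at 0. On balanced data (every video the same number
of reads) the components come from the ANOVA method of moments and the
interval is the exact F interval; this is also the estimator the test suite
checks against independent mean-squares arithmetic. With adjudicated videos
carrying three reads the design is unbalanced: the point estimate is then
REML via `lme4::lmer`, and the interval applies the F form with the
Satterthwaite-style average group size $k_0 = (N - \sum k_i^2/N)/(n-1)$.
Bands: <0.50 poor, [0.50, 0.75) moderate, [0.75, 0.90] good, >0.90
excellent — the boundary 0.90 is assigned to "good" because the excellent
band is stated strictly ("greater than 0.90"), and the lower boundaries go to
the higher band as half-open intervals; the banding rule is recorded in the
report JSON.

**Weighted kappa.** $\kappa_w = 1 - \sum d_{ij} o_{ij} / \sum d_{ij}
e_{ij}$ with disagreement weights $d_{ij} = |i-j|/(k-1)$ (linear, default)
or its square (quadratic, by flag), computed on the severity bands of the
two primary reads of each video for each reader pair. Linear weights are the
default because the severity scale's steps are not equally spaced in any
quantitative sense — quadratic weights would reward distant disagreements
disproportionately. The variance is the Fleiss–Cohen–Everitt large-sample
form, which yields the 95% interval. With two categories and linear weights
the statistic reduces to unweighted Cohen kappa (a closed-form identity the
tests verify). Both raters constant at one category makes expected agreement
1 and kappa undefined: an error. Bands: <0.41 below moderate, 0.41–0.60
moderate, 0.61–0.80 good, >0.80 very good.

**Pooling.** Stratum-level mean differences (strata = reader pairs for
inter-rater, readers for intra-rater; sign = first-listed minus second-listed
in the fixed order) are pooled by inverse variance, $w_i = 1/\widehat{\mathrm
{var}}(\bar d_i)$, with a normal interval from $1/\sum w_i$. Pairwise kappas
are pooled the same way — the pooling method for kappas is not canonical, and
mirroring the mean-difference pooling keeps one rule throughout. A stratum
with fewer than 2 observations has no estimable variance and is dropped with
a warning. A zero-variance stratum (identical differences, or a perfect-
agreement reader pair) would carry infinite weight; the pooled estimate then
collapses to those strata, which is the limit of the weighting rule — small
studies can hit this, and the print output makes it visible.

Missing data are never imputed: every analysis is complete-case, and no
multiplicity adjustment is applied (the report is descriptive).

## The synthetic-study generator

The generator emulates the *layout and statistical structure* of a
two-cohort central-reading validation study, not any real patient data.

- **Latent severity.** Each patient has a scalar latent severity
  $\theta_\mathrm{pre}$; each of the 5 segments has a persistent
  patient-segment offset $\delta_{ps} \sim N(0, 0.7^2)$ creating ileum-only /
  colon-only involvement patterns, plus draw-level jitter $N(0, 0.5^2)$. A
  segment's grade is the number of fixed thresholds $\{1,2,3,4\}$ exceeded by
  $\theta + \delta_{ps} + \varepsilon$. The baseline severity band is drawn
  from the configured mix (default 4.5 / 19.1 / 40.9 / 35.5% over the SES-CD
  bands, the marginal a moderate-to-severe trial population produces) and the
  realized SES-CD band is matched to it by rejection sampling of $\theta$
  (up to 60 tries; the last draw is kept on failure, so the marginal is
  matched approximately, not enforced exactly).
- **Treatment.** $\theta_\mathrm{post} = \theta_\mathrm{pre} - \Delta$,
  $\Delta \sim N(0.8, 0.6^2)$ truncated so $\theta_\mathrm{post} \ge -1$;
  0.8 latent units produces score improvements of the order seen in effective
  biologic treatment, and `treatment_effect = 0` gives an exact null for
  sensitivity-to-change testing.
- **SES-CD items** derive from the segment grade by a fixed monotone table
  (`SES_ITEM_MAP`): grades 0–4 map to item vectors summing to 0, 2, 6, 10,
  12, reaching maximal ulcer size and a non-passable stricture at grade 4.
  No such mapping is canonical; the table is the simplest monotone one
  consistent with the grade descriptions, and it is exported so analyses can
  inspect it.
- **Reader noise** is region-level (readers record region grades, not
  segment findings): a region grade is reproduced exactly with probability
  `p_exact` (default 0.8 for all readers, a plausible exactness for trained
  central readers), else moved one step with direction bias `bias`
  (default 0), clipped to 0–4. The colon's one-step shift applies to every
  involved segment's implied grade; involvement flags follow (flagged iff the
  perturbed implied grade is positive), and a reader upgrading a disease-free
  colon flags one random segment. A not-assessed ileum is never perturbed.
- **Ancillary labels.** Ileum non-intubation 2% of videos; video quality
  i.i.d. optimal with probability 0.482; usability ratings drawn per reading
  from a fixed 7-point distribution concentrated on "easier".

Everything is driven by one mandatory seed; identical seeds give
byte-identical CSV and JSON outputs.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: visual reading of videos (noise is a one-step
ordinal kernel, not perceptual error, and carries no video-quality or
fatigue dependence); correlation between the two indices' *errors* (the
comparator SES-CD is taken noiseless, as the trials' previously-completed
central reads); cohort physiology beyond the label; and any calibration to
the real trials' joint score distribution, which is not publicly available.
Structural correlations between SEMA-CD and SES-CD are therefore higher on
synthetic data than a real study would report.

## Problem sizes used by the test suite

The suite checks estimators against independent oracles at sizes chosen to
make Monte-Carlo error negligible relative to the asserted tolerances:
exhaustive enumeration of all valid rating states; 1,000 random contingency
tables for kappa; a 2,000-video study (1,000 patients) for recovery of the
noise-model-implied ICC within ±0.05 of a 40,000-draw simulation oracle;
100,000 paired draws for the adjudication-rate law (agreement within 3
combined standard errors); and 500 replicates at n = 60 pairs (Spearman,
bivariate normal truth $\rho_s = (6/\pi)\arcsin(r/2)$) and 30×2 scores
(ICC, known variance components) for ≥90% empirical coverage of the nominal
95% intervals — the 5-point slack documents small-sample approximation error
of the Fisher-z and F intervals.

## Known limitations

- The one-way ICC attributes all reader effects to the residual; systematic
  reader bias inflates $\sigma^2_w$ rather than appearing as a reader
  variance component. That matches the rotating-pair design but understates
  agreement decompositions a crossed design would support.
- The unbalanced-case ICC interval is an approximation (Satterthwaite-style
  $k_0$); its coverage is checked only in the balanced design.
- Pooled kappa inherits the limitations of inverse-variance pooling of
  bounded statistics: with perfect-agreement pairs (variance 0) it collapses
  to those pairs.
- The generator's rejection step targets the *baseline* band marginal only;
  post-treatment severity is whatever the latent shift induces.

```{r example}
rep <- run_study(study_config(seed = 1))
summary(rep)
```
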