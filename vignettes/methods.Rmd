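---
title: "Methods: models, parameters and design choices in episelect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in episelect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Epigenetic breeding schemes diversify a genetically isogenic crop population
(here, sorghum in a single inbred background) and then ask whether the induced
heritable variation can be captured by ordinary selection. `episelect`
implements the analysis chain such an experiment needs:

1. **Two-level percentile classification.** Families ("lines") from a
   single-plant trial are classed Low/Medium/High against the 30th and 70th
   percentiles of wild-type per-plant grain yield; each individual plant is
   classed with the same cutoffs; the cross of the two gives nine categories
   (`LL.LI` … `HL.HI`).
2. **Strategy evaluation.** In the next-generation multi-location plot trial,
   three retroactive strategies — unselected, line-mean groups, line-mean ×
   individual categories — are compared against wild-type checks by
   mixed-model least-squares means.
3. **GxE resilience.** Per-line percent yield differential between the
   favorable and the stress (low-nitrogen) location, with a
   stable / intermediate / dynamic classification.
4. **Cold-stress emergence.** Early-planting emergence normalized by the
   standard planting, integrated into the area under the plant emergence
   curve (AUPEC).
5. **Genome-stability control.** Reversion frequencies of an unstable
   dwarfing allele, compared between cohorts with Fisher's exact test.

A synthetic generator produces trials with exactly the statistical structure
this chain assumes, so every stage is testable without external data.

## Models and estimation

The trial model is the standard augmented-design analysis

$$y_{ij} = \mu + g_i + b_j + e_{ij},$$

with genotype $g_i$ fixed, incomplete block $b_j \sim N(0, \sigma_b^2)$
random, and $e_{ij} \sim N(0, \sigma_e^2)$, fitted by REML (`lme4`). All
wild-type checks are pooled into one reference genotype level, so the fixed
coefficients are line-vs-WT differences and the LS-means marginalize over
blocks. Tiller counts use a Poisson model with log link, days to flowering a
Gamma model; the Gamma link is not dictated by the field's conventions, and we
use the log link for positivity and comparability with the Poisson fit.
Generalized fits use `nAGQ = 0` (fixed effects estimated inside PIRLS):
with ~100 genotype levels the outer Laplace optimization is infeasible and
adds nothing at this design size. Contrast p-values are Wald with a normal
reference — residual degrees of freedom in these designs are in the hundreds,
where t and z are indistinguishable; the type-I calibration test keeps this
honest. No multiplicity correction is applied by default (raw pairwise
reporting is the convention being mirrored); `adjust = "BH"` is available.

Fisher's exact test uses the two-sided point-probability convention: the
p-value sums all hypergeometric tables (at the observed margins) whose
probability does not exceed the observed one, with a `1 + 1e-7` relative
guard against floating-point ties — the same convention as
`stats::fisher.test`, which the test suite uses as an independent oracle.

Plot yields are standardized to kg/ha at 140 g/kg grain moisture by the
dry-matter-preserving rescale
$y = w \cdot \frac{1000 - m}{1000 - 140} \cdot \frac{10000}{A}$
for raw plot weight $w$ (kg), moisture $m$ (g/kg) and plot area $A$ (m²).

## Classification conventions

* Percentiles default to linear interpolation of order statistics
  (`stats::quantile` type 7). Published cutoffs rarely state a convention, so
  the type is exposed; when reproducing published numbers the cutoffs
  (58 g, 80 g) are taken as given via `yield_cutoffs()`.
* Boundary semantics are exactly the printed inequalities: Low `< p30`,
  Medium `p30 ≤ y ≤ p70` (both cutoffs inclusive), High `> p70`.
* Reported percentages (percent increase, yield differential, reversion
  frequency) are rounded half-up at the conventional printed precision (one
  decimal for percents, two for reversion frequencies); full precision is
  available with `digits = NULL`.
* Percent gains reproduced from printed group means use raw arithmetic —
  6,565 vs 5,999 gives 9.4% and 2,846 vs 2,335 gives 21.9% only under raw
  arithmetic, so that is what the reproduction targets use; full analyses of
  plot data default to LS-means with a `mode = "raw"` fallback.

## Resilience thresholds

The yield differential is $100 (y_\mathrm{normal} - y_\mathrm{low}) /
y_\mathrm{normal}$. Stable means differential `< 30%`, dynamic `> 70%`,
intermediate otherwise. The source material is internally inconsistent about
the dynamic cutoff (a figure legend says `>30%`, the body text `>70%`); the
count of dynamic lines reported there is consistent only with the high
cutoff, so 70 is the default and both thresholds are plain arguments.
Negative differentials (stress yield above normal) are retained and classed
stable.

## Emergence analysis

"Early emergence divided by standard emergence" is ambiguous between a
daywise ratio and a fixed denominator. The default divides every early count
by the standard planting's **final** (maximum) count: the standard planting's
role is to control for per-line seed quality, which is a single per-line
denominator; the daywise mode is available (`mode = "daywise"`). Adjusted
values above 1 are kept, not clipped. AUPEC is the trapezoid rule
$\sum_n \frac{PE_n + PE_{n+1}}{2}(Y_{n+1} - Y_n)$ — the printed formula drops
the brackets around the day difference, but the AUDPC analogy and the
formula's intent dictate the standard trapezoid sum. The "emergence rate" has
no published formula; we use the least-squares slope of adjusted emergence
against day over the recorded window and document it as a stand-in.
Multi-season data are averaged as a plain mean of per-season AUPEC per line.

## The synthetic generator: what it emulates and what it does not

The generator is purely phenotypic/statistical; it models no methylation or
gene-regulatory mechanism.

**Stated world (defaults).** The single-plant trial has 100 epi families × 3
replications × 15 measured plants, wild-type checks inserted in every
incomplete block (10 epi entries + 1 check), per-plant wild-type yield
centred at 69 g with s.d. ≈ 21 g so the 30th/70th percentiles fall near the
58/80 g cutoffs. The plot trial has 150 epi + 19 wild-type lines in 13-entry
incomplete blocks (a 13 × 13 lattice at default counts), 3 replications at
the normal-input location (WT mean 5,999 kg/ha) and 2 at the low-nitrogen
one (WT mean 2,335 kg/ha). The emergence grid is the 13 recorded days 13–46
after planting.

**Epi effects** are a line-level three-component mixture (up / null / down),
constant across a line's plants, skewed upward — defaults 9% up (+11 g) and
4% down (−9 g), the asymmetry that the yield trait shows at these trial
sizes. With the per-line s.e. of ≈3 g implied by the design, these defaults
make roughly the published counts of lines detectably higher/lower; the
exact counts are sampling-variable and are checked only qualitatively
(more up than down).

**Tiller–yield correlation** is induced by a Gaussian copula: the plant's
standardized total yield deviation drives a latent normal that is mapped
through the Poisson quantile function (mean 2 tillers). The latent
correlation is inflated by the analytically computed discretization
attenuation so the *realised* count–yield correlation matches the target
(default 0.52). The published correlation does not say whether it is plant-
or line-level; we default to plant-level, and the calibration invariant
(±0.05 at ≥4,500 plants) is tested at that level.

**GxE** is a per-line multiplicative sensitivity applied in the low-input
environment only: $y = m_e \, s_\ell \,(1 + \beta_{c(\ell), e}) + d_\ell + b + e$
with $s_\ell = 1 + \gamma u_\ell$, $u_\ell \sim N(0,1)$, $\gamma$ =
`gxe_scale` (default 0.15), because per-line slopes between environments are
the phenomenon of interest. Wild-type lines have $s_\ell = 1$ and no
category effect, so their generating differential is exactly the ratio of
the environment means (61.1% at the default means). Category effects
$\beta$ are proportional shifts relative to the environment wild-type mean.

**Not emulated:** spatial field trends within blocks, yield–moisture
correlation, inter-plant competition, seed-quality/emergence carryover into
yield, and any multi-generation epiallele dynamics. A green recovery test
therefore establishes that the estimators recover effects *under the assumed
model*, not that the model captures every feature of real field data.

**Determinism.** One root seed; every operation draws from its own derived
sub-stream (a fixed affine map into the 32-bit seed space) and restores the
caller's RNG state, so outputs are byte-identical across calls and adding a
stage never perturbs another.

## Numerical and testing choices

* Degenerate variances short-circuit to exact structural means (`rnorm` with
  `sd = 0` is exact), which the tests assert with `==`.
* The Fisher acceptance sweep is exhaustive for all tables with total ≤ 30
  plus 1,500 random tables with totals up to 200; the full ≤ 200 sweep is
  ~1.4M oracle calls and exceeds a one-CPU test budget.
* The variance-recovery acceptance test builds its 95% intervals from the
  across-replicate spread of the REML estimates rather than `lme4` profile
  CIs: the profile interval for the residual s.d. is computed on the
  deviance scale and sits systematically below the REML value when the
  fixed-effect count is large, which would fail coverage for reasons
  unrelated to recovery. It runs at a reduced design (50 lines × 3 reps × 3
  plants, 15 blocks) for budget.
* Type-I calibration runs 10 paper-scale null trials (1,000 null contrasts)
  and requires the false-positive rate to sit in the 95% binomial interval
  around α = 0.05.

## Known limitations

* Wald (normal) contrast p-values are mildly liberal in small designs; use
  larger designs or treat borderline p-values with care.
* `line_category_map()` collapses a family's plants to one category by the
  modal individual class (ties toward the higher class); a real breeding
  program would instead track which selected individual seeded each F3 line,
  information a retrospective table does not carry.
* The Gamma model for days-to-flowering can fail to converge on degenerate
  data; the fit is then flagged (`converged = FALSE`) and falls back to a
  fixed-effects GLM rather than failing silently.
* Published group-level gains that depend on unpublished underlying means
  (e.g. the strongest category's gains) are reproduced only qualitatively on
  synthetic data, via injected-effect recovery tests.
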