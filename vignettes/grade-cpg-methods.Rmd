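---
title: "Calling grade-associated methylation drift in paired cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling grade-associated methylation drift in paired cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methdrift)
```

## The problem and the model

Atherosclerotic lesions are graded histologically (AHA grades III–VII).
Within one donor, the methylation difference between a lesioned (A) and a
normal (N) aortic segment removes between-donor variation, and the question
becomes whether that intra-pair difference *drifts* with lesion grade: an
epigenetic signature of progression rather than of mere presence of
disease.

`methdrift` screens each probe of a paired Beta matrix in three stages.
Beta values are first moved to the M scale, $M = \log_2\!\big(\beta/(1 -
\beta)\big)$, with a symmetric clamp at `epsilon_clip` (default $10^{-6}$)
so boundary Betas stay finite. The M scale is approximately
variance-stabilised across the methylation range, which is why all testing
happens there; effect sizes are reported as ΔBeta because methylation
fractions are what practitioners read.

A probe is a **grade-CpG** when all of the following hold
(`analysis_config()` collects the thresholds):

1. *Effect size.* The absolute difference between the mean intra-pair
   ΔBeta of the grade-VII donors and of the grade-III donors strictly
   exceeds `effect_delta_beta` (default 0.05). The strict inequality
   matters at the boundary: an effect of exactly 0.05 fails.
2. *Correlation with grade, not with nuisance covariates.* Tie-corrected
   (mid-rank) Spearman correlation of ΔM against numeric grade 3–7 must
   reach p < `alpha` (default 0.05), while the same rank correlation
   against donor age, sex (coded M = 0, F = 1) and post-mortem time must
   not. The call is then corroborated by a least-squares fit
   ΔM ~ grade + age + sex + post-mortem time with grade categorical; the
   partial F-test for the grade term must also reach p < `alpha`.
3. *Baseline stability.* A Welch two-sample t-test must find no
   significant difference between the N-sample M values of grade-VII and
   grade-III donors. This rejects probes whose apparent drift is an
   artefact of the reference tissue itself changing with grade.

Direction is `hyper` when ρ > 0. Because a 15-pair screen cannot reach
array-wide Bonferroni significance, the Bonferroni threshold
(`bonferroni_base_alpha / n_tested`) and the number of probes below it are
reported rather than used as a filter.

### Numerical and inferential choices

* **Spearman p-values** are two-sided. With at most 9 donors and tie-free
  differences the exact permutation distribution is enumerated; otherwise
  the t approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ degrees
  of freedom is used. Grades are heavily tied (nine donors share grade
  VII), which mid-ranks handle; a constant difference vector has undefined
  correlation and is recorded as ρ = NA, p = 1, never called.
* **Constant covariates** (e.g. a single-sex cohort) make the covariate
  screen undefined for that covariate; it is recorded as p = 1 with a
  warning rather than failing every probe.
* **The adjusted ANOVA** treats grade as a factor by default; a numeric
  trend alternative sits behind `grade_as_factor = FALSE`. The factor
  reading is the stricter one (it spends 4 df) and matches how a
  severity scale with non-linear steps should enter an adjustment model.
  Rank-deficient designs and designs without residual degrees of freedom
  are refused with a diagnostic instead of returning an unstable fit.
* **Stability with tiny groups.** When an extreme-grade group has fewer
  than two N samples the Welch test is undefined; the criterion is
  recorded as an indeterminate pass with a warning, because a cohort that
  thin cannot witness instability either way.
* **Noiseless degeneracies.** With zero residual variance the partial F
  statistic is 0/0 for flat probes (p = 1) and ∞ for perfectly fitting
  ones (p = 0); both paths are handled explicitly, which is what makes the
  noiseless-limit recovery exact.
* **Criterion order** is cheap-first internally, but the decision is a
  pure conjunction, so ordering cannot change any call.

## What the synthetic cohort emulates

`generator_config()` defaults define the study conditions: 15 donor pairs
with grade composition III:2, IV:2, V:1, VI:1, VII:9, and 10,000 probes of
which 100 hypermethylate and 100 hypomethylate with grade at a ΔBeta
amplitude of 0.15 (at grade VII), next to 200 constant-offset
differentially methylated probes (ΔBeta 0.10), 100 probes confounded with
each of age, sex and post-mortem time, 100 baseline-unstable probes and 50
blacklisted probes carrying drift. Noise is Normal on the M scale with
sd 0.17 per sample (≈ 0.03 Beta near β = 0.5, a typical 450k technical
scale). Where donor counts per grade were not fully determined by the
15-pair, nine-grade-VII design, the 2/2/1/1 split across III–VI is an
assumption exposed in the config.

Generator mechanics, per probe $j$ and donor $d$ with grade $g_d$:

$$N = \mu_j + u_j\,(g_d-3)/4 + \varepsilon,\qquad
  A = N + \delta_j(d) + \varepsilon'$$

with $\varepsilon,\varepsilon' \sim \mathcal N(0, \texttt{noise\_sd\_m})$,
$u_j$ nonzero only for the unstable class, and $\delta_j(d)$ the planted
intra-pair shift: linear in grade for drift probes (scaled on the M scale
so the noiseless ΔBeta at grade VII is exactly ±0.15), constant for
dm-probes, and proportional to the standardised covariate (same M-scale
amplitude as grade drift, so the covariate screen's job is nontrivial) for
confound probes. Betas are emitted through the inverse logit, hence always
inside (0, 1). Drift is linear in numeric grade on the M scale — the
simplest generative form a rank-correlation screen should recover, since
the screen itself only assumes monotonicity.

Three deliberate design choices:

* **Covariates are drawn orthogonal to grade.** Age, sex and post-mortem
  time are redrawn until none shows even marginal rank correlation with
  grade (p ≥ 0.25). In a random 15-donor draw, roughly one cohort in
  seven would carry an accidental covariate–grade correlation strong
  enough to covariate-screen out *every* planted probe, which would make
  the noiseless limit ill-posed. Confounding is therefore planted
  explicitly at probe level, where it is measurable against truth.
* **Planted-effect probes take mid-range baselines** (β₀ ∈ 0.35–0.65) so
  a ±0.15 displacement stays inside (0, 1); null probes follow a
  trimodal mixture with modes near 0, 0.5 and 1, emulating the
  array-typical Beta distribution.
* **The unstable-N shift is 2.5 M units** (≈ 0.35 Beta mid-range) between
  grades III and VII. The stability screen compares 2 against 9 N
  samples, so its Welch degrees of freedom sit near 1.5 and its detection
  limit is high; this class models reference-tissue instability the
  criterion exists to exclude, so its coupling is set well beyond that
  limit (~95% per-probe rejection), not at the edge of it.

What the generator does **not** emulate: Infinium I/II probe-chemistry
bias, spatial/LD correlation between probes, batch effects, cellular
heterogeneity, or realistic gene multiplicity (each synthetic probe maps
to at most one gene). Passing recovery tests therefore demonstrates the
decision rule's operating characteristics under clean paired drift, not
performance on raw array data, which additionally needs normalisation and
quality control upstream.

Expression integration is simulated by giving each gene with a planted
promoter drift probe a log₂ fold change of `coupling_slope` × direction
plus Normal noise (default slope −1, sd 0.3), with mouse-style symbols so
the case-insensitive ortholog matching is exercised; WGBS validation data
reproduce one grade-VII donor's array ΔBeta at promoter drift probes plus
noise (sd 0.02, a single-genome bisulfite scale).

## Downstream analyses

*Genomic context.* Multi-valued gene annotation collapses to one
compartment per probe: any TSS200/TSS1500 entry wins (Promoter), then
5′UTR > first exon > body > 3′UTR; no entry means intergenic. Distribution
against the array background uses the Pearson goodness-of-fit chi-square
with zero-expected categories pooled into the smallest represented one so
the statistic stays defined. Direction contrasts use the 2×2 Pearson
chi-square without continuity correction. Baseline strata follow the
printed rule exactly — High strictly above 0.75, Low strictly below 0.25,
boundaries Intermediate. Gene-set overlap uses the upper-tail
hypergeometric test with the universe size an explicit argument, because
the appropriate universe (array genes versus genome) is a judgement the
caller must make. SNP proximity is an inclusive ±250 kb same-chromosome
window with no liftover.

*Clustering.* `ward_bicluster()` clusters probes and donors independently
on the called ΔBeta matrix (Euclidean distance, `ward.D2`). ΔBeta rather
than raw Beta or M: intra-pair differences are already donor-centred and
of comparable scale, so no additional scaling is applied. The 2-cluster
donor cut is the low/high-grade readout; on the default recovery
simulation it separates grade-III/IV from grade-VI/VII donors perfectly,
with the single grade-V donor joining the high-grade block.

*Integration.* Expression tables are filtered at a strict >2-fold change;
orthologs match by case-folded symbol equality (sufficient for
symbol-level lists; a curated homology table can replace the mapping
tibble); probes mapping to two or more filtered genes are excluded rather
than duplicated so correlation pairs stay independent, and groups under
n = 3 report NA. The per-compartment Pearson correlation pairs each
probe's grade-ρ with its gene's log₂ fold change; grouping by CGI relation
is available through the same interface, so open-sea correlations can be
computed with or without promoter-overlapping probes by pre-filtering the
record table.

## Problem sizes and what the checks show

The package's own acceptance run (`scripts/acceptance.R`) uses 10,000-probe
cohorts for recovery and the noiseless limit, a 5,000-probe all-null cohort
for type-I calibration, 100 regenerated expression tables (23 promoter
pairs each) for the integration property, and exhaustive small-vector
enumeration for the rank-statistic oracles. At these sizes the whole run
completes in well under a minute, and the quantities are stable to within a
few percent across seeds. The known limitations are those of the
generator listed above, plus: the covariate screen tests covariates
marginally (one at a time), the Welch stability criterion is
low-powered for thin extreme-grade groups by construction, and
Bonferroni reporting is the only multiplicity treatment — FDR control is
deliberately out of scope for a screen defined by fixed per-test
thresholds.
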