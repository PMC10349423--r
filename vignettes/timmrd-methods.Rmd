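---
title: "Tumor-informed methylation MRD scoring: model, estimation and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumor-informed methylation MRD scoring: model, estimation and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timmrd)
```

## The problem

After curative-intent resection of a solid tumor, a fraction of patients
harbor minimal residual disease (MRD) below the detection limit of imaging.
Circulating tumor DNA (ctDNA) in plasma offers a molecular readout, but at
low burden a single-locus mutation assay runs out of informative fragments:
at an allele fraction of 0.05% and roughly 10^4 genome equivalents of
cell-free DNA per draw, only a handful of mutant fragments exist per tracked
locus. Methylation offers a way out: a targeted bisulfite panel measures
thousands of CpG blocks simultaneously, and tumors carry broad, patient-
observable hypermethylation. Pooling faint signal across hundreds of
patient-specific differentially methylated blocks (DMBs) buys back the
sensitivity a per-locus assay lacks.

`timmrd` implements a tumor-informed scoring pipeline on this idea: the
patient's own tumor and matched adjacent-normal tissue define the markers,
healthy-donor plasma defines the background, and each plasma sample is
reduced to an estimated ctDNA fraction and a decision statistic.

## The model

For plasma sample $i$ and block $j$, let $N_{ij}$ be the number of CpG
observations and $M_{ij}$ the number read as methylated. Conditional on a
block-level methylation probability $\beta_{ij}$,

$$M_{ij} \mid N_{ij}, \beta_{ij} \sim \mathrm{Binomial}(N_{ij}, \beta_{ij}).$$

Plasma cfDNA is a mixture of tumor-derived, adjacent-normal-derived and
background (largely hematopoietic) DNA, so the methylation probability
deconvolves as

$$\beta_{ij} = \alpha_i\,\beta_{ij}^{(T)} + \gamma_i\,\beta_{ij}^{(N)} +
  (1 - \alpha_i - \gamma_i)\,\beta_{ij}^{(0)},$$

with $\alpha_i \ge 0$ the ctDNA fraction (the malignancy-density ratio),
$\gamma_i \ge 0$ the adjacent-normal fraction, $\alpha_i + \gamma_i < 1$,
tissue levels $\beta^{(T)}, \beta^{(N)}$ measured from the patient's
resected tissue, and the background level a latent draw
$\beta_{ij}^{(0)} \sim \mathrm{Beta}(p_j, q_j)$ with shapes fitted per block
from healthy-donor plasma. Marginalizing the latent background gives the
per-block likelihood

$$\ell_{ij}(\alpha_i, \gamma_i) = \int_0^1
  \binom{N_{ij}}{M_{ij}} \beta_{ij}^{M_{ij}} (1-\beta_{ij})^{N_{ij}-M_{ij}}
  \, g(\beta^{(0)}; p_j, q_j)\, d\beta^{(0)},$$

and the sample log-likelihood sums $\log \ell_{ij}$ over the $m$ selected
DMBs. We integrate over $\beta^{(0)}$ directly, which carries the
change-of-variables Jacobian $1/(1-\alpha-\gamma)$ implicitly; this makes
each block marginal a normalized pmf in $M_{ij}$ (the package tests assert
$\sum_M \ell_{ij} = 1$), and at $\alpha = \gamma = 0$ the marginal collapses
to the closed-form beta-binomial.

$(\hat\alpha, \hat\gamma)$ is the constrained MLE; the **timMRD-score** is
the Wald statistic $\hat\alpha^2 / \widehat{\mathrm{var}}(\hat\alpha)$ for
the null hypothesis $\alpha = 0$, compared against a $\chi^2_1$ quantile.
The default threshold is the 98th percentile, 5.412; a sample scoring
strictly above it is called **timMRD-high**. Stricter cutoffs (99.95th,
99.99th percentile) trade sensitivity for specificity and are exposed
through `scoring_options(percentile = ...)`.

## Numerical design

**Quadrature.** The block marginal integrates a binomial pmf against a beta
density whose shapes routinely fall below 1 (background methylation in a
hypermethylation panel is near zero, so $p_j < 1$ is common), making the
integrand unbounded at the endpoints. Rules with a flat weight converge
only algebraically there, so the package uses Gauss–Jacobi quadrature with
the weight $x^{p-1}(1-x)^{q-1}$ itself (Golub–Welsch on the Jacobi
recurrence). The remaining integrand is a polynomial of degree $N_{ij}$ in
$\beta^{(0)}$, so an $n$-node rule is *exact* whenever
$N_{ij} \le 2n - 1$. The base order is 128 (covering depths to 255); for
deeper blocks the order is raised to $\lceil (N+1)/2 \rceil$, rounded up to
a multiple of 64 for cache reuse and capped at 512 (exact to depth 1023,
which covers every depth model used here). Blocks are grouped by order so a
few deep blocks do not inflate the cost of the whole panel, and rules are
memoized per $(n, p, q)$. Accumulation is in log space with a row-wise
log-sum-exp.

**Optimization.** The likelihood is maximized over
$\{\alpha \ge 0,\ \gamma \ge 0,\ \alpha + \gamma \le 1 - 10^{-6}\}$ after
reparameterizing $\gamma = v\,(1 - 10^{-6} - \alpha)$, $v \in [0, 1]$, which
turns the simplex into a box for L-BFGS-B with an analytic gradient. The
start grid $\{0, 10^{-3}, 10^{-2}\} \times \{0, 0.05, 0.2\}$ is screened by
log-likelihood and the optimizer is polished from the best three starts;
the profiled null solution $(0, \hat\gamma_0)$ is always polished too, which
both guards against the multi-modality that can arise when
$\beta^{(N)} \approx \beta^{(T)}$ and guarantees
$\hat\ell_{\mathrm{full}} \ge \hat\ell_{\mathrm{null}}$ by construction.
Everything is deterministic: no randomness enters the fit.

**Wald variance.** The variance of $\hat\alpha$ is the $(\alpha,\alpha)$
entry of the inverse observed information, from a central-difference Hessian
(base step $10^{-4}$, shrunk to stay inside the constraints). When
$\hat\gamma$ sits on its boundary — the typical case — the nuisance
direction is inactive and the slice curvature in $\alpha$ is used; if the
information matrix is indefinite the estimator falls back to the curvature
of the $\alpha$ profile likelihood. Estimates with
$\hat\alpha \le 10^{-8}$ are on the null boundary and score exactly 0.

**Null distribution caveat.** Under $\alpha = 0$ the parameter lies on the
boundary of its space, so the score's null law is a mixture of a point mass
at zero and (approximately) $\chi^2_1$, not plain $\chi^2_1$. Thresholding
at the $\chi^2_1$ quantile is therefore conservative: the realized
false-positive rate at the 0.98 threshold runs at or below the nominal 2%.
The package keeps the $\chi^2_1$ convention for thresholds and documents the
conservatism rather than re-calibrating.

## Background prior and marker selection

Per block, the beta shapes are fitted by the method of moments from
healthy-plasma ratios $M/N$ (samples with depth $\ge$ `min_depth`):
$c = \bar m(1-\bar m)/v - 1$, $p = \bar m c$, $q = (1-\bar m)c$. Moments
were chosen over beta MLE because they are closed-form, deterministic and
entirely adequate for a prior; ratios exactly 0 or 1 are clipped inward by
$10^{-4}$, and degenerate blocks (variance $\le 10^{-8}$, or $c \le 0$, or
fewer than two usable samples) fall back to a pseudocount fit
$p = \bar m c_0 + \varepsilon$ with $c_0 = 100$, $\varepsilon = 0.5$ —
without the fallback an all-zero block would imply infinite concentration.

Cohort-level DMB discovery (`discover_cohort_dmbs`) uses a paired two-tailed
Wilcoxon signed-rank test per block with Benjamini–Hochberg correction
across blocks, an absolute effect floor (default 0.1) and a q-value ceiling
(default 0.05). Patient-specific selection (`select_patient_dmbs`) keeps
blocks whose tumor level exceeds the prior mean by `delta_prior` (default
0.2) and the matched normal by `delta_normal` (default 0.1), with prior
concentration $p+q \ge 10$ so the background is stably characterized; blocks
are ranked by tumor-minus-prior-mean margin with lexicographic tie-breaks
for full determinism, and truncated to `m_max` (default 5000).
Hypermethylation is the default direction — that is where the mixture
signal separates from a near-zero background — with a `direction = "hypo"`
switch. These margins are explicit, configurable reconstructions of
tumor-informed selection logic; they are the package's own operating
definitions rather than a published recipe.

## What the synthetic cohort emulates — and what it does not

The generator (`simulation_spec`, `longitudinal_spec`) produces data from
exactly the generative model the scorer assumes: per-block
$\mathrm{Beta}(p_j, q_j)$ background (shapes drawn uniformly from
$p \in [0.4, 2]$, $q \in [40, 150]$, i.e. background means of roughly
0.5–3% at concentrations well above the selection floor), planted
tumor-hypermethylated blocks at levels 0.6–0.9, negative-binomial depths
(mean 200, size 10, mimicking variable cfDNA input), and binomial read
sampling. Replicates of a dilution series share background and depth draws
across fractions (common random numbers), which couples power curves across
the fraction grid and sharpens monotonicity comparisons without changing
any marginal distribution.

The longitudinal cohort draws 200 patients, 25% of whom relapse between day
240 and 540 — enriched relative to typical resected-cohort relapse rates so
that surveillance metrics rest on a usable number of events. Sampling
follows the perioperative scheme (baseline day −1, day 3, day 36, then
follow-up every 60 days to day 540). Cured patients drop to $\alpha = 0$
after resection; relapsing patients clear their baseline fraction with a
1-day half-life and re-grow exponentially to $\alpha = 0.03$ on the relapse
day, with a time constant set so the fraction crosses the panel's
detectability range about one drawn lead time — $N(250, 60)$ days,
truncated at 30 — before relapse, consistent with methylation lead times of
several months reported for this class of assay. Patient panels carry 300
planted DMBs (mid-range for a tumor-informed design tracking hundreds of
markers). The mutation assay is emulated as maxAF $\approx \alpha/2$
(clonal heterozygous variant) with lognormal noise on the logit scale,
Poisson read sampling at an effective unique depth of 800 (about what
10–30 ng of cfDNA supports after deduplication), a 2-read calling minimum
and a 0.05% reporting floor — the standard reasons a per-locus assay loses
sensitivity at low burden.

Because simulator and scorer share the generative model, passing tests
demonstrate *internal* correctness — estimator consistency, calibration,
monotone power, correct bookkeeping — not robustness to the ways real data
deviate: batch effects between healthy cohort and patients, incomplete
bisulfite conversion, copy-number-driven depth structure, clonal
hematopoiesis, or mis-specified tissue levels from impure tumor samples.
Cohort-level clinical endpoints reported for real cohorts (hazard ratios,
AUCs, predictive values) depend on restricted patient data and are treated
as directional properties on synthetic data here, not as reproduction
targets.

## Problem sizes used by the test suite and acceptance script

Simulation scales were fixed once, as desk-scale stand-ins for the assay
(panels of 8312 blocks are emulated by 200–1000-block panels): grid-oracle
cross-checks use 20-block panels at grid step 0.005; parameter recovery
uses $m = 500$ DMBs at depth 200 with 100 replicates per fraction; null
calibration uses 500 background-only replicates on a 200-block panel; the
dilution grid spans tumor fractions $10^{-1}$ to $2\times10^{-4}$ and 0 at
depth 200 with 20 coupled replicates each, plus a focused high-depth arm
(depth 900, tight priors, fractions $2\times10^{-4}$ vs 0) probing the
limit-of-detection regime; the surveillance cohort is the 200-patient
design above, evaluated at a 120-day horizon. `scripts/acceptance.R`
re-runs the same experiments at reduced replicate counts (reported in its
output as `n`) and derives every number it writes from a fresh computation
under the supplied seed.

## Known limitations

* The Wald score is reported, not a likelihood-ratio statistic; the two
  agree asymptotically (the suite checks ~5% agreement at $\alpha = 0.05$)
  but diverge at very small effects, where the Wald statistic is the more
  conservative of the two here.
* $\gamma$ is weakly identified when the adjacent-normal profile resembles
  the background; the fit handles this by construction (the score concerns
  $\alpha$ only), but $\hat\gamma$ itself should not be over-interpreted.
* The beta background is the only noise model; overdispersion beyond
  beta-binomial (e.g. positional error modes) is not represented.
* Survival modelling is intentionally out of scope: `export_survival_table`
  hands per-patient `(dfs_days, event, group)` rows to standard survival
  tooling.
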