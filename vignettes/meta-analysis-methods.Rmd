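---
title: "Pooling muscle transcriptomic responses across studies: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooling muscle transcriptomic responses across studies: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exermeta)
```

## The problem

Dozens of small human studies have profiled the skeletal-muscle
transcriptome before and after an exercise or inactivity intervention —
acute aerobic and resistance bouts, bed-rest/unloading, and weeks of
aerobic, resistance, HIIT or combined training — on heterogeneous array
and RNA-seq platforms, in cohorts that differ in sex composition, age,
BMI and metabolic health. Individually these studies are underpowered
and often disagree; pooled, they can resolve responses far too subtle
for any single cohort. `exermeta` implements that pooling as a gene-wise
random-effects meta-analysis, together with the surrounding stages: per-
study differential expression, cross-study concordance, significance-set
logic and enrichment, per-gene forest interrogation with subgroup
filters, and a multi-study simulator used to validate the whole chain.

## Within-study differential expression

Each study contributes, per gene, an observed log2 fold-change and its
sampling variance. For the paired designs that dominate this literature
(the same subject biopsied pre and post), with per-subject differences
$d_s$ over $n$ subjects:

$$\hat y = \bar d, \qquad \hat v = \frac{s_d^2}{n},$$

with a paired $t$ statistic on $n-1$ degrees of freedom, two-sided
p-value, 95% CI, and Benjamini–Hochberg FDR across the study's genes.
Unpaired designs use Welch statistics with Satterthwaite degrees of
freedom. The sign convention everywhere is post minus pre; inactivity
studies contribute post-bed-rest minus baseline.

Two practical wrinkles:

* **Degenerate variances.** Constant differences (common in toy
  fixtures, possible after aggressive normalization) yield $s_d^2 = 0$
  and infinite $t$. We floor the variance at $10^{-8}$ and flag the
  record, so the effect size survives into pooling while the inference
  is marked unreliable.
* **Variance moderation.** With $n \approx 10$ subjects, $\hat v$ is
  itself noisy (9 degrees of freedom), and the pooling stage treats it
  as known. `paired_de(..., moderate = TRUE)` applies an
  empirical-Bayes, method-of-moments shrinkage of the log variances
  toward their grand mean: the sampling variance of $\log s^2$ on $d$
  degrees of freedom is $\psi'(d/2)$, and the excess spread over that is
  attributed to real between-gene variance heterogeneity. The default is
  the plain per-gene path, but moderation is the recommended setting for
  small-$n$ studies: in our end-to-end simulations (below) the plain
  path's observed false-discovery proportion exceeds the nominal level
  precisely because noisy variances masquerade as precise ones, while
  the moderated path restores control at a small gain in sensitivity.

## The random-effects model

For one gene and one protocol, study effects $y_i$ with sampling
variances $v_i$ ($i = 1, \dots, k$) are modelled as

$$y_i = \mu + u_i + \varepsilon_i, \qquad u_i \sim N(0, \tau^2),
\quad \varepsilon_i \sim N(0, v_i),$$

where $\mu$ is the pooled log2 fold-change and $\tau^2$ the
between-study heterogeneity. $\tau^2$ is estimated by restricted
maximum likelihood: with $w_i = 1/(v_i + \tau^2)$ and
$\hat\mu(\tau^2) = \sum w_i y_i / \sum w_i$,

$$\ell_R(\tau^2) = -\tfrac12 \Big[ \sum_i \ln(v_i + \tau^2)
  + \ln \sum_i w_i + \sum_i w_i (y_i - \hat\mu)^2 \Big]$$

is maximized over $\tau^2 \in [0, 10 \cdot \mathrm{var}(y)]$ by bounded
derivative-free scalar optimization (absolute tolerance $10^{-10}$),
with the boundary value $\tau^2 = 0$ compared explicitly so that the
zero-heterogeneity limit reduces *exactly* to the fixed-effect
inverse-variance mean. The optimizer is validated against a dense-grid
maximizer of $\ell_R$ (three-stage refinement to a $10^{-8}$ step) and
against an independent reference implementation; if it ever returns a
non-finite value, the non-iterative DerSimonian–Laird moment estimate

$$\hat\tau^2_{DL} = \max\!\Big(0, \frac{Q - (k-1)}{C}\Big), \qquad
C = \sum w_i - \frac{\sum w_i^2}{\sum w_i}, \; w_i = 1/v_i$$

is substituted and the record flagged `NONCONVERGED_FALLBACK`.
Heterogeneity is reported as Cochran's $Q$ and
$I^2 = \max(0, (Q - (k-1))/Q) \cdot 100$.

Inference on $\mu$ is Wald: $z = \hat\mu / \mathrm{SE}$,
$p = 2\Phi(-|z|)$, CI $= \hat\mu \pm 1.96\,\mathrm{SE}$ with
$\mathrm{SE} = (\sum w_i)^{-1/2}$ at $\hat\tau^2$. P-values are
BH-adjusted across genes *within* each protocol, since protocols are
reported as separate columns, never jointly. A Knapp–Hartung option
(`knha = TRUE`: robust SE and a $t_{k-1}$ reference) is available but
off by default, as nothing indicates the original analyses used it. The
known cost of that fidelity is small-$k$ undercoverage: at $k = 8$ with
moderate heterogeneity our own simulations put the 95% Wald interval's
coverage near 92% (the acceptance script recomputes this as
`ci_coverage_pct`), which the Knapp–Hartung adjustment would repair at
the price of departing from the reference procedure.

Genes observed in fewer than `min_k` studies (default 3) are reported
with status `TOO_FEW_STUDIES` and all estimates missing — the same
refusal to pool 1–2 studies that motivates printing "NA" for HIIT and
combined-training protocols in per-gene forest views.

## Reporting conventions

Pooled effects are log2 fold-changes; `logfc_to_fold()` converts to the
fold and percent scale used in prose (e.g. $\mu = 1$ is a 2-fold
increase, $\mu = -0.415$ a 25% decrease). `forest_data()` returns one
row per contributing study (effect, CI, within-study FDR, annotations,
missingness flag) plus the pooled row under the identical subgroup
filter, which is what a per-gene browser renders.

## Cross-study concordance

`assemble_fc_matrix()` lays out genes × studies log2 fold-changes with
explicit missingness (platform coverage differs by study). Following
the published order of operations, genes with more than 10% missing
values are excluded *first*; each remaining missing cell is then
imputed by nearest-neighbour averaging: the mean, in that column, of
the `k_neighbors = 10` complete-profile genes closest in Euclidean
distance over the columns actually observed for the target gene.
Restricting candidates to complete profiles and distances to observed
columns guarantees imputations never feed on imputations; observed
cells are never modified. The neighbour count, distance metric and PCA
scaling are not specified by the source methods, so the defaults here
are declared choices: $k = 10$ is the long-standing default of
nearest-neighbour expression imputation, Euclidean distance is its
standard metric, and PCA runs on centered, *unscaled* fold-changes
because all columns already share the log2 scale. PCA component signs
are fixed by making the largest-magnitude loading positive, and
variance explained sums to 100%.

## Significance sets, enrichment, projections

Set logic operates on pooled tables: `significant_set()` (FDR
threshold and direction), `venn_counts()` (2–5 sets), `top_n_genes()`
(deterministic ordering: effect, then FDR, then gene id),
`healthy_specific()` (FDR < 0.01 in healthy *and* FDR > 0.9 in
metabolically impaired — the published rule, reproduced exactly on the
bundled printed table), and `concordance_overlap()` for genes moved one
way by exercise and the other by inactivity; its thresholds are
caller-supplied because the printed inactivity FDR of *NR4A3* (9.4e-2)
shows the published overlap cannot have used 0.05 uniformly.
Over-representation uses the one-sided hypergeometric upper tail
against a measured-gene universe with BH across sets — the core
computation of the standard enrichment tools — with gene sets supplied
as GMT files rather than bundled ontologies. `complex_projection()`
averages pooled member-gene effects per protein complex, tolerating
unmeasured members.

## What the simulator emulates — and what it does not

`simulation_config()` defaults define the study collection the
generator emulates: per-protocol study counts (12 acute aerobic, 8
acute resistance, 7 inactivity, 11 aerobic training, 13 resistance
training healthy groups; 8 + 3 metabolically impaired training groups),
12 subjects per study, residual log2 SD 1.0 per subject difference, 90%
platform gene coverage, 5% truly responsive genes with effect
magnitudes $N(1.0, 0.3^2)$ and Rademacher signs, between-study
heterogeneity $\tau^2 = 0.05$, and a 0.25 multiplicative attenuation of
true effects in metabolically impaired groups (the simplest mechanism
that produces healthy-specific genes). Non-responsive genes are exactly
null with $\tau^2 = 0$. Sampling: $\theta_{gi} \sim N(a_i \mu_g,
\tau^2)$, then either direct observed effects $y_{gi} \sim
N(\theta_{gi}, \sigma^2/n)$ or full paired expression matrices
($\mathrm{PRE} \sim N(7,1)$, $\mathrm{POST} = \mathrm{PRE} +
\theta_{gi} + N(0, \sigma^2)$). A root seed spawns per-study
substreams, so adding a study never perturbs earlier draws and equal
seeds give bitwise-equal output.

The generator deliberately omits probe-level artifacts, batch and lab
effects, count overdispersion, correlated genes and non-normal effect
distributions. Passing recovery tests therefore demonstrates that the
estimation chain is correct under its own assumptions, not that real
multi-platform collections satisfy those assumptions.

## Problem sizes and validation results

The package validates itself at these scales, chosen to give stable
Monte-Carlo estimates: 200 random instances ($k \in [3,12]$) for
REML-vs-grid agreement (observed deviations below $10^{-7}$ in
$\tau^2$); 1000 replicates for CI coverage at $k = 8$; 2000 null genes
for type-I error (observed fraction of $p < 0.05$ close to, and
slightly below, nominal — truncating $\hat\tau^2$ at zero makes the
test mildly conservative under homogeneity); 500 genes × 50 studies for
parameter recovery (bias of $\hat\mu$ under 0.02, relative bias of
$\hat\tau^2$ under 15%); and a 2000-gene, 16-study end-to-end run from
raw paired matrices through moderated within-study statistics to pooled
discoveries (sensitivity above 0.9, observed FDP below 0.1 at meta
FDR < 0.05). `scripts/acceptance.R` recomputes all of these from
scratch at any seed.

## Known limitations

* Wald intervals undercover for small $k$ (see above); use
  `knha = TRUE` when calibrated intervals matter more than fidelity to
  the reference procedure.
* Reported sampling variances are treated as known by the pooling
  stage; with very small cohorts, prefer moderated within-study
  variances.
* Subgrouping is by filtering studies only; there is no meta-regression
  on moderators such as age or sex, and no multivariate/network
  pooling.
* Probe-to-gene collapse uses the per-sample median across probes — a
  robust default for a step whose original rule is unstated.
* Identifiers live in a single user-declared namespace; no cross-
  namespace translation is attempted.
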