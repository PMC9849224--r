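---
title: "Cross-phenotype GWAS analysis with shared controls: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-phenotype GWAS analysis with shared controls: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossgwas)
```

This vignette is the package's own account of the statistics it
implements: the models, their assumptions, the tunable parameters and
their defaults, the numerical choices, and what the simulation-based
tests do and do not demonstrate about real data.

## The setting

Several binary phenotypes are each analyzed by case-control GWAS against
a *single shared control pool* — the registry-biobank design in which
every diagnosis group is compared to the same set of unaffected
participants. The per-phenotype effect estimates at any variant are then
correlated even when the variant affects nothing, because the control
genotypes enter every analysis. All cross-phenotype machinery in this
package is built around that estimate correlation.

## Bayesian classification of cross-phenotype effects

For one variant, let $\hat\beta \in \mathbb R^K$ be the log-odds
estimates across $K$ phenotypes with standard errors $s$. Every
candidate model $m$ is a zero-mean multivariate normal for $\hat\beta$:

$$\hat\beta \mid m \sim \mathcal N(0,\ D R D + \Sigma_m), \qquad
D = \operatorname{diag}(s),$$

with $R$ the overlap-induced estimate correlation and $\Sigma_m$ the
model's prior effect covariance:

* **null** — $\Sigma = 0$;
* **fixed** — one common effect on all phenotypes:
  $\Sigma = \tau^2 J$ (correlation 1);
* **correlated** — similar but not identical effects:
  $\tau^2$ on the diagonal, $r\,\tau^2$ off it, $r < 1$;
* **single-phenotype** (one per phenotype) — $\tau^2$ on that phenotype
  alone;
* **subset** (declared explicitly) — a fixed effect restricted to a
  subset of phenotypes.

The *compared* models are null, shared, each single, and each subset;
each receives prior $1/C$. "Shared" is the union of fixed and
correlated, whose prior mass is split equally between them ($1/2C$
each), so that the compared models are a priori exchangeable. Posteriors
are computed in log space; a compared model is *called* when its
posterior reaches `decision_threshold`, else the variant is
"uncertain". With $K = 1$ the space degenerates to null-vs-effect and
the posterior odds equal a Wakefield-style approximate Bayes factor with
$W = \tau^2$ — a property the test suite checks to $10^{-9}$ against a
hand computation.

### Parameters

* `tau` (default **0.2**, log-odds scale): prior SD of a nonzero effect.
  This is the standard approximate-Bayes-factor scale for binary traits
  (matching the fine-mapper's default $W = \tau^2 = 0.04$) — a 1-SD
  prior effect is an odds ratio of about 1.22.
* `r_corr` (default **0.9**): effect correlation under the correlated
  model. It must be strictly below 1 to keep "correlated" identifiable
  from "fixed"; 0.9 encodes "nearly the same effect" while still paying
  a likelihood price for exact equality.
* `decision_threshold` (default **0.70**; 0.75 is a common stricter
  choice for shared calls and is available through the same parameter).

A consequence worth understanding before interpreting calls: the
null-vs-single Bayes factor at $|z| = \hat\beta/s$ is
$\sqrt{1+\tau^2/s^2}\,\exp\!\big(-z^2\tau^2/2(\tau^2+s^2)\big)$. In a
large study ($s \approx 0.02$, so $\tau/s \approx 10$) a single moderate
$|z| \in (1.5, 2.5)$ — which happens frequently under the null — leaves
enough posterior mass on weak-effect models that the null posterior
falls below 0.70. The classifier then says "uncertain", not "null".
Its wrong-model rate under the null is below 2%, but its *null-call*
rate at the 0.70 threshold is only about 60%: it is deliberately
conservative about certifying absence of effect. Forcing near-complete
null certification would require $\tau$ around 1 (prior odds ratios of
$e$ per SD), which we consider indefensible for common-variant
log-odds; we kept $\tau = 0.2$ and accept the conservative behaviour.
The same trade-off caps the contrast between the unadjusted and
adjusted classifiers' false-shared rates under correlated nulls at
about 1.5x with these defaults (rising above 2x only for
$\tau \gtrsim 0.4$): at $\tau = 0.2$ the correctly-specified
classifier's own false-shared rate is not small enough to be doubled by
a 0.3 estimate correlation. The acceptance script reports all of these
rates as measured.

### The overlap correlation

Two routes estimate $R$:

* **Empirical** (default, any $K$): correlation of z-scores across
  variants that look null in every phenotype ($|z| < 2$, at least 1,000
  retained). This measures whatever overlap exists — shared controls,
  shared cases (comorbidity), cryptic relatedness — without modelling it.
* **Design-based** (two-study, controls-only-shared): the large-sample
  score approximation
  $r_{kl} = (1/n_0)\big/\sqrt{(1/n_{c_k}+1/n_0)(1/n_{c_l}+1/n_0)}$
  from case counts and the shared control pool size. Note its
  assumption: *disjoint case sets*. When individuals can carry several
  phenotypes (the realistic registry situation), the shared cases add
  correlation this formula does not capture, which is exactly why the
  empirical route is the default. The test suite verifies the formula
  against a genotype-level simulation with case sets made disjoint.

Sampling-noise departures from positive semi-definiteness are repaired
by eigenvalue clipping with a warning.

## Two-cohort replication

The heterogeneity statistic for one variant measured in two cohorts is
$z = (\beta_1-\beta_2)^2/(SE_1^2+SE_2^2)$, referred to $\chi^2_1$;
pairs with $p_z < 0.05$ are heterogeneous. Co-directional pairs are
pooled by fixed-effect inverse-variance weighting (for two studies
Cochran's Q equals the statistic above, a consistency the tests assert).
The replication classification is tiered: genome-wide-significant
co-directional meta-analysis; else GWS discovery with co-directional
replication at $p < 0.05$; else discovery-only at the stricter
multiple-testing threshold; else not supported. Replication p-values
are two-sided by default (`rep_alpha`); a zero effect counts as
co-directional with anything so boundary variants are not dropped.
Printed odds-ratio tables are inverted with
$se = (\ln \mathrm{CI_{hi}} - \ln \mathrm{CI_{lo}})/(2 \times 1.959964)$;
the sub-rounding difference from using 1.96 is below printed precision.

## Loci, fine-mapping, colocalization

**Clumping** takes the lowest-p unassigned GWS variant as a lead and
assigns every unassigned GWS variant within 2 Mb *and* with $r^2 > 0.1$
of the lead. The conjunction (rather than either condition alone) is the
conservative reading and is configurable; ties on p break by genomic
position. The implementation is verified against an independent
brute-force transcription of the rule on random instances.

**Fine-mapping** is a single-causal-variant approximate-Bayes-factor
mapper: $ABF_i = \sqrt{s_i^2/(s_i^2+W)}\exp\!\big(z_i^2 W/2(s_i^2+W)\big)$,
normalized to posterior inclusion probabilities with a flat prior over
variants, computed in log space (safe to $|z|$ well beyond 60). The 95%
credible set is the smallest descending-PIP prefix with cumulative PIP
$\ge 0.95$; sets lacking a GWS member are marked excluded. Multi-signal
loci require conditionally decomposed inputs; the package deliberately
does not implement multi-causal search, so its sets at genuinely
multi-causal loci are approximations.

**Colocalization** of credible sets $A$ and $B$ uses
$\mathrm{CLPP}=\sum x_i y_i$ over shared variants (significant > 0.20)
and $\mathrm{CLPA}=\sum \min(x_i,y_i)$ (significant > 0.50); since
$xy \le \min(x,y)$, CLPP never exceeds CLPA. Variant identity uses
harmonized chrom:pos:ref:alt keys; PIPs are orientation-free. When a
locus has several credible sets, pairs are scored pairwise, not pooled.

## Genetic correlation

The LD score regression stand-in regresses $\chi^2_j$ on
$N \ell_j / M$ (slope = observed-scale $h^2$, intercept $\approx 1$
absent confounding) and $z_{a j} z_{b j}$ on
$\sqrt{N_a N_b}\,\ell_j/M$ (slope = genetic covariance; the intercept
absorbs sample overlap, so shared controls bias the intercept, not
$r_g$). Weights are the standard two-pass
$1/\big(\ell_j (1+N h^2 \ell_j/M)^2\big)$ form; standard errors come
from a delete-one block jackknife (20 contiguous blocks). $r_g$ is the
covariance slope over $\sqrt{h^2_a h^2_b}$ and is undefined (flagged)
when either heritability estimate is non-positive. This module makes no
claim of numerical equivalence with the reference LD-score software; it
exists so the grouping logic has a tested estimator behind it.
Phenotype groups are connected components of the graph with edges where
$r_g > t$, evaluated at nested thresholds (defaults 0.75 and 0.90);
higher thresholds provably refine lower ones.

## Synthetic data: what it emulates, what it does not

* **Genotypes**: independent LD blocks; within a block, haplotypes are a
  latent Gaussian AR(1) process thresholded at per-variant MAF
  quantiles, two haplotypes summed. This gives controllable adjacent
  $r^2$ at desk scale. It does *not* emulate realistic human LD maps,
  recombination hotspots, population structure or relatedness — so
  passing tests demonstrate correctness of the algorithms under their
  stated models, not robustness to those real-data features.
* **Phenotypes**: independent logistic models per phenotype; the shared
  control pool is the set of individuals with no phenotype. Individuals
  may carry several phenotypes, as in registries.
* **Direct summary statistics**: per variant,
  $\hat\beta \sim \mathcal N(\beta, D R D)$ — the exact sampling model
  the classifier assumes; used for calibration studies where LD is
  irrelevant.
* **Correlated effects**: the generator draws the effect vector from
  $\mathcal N(\bar\beta \mathbf 1, (\bar\beta/4)^2 R(r))$ — "similar
  but not identical" effects with a 25% coefficient of variation. The
  dispersion is a package choice (the model family only fixes $r$);
  it was set once on the grounds that cross-disease effect sizes at
  shared loci typically differ by tens of percent, not factors.
* **Polygenic z-scores** (for the $r_g$ estimator): drawn directly from
  the LD-score model with LD scores $1+\Gamma(2,1)$, i.e. mean 3 and
  realistic spread after scaling.

## Problem sizes and numerical choices

The test suite and acceptance script use: 200 variants per generating
model for classifier calibration (se 0.02, $K=2$); 20,000 variants per
arm for the overlap-adjustment rates; 10,000 replicates for the
heterogeneity type-I error; 500 replicates of 50-variant AR(1)
($\rho=0.5$) loci for fine-map coverage; 100 random instances (up to 50
variants) for the clumping oracle; 1,000 random credible-set pairs for
the colocalization oracle; and 500 replicates of 20,000 variants for
$r_g$ recovery. The end-to-end pipeline demonstrations run 3,000
individuals by 200 variants. These sizes were chosen so every
stochastic band is estimated with Monte-Carlo error well inside its
width on a single CPU.

Numerics: all model comparison and fine-mapping in log space with
max-subtraction; posterior normalization is exact to $10^{-9}$;
monomorphic variants are skipped and separation-scale logistic fits
flagged rather than reported; degenerate inputs (empty loci, zero SEs,
non-PSD covariances, constant LD scores) raise immediate errors naming
the offending quantity; clumping ties break by (chrom, pos) so results
are order-independent; hierarchical clustering of effect matrices uses
average linkage on Euclidean distances of $z$-scores (the method is a
package choice — none is prescribed by the grouping it reproduces — and
is configurable).

## Known limitations

* The classifier's sampling model takes $R$ as known; uncertainty in
  the estimated overlap correlation is not propagated.
* $\tau$ is fixed, not estimated by empirical Bayes; phenotype-specific
  prior scales and mixture-over-$\tau$ grids are out of scope.
* The fine-mapper assumes one causal variant per locus.
* The $r_g$ estimator omits liability-scale conversion, reference-panel
  variant filtering and partitioned heritability.
* Palindromic (A/T, C/G) variants cannot be oriented across cohorts
  from alleles alone; they are flagged ambiguous and excluded from
  downstream statistics by default rather than guessed from allele
  frequency.
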