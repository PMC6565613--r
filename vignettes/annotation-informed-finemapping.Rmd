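---
title: "Annotation-informed fine-mapping: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotation-informed fine-mapping: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annofine)
```

## The problem

Genome-wide association studies report per-variant effect sizes ($\beta$) and
standard errors (SE), but linkage disequilibrium makes the association signal
at a risk locus diffuse: dozens of variants are statistically
indistinguishable. Functional genomic annotations — open chromatin from
ATAC-seq, active regulatory marks such as H3K27ac, coding and promoter
regions — carry independent information about where causal variants are
likely to sit. This package implements a hierarchical Bayesian workflow that
(i) measures how strongly each annotation is enriched for association signal
genome-wide, (ii) folds that enrichment back into the per-variant prior, and
(iii) reports per-variant posterior probabilities of association (PPA) and
95% credible sets before and after the annotation update. Companion modules
test allele-specific expression/accessibility at heterozygous sites and
compare peak interval sets, the follow-up analyses used to corroborate a
prioritized regulatory variant.

## The model

**Approximate Bayes factors.** For a variant with Z score $z = \beta/\mathrm{SE}$
and sampling variance $V = \mathrm{SE}^2$, the evidence for association under a
normal effect-size prior with variance $W$ is the Wakefield approximate Bayes
factor
$$\mathrm{ABF}_W = \sqrt{\frac{V}{V+W}}\;
  \exp\!\left(\frac{z^2}{2}\frac{W}{V+W}\right),$$
averaged arithmetically over a small grid of $W$. `ln_abf()` evaluates the
whole computation in log space, so Z scores up to $|z| \approx 40$ (log Bayes
factors of several hundred) are handled without overflow. The default grid
$W \in \{0.01, 0.1, 0.5\}$ is the convention of the hierarchical-enrichment
literature; it is exposed as an argument everywhere because the appropriate
scale of $W$ relative to $V$ depends on the study's power.

**Regional mixture likelihood.** The genome is cut into consecutive 1-Mb
blocks (`segment_blocks()`, windows anchored at coordinate 0). Each block
either contains no causal variant, with probability $1-\Pi$, or exactly one,
with probability $\Pi$; given a signal, variant $i$ is the causal one with
prior
$$\pi_i = \frac{\exp(x_i \cdot \lambda)}{\sum_j \exp(x_j \cdot \lambda)},$$
where $x_i$ is the variant's binary annotation vector and $\lambda$ the
annotation effects on the natural-log-odds scale. The marginal likelihood of
a block is $(1-\Pi) + \Pi \sum_i \pi_i \mathrm{BF}_i$, and the fitted
objective over blocks is
$$\ell(\lambda, \Pi) = \sum_b \log\left[(1-\Pi) + \Pi \sum_{i \in b}
  \pi_i \mathrm{BF}_i\right] - p \sum_k \lambda_k^2,$$
a ridge penalty $p$ (default 0.30, the cross-validated value in the AMD
application this package was built around) applied to annotation effects
only — penalizing the intercept would bias $\Pi$.

**Posteriors.** With regional Bayes factor $R = \sum_i \pi_i \mathrm{BF}_i$,
the posterior probability that a region carries a signal is
$\Pi R / (1 - \Pi + \Pi R)$, and a variant's PPA is that probability times
its conditional share $\pi_i \mathrm{BF}_i / R$: the proportion of the
locus's Bayes-factor-measured risk signal attributed to the variant,
multiplied by the probability the region contains a real signal. PPAs
therefore sum to the regional signal probability — a conservation law the
test suite checks to $10^{-9}$ on randomized regions.

**Credible sets.** `credible_set()` sorts variants by conditional posterior
mass (ties broken by genomic position, for determinism) and takes the
smallest prefix reaching the level. The default mass is the within-locus
*normalized* posterior, so a 95% set is well defined even when the region's
signal probability is below 0.95; accumulating raw PPA instead is available
via `mass = "ppa"` for users who want sets that may refuse to close.

## Fitting, penalty selection and annotation reduction

`fit_model()` maximizes $\ell$ by BFGS with analytic gradients. Two numerical
facts shaped the implementation. First, the likelihood plateaus in the
regional intercept as $\Pi \to 0$ or $1$ (the gradient vanishes
exponentially), so a quasi-Newton run started far from the optimum can
strand on the plateau; the intercept is therefore warm-started by a
one-dimensional search and each run is followed by a coordinate polish that
re-optimizes the intercept and restarts BFGS if that helps. Second, an
annotation marking every variant leaves the within-block softmax flat; the
ridge term then pulls its coefficient to exactly zero, which is the behaviour
`fit_model()` exhibits and the tests assert. Convergence is declared when
successive objective values agree to about $10^{-8}$ (BFGS relative
tolerance $10^{-10}$); failures trigger restarts from $\lambda = \pm 0.5$
and, if persistent, a warning with `converged = FALSE`.

`cross_validate_penalty()` partitions blocks (not variants) into seeded
folds, fits at each candidate penalty on the training folds and scores the
*unpenalized* likelihood on the held-out fold; ties go to the smaller
penalty. `stepwise_reduce()` performs backward elimination, removing at each
step the annotation whose removal most increases the cross-validated
held-out likelihood and stopping when no removal increases it. The stopping
rule could equally be read against the in-sample penalized likelihood; that
interpretation is available via `criterion = "in_sample"`, but cross-validated
likelihood is the default because in-sample likelihood almost never decreases
when a ridge-shrunk parameter is dropped, making the in-sample rule nearly
vacuous.

Single-annotation fits (`fit_single()`) report a 95% profile-likelihood
interval: bounds where the profile (intercept maximized out) drops 1.92 log
units. When an annotation separates signal from null perfectly the point
estimate diverges while the lower bound stays finite; the bound search is
therefore conducted on an absolute window rather than relative to the
estimate.

**Locus windows.** Fine-mapping windows flanking a reported lead variant
default to lead $\pm$ 500 kb (a 1-Mb total window); `flank = "each_side"`
gives lead $\pm$ `window_bp` instead, since "1-Mb windows flanking" admits
both readings. Similarly, the "original" (annotation-free) PPA uses the
fitted model's intercept by default, with `original_logit` available to
supply a flat or externally chosen regional prior; neither reading is
treated as canonical.

## Allele-specific signal

`binomial_ase()` is the exact two-sided binomial test of allelic read counts
against the 50% expectation at a heterozygous site. Two-sided means
minimum-likelihood enumeration — the sum of probabilities of all outcomes no
more probable than the observed one — which is the common exact-test
convention; doubling the smaller tail is available as `method = "double"`.
`meta_ase()` combines heterozygotes by Stouffer's method on signed Z scores
(sign from the direction of imbalance) weighted by the square root of read
depth, chosen because it preserves direction and lets discordant samples
cancel; since the combination rule is not dictated by the source analyses, a
pooled-count binomial alternative is one flag away. RNA ASE site filters
follow the strict readings of their thresholds: more than eight reads on
either allele (strictly greater), reference allele frequency strictly
between 2% and 98%, and unique-mappability pass. `all_homref_probability()`
is the Hardy–Weinberg computation $(f^2)^n$; at $f = 0.48$ and $n = 4$
subjects it evaluates to 0.0028, i.e. 0.003 at one significant figure.

## Peak similarity and motif-profile clustering

`jaccard()` computes intersection-over-union of covered base pairs (not of
peak counts): the base-pair form is the standard genome-arithmetic
convention and is robust to differing peak-width distributions. Interval
bookkeeping is delegated to GenomicRanges. Motif-enrichment tables are
rank-transformed within each sample (rank 1 = strongest enrichment, average
ranks on ties) to remove study-specific scaling of enrichment p-values, and
samples are clustered with average linkage on $1 - \rho_s$ (Spearman) over
rank columns; samples are sorted by name beforehand so leaf order is
deterministic, and constant rank profiles are rejected by name since their
correlation is undefined.

## The synthetic-data generator

`simulate_gwas_dataset()` emulates exactly the statistical structure the
model assumes: annotations assigned per variant by independent Bernoulli
draws; each block carrying a causal variant with probability `pi_regional`;
the causal variant chosen within a signal block by softmax of
$x \cdot \lambda_{true}$; causal Z drawn as $\pm N(\text{causal\_z\_mean}, 1)$
with random sign, null Z standard normal, and $\beta = Z \cdot \mathrm{SE}$.
Positions sit on one synthetic chromosome at even spacing so that blocks are
exactly 1 Mb and `segment_blocks()` reproduces the design. What it does *not*
emulate is linkage disequilibrium — nulls are independent and at most one
variant per block is causal — nor effect sizes drawn from the ABF's own
normal prior. The second point matters for interpretation: because the
generator's alternative ($|Z|$ near a fixed mean) differs from the analysis
model's alternative ($\beta \sim N(0, W)$), parameter recovery is only clean
when the Bayes factors separate null from signal blocks sharply, which
requires $W$ large relative to $V$. The packaged study conditions therefore
pair the default grid ($W$ up to 0.5) with a summary-statistic scale of
`se_value = 0.007`, the SE magnitude of a large GWAS meta-analysis; under
those conditions the enrichment effect is recovered within $\pm 0.3$, the
regional prior within $\pm 0.1$, and planted causal variants fall inside the
95% credible set in well over 93% of signal blocks. Passing these tests
shows the estimator is correct under its own assumptions; it does not show
robustness to LD or to winner's-curse effects in real summary statistics.

Read-depth simulation for allelic counts uses a negative binomial
parameterized by mean and dispersion (variance $\mu + \phi\mu^2$) —
overdispersed depth is realistic yet simple — with `dispersion = 0` giving
constant depth for exact power calculations. `simulate_peak_sets()` shifts
every interval of a non-overlapping set by a fraction $s$ of the interval
length, so the pairwise Jaccard similarity is exactly $(1-s)/(1+s)$; shifts
are rounded to whole base pairs, so exact equality holds when
$s \times \text{length}$ is an integer.

## Problem sizes and determinism

All stochastic tests and the acceptance script fix seeds and state their
replicate counts: enrichment recovery uses five to fifty replicates of
2,000 blocks × 50 variants, calibration uses 1,000 signal blocks, and the
selection study 20 replicates of 500 blocks × 20 variants — sizes at which
the sampling error of each checked quantity is comfortably inside its
assertion band. Every simulator takes an explicit integer seed and restores
the caller's RNG state (`withr::with_seed`), so a fixed configuration is
bit-reproducible across runs and platforms.

## Known limitations

* One causal variant per block: loci with multiple independent signals are
  outside the model, as are LD-aware conditional analyses.
* Annotations are binary and variant-level; region-level covariates such as
  distance to TSS are not modelled.
* The profile-likelihood CI assumes the usual chi-square asymptotics; under
  strong model misspecification its coverage is approximate.
* Gene-level, haplotype-phased ASE (e.g. MBASED-style models) is out of
  scope; only per-site exact tests, filters and cross-sample meta-analysis
  are provided.
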