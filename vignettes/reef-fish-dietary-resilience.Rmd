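---
title: "Methods: quantifying dietary resilience of reef fishes to habitat degradation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying dietary resilience of reef fishes to habitat degradation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefdiet)
```

## The scientific setting

Coral reefs that lose live coral cover change the prey landscape available
to benthic-feeding fishes. Whether a consumer can shift its diet — and what
that shift costs in body condition and growth — is the question this
package's analysis chain is built to answer. The sampling design it assumes
is hierarchical: habitat **zones** that differ in live coral cover (here,
an outer high-cover zone, an intermediate inner zone, and a disturbed
near-zero-cover zone), with replicate **reefs** nested inside zones, and
individual fish of two focal species (a browsing corallivore and an active
invertebrate predator) collected within reefs. Three data streams meet in
the analysis: morphometrics and otolith ages per fish, a dietary
metabarcoding read table (samples × prey OTUs with a taxonomy), and
ecological surveys (benthic photo quadrats, invertebrate quadrats, fish
belt transects).

## Body condition

The length–weight relationship is fitted once per species as the log-log
regression $\ln W = \ln a + b \ln L$ (`fit_length_weight()`). Le Cren's
relative condition factor is then

$$K_n = \frac{W}{a L^b},$$

computed on the **raw measurement scale** (`compute_kn()`). The defining
property — and the reason we pin the raw scale rather than working with
logged weights throughout — is that $K_n$ is centred at 1: a fish of
average plumpness for its length has $K_n = 1$, and because OLS residuals
on the log scale sum to zero, the geometric mean of $K_n$ over the fitting
sample is exactly 1. This anchoring is what makes the conventional reading
of condition plots (values above/below 1 as good/suboptimal condition)
meaningful, and it is asserted in the test suite.

Zone effects on condition are modelled as `Kn ~ log(L) * zone`
(`fit_condition_interaction()`): a sequential (Type I) ANOVA with partial
$\eta^2 = SS_{term}/(SS_{term}+SS_{resid})$ per term, per-zone marginal
slopes, and all pairwise slope contrasts with Tukey adjustment over the
contrast family (studentized range with the model's residual df, via
emmeans).

Differences in condition *variability* — the signature of divergent
individual responses on degraded reefs — are tested with pairwise log
variance ratios on the **residuals of the interaction model**, so that
variance is compared while controlling for fish size:

$$\mathrm{lnVR} = \ln\frac{SD_1}{SD_2} + \frac{1}{2(n_1-1)} -
\frac{1}{2(n_2-1)}.$$

The two correction terms are the small-sample bias correction of the
meta-analytic lnVR effect size; they are on by default and can be disabled
(`bias_correction = FALSE`), since published analyses do not always state
whether they were used. Confidence intervals are percentile bootstrap with
case resampling independently within each group, `B = 1000` by default and
an explicit seed; a contrast is "significant" when its 95% CI excludes
zero. `lnvr_fold()` returns $e^{|\mathrm{lnVR}|}$, the fold difference
conventionally quoted alongside these contrasts. A raw-$K_n$ mode is
available implicitly by passing any values to `lnvr_pairwise()`; the
residual route is what the pipeline uses.

## Growth

Length-at-age follows the von Bertalanffy growth function
$L(t) = L_\infty(1 - e^{-K(t - t_0)})$, fitted by Levenberg–Marquardt
nonlinear least squares (`fit_vbgf()`, via minpack.lm). Two numerical
choices matter:

* **$t_0$ is fixed at $-2$ yr by default.** Adult-only collections (ages
  3+) carry almost no information about the age at length zero, and
  zone-specific fits published for this system report identical $t_0$
  values across all fits, implying it was pinned. Freeing $t_0$
  (`t0 = NULL`) is supported and requires one more distinct age.
* **Analytic starts with a restart ladder.** $L_{\infty,0}$ = 1.1 × the
  maximum observed length; $K_0$ from a linearised regression of
  $\log(1 - L/L_{\infty,0})$ on age; on failure the fitter retries over a
  small grid of scaled starts before giving up with the collected error
  messages.

Zone comparison uses case-resampled bootstrap refits within each zone
(`bootstrap_vbgf()`, percentile CIs, `B = 1000` default): two zones
"differ" in $L_\infty$ or $K$ when their 95% CIs are disjoint. This
CI-overlap rule is deliberately conservative and matches how such
comparisons are usually read off bootstrap plots. If more than 20% of
resample fits fail to converge the bootstrap aborts rather than report
CIs from a biased subset. BCa intervals were considered and rejected:
the downstream decision rule only uses interval overlap, and percentile
intervals keep the procedure transparent and cheap.

## Diet community structure

Dissimilarity is Bray–Curtis, $d = \sum|x-y| / \sum(x+y)$
(`bray_curtis()`). The default mode normalises each sample to proportions
first, because metabarcoding depths vary by orders of magnitude between
samples and relative read abundance is the quantity of interest; the
matrix is then invariant to per-sample depth rescaling (a tested
invariant). Presence–absence mode binarises first (Sørensen), the usual
robustness companion analysis.

Ordination is by PCoA (`pcoa_ord()`, classical scaling of the
double-centred matrix; axes with non-positive eigenvalues are dropped and
flagged) and NMDS (`nmds_ord()`, Kruskal stress-1 minimised over monotone
regression with ties averaged, best of 20 random starts plus a metric
start, maximum 300 iterations). NMDS defaults mirror common ecological
practice; stress is reported on the 0–1 scale and a failure to converge in
any start returns the best configuration flagged `converged = FALSE`.

The zone test is a one-way PERMANOVA implemented from the sum-of-squares
definitions (`permanova()`):

$$SS_{total} = \tfrac{1}{N}\sum_{i<j} d_{ij}^2,\qquad
SS_{within} = \sum_g \tfrac{1}{n_g}\sum_{i<j \in g} d_{ij}^2,\qquad
F = \frac{(SS_{total}-SS_{within})/(g-1)}{SS_{within}/(N-g)}.$$

The p-value is the permutation estimator $(1+b)/(1+m)$, which can never
return zero and whose floor on small designs is set by the number of
distinct relabellings — a property the test suite checks against
brute-force enumeration on six-sample instances, alongside an exact
cross-check of $F$ and $R^2$ against an independent implementation
(vegan's `adonis2`). Permutation is free by default; a `strata` argument
restricts relabelling within blocks (e.g. reefs) when a restricted scheme
is wanted. Pairwise zone contrasts rerun the test on each pair's
sub-matrix with Bonferroni correction $p_{adj} = \min(1, p \cdot C(g,2))$
(`pairwise_permanova()`). The pipeline default is 999 permutations for
test-speed reasons; analyses intended for publication-grade inference
should pass `n_perm = 10000`.

## Diet profiles and feeding strategy

`aggregate_taxa()` collapses the OTU table at any taxonomy rank, pooling
OTUs unassigned at that rank into an explicit `unassigned` column;
total reads are conserved at every rank (tested). Sample-based
rarefaction (`rarefaction_curve()`) reports the expected OTU richness over
random subsets of samples; whenever $\binom{n}{s}$ does not exceed
`n_draws` the subsets are enumerated exhaustively, which makes small
cases exact and directly comparable to an enumeration oracle.

The Amundsen–Costello analysis (`amundsen()`) places each prey at
(frequency of occurrence, prey-specific abundance):

$$FO_i = 100\,\frac{\#\{\text{fish containing } i\}}{\#\text{fish}},\qquad
P_i = 100\,\frac{\sum S_i}{\sum S_{ti}},$$

with both sums over only the fish containing prey $i$. With relative read
abundance (the default) $P_i$ is the mean share of prey $i$ in the diets
that contain it. The original method is read visually; to make the output
testable we label quadrants at configurable thresholds (default
FO = 50%, $P_i$ = 50%): upper-right "dominant-specialized", lower-left
"rare-occasional", upper-left "BPC-leaning" (between-phenotype niche
component), lower-right "WPC-leaning" (within-phenotype). The quadrant
counts are a diagnostic summary, not a scalar niche-width index — the
literature offers no agreed formula for WPC/BPC and we do not invent one.

## Prey abundance versus coral cover

`fit_prey_glmm()` links the read abundance of a prey group to a predictor
(reef-mean percent coral cover, or fish age) with a negative-binomial
mixed model (log link) and tests the predictor by likelihood ratio against
the matching null model ($\chi^2_1$). The random-intercept structure
follows the design: reef nested in zone by default, zone only for the
hard-coral response (hard-coral availability is collinear with coral
cover). Two response conventions are offered because practice varies:

* **`mode = "offset"` (recommended):** raw counts with `log(depth)` as an
  offset, the statistically clean treatment of unequal sequencing effort.
* **`mode = "mimic"`:** a variance-stabilising transformation (square
  root, fourth root, or log1p) applied to the counts and rounded back to
  integers before the NB fit. Transform-then-count-model workflows appear
  in applied work; the mode is provided for comparability and clearly
  labelled in its result, but a count model on transformed counts is
  statistically irregular and we do not assert it as the preferred route.

Models are fitted with glmmTMB; an independent cross-check against
`lme4::glmer.nb` on a common instance is part of the test suite.

## Survey statistics

Percent coral cover per reef is the two-stage mean — quadrats averaged
within transects, transect means averaged within reefs — rather than a
pooled quadrat mean; the two differ whenever transects carry unequal
quadrat counts, and the two-stage form is the design-consistent one.
Zone tests use Kruskal–Wallis with the rank effect size
$\varepsilon^2 = H(n+1)/(n^2-1)$ and Dunn's post hoc on tie-corrected mean
ranks with Benjamini–Hochberg adjustment; normally distributed responses
use one-way ANOVA with Tukey HSD. Shannon diversity is reported in
natural-log units (nats); the base is a convention, and nats are stated
explicitly wherever the value is written. Densities are counts divided by
sampled area (100 m² belt transects, 0.25 m² quadrats) summarised as reef
mean ± SD over replicates and zone means over reef means.

Degenerate inputs follow explicit contracts rather than propagating NaN:
all-tied samples give $H = 0$ and $\varepsilon^2 = 0$; zero residual
variance with unequal means reports $F = \infty$ with a `degenerate`
flag; all-zero community samples and zero-variance lnVR groups raise
errors naming the offending sample or group.

## What the synthetic generator emulates — and what it does not

`sim_config()` encodes the study conditions as defaults: 2 species × 3
zones × 3 reefs × 20 fish; integer ages 3–9 (browser) and 3–8 (predator);
zone-specific published VBGF parameter sets; allometric weight
$W = aL^b e^\varepsilon$ with $a = 2\times10^{-5}$ g·mm⁻³ and $b = 3$
(isometric growth, a standard value for laterally compressed reef fish of
this size; the source analysis does not print its fitted allometry);
multiplicative weight noise of SD 0.05, doubled to 0.10 for the browser in
the disturbed zone to emulate the inflated condition variance reported
there; Dirichlet-multinomial diet reads with lognormal depths (medians
25,000 and 6,000 reads, matching the two species' reported depth modes);
benthic quadrats as 100-point multinomials with zone coral-cover means of
33.46, 12.06 and 0.34% (reef-level SDs 3.41, 2.30, 0.39); Poisson
invertebrate and fish-transect counts. The Dirichlet concentration
profiles move the browser from anthozoan- to annelid-dominated diets and
the predator from benthic macrocrustaceans to planktonic copepods across
the gradient; their absolute values are illustrative, because the source
reports only stacked-bar dominance patterns, not per-taxon proportions.

One global seed drives everything through named substreams
(`fish`, `diet`, `surveys`), so stages can be re-run independently and
the whole dataset is bitwise reproducible.

The generator deliberately omits: sequence-level artefacts (no FASTQ,
chimeras, PCR bias, tag jumping), spatial autocorrelation between reefs,
within-zone gradients in diet, age–length measurement error structure
beyond Gaussian noise, and any fish–survey coupling (prey fields and
diets are drawn independently). Passing tests on synthetic data therefore
demonstrate that the estimators recover the structure they assume — not
that real gut-content data meet those assumptions.

## Problem sizes used in the automated checks

The calibration suites run at deliberately modest sizes chosen to give
each check adequate power while keeping the whole suite quick to run on a
laptop: PERMANOVA null calibration over 200 replicate simulations of 45
samples with 199 permutations each; GLMM LRT null calibration over 200
replicates of 90 fish; lnVR bootstrap coverage over 500 replicates of two
groups of 60 with `B = 1000`; VBGF bootstraps in tests at `B = 200`. The
end-to-end check runs the full study-design generator (360 fish) through
the condition and diet stages with `B = 1000` and 999 permutations.

## Known limitations

* The PERMANOVA is one-way (the design's single zone factor); nested or
  multi-factor partitions are out of scope, and restricted permutation is
  available only as flat strata.
* lnVR bootstrap CIs are percentile intervals; their small-sample
  miscoverage (checked to sit within a few points of nominal) is inherited
  by the significance flags.
* $K_n$ comparisons are only meaningful within the population whose
  length–weight fit defines them; the package intentionally refuses the
  cross-population relative-weight standard.
* NB mixed models with few clusters (three zones) estimate the zone
  variance poorly; the LRT concerns the fixed predictor and is calibrated
  for fish-level predictors, while reef-level predictors with nine reefs
  should be read with the usual small-cluster caution.
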