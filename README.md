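# reefdiet

Quantifying the dietary and performance responses of coral reef fishes to
habitat degradation.

Benthic-feeding reef fishes living across a gradient of coral loss face a
changing prey landscape. `reefdiet` implements the analysis chain used to
ask whether such fishes shift their diets, and what those shifts cost in
body condition and growth, from three tabular data streams collected in a
zones-with-nested-reefs design:

* **morphometrics and otolith ages** per fish (total length mm, wet
  weight g, age yr);
* a **dietary metabarcoding OTU table** (fish samples × prey OTUs, with a
  taxonomy);
* **ecological surveys** (100-point benthic photo quadrats, invertebrate
  quadrats, fish belt transects).

## What it computes

| Block | Statistics | Key functions |
|---|---|---|
| Condition | log-log allometry `W = aL^b`; Le Cren `K_n = W/(aL^b)`; `K_n ~ log L × zone` with Type I ANOVA, partial η², Tukey-adjusted slope contrasts; bootstrapped pairwise log variance ratios `lnVR = ln(SD1/SD2) + 1/(2(n1−1)) − 1/(2(n2−1))` on model residuals | `fit_length_weight()`, `compute_kn()`, `fit_condition_interaction()`, `lnvr_pairwise()` |
| Growth | von Bertalanffy `L(t) = L∞(1 − e^{−K(t−t0)})` by Levenberg–Marquardt NLS (t0 fixed at −2 by default); zone comparison by bootstrap CI overlap | `vbgf_predict()`, `fit_vbgf()`, `bootstrap_vbgf()` |
| Diet community | Bray–Curtis (relative / presence–absence), PCoA, NMDS; one-way PERMANOVA pseudo-F with `(1+b)/(1+m)` permutation p and pairwise Bonferroni tests | `bray_curtis()`, `pcoa_ord()`, `nmds_ord()`, `permanova()`, `pairwise_permanova()` |
| Diet profiles | taxonomic aggregation, relative abundance, sample-based rarefaction (exact by enumeration when feasible), Amundsen–Costello feeding strategy (FO vs prey-specific abundance P_i), negative-binomial GLMMs of prey reads vs coral cover or age with LRT | `aggregate_taxa()`, `rarefaction_curve()`, `amundsen()`, `fit_prey_glmm()` |
| Surveys | Kruskal–Wallis with ε², Dunn/BH post hoc, ANOVA/Tukey, Shannon H′ (nats), densities, two-stage coral-cover means | `kruskal_epsilon()`, `dunn_posthoc()`, `anova_tukey()`, `shannon_index()`, `coral_cover_summary()`, `density_summary()` |
| Simulation | seed-reproducible generator of the full zone-structured design (Dirichlet-multinomial diets, lognormal depths, VBGF lengths, multinomial quadrats) | `sim_config()`, `simulate_dataset()` |

`run_pipeline()` chains the blocks on a dataset (real or synthetic) and
writes plot-ready CSVs plus a JSON manifest with per-stage checksums.

## Worked example

Simulate the full study design (2 species × 3 zones × 3 reefs × 20 fish)
and run the condition and diet analyses for the browsing species:

```r
library(reefdiet)

ds <- simulate_dataset(sim_config(seed = 2024))
fish <- ds$fish[ds$fish$species == "browser", ]

fit_length_weight(fish)
#> Length-weight fit: ln W = -10.8884 + 3.01601 ln L  (n = 180)
#>   a = 1.86744e-05 g/mm^b, residual SD (log) = 0.06676
```

The fitted exponent sits at the generating isometric value b = 3. Condition
variability across zones, controlling for fish size:

```r
kn <- compute_kn(fish, fit_length_weight(fish))
inter <- fit_condition_interaction(kn)
lnvr_pairwise(inter$residuals$residual, inter$residuals$zone,
              B = 1000, seed = 2024)
#>      group1              group2       lnvr   ci_lower   ci_upper ... significant
#> 1 outer_bay           inner_bay  0.1397949 -0.1908451  0.4761832 ...       FALSE
#> 2 outer_bay inner_bay_disturbed -0.4707575 -0.7061931 -0.2244514 ...        TRUE
#> 3 inner_bay inner_bay_disturbed -0.6105524 -0.9416324 -0.3299814 ...        TRUE
```

Both contrasts against the disturbed zone exclude zero: condition is
significantly more variable on the degraded reefs (negative lnVR here
means the second-named group has the larger SD), while the two
higher-cover zones do not differ. Diet composition separates by zone:

```r
otu <- ds$otu[fish$id, ]
permanova(bray_curtis(otu), fish$zone, n_perm = 999, seed = 2024)
#> PERMANOVA (180 samples, 3 groups, 999 permutations)
#>   pseudo-F = 163.33, R2 = 0.6486, p = 0.001
```

and the feeding-strategy plot shows the browser's dominant prey in the
disturbed zone is the terebellid worm, not the coral that dominates in
the outer bay:

```r
head(amundsen(otu[fish$zone == "inner_bay_disturbed", ]), 3)
#>            prey  fo        pi             quadrant
#> 1 Loimia_medusa 100 53.195242 dominant-specialized
#> 2   Aiptasia_sp 100 12.487581          WPC-leaning
#> 3   Mussidae_sp 100  9.362697          WPC-leaning
```

Growth parameters per zone come from `fit_vbgf()` /
`bootstrap_vbgf()`; e.g. the outer-bay fit on this dataset recovers
`Linf = 98.3 mm, K = 0.232 /yr` against generating values 97.86 and 0.23.

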