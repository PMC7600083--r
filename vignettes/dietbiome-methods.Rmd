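---
title: "dietbiome: models, defaults and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dietbiome: models, defaults and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietbiome)
```

`dietbiome` links 24-hour dietary recalls (24-HDR) to gut-microbiota
composition and diversity. This vignette documents the statistical models
each stage implements, the tunable parameters and their defaults, what the
synthetic-data generator emulates (and deliberately does not), and the
design decisions taken where the design was genuinely open. It states no
empirical result that the package's tests do not themselves compute.

## 1. Diet-quality scoring

### Adapted Healthy Eating Index (75 points)

HEI-2015 scores diet *density*: amounts per 1000 kcal, so that quality is
independent of how much a person eats. Each component interpolates linearly
between a zero-point density and a max-point density, clamped outside that
band; moderation components (sodium, added sugars, saturated fat) are
reverse-scored. Portion constants are 250 g per cup and 28.25 g per ounce.

The adapted index drops the whole-grain, refined-grain and
seafood-and-plant-protein components: the food-composition databases this
index was designed around record neither the whole/refined grain split nor
seafood detail. Removing those 25 points leaves ten components summing to
exactly **75**, the index ceiling — this is the package's resolution of an
open question (the exact component table was not published); the retained
HEI-2015 cutpoints live in `hei_standards()` and can be replaced wholesale
via `read_standards()`/`write_standards()` if the original table becomes
available. The fatty-acid component is the ratio (MUFA+PUFA)/SFA scored
between 1.2 (zero points) and 2.5 (ten points); it is the only "adequacy"
component with a nonzero floor.

Mapping recall data onto components requires judgement calls, all in
`hei_components_from_intake()`: fruits feed both total and whole fruits
(juice cannot be distinguished), beans feed greens-and-beans, and protein
foods sum meats, eggs, beans and nuts. These choices only affect the
pipeline convenience path; the scorer itself takes any density vector.

### GABA index (70 points)

The index based on the Colombian Food-Based Dietary Guidelines scores seven
food-group components at 10 points each. For each component the guideline
recommends daily portions at a reference energy intake (2650 kcal males,
2100 kcal females); consumption in portions per 1000 kcal is scored
linearly up to the implied recommended density and capped. The
grams-per-portion constants and per-(sex, age-group) recommendations in
`gaba_standards()` are editable defaults; only the 70-point ceiling is
fixed.

### Ultraprocessed calories

`upf_percentage()` is the energy share of items flagged ultraprocessed.
About 7% of items in real databases can be argued either way (the
*arepa* problem: industrial or homemade); these carry an `ambiguous` flag
and the `ambiguous_policy` argument computes the share under either
convention, which is the package's sensitivity analysis. The acceptable
macronutrient distribution (`amdr_classify()`) uses 4/4/9 kcal/g and
inclusive bands: carbohydrate 50–65%, protein 14–20%, fat 20–35% of energy.

## 2. Usual-intake estimation

One recall day measures usual intake with error. On a transformed scale
(default `log1p`; intakes are non-negative and right-skewed) the model is
one-way random effects,

$$x_{ij} = \mu + b_i + e_{ij},\qquad b_i \sim (0, \sigma_b^2),\quad
e_{ij} \sim (0, \sigma_w^2),$$

with variance components from the unbalanced method-of-moments (ANOVA)
estimators using Searle's $n_0 = (N - \sum n_i^2/N)/(a-1)$, and

$$\mathrm{BLUP}_i = \hat\mu + \lambda_i(\bar x_i - \hat\mu),\qquad
\lambda_i = \frac{\hat\sigma_b^2}{\hat\sigma_b^2 + \hat\sigma_w^2/n_i}.$$

Decisions:

- A negative moment estimate of $\sigma_b^2$ is clamped to zero, collapsing
  every BLUP to the grand mean — the honest answer when repeats show no
  stable between-person signal. On small cohorts this genuinely happens for
  noisy nutrients.
- Persons with a single recall are shrunk with the cohort-level components
  ($n_i = 1$), not passed through; they shrink *more* than persons with two
  days, which is the intended behaviour of a BLUP.
- The full ISU/PC-SIDE method (Box–Cox, heterogeneous within-person
  variance, percentile back-mapping) is out of scope; the simplified
  estimator preserves the shrinkage contract that the tests verify
  (component recovery, `|BLUP - mu| <= |xbar - mu|`, BLUP MSE below
  raw-mean MSE).
- Food groups are not BLUP-normalized, only nutrients and energy.

## 3. Microbiota processing

- **Rarefaction** (`rarefy_table()`) draws each sample's reads without
  replacement (multivariate hypergeometric) to a common depth, default the
  minimum sample sum; a single draw per sample, seeded. Samples below the
  target raise an error naming them — nothing is dropped silently.
- **Alpha diversity**: Shannon in natural log (the ecology convention; the
  base is an argument), observed OTUs, evenness $J = H/\ln S$ with $J = 0$
  for single-OTU samples.
- **UniFrac** is computed from branch-wise descendant proportions
  accumulated in one post-order traversal. Unweighted: unique branch length
  over union branch length. Weighted uses the *normalized* variant
  $\sum_b l_b |p_{Ab} - p_{Bb}| / \sum_b l_b (p_{Ab} + p_{Bb}) \in [0,1]$
  (the GUniFrac default); the raw variant is available with
  `normalized = FALSE`. Multifurcating trees are accepted — only branch
  lengths matter. Tests verify the traversal against an independent
  branch-enumeration oracle on all small trees and against phyloseq.
- **Abundant-OTU panel** (`filter_top_otus()`): rank by mean relative
  abundance, keep the top 100, drop OTUs whose median relative abundance is
  below 0.01% (rare OTUs are dominated by sequencing artifacts); ranking
  ties break lexicographically by OTU id for determinism.
- **Class profiles** pool classes whose cohort-median relative abundance is
  zero into `"Other"`.

## 4. Association layer

- **PCA** on z-scored variables (constant columns dropped with a warning);
  component signs are fixed so each loading column's largest-magnitude
  entry is positive, making score tables reproducible across platforms.
- **Adjustment**: every diet variable is residualized on dummy-coded city,
  sex, age group, BMI class and socioeconomic level before the
  random-forest stage; OTUs are left unadjusted (the diet side carries the
  confounding; a flag-equivalent is simply residualizing the OTU matrix
  yourself before the call).
- **PERMANOVA** partitions squared distances for a single factor;
  $p = (1 + \#\{F^* \ge F\})/(1 + n_{perm})$, so $p \ge 1/(n_{perm}+1)$
  and is never zero. Multi-term sequential decomposition is out of scope;
  per-factor calls match the reported per-variable $R^2$ convention.
- **Procrustes** centers and scales both configurations to unit sum of
  squares, takes the rotation from the SVD of the cross-product, and
  reports $m^2 = 1 - (\sum \sigma_k)^2$ and correlation $\sqrt{1 - m^2}$;
  significance by row permutation with the same +1 convention. Inputs in
  the pipeline are three diet-side axes (PCA scores, or the z-scored
  quality triple) against three principal-coordinate axes of each UniFrac
  matrix; dimensionality is an argument — three matches the number of
  interpreted components. Both UniFrac variants are always reported.
- **Random forest** (Rcpp, in-package): no regression-forest package is
  assumed at run time. Trees are CART with variance-reduction splits,
  `mtry = floor(p/3)`, node size 5, each tree trained on a random 2/3 of
  samples *without* replacement so the held-out third is the out-of-bag
  set — mirroring the train/test description the method follows rather
  than bootstrap resampling. Importance is the mean increase in OOB MSE
  under within-OOB permutation of a variable. "Selecting the model that
  maximizes explained variance" is operationalized as recursive feature
  elimination: halve the panel by importance, refit, and keep the subset
  with the best OOB $R^2$. The reference configuration uses 50,000 trees;
  tests and examples use 150–1000, which is statistically (not bit-wise)
  equivalent for rankings.

## 5. The synthetic world

The generator emulates a balanced urban cohort: five cities × two sexes ×
two age groups × three BMI classes dealt round-robin (every cell within one
person of every other), socioeconomic levels 2–4 holding >80% of the mass.
Recalls follow the random-effects energy model with sex means 2135/1750
kcal, between-person SD 250 kcal and a within:between variance ratio of 1.5
(the ratio is unknown for this population; 1.5 is a placeholder exposed as
`var_ratio`). 21% of persons get a second day — `ceiling(0.21 n)` by
convention, with an integer override (`n_repeat`) because a real cohort's
94/441 rounds differently. Each person draws items from a personal
repertoire (log-normal preference weights shared across their days): this
is what makes between-person nutrient variance identifiable from repeat
recalls, as in real data where people re-eat their habitual foods.

OTU counts follow a log-normal compositional model — softmax of a base
log-abundance (SD 2 across OTUs, Clostridia/Bacteroidia nudged up so
Firmicutes and Bacteroidetes dominate), covariate offsets with city (SD
0.45) > sex (0.2) > BMI (0.12), planted `effect_size * z(driver)` shifts,
and person-level noise (SD 0.6) — then multinomial draws at depths uniform
in 3667–102,660 reads. Log-normal + multinomial was chosen over
Dirichlet-multinomial so planted effects act transparently on one scale;
the person-noise SD is the overdispersion knob. Designated "SCFA-producer"
OTUs are labelled Clostridia and "bile-tolerant/pathogen" OTUs
Bacteroidia/Gammaproteobacteria, so recovery tests can phrase their
expectations in the guild vocabulary of the field.

What a green test does **not** establish: the generator has no sequencing
error, chimeras, batch effects, compositional interactions between OTUs,
or realistic rank-abundance tails; diet–covariate confounding is present
only through the energy model. Recovery of planted effects shows the
machinery works, not that effect sizes in any real population are
detectable at these sample sizes.

All randomness flows from one master seed through a documented
congruential stream split (`split_seed()`), so end-to-end runs are
byte-identical under a fixed seed while stages remain decoupled.

## 6. Numerical choices and degenerate inputs

- Permutation p-values use the +1 convention everywhere.
- An all-zero distance matrix makes PERMANOVA meaningless and errors.
- Densities are undefined at `kcal <= 0` and error rather than return 0.
- BLUP estimation refuses cohorts with no repeated recalls (identifiability)
  and instructs pass-through.
- Importance ties and abundance-ranking ties break by name for determinism.
- Procrustes singular-value sums are clamped at 1 against rounding above 1.

## 7. Known limitations

- The HEI component mapping from 11 food groups is coarse (no juice/whole
  fruit split; protein foods pooled).
- The BLUP is homoscedastic on the transformed scale; nutrients with
  strongly person-dependent day-to-day variance are shrunk with one
  cohort-level $\sigma_w^2$.
- PERMANOVA is single-factor; confounder-adjusted beta-diversity tests
  (e.g. marginal multi-term models) are not provided.
- The random forest is a regression forest only, with permutation
  importance computed per tree on OOB samples; it does not implement
  surrogate splits or missing-value handling.
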