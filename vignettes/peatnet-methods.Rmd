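---
title: "Methods: models, defaults and design choices in peatnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, defaults and design choices in peatnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

peatnet identifies keystone bacterial taxa associated with soil carbon
mineralization in peatlands. This vignette documents the statistical
machinery, the defaults and why they were chosen, the synthetic-data
generator used to validate the pipeline, and the limits of what validation
on synthetic data can show.

## The analysis pipeline

For each land-use group (natural and cultivated peatlands are analysed as
separate networks, on disjoint sample sets), `run_group_analysis()`
executes:

1. archaea removal (`remove_archaea()`),
2. rarefaction to a common depth (`rarefy()`),
3. selection of the most abundant taxa (`top_abundant()`, default 2000),
4. SparCC correlation estimation (`sparcc()`),
5. permutation p-values (`permutation_pvalues()`),
6. network thresholding at |ρ| ≥ 0.6 and p < 0.05 (`build_network()`),
7. module detection (`detect_modules()`),
8. Zi–Pi node-role classification (`node_roles()`),
9. module eigengenes (`module_eigengene()`),
10. module–trait correlations (`module_trait_correlation()`),
11. per-taxon GS/MM scores and hub-gene calls (`gene_scores()`,
    `hub_genes()`),
12. the keystone report (`keystone_report()`).

Every stage appends to the table's provenance log, and a manifest with
seeds, thresholds and file checksums is written when an output directory
is configured.

## Soil carbon chemistry

`compute_cmr()` evaluates

$$\mathrm{CMR} = \Delta c \cdot V \cdot M / (m \cdot \Delta t \cdot 22.4)
\cdot \alpha / \mathrm{SOC}, \qquad \alpha = 273/(273 + T).$$

Unit bookkeeping lives in one place: Δc in volume ppm is µmol CO2 per mol
headspace gas, so Δc·V/22.4·α is µmol CO2, ×M (12 g/mol, the carbon in
CO2 — fixed at 12 because the output is expressed in mg *C*) gives µg C,
and dividing by soil mass (kg), duration (d) and SOC (g C/kg soil) yields
mg C·kg⁻¹ SOC·d⁻¹. The headspace volume V is a direct input; how it is
derived from flask and soil volume is a lab bookkeeping question outside
the formula. Whether gas-chromatograph readings were already
temperature-corrected cannot be inferred from the reported protocol, so
the formula is applied exactly as stated, α included.

The DOC carbohydrate calibration (49204·carb − 1.7606, in %) can go
negative below its calibration range; such values are *flagged*, not
clamped, so out-of-range inputs stay auditable
(`carbohydrate_content()$below_range`).

## SparCC

SparCC estimates correlations between latent (basis) abundances from
compositional fractions. From log fractions it forms the pairwise
log-ratio variance matrix `t`, solves the linear system with p−1 on the
diagonal and 1 elsewhere for basis variances ω, and sets
ρ_ij = (ω_i + ω_j − t_ij)/(2√(ω_i ω_j)). Strongly correlated pairs
(|ρ| > 0.1, strongest first) are iteratively excluded from the system and
it is re-solved, up to 10 rounds — the exclusion step is what removes the
bias that a few genuinely correlated pairs would otherwise spread through
the basis-variance estimates. The full estimate repeats this over 20
Dirichlet-smoothed fraction draws (counts + 1 pseudocount) and takes the
element-wise median.

These internals (20 resamples, 0.1 exclusion threshold, 10 rounds, median
aggregation, +1 pseudocount) are the original method's conventions; the
analysis protocol we implement names only the method and the two
downstream thresholds (0.6, 0.05), so every internal value is exposed in
`sparcc_config()` rather than hard-coded.

Numerical guards: non-positive basis variances are floored at 1e-10 with a
warning; correlations are clamped to [−1, 1]; and the exclusion loop never
lets a component's diagonal entry in the system drop below 2 — repeated
exclusions in small communities can otherwise make the system exactly
singular.

**Significance.** The null shuffles each taxon's counts across samples
independently, destroying all between-taxon association while preserving
marginals, recomputes the full SparCC matrix per permutation (100 by
default) and uses the add-one estimator
p = (1 + #{|ρ_perm| ≥ |ρ_obs|})/(1 + B). Tests are two-sided on |ρ|,
matching the use of both positive and negative edges. No multiple-testing
correction is applied by default (the protocol states a raw 0.05 level);
`p_adjust = "BH"` is available.

## Modules and node roles

Module detection is greedy modularity maximization
(Clauset–Newman–Moore via igraph) on the *unweighted, unsigned* adjacency
— edge signs are standard to ignore for topology and are retained for
reporting. Greedy was chosen over Louvain for determinism; Louvain is
available behind `method = "louvain"` with seed control. Isolated nodes
are excluded from the partition and reported. One numerical subtlety: the
greedy dendrogram can contain merges whose modularity ties the maximum
within floating-point noise (a single clique is the minimal example), so
the partition is cut at the fewest communities within 1e-10 of the
maximum. Module labels are renumbered by first appearance in node-ID
order, making them independent of input order.

Roles use Zi = (k_is − mean_s)/sd_s (within-module degree z-score, with
mean/sd over the nodes of module s) and Pi = 1 − Σ_t (k_it/k_i)². When a
module's within-degrees have zero spread (small or degree-regular
modules), Zi is defined as 0 rather than NaN so classification never
crashes; this is logged behaviour, not silent. Classification uses
module hub (Zi > 2.5, Pi ≤ 0.625), connector (Zi ≤ 2.5, Pi > 0.625),
network hub (both exceeded), peripheral otherwise. Values falling exactly
on a threshold go to the lower category — the convention for boundary
cases is not specified by the thresholds themselves, and strict
inequalities match how they are printed.

## Eigengenes, GS/MM and keystones

Module eigengenes are computed from per-taxon standardized relative
abundances (mean 0, sd 1 across samples): the eigengene is the first
left-singular vector of the samples × members matrix (unit norm), and its
share of total standardized variance is reported. Which abundance scale to
use is genuinely open (counts, relative, transformed); standardized
relative abundances were chosen because standardization makes the
eigengene scale-free per taxon and relative abundances are what the
compositional pipeline already works with. Principal components are
sign-ambiguous, so the eigengene is oriented to correlate positively with
the mean standardized member profile; when members cancel to a flat mean
profile the orientation is undefined and left as computed. Constant
members are dropped with a warning; modules reduced below 2 members are
skipped and reported.

GS is each taxon's Pearson correlation with an external trait, by default
CMR — the trait actually used for gene screening in this analysis context;
the target trait is an argument, not a constant. MM is the correlation
with the own-module eigengene. Hub genes require both p < 0.05 (raw). The
keystone rule is

    keystone = (hub gene OR critical node) AND function flag,

where critical nodes are module hubs, connectors and network hubs, and
the carbon-metabolism function flag is a *user-supplied annotation*:
literature-based functional assignment is not a computation this package
can perform. With no annotation table, all candidates pass the gate and a
warning says the criterion was not screened.

All correlation/p pairs in the package flow through one routine,
`pearson_with_p()` (t transform on n−2 df, two-sided).

## The synthetic generator

`generate_design()` emulates the paired sampling layout: 3 sites × 2
land-use types × 4 plots × 2 depths = 48 composite samples (every count
configurable). `generate_counts()` draws, per sample, latent
log-abundances = per-taxon baseline (Normal(0,1), drawn once) + an
equicorrelated Gaussian block per planted module (`within_correlation`
inside, 0 elsewhere; positive-definiteness is validated), passes them
through softmax and draws multinomial counts at the configured depth, so
column sums are exact. The logistic-normal–multinomial map was chosen
because SparCC's own generative assumptions are log-ratio based: the
generator plants correlations on the scale the estimator is supposed to
recover. Archaeal lineages (to exercise the archaea filter) are assigned
only to background taxa so planted modules survive filtering intact.

`generate_traits()` builds each linked trait as
sign(r)·G + σ·ε, where G is the module's mean standardized latent signal
(itself standardized), ε is independent Gaussian noise and
σ² = 1/r² − 1 is solved in closed form (`solve_noise_sd()`) so the
expected trait–signal correlation equals the target r — closed-form rather
than numerically tuned, which keeps generation deterministic. Unlinked
traits are independent noise. A positive affine map per trait
(`trait_scales`) puts traits on realistic measurement scales without
touching any correlation.

**Scenarios.** `scenario_natural()` and `scenario_cultivated()` are the
two default study conditions, mirroring the separate per-land-use
analyses. Each plants three community modules (25/25/20 taxa at the
default 300-taxon community, 0.85/0.85/0.7 within-correlation) and ties
CMR to module 1 at link strength 0.9 — a strong but not deterministic
coupling, consistent with module–trait correlations reported as highly
significant at n = 24. The other trait links are set to
(field value)/0.9, because two traits tied to the same signal with
independent noises have expected mutual correlation equal to the product
of their link strengths. The planted field values are the observed
trait–CMR correlations for the two systems: carbohydrates–CMR = 0.60
(natural), phenolics–CMR = −0.58 and carbohydrates–CMR = −0.66
(cultivated). These constants live in the scenario constructors, not in
operation logic. Community size (300 taxa) and depth (5000 reads) are
deliberate desk-scale choices: large enough for compositional effects to
matter (depth ≥ 10 × taxa), small enough that hundreds of replicates run
in seconds. Per-site biological detail (peat thickness, cultivation age)
is recorded as metadata only; no site-specific effect sizes are planted
because none are quantified to plant.

**What the generator does not emulate.** Real 16S data have heavier
zero-inflation and overdispersion than a multinomial over logistic-normal
latents, taxonomically structured (not block-random) correlation,
depth-dependent community shifts, and spatial autocorrelation between
plots. Passing the synthetic recovery tests therefore shows the
*machinery* is correct — SparCC recovers planted basis correlations,
module detection recovers planted blocks (adjusted Rand index ≥ 0.9 at
within-correlation 0.9), eigengene–trait associations recover planted
effect sizes — not that any particular real dataset satisfies the model.

## Filtering conventions

Rarefaction is subsampling without replacement (multivariate
hypergeometric, via vegan), the community convention; samples below the
target depth are dropped rather than kept unrarefied, with a loud log
entry, because mixing rarefied and unrarefied samples silently biases
downstream variances. The study convention for depth is 39 575 reads; the
pipeline default rarefies to the minimum sample total so synthetic and
shallower datasets run unchanged. `top_abundant()` breaks ties at the
abundance cutoff by taxon ID (lexicographic), making selection
reproducible. Both Greengenes-style `d__`-prefixed and bare SILVA
lineages are accepted by the archaea filter, case-insensitively. Depths
(0–15 and 15–30 cm) are pooled within each land-use group's network by
default — the grouping variable is configurable — giving 24 samples per
network under the default design.

## Problem sizes in the test suite

The suite validates SparCC on 50-taxon × 100-sample tables (null) and
20-seed planted-pair panels; permutation calibration at 100 permutations;
module recovery on two 10-taxon blocks among 40 taxa at 100 samples; and
trait-effect recovery on 200 replicates of 24 samples. These sizes were
chosen so that each property is measured with comfortable statistical
margin while the whole suite runs in about a minute.

## Known limitations

- SparCC assumes a large, diverse composition; with very few taxa (< ~10)
  basis-variance estimates are rough and the exclusion guard becomes
  active. The hard floor is 4 taxa.
- Permutation p-values are lower-bounded at 1/(B+1); with the default
  B = 100 the smallest attainable p is ~0.0099, which is adequate for an
  α = 0.05 gate but not for fine p-value ranking.
- Greedy modularity has a known resolution limit; very small modules
  attached to large ones may be absorbed.
- The keystone call is correlational evidence plus annotation; it does not
  establish causal influence on carbon mineralization.
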