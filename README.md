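# peatnet

Identify keystone bacterial taxa that regulate soil carbon mineralization
in peatlands — an end-to-end, seed-reproducible R pipeline from OTU count
tables and soil traits to co-occurrence networks, node roles, module
eigengenes and keystone calls.

## Who it is for

Soil microbial ecologists comparing paired land-use systems (e.g. natural
vs. rice-cultivated peatlands) who want to move from a taxa-by-samples
count table plus soil chemistry measurements to a defensible list of
keystone taxa, with every filtering and inference step logged, seeded and
testable against synthetic data with known ground truth.

## What it computes

**Soil carbon chemistry.** The carbon mineralization rate from a closed
CO2 incubation,

    CMR = Δc · V · M / (m · Δt · 22.4) · α / SOC,   α = 273 / (273 + T)

in mg C · kg⁻¹ SOC · d⁻¹ (Δc in volume ppm, V headspace litres, M = 12
g/mol for the carbon in CO2, m soil mass in kg, Δt days, SOC in g C/kg
soil); the FTIR 1630/1030 peak-area recalcitrance index; and the DOC
carbohydrate calibration (carbohydrate % = 49204 · carb − 1.7606, carb the
area-normalized ~1030 cm⁻¹ peak height).

**Network inference.** SparCC compositionally robust correlations between
taxa (log-ratio variance system, iterative strong-pair exclusion,
Dirichlet resampling with median aggregation) with permutation p-values
(per-taxon shuffling null, add-one estimator), thresholded into a
co-occurrence network at |ρ| ≥ 0.6 and p < 0.05.

**Topology and keystones.** Greedy-modularity module detection; per-node
within-module degree z-score Zi and participation coefficient
Pi = 1 − Σ_t (k_it/k_i)², classified as module hubs (Zi > 2.5,
Pi ≤ 0.625), connectors (Pi > 0.625), network hubs (both) or peripheral;
module eigengenes (first principal component of standardized member
abundances) correlated against soil traits; per-taxon gene significance
(GS, correlation with CMR) and module membership (MM, correlation with the
own-module eigengene); hub genes (both p < 0.05); and the final keystone
rule: (hub gene OR critical node) AND carbon-metabolism function flag.

**Synthetic ground truth.** A logistic-normal–multinomial generator
emulating a 3-site × 2-land-use × 4-plot × 2-depth design (48 samples)
with planted correlation modules and planted trait–module associations at
analytically controlled effect sizes, so every downstream stage can be
validated against known truth.

## Worked example

```r
library(peatnet)

# a synthetic natural-peatland community: two planted modules of 12 taxa,
# module 1 anchored to the carbon mineralization rate
cfg <- synth_config(
  n_taxa = 60, sequencing_depth = 3000,
  module_spec = list(list(size = 12, rho = 0.9), list(size = 12, rho = 0.9)),
  trait_links = data.frame(trait = "CMR", module = 1L, target_r = 0.85),
  seed = 101
)
sim <- simulate_study(cfg, design_spec(n_sites = 5, n_plots_per_type = 5),
                      land_use = "natural")

res <- run_group_analysis(
  sim$counts, sim$metadata, sim$traits,
  run_config(top_n = 60,
             sparcc = sparcc_config(n_permutations = 50, seed = 101),
             seed = 101))

res$natural$network
#> Co-occurrence network: 58 nodes, 106 edges ( 106 positive / 0 negative )
res$natural$partition
#> Module partition: 2 modules over 23 nodes (Q = 0.47 )
#> Isolated nodes excluded: 35

mt <- res$natural$module_trait
mt[mt$trait == "CMR", ]
#>    module trait          r            p  n stars
#> 1 module1   CMR  0.7306367 1.710528e-09 50   ***
#> 2 module2   CMR -0.1499109 2.987558e-01 50
```

Both planted blocks are recovered as network modules (the 35 background
taxa stay isolated and are excluded); the eigengene of the recovered
module 1 correlates strongly and significantly with CMR (r = 0.73, the
planted 0.85 link attenuated by sampling noise), while module 2, planted
without a trait link, does not. Its 12 members are all flagged as hub
genes (GS ≈ 0.6, MM ≈ 0.9, both p < 0.05) and hence keystone candidates:

```r
sum(res$natural$keystones$keystone)
#> 12
```

The chemistry helpers work standalone:

```r
rec <- incubation_record(c0 = 400, c1 = 900, void_volume_V = 0.25,
                         soil_mass_m = 0.03, duration_dt = 10 / 24,
                         temperature_T = 20, soc = 250)
compute_cmr(rec)
#> [1] 19.96587    # mg C / kg SOC / d
```

## Documentation

See the methods vignette (`vignettes/peatnet-methods.Rmd`) for the model,
its assumptions, the defaults and their rationale, and known limitations.
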