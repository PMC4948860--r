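# stageshift

Community assembly processes leave signatures in how the diversity of a
plant community changes between life stages. On habitat islands, a cohort
of seedlings is winnowed to saplings and then to adult trees; whether
species richness (SD) and Faith's phylogenetic diversity (PD) fall or rise
across those transitions — relative to what random survival would produce —
distinguishes environmental filtering, dispersal limitation, interspecific
competition, density dependence, and plain chance. `stageshift` is an R
package for ecologists who have (or want to simulate) island × species
abundance tables for three life stages, a phylogeny, and island attributes,
and who want per-island mechanism calls plus an attribution of those calls
to landscape structure (area, shape, isolation).

## The statistic

For each island and transition (SS: seedling → sapling, ST: sapling →
tree), and each diversity metric D ∈ {SD, PD}:

    Z_D = [ (D_obs,old − D_obs,young) − mean(D_ran,old − D_ran,young) ]
          / sd(D_ran,old − D_ran,young)

where the `ran` values come from 1,000 randomizations of each stage
*independently*: an individual-pool permutation that fixes island totals
and species totals (for SD), and the independent-swap algorithm that fixes
occurrence frequencies, island richness and species totals (for PD).
Significantly negative Z_D = clustering, positive = overdispersion; the
joint (SD, PD) pattern maps to mechanisms (both clustered → filtering or
dispersal limitation; SD clustered with PD overdispersed → competition;
both overdispersed → density dependence). Regression trees (a built-in
CART) then attribute per-island Z_D to island attributes and report the
apparent ("approximate") R² per split. Blomberg's K with a permutation
test is included for checking the phylogenetic niche conservatism that the
PD logic assumes.

## Worked example

Simulate a 29-island + mainland landscape in which environmental filtering
(strength 12) acts on the seedling-to-sapling transition, then run the full
pipeline:

```r
library(stageshift)

cfg <- scenario_config(n_islands = 29, n_species = 92,
                       process_ss = "filtering", strength = 12, seed = 2024)
ds <- simulate_dataset(cfg)
ds
#> synthetic_dataset: 30 sites x 92 species, processes SS=filtering ST=neutral (strength 12.00)
#>   individuals: seedling=30000, sapling=3535, tree=843

report <- run_analysis(ds$communities, ds$phylogeny, ds$attributes,
                       n_rand = 999, seed = 7)
report
#> assembly_report
#>   30 islands, n_rand = 999, method = t_test, seed = 7
#>   sign counts (z > 0 / z < 0):
#>     SS PD: 0 increase / 30 decrease
#>     SS SD: 0 increase / 30 decrease
#>     ST PD: 26 increase / 4 decrease
#>     ST SD: 30 increase / 0 decrease
#>   SD~PD Spearman rho by stage: seedling 0.759, sapling 0.922, tree 0.765
#>   tree SS/PD: driver isolation_km, apparent R^2 0.140
#>   tree SS/SD: driver area_ha, apparent R^2 0.338
#>   tree ST/PD: driver isolation_km, apparent R^2 0.187
#>   tree ST/SD: driver area_ha, apparent R^2 0.256
```

Reading the output: standardized SD and PD *decrease* across SS on every
island (the filtering signature: clustering of both metrics), while the ST
transition — generated neutrally — shows the opposing trend that nested
cohorts produce after a filtered sapling stage. The regression tree for
SS/SD picks island area as the primary driver (apparent R² 0.34), which is
the generative truth: in the simulator, smaller islands hold fewer habitat
types and filter hardest. `assembly_calls(report$shifts)` returns the
per-island mechanism table, `autoplot(report$shifts)` plots the Z_D field,
and `write_dataset(ds, dir)` / `run_analysis(..., out_dir = dir)` exchange
everything through plain CSV/Newick/TSV/JSON files. A thin command-line
wrapper with `simulate`, `run` and `ingest-supplement` subcommands lives at
`inst/cli/stageshift.R`.

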