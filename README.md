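# goatclines

Did the post-domestication dispersal of goats leave a detectable footprint
in the genomes of modern breeds? An overland range expansion proceeds by
serial founder events, each eroding expected heterozygosity by a factor
(1 − 1/(2N_b)), so breed diversity should decline — and differentiation
from origin-adjacent breeds should grow — with distance from the region of
early goat management. `goatclines` is an R package plus analysis workflow
for testing exactly that on SNP-array genotype data, written for population
geneticists working with livestock diversity panels.

The pipeline, per continent:

1. **QC** (`filter_variants`): drop individuals with missing call rate
   > 0.1, then unmapped SNPs, SNPs with missing rate > 0.05, MAF < 0.05,
   and exact-test Hardy–Weinberg outliers (p ≤ 0.001), in that order;
   `representative_subsample` caps over-sampled breeds while preserving
   their covariance structure.
2. **Diversity** (`diversity_by_breed`): per-breed observed heterozygosity
   H_o; unbiased expected heterozygosity H_e = (2n/(2n−1))·2p̂(1−p̂)
   averaged over loci; F_is = 1 − H_o/H_e; Weir–Cockerham θ (F_ST) against
   a reference breed near the origin (default the Iranian Markhoz).
3. **Geodesy + clines** (`distances_to_origin`, `pearson_cline`,
   `cline_report`): Vincenty WGS84 ellipsoid distance of each sampling site
   to Ganj Dareh (34.27°N, 47.47°E, central Zagros Mountains), then Pearson
   r of each statistic against distance with exact t-based two-sided
   p-values, over documented breed subsets (with/without insular
   populations; African commercial breeds always excluded).
4. **Maps and structure** (`idw_interpolate`, `pca_genotypes`):
   inverse-distance-weighted surfaces in ten equal classes, and
   Patterson-normalized genotype PCA with per-breed centroids.
5. **Validation** (`simulate_dispersal`, `expected_he_decay`,
   `run_dispersal_pipeline`): a seeded serial-founder simulator whose He
   decay has the closed form E[2p₀(1−p₀)]·(1 − 1/(2N_b))^steps, pushed
   through the full pipeline to confirm the method recovers a known cline.

A packaged table (`load_goat_tables()`) carries published per-breed
statistics and coordinates for 105 goat populations (40 European, 43
African, 22 Asian), so the distance/correlation layers run and are verified
without the separately deposited genotype data.

## Worked example

```r
library(goatclines)

tab <- load_goat_tables()$table
cline_report(tab)[, c("subset_label", "statistic", "n_breeds", "r", "p")]
#>               subset_label statistic n_breeds       r        p
#>                 europe_all        ho       40 -0.4731 0.002049
#>                 europe_all        he       40 -0.4002 0.010504
#>                 europe_all       fst       40  0.3701 0.018738
#>    europe_no_british_irish        ho       38 -0.2800 0.088647
#>    europe_no_british_irish        he       38 -0.2435 0.140644
#>    europe_no_british_irish       fst       38  0.3023 0.065104
#>        africa_with_islands        ho       40 -0.5090 0.000796
#>        africa_with_islands        he       40 -0.5329 0.000400
#>        africa_with_islands       fst       40  0.5708 0.000120
#>          africa_no_islands        ho       37 -0.4576 0.004409
#>          africa_no_islands        he       37 -0.4895 0.002105
#>          africa_no_islands       fst       37  0.6154 0.000050
#>                   asia_all        ho       22 -0.3202 0.146351
#>                   asia_all        he       22 -0.2594 0.243621
#>                   asia_all       fst       21  0.2369 0.301248
```

Reading the table: African diversity declines significantly with distance
to Ganj Dareh whether or not island populations are included (H_o r ≈
−0.46 to −0.51), and differentiation from the Markhoz rises in mirror
image (F_ST r ≈ 0.57–0.62) — the signature of an overland serial-founder
expansion. The apparent European cline (r = −0.47) collapses once the
low-diversity British and Irish goats are removed, and Asia shows no
significant cline at all: on those continents, maritime dispersal and
millennia of gene flow plausibly erased the founder signature.

The same machinery validates itself on synthetic data with a known cline:

```r
out <- run_dispersal_pipeline(dispersal_config(seed = 7))
out$he_cline
#>   statistic subset_label n_breeds n_dropped          r            p
#> 1        he    simulated       12         0 -0.9964521 4.400838e-12
```

Twelve simulated populations, 0–11 founder bottlenecks of 25 diploids each
along a 500 km-spaced route: the pipeline recovers the diversity cline at
r ≈ −0.996.

The numbered scripts under `analysis/` run the full workflow narrative
(`01_published_tables.R` … `05_simulation_study.R`) and write their tables
under `results/`.

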