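---
title: "Measuring post-domestication diversity clines in goat breeds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring post-domestication diversity clines in goat breeds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goatclines)
```

## The question and the model

Goats were domesticated in the Fertile Crescent roughly ten thousand years
ago and then spread with their keepers across Europe, Africa and Asia. An
overland range expansion proceeds by serial founder events: each newly
founded population carries only a sample of its source's allele copies, so
expected heterozygosity is eroded multiplicatively at every founding step.
If modern breeds still carry that signature, their genome-wide diversity
should decline — and their genetic differentiation from breeds near the
origin should grow — with geographic distance from the region of early goat
management. Sea-borne, leap-frog dispersal and later gene flow (trade,
cosmopolitan improvement breeds, artificial insemination) erase the
gradient, so presence or absence of a cline is informative about how each
continent was colonized.

`goatclines` implements that test end to end: genotype QC, per-breed
diversity statistics, ellipsoid distances of sampling sites to Ganj Dareh
(a Neolithic settlement in the central Zagros Mountains, used as the
origin; 34.27&deg;N, 47.47&deg;E), correlation of diversity with distance
over documented breed subsets, interpolation surfaces, genotype PCA, and a
serial-founder simulator that provides an analytic ground truth. A packaged
table carries the published per-breed statistics of 40 European, 43 African
and 22 Asian goat populations, so the correlation layer can be exercised
and checked without the (separately deposited) genotype data.

## Estimators

**Observed heterozygosity** is the fraction of heterozygous individuals per
locus among non-missing calls, averaged unweighted over loci.

**Expected heterozygosity** uses the unbiased Nei gene diversity,
$\hat H_e = \frac{2n}{2n-1}\,2\hat p(1-\hat p)$ per locus with $n$
non-missing genotypes — the probability that two allele copies drawn
*without replacement* from the sample differ. The small-sample factor
matters here because it makes the estimator unbiased for $2p(1-p)$ at the
population level, which is what the simulator's closed-form decay predicts.

**Fis** is reported as $1 - \bar H_o / \bar H_e$ from the per-breed means,
the contrast actually printed alongside the published tables. AMOVA-style
software weights loci by their diversity when aggregating, which is why a
published Fis column can differ in the third decimal from the ratio of the
published rounded means; a locus-weighted variant
(`fis_locus_weighted = TRUE` in `diversity_by_breed()`) is provided for
that convention. Negative Fis means a heterozygote excess (admixture-like),
positive an excess of homozygotes (inbreeding-like).

**FST** against a reference breed (default the Iranian Markhoz, raised near
the origin) is the two-population Weir–Cockerham (1984) $\theta$, combined
across loci as the ratio of summed variance components
$\sum a / \sum(a+b+c)$, with loci monomorphic across both populations
excluded. Slightly negative estimates are legitimate noise around zero. The
published per-breed FST values were produced by a different (AMOVA-based)
implementation; numeric identity with them is not claimed, and the packaged
published values are what the cline layer consumes.

**Hardy–Weinberg QC** uses the conditional exact test: given the observed
allele counts, the heterozygote count has a known distribution over values
of the same parity, and the p-value is the total probability of all
outcomes no more probable than the observed one. No mid-p correction is
applied, matching standard SNP-QC toolchains. The test suite checks the
implementation against an exhaustive integer-arithmetic enumeration for
every genotype table with up to 30 individuals.

## QC and subsampling

`filter_variants()` applies, in a fixed and reported order: individuals
with missing rate > 0.1; then unmapped SNPs, SNPs with missing rate > 0.05,
SNPs with MAF < 0.05, and SNPs with exact-test Hardy–Weinberg $p \le
0.001$, each criterion evaluated on the survivors of the previous one with
MAF and HWE computed over all retained individuals pooled. Pooled HWE is
the default because filtering is applied to continental merged data sets;
whether the original toolchain pooled or stratified is not documented, so a
per-breed mode (`hwe_by_breed = TRUE`, SNP dropped if it fails in any
breed) is available behind a flag. Thresholds of 0 (MAF, HWE) or 1
(missingness) disable a filter, making the identity configuration
expressible.

`representative_subsample()` reduces an over-sampled breed to a target size
(published practice: 15–50 individuals per breed) while preserving its
variance structure: it minimizes the Frobenius distance between the
subsample's and the full breed's genotype covariance over the top five
principal axes, by greedy swap refinement from a seeded random start. The
covariance uses the divide-by-$n$ normalization, under which a balanced
pick from duplicated genotypes reproduces the full covariance exactly. The
original tool's algorithm is unpublished at formula level, so equivalence
with it is not claimed; determinism and dominance over random subsets are
the tested guarantees.

## Geodesy and the cline layer

Distances are inverse geodesics on the WGS84 ellipsoid
(`geosphere::distVincentyEllipsoid`, the same routine used for the
published distances). Correlations use the Pearson coefficient with the
two-sided p-value from the exact $t$ transform on $n-2$ degrees of freedom
— preferred over the normal approximation because continental breed counts
are small — and the suite verifies the $t$-based p against a
1000-permutation null. Rows with an absent statistic or distance are
dropped pairwise and counted.

Subset presets encode the documented analysis sets: Africa always excludes
the three commercial South African breeds (Boer, Savanna, Kalahari Red,
part-Asian ancestry), the African island set is Madagascar (Menabe, Sofia)
plus the Canary Islands Palmera, and the European "no British/Irish" preset
excludes the Old English and Old Irish goats. Which Mediterranean-island
breeds the published European FST re-analysis removed is ambiguous, so a
broader `europe_no_all_islands` preset (also excluding the Corsican,
Sardinian, Balearic and Sicilian breeds) exists but is not used for any
verification.

Two reproduction limits were established quantitatively and are asserted as
such rather than hidden. First, the published distances derive from
unrounded sampling coordinates: recomputing from the printed
two-decimal-degree coordinates leaves residuals up to about 0.6 km (0.005
degrees is about 0.55 km on the ground), and no single origin choice
removes them, so distance reproduction is verified to a 1 km bound, not to
the printed metre-level precision. Second, with the documented two-breed
exclusion the Europe-minus-British/Irish heterozygosity correlations
compute to about −0.28/−0.24, not the published −0.22/−0.22; no exclusion
superset over the island and northern candidates reproduces the published
pair, so that single published value is treated as not recoverable from the
published table columns. All other published correlations and the
continental means reproduce to well within ±0.01.

## Interpolation surfaces

`idw_interpolate()` is plain inverse-distance weighting with all points
contributing, default power 2 (the common GIS default), cell values being
convex combinations of the data. Distances from cell centres to sites are
great-circle rather than planar degrees, a deliberate divergence from
unspecified GIS projection settings, because planar degrees are anisotropic
at continental extents. A cell centre within $10^{-9}$ degrees of a site
takes the site's value exactly. Classing is into $k$ equal-width intervals
(default 10) with half-open boundaries — a value exactly on a boundary
joins the upper class, and the global maximum joins class $k$. No figure-level
numeric reproduction of published maps is attempted (no gridded values are
published); the tested claims are structural, e.g. that Madagascar falls in
the lowest He classes of the African surface and that the European Fis
surface is predominantly negative near sampled breeds.

## PCA

`pca_genotypes()` uses Patterson normalization (centre by mean call, scale
by $\sqrt{2\hat p(1-\hat p)}$), mean-imputes missing calls as zero after
centring, and eigendecomposes the individual covariance. Component signs
are fixed by forcing the largest-magnitude SNP loading positive. Breed
centroids are unweighted means of member scores on PC1/PC2, the standard
device for displaying structure across a hundred breeds without
overplotting. Equivalence with any specific published PCA coordinates is
not claimed (none are published numerically).

## The simulator and what passing tests mean

`simulate_dispersal()` implements the pure-drift serial-founder model:
origin allele frequencies i.i.d. Uniform(0.05, 0.95) (array-like common
variants), populations chained along the route, each founding event a
binomial resample of $2N_b$ allele copies, genotypes drawn Binomial(2, p)
within populations (Hardy–Weinberg), calls masked missing independently,
coordinates placed by geodesic steps along a bearing so that distance to
the origin grows with route position. The chained design (population $k$
descends from $k-1$) is what "serial founder" means demographically and
also makes differentiation grow with route separation. Defaults are the
study conditions used throughout validation: 12 populations, founder steps
0–11, $N_b = 25$, 30 sampled individuals, 2000 loci, 1% missingness,
500 km spacing. A `migration_rate` flag mixes each population's
frequencies with its upstream neighbour's — the mechanism invoked to
explain absent clines — and is 0 by default.

The model was chosen over a coalescent simulator because it has a
closed-form validation surface: $E[H_e] = E[2p_0(1-p_0)]\,(1 -
\frac{1}{2N_b})^{\text{steps}}$, with the origin expectation available
analytically for the uniform law. The acceptance layer runs 100 seeded
replicates of the full pipeline and requires the He-versus-distance
Pearson $r$ to be below −0.8 in at least 95 of them, and the per-step mean
He (on unfiltered genotypes, since MAF filtering selectively removes
drifted-down loci and would bias He upward) to sit within three Monte
Carlo standard errors of the closed form at every step count.

What the generator does not emulate: linkage disequilibrium, selection
(including trypanosomiasis-driven pressure), realistic geography, uneven
sampling, ascertainment bias of array SNPs, or admixture beyond
nearest-neighbour mixing. Passing tests therefore demonstrate that the
statistics and the pipeline plumbing are correct and that the method
recovers a cline when the generating process matches its assumptions — not
that real breed histories satisfy those assumptions.

## Numerical choices

* Allele coding: the counted allele at each SNP is the lexicographically
  later observed allele — deterministic and irrelevant to every statistic
  used (all are symmetric in the allele labels). PED round-trips preserve
  codes exactly when both alleles are observed; a sample-monomorphic SNP
  necessarily reads back as all-counted-allele, the same behaviour as the
  standard toolchain.
* Exact-test ties: probabilities equal to the observed one are included
  using a $1 + 10^{-12}$ relative tolerance, guarding against floating-point
  ordering artifacts in what is mathematically a sum over exact rationals.
* Greedy subsample: first-improvement swaps, stopping when no swap improves
  the objective by more than $10^{-12}$; seeded restart gives determinism.
* Degenerate inputs error loudly and early: empty marker sets, all-missing
  loci, zero-variance cline inputs, constant surfaces, monomorphic-only PCA
  input. The one deliberate warning-not-error is QC removing every SNP,
  which returns an empty matrix so batch pipelines can continue.
* Problem sizes in the test and acceptance layers (replicate counts,
  loci per replicate) are chosen so the full validation runs in minutes on
  one core while leaving Monte Carlo error well below every asserted
  tolerance; they are stated next to each check.

## Known limitations

The published genotype deposit is not packaged, so genotype-level survivor
counts of the original QC are not reproduced here; the cline layer is
verified against the published per-breed tables and the genotype layer
against oracles and simulation. Published F_ROH values (runs-of-homozygosity
inbreeding) live in supplementary material not packaged here; the column
exists in the interface and F_ROH clines compute wherever a user supplies
values. ADMIXTURE-style model-based clustering is out of scope as an
external published tool.
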