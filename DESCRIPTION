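Package: goatclines
Title: Post-Domestication Diversity Clines in Goat Breeds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for testing whether the genome-wide diversity
    of domestic goat breeds declines with distance from the Fertile Crescent
    origin of goat husbandry (Ganj Dareh, western Iran). Reads PLINK-format
    SNP genotypes, applies marker and individual quality filters (minor
    allele frequency, call rate, exact Hardy-Weinberg test), computes
    per-breed observed and expected heterozygosity, Fis and Weir-Cockerham
    FST against a reference breed, measures Vincenty ellipsoid distances of
    breed sampling sites to the origin, and correlates diversity with
    distance over configurable breed subsets. Includes inverse-distance
    weighted interpolation surfaces, genotype PCA with breed centroids, a
    serial-founder dispersal simulator with closed-form heterozygosity decay
    for validation, and a packaged table of published per-breed diversity
    statistics for 105 European, African and Asian goat populations.
License: MIT
Encoding: UTF-8
Imports:
    geosphere,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
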