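# Shared builders and independent oracles used across the test files.

# Small genotypes object with explicit metadata
toy_genotypes <- function(calls, breed = NULL, mapped = NULL) {
  calls <- as.matrix(calls)
  n <- nrow(calls); m <- ncol(calls)
  if (is.null(breed)) breed <- rep("B1", n)
  if (is.null(mapped)) mapped <- rep(TRUE, m)
  genotypes(
    calls,
    ind = data.frame(individual_id = sprintf("I%02d", seq_len(n)),
                     breed_id = breed, stringsAsFactors = FALSE),
    snps = data.frame(snp_id = sprintf("S%02d", seq_len(m)), chrom = "1",
                      pos = seq_len(m), allele_a = "A", allele_b = "C",
                      mapped = mapped, stringsAsFactors = FALSE))
}

random_genotypes <- function(n_ind, n_loci, seed, breed = NULL,
                             missing_rate = 0, ensure_biallelic = FALSE) {
  set.seed(seed)
  p <- runif(n_loci, 0.1, 0.9)
  calls <- matrix(rbinom(n_ind * n_loci, 2, rep(p, each = n_ind)),
                  n_ind, n_loci)
  if (missing_rate > 0)
    calls[runif(length(calls)) < missing_rate] <- NA
  if (ensure_biallelic) {
    # PED allele coding is recoverable only when both alleles are observed
    calls[1, ] <- 0L
    calls[2, ] <- 1L
  }
  toy_genotypes(calls, breed = breed)
}

# Hardy-Weinberg oracle: exact rational enumeration of the conditional
# distribution of heterozygote counts via integer combinatorics (no
# log-gamma), normalized as a ratio of integer weights.
hwe_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_b <- 2 * n_bb + n_ab
  n_a <- 2 * n - n_b
  hets <- seq.int(n_b %% 2, min(n_a, n_b), by = 2)
  w <- vapply(hets, function(h)
    choose(n, (n_a - h) / 2) * choose(n - (n_a - h) / 2, h) * 2^h,
    numeric(1))
  obs <- w[match(n_ab, hets)]
  sum(w[w <= obs * (1 + 1e-9)]) / sum(w)
}

# Great-circle (spherical law of cosines) distance in km on the mean Earth
# radius, for bounding the ellipsoid distance
sphere_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distCosine(cbind(lon1, lat1), cbind(lon2, lat2),
                        r = 6371008.8) / 1000
}

write_toy_ped_map <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  ped <- file.path(dir, "toy.ped")
  map <- file.path(dir, "toy.map")
  writeLines(c("1 snp1 0 100", "1 snp2 0 200"), map)
  writeLines(c("FAM1 IND1 0 0 0 -9 A A G T",
               "FAM1 IND2 0 0 0 -9 C C 0 0"), ped)
  list(ped = ped, map = map)
}
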