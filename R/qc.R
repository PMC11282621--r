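#' Quality-control configuration
#'
#' Thresholds for the marker and individual filters applied before diversity
#' estimation, mirroring standard SNP-array practice: drop individuals with
#' high missing call rate first, then drop unmapped SNPs, SNPs with high
#' missing rate, SNPs with low minor allele frequency, and SNPs out of
#' Hardy-Weinberg equilibrium by the exact test.
#'
#' @param maf_min minimum minor allele frequency (default 0.05); SNPs with
#'   MAF strictly below it are removed, so 0 disables the filter.
#' @param snp_missing_max maximum SNP missing call rate (default 0.05);
#'   strictly greater rates are removed, so 1 disables the filter.
#' @param hwe_alpha Hardy-Weinberg exact-test significance level (default
#'   0.001); SNPs with p <= `hwe_alpha` are removed, so 0 disables it.
#' @param ind_missing_max maximum individual missing call rate (default 0.1).
#' @param drop_unmapped drop SNPs without a genomic position (default TRUE).
#' @param hwe_by_breed test Hardy-Weinberg within each breed instead of on
#'   the pooled individuals; a SNP is removed if it fails in any breed.
#'   Default FALSE (pooled), matching per-continent merged filtering.
#' @param subsample_min,subsample_max target range of individuals retained
#'   per breed by [representative_subsample()] (defaults 15 and 50).
#' @param seed integer seed for the seeded subsampling search.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(maf_min = 0.05, snp_missing_max = 0.05,
                      hwe_alpha = 0.001, ind_missing_max = 0.1,
                      drop_unmapped = TRUE, hwe_by_breed = FALSE,
                      subsample_min = 15L, subsample_max = 50L,
                      seed = 1L) {
  stopifnot(maf_min >= 0, maf_min <= 1, snp_missing_max >= 0,
            snp_missing_max <= 1, hwe_alpha >= 0, hwe_alpha <= 1,
            ind_missing_max >= 0, ind_missing_max <= 1,
            subsample_min <= subsample_max)
  structure(list(maf_min = maf_min, snp_missing_max = snp_missing_max,
                 hwe_alpha = hwe_alpha, ind_missing_max = ind_missing_max,
                 drop_unmapped = isTRUE(drop_unmapped),
                 hwe_by_breed = isTRUE(hwe_by_breed),
                 subsample_min = as.integer(subsample_min),
                 subsample_max = as.integer(subsample_max),
                 seed = as.integer(seed)),
            class = "qc_config")
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided conditional exact test for a biallelic locus. Conditional on
#' the observed allele counts, the number of heterozygotes under
#' Hardy-Weinberg proportions follows the distribution
#' \deqn{P(n_{ab}) = \frac{n!}{n_{aa}! \, n_{ab}! \, n_{bb}!}
#'   \frac{2^{n_{ab}} \, n_A! \, n_B!}{(2n)!}}
#' over heterozygote counts of the same parity as the minor allele count.
#' The p-value is the total probability of all outcomes no more probable
#' than the observed one (probability-ordering definition, no mid-p
#' correction), the convention used by SNP-array QC toolchains.
#'
#' @param n_aa,n_ab,n_bb genotype counts (AA homozygote, heterozygote, BB
#'   homozygote).
#' @return The exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  stopifnot(length(n_aa) == 1, length(n_ab) == 1, length(n_bb) == 1,
            n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n < 1) stop("no genotypes")
  n_b <- 2 * n_bb + n_ab
  n_a <- 2 * n - n_b
  hets <- seq.int(n_b %% 2, min(n_a, n_b), by = 2)
  logp <- lgamma(n + 1) - lgamma((n_a - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma((n_b - hets) / 2 + 1) + hets * log(2) +
    lgamma(n_a + 1) + lgamma(n_b + 1) - lgamma(2 * n + 1)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_ab, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

hwe_p_from_calls <- function(col) {
  col <- col[!is.na(col)]
  if (!length(col)) return(NA_real_)
  hwe_exact_test(sum(col == 0L), sum(col == 1L), sum(col == 2L))
}

#' Filter individuals and SNPs
#'
#' Applies the filters of a [qc_config()] in a fixed order: individuals with
#' missing rate above `ind_missing_max` are removed first; the SNP criteria
#' (unmapped, missing rate, MAF, Hardy-Weinberg) are then evaluated
#' sequentially on the reduced matrix, each on the survivors of the previous
#' step, with MAF and the pooled Hardy-Weinberg test computed over all
#' retained individuals. Survivor counts therefore depend on this order,
#' which is why the report records it.
#'
#' @param g a [genotypes] object.
#' @param config a [qc_config()].
#' @return A list with the filtered `genotypes` and a `report` data frame
#'   (step, removed, remaining). If every SNP is removed the genotype matrix
#'   is returned empty with a warning rather than an error.
#' @export
filter_variants <- function(g, config = qc_config()) {
  stopifnot(inherits(g, "genotypes"), inherits(config, "qc_config"))
  if (nrow(g$calls) == 0 || ncol(g$calls) == 0) stop("empty genotype matrix")
  report <- data.frame(step = character(), removed = integer(),
                       remaining = integer(), stringsAsFactors = FALSE)
  note <- function(step, removed, remaining)
    rbind(report, data.frame(step = step, removed = removed,
                             remaining = remaining))

  ind_miss <- rowMeans(is.na(g$calls))
  keep_ind <- ind_miss <= config$ind_missing_max
  report <- note("individual_missing_rate", sum(!keep_ind), sum(keep_ind))
  calls <- g$calls[keep_ind, , drop = FALSE]
  ind <- g$ind[keep_ind, , drop = FALSE]
  if (!nrow(calls)) stop("all individuals removed by missing-rate filter")

  keep <- rep(TRUE, ncol(calls))
  if (config$drop_unmapped) {
    drop <- !g$snps$mapped
    keep <- keep & !drop
    report <- note("unmapped", sum(drop), sum(keep))
  }
  snp_miss <- colMeans(is.na(calls))
  drop <- keep & snp_miss > config$snp_missing_max
  keep <- keep & !drop
  report <- note("snp_missing_rate", sum(drop), sum(keep))

  p <- colMeans(calls, na.rm = TRUE) / 2
  p[is.nan(p)] <- 0
  maf <- pmin(p, 1 - p)
  drop <- keep & maf < config$maf_min
  keep <- keep & !drop
  report <- note("maf", sum(drop), sum(keep))

  if (config$hwe_alpha > 0) {
    idx <- which(keep)
    if (config$hwe_by_breed) {
      fail <- vapply(idx, function(j) {
        ps <- vapply(split(calls[, j], ind$breed_id), hwe_p_from_calls,
                     numeric(1))
        any(!is.na(ps) & ps <= config$hwe_alpha)
      }, logical(1))
    } else {
      fail <- vapply(idx, function(j) {
        pv <- hwe_p_from_calls(calls[, j])
        !is.na(pv) && pv <= config$hwe_alpha
      }, logical(1))
    }
    keep[idx[fail]] <- FALSE
    report <- note("hwe", sum(fail), sum(keep))
  } else {
    report <- note("hwe", 0L, sum(keep))
  }

  if (!any(keep)) warning("all SNPs removed by QC filters")
  out <- genotypes(calls[, keep, drop = FALSE], ind,
                   g$snps[keep, , drop = FALSE])
  list(genotypes = out, report = report)
}

# population (divide-by-n) covariance: with it, any balanced pick from a set
# of duplicated genotypes matches the full covariance exactly
pop_cov <- function(x) {
  x <- sweep(x, 2, colMeans(x))
  crossprod(x) / nrow(x)
}

subsample_objective <- function(scores, sub, full_cov) {
  sum((pop_cov(scores[sub, , drop = FALSE]) - full_cov)^2)
}

#' Variance-preserving subsample of one breed
#'
#' Selects `target_n` individuals of a breed whose genotype covariance over
#' the top principal axes is as close as possible (Frobenius norm) to that
#' of the whole breed, so the subsample preserves the breed's variance
#' structure. The search is a greedy swap refinement from a seeded random
#' start and is fully reproducible from `seed`. If the breed has at most
#' `target_n` members, all are returned.
#'
#' @param g a [genotypes] object.
#' @param breed_id breed to subsample.
#' @param target_n number of individuals to keep.
#' @param seed integer seed for the random start.
#' @param n_axes number of principal axes used for the covariance match
#'   (default 5, capped by the available dimensions).
#' @return Sorted integer indices into the rows of `g$calls`.
#' @export
representative_subsample <- function(g, breed_id, target_n, seed = 1L,
                                     n_axes = 5L) {
  stopifnot(inherits(g, "genotypes"), target_n >= 1)
  idx <- which(g$ind$breed_id == breed_id)
  if (!length(idx)) stop("unknown breed_id: ", breed_id)
  if (length(idx) <= target_n) return(idx)

  x <- g$calls[idx, , drop = FALSE]
  x[is.na(x)] <- NA
  mu <- colMeans(x, na.rm = TRUE)
  x <- sweep(x, 2, mu)
  x[is.na(x)] <- 0
  k <- min(n_axes, nrow(x) - 1L, ncol(x))
  sv <- svd(x, nu = k, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  full_cov <- pop_cov(scores)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  n <- length(idx)
  sub <- sort(sample.int(n, target_n))
  best <- subsample_objective(scores, sub, full_cov)
  repeat {
    improved <- FALSE
    outside <- setdiff(seq_len(n), sub)
    for (i in seq_along(sub)) {
      cand <- sub
      for (j in outside) {
        cand[i] <- j
        obj <- subsample_objective(scores, cand, full_cov)
        if (obj < best - 1e-12) {
          best <- obj
          sub <- sort(cand)
          improved <- TRUE
          break
        }
      }
      if (improved) break
    }
    if (!improved) break
  }
  sort(idx[sub])
}
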