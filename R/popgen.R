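#' Observed heterozygosity
#'
#' Fraction of heterozygous individuals per locus among non-missing calls,
#' averaged without weighting over all loci that have at least one
#' non-missing call.
#'
#' @param calls genotype matrix (individuals x loci, codes 0/1/2/NA) for one
#'   population.
#' @return Mean observed heterozygosity.
#' @export
observed_heterozygosity <- function(calls) {
  calls <- as.matrix(calls)
  if (!nrow(calls)) stop("no individuals")
  n_obs <- colSums(!is.na(calls))
  usable <- n_obs >= 1L
  if (!any(usable)) stop("no usable loci")
  het <- colSums(calls == 1L, na.rm = TRUE)[usable] / n_obs[usable]
  mean(het)
}

#' Expected heterozygosity (unbiased gene diversity)
#'
#' Per locus with `n` non-missing genotypes and counted-allele frequency
#' `p`, the unbiased Nei gene diversity \eqn{\frac{2n}{2n-1} 2p(1-p)} -- the
#' probability that two allele copies drawn without replacement from the
#' sample differ -- averaged without weighting over usable loci.
#'
#' @inheritParams observed_heterozygosity
#' @return Mean expected heterozygosity.
#' @export
expected_heterozygosity <- function(calls) {
  calls <- as.matrix(calls)
  if (!nrow(calls)) stop("no individuals")
  n_obs <- colSums(!is.na(calls))
  usable <- 2 * n_obs >= 2L
  if (!any(usable)) stop("no usable loci")
  n <- n_obs[usable]
  p <- colSums(calls, na.rm = TRUE)[usable] / (2 * n)
  mean(2 * n / (2 * n - 1) * 2 * p * (1 - p))
}

#' Inbreeding coefficient from heterozygosities
#'
#' `fis = 1 - ho / he`. Positive values indicate an excess of homozygotes
#' (inbreeding), negative values a deficit (for example through admixture).
#'
#' @param ho,he observed and expected heterozygosity.
#' @return The inbreeding coefficient.
#' @export
fis_from_het <- function(ho, he) {
  if (any(he == 0)) stop("undefined Fis: he = 0")
  1 - ho / he
}

wc_components <- function(calls_a, calls_b) {
  # Weir-Cockerham (1984) variance components a, b, c per locus, two
  # populations, from genotype calls; returns a 3 x loci matrix
  n1 <- colSums(!is.na(calls_a)); n2 <- colSums(!is.na(calls_b))
  p1 <- colSums(calls_a, na.rm = TRUE) / (2 * n1)
  p2 <- colSums(calls_b, na.rm = TRUE) / (2 * n2)
  h1 <- colSums(calls_a == 1L, na.rm = TRUE) / n1
  h2 <- colSums(calls_b == 1L, na.rm = TRUE) / n2
  nbar <- (n1 + n2) / 2
  nc <- 2 * nbar - (n1^2 + n2^2) / (2 * nbar)
  pbar <- (n1 * p1 + n2 * p2) / (2 * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  hbar <- (n1 * h1 + n2 * h2) / (2 * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  usable <- n1 >= 1 & n2 >= 1 & nbar > 1 & pbar > 0 & pbar < 1
  rbind(a, b, cc)[, usable, drop = FALSE]
}

#' Pairwise Weir-Cockerham FST
#'
#' Two-population Weir-Cockerham (1984) theta, combined across loci as the
#' ratio of summed variance components `sum(a) / sum(a + b + c)`. Loci
#' monomorphic across both populations are excluded; small negative
#' estimates are possible in the absence of differentiation.
#'
#' @param calls_a,calls_b genotype matrices (individuals x loci) for the two
#'   populations, over the same loci.
#' @return A list with `theta` and `n_loci_used`.
#' @export
pairwise_fst <- function(calls_a, calls_b) {
  calls_a <- as.matrix(calls_a); calls_b <- as.matrix(calls_b)
  if (ncol(calls_a) != ncol(calls_b)) stop("locus sets differ")
  if (nrow(calls_a) < 2 || nrow(calls_b) < 2)
    stop("each population needs at least 2 individuals")
  comp <- wc_components(calls_a, calls_b)
  if (ncol(comp) < 2) stop("fewer than 2 usable loci")
  list(theta = sum(comp[1, ]) / sum(comp),
       n_loci_used = ncol(comp))
}

#' Per-breed diversity statistics
#'
#' Computes observed and expected heterozygosity, Fis and (optionally) the
#' Weir-Cockerham FST of every breed against a reference breed. Fis is
#' reported as `1 - mean(Ho) / mean(He)` over loci by default; with
#' `fis_locus_weighted = TRUE` it is instead the ratio of locus-summed
#' heterozygosity deficits, the weighting used by AMOVA-style software.
#'
#' @param g a [genotypes] object.
#' @param reference breed id used as the FST reference, or `NULL` to skip
#'   FST (default `"IRA_KUR"`, the Iranian Markhoz).
#' @param fis_locus_weighted see above.
#' @return A data frame with one row per breed: `breed_id`, `n_individuals`,
#'   `n_loci_used`, `ho`, `he`, `fis`, `fst_vs_ref`.
#' @export
diversity_by_breed <- function(g, reference = "IRA_KUR",
                               fis_locus_weighted = FALSE) {
  stopifnot(inherits(g, "genotypes"))
  breeds <- unique(g$ind$breed_id)
  if (!is.null(reference) && !reference %in% breeds)
    reference <- NULL
  ref_calls <- if (!is.null(reference))
    g$calls[g$ind$breed_id == reference, , drop = FALSE]
  rows <- lapply(breeds, function(b) {
    calls <- g$calls[g$ind$breed_id == b, , drop = FALSE]
    n_obs <- colSums(!is.na(calls))
    usable <- 2 * n_obs >= 2
    n <- n_obs[usable]
    p <- colSums(calls, na.rm = TRUE)[usable] / (2 * n)
    ho_l <- colSums(calls == 1L, na.rm = TRUE)[usable] / n
    he_l <- 2 * n / (2 * n - 1) * 2 * p * (1 - p)
    ho <- mean(ho_l); he <- mean(he_l)
    fis <- if (fis_locus_weighted) {
      poly <- he_l > 0
      1 - sum(ho_l[poly]) / sum(he_l[poly])
    } else fis_from_het(ho, he)
    fst <- if (!is.null(reference) && b != reference && nrow(calls) >= 2)
      pairwise_fst(calls, ref_calls)$theta else NA_real_
    data.frame(breed_id = b, n_individuals = nrow(calls),
               n_loci_used = sum(usable), ho = ho, he = he, fis = fis,
               fst_vs_ref = fst, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Unweighted means of diversity statistics over a breed subset
#'
#' @param tab a diversity table with columns `breed_id`, `ho`, `he`, `fis`.
#' @param breed_ids breeds to average over; `NULL` means all rows.
#' @return A one-row data frame with `n_breeds`, `ho`, `he`, `fis`.
#' @export
summarize_diversity <- function(tab, breed_ids = NULL) {
  if (!is.null(breed_ids)) {
    missing <- setdiff(breed_ids, tab$breed_id)
    if (length(missing))
      stop("unknown breed_id: ", paste(missing, collapse = ", "))
    tab <- tab[tab$breed_id %in% breed_ids, ]
  }
  if (!nrow(tab)) stop("empty subset")
  data.frame(n_breeds = nrow(tab), ho = mean(tab$ho), he = mean(tab$he),
             fis = mean(tab$fis))
}
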