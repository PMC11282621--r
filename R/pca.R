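#' PCA of a genotype matrix
#'
#' Principal component analysis of SNP genotypes with Patterson
#' normalization: each polymorphic SNP is centred by its mean call and
#' scaled by \eqn{\sqrt{2\hat p(1-\hat p)}}, missing calls are set to zero
#' after centring (mean imputation), and the components are the
#' eigenvectors of the individual-by-individual covariance, ordered by
#' eigenvalue. The sign of each component is fixed by forcing its
#' largest-magnitude SNP loading positive, so results do not depend on the
#' eigensolver's arbitrary sign.
#'
#' @param g a [genotypes] object, or a plain calls matrix.
#' @param n_components number of components to return (default 10, capped).
#' @return A list of class `pca_result`: `scores` (individuals x
#'   components), `explained_fraction`, and the breed labels if available.
#' @export
pca_genotypes <- function(g, n_components = 10) {
  calls <- if (inherits(g, "genotypes")) g$calls else as.matrix(g)
  breed <- if (inherits(g, "genotypes")) g$ind$breed_id else rownames(calls)
  if (nrow(calls) < 2) stop("need at least 2 individuals")
  p <- colMeans(calls, na.rm = TRUE) / 2
  poly <- is.finite(p) & p > 0 & p < 1
  if (sum(poly) < 2) stop("no polymorphic SNPs")
  x <- calls[, poly, drop = FALSE]
  p <- p[poly]
  x <- sweep(x, 2, 2 * p)
  x <- sweep(x, 2, sqrt(2 * p * (1 - p)), "/")
  x[is.na(x)] <- 0

  cov_ii <- tcrossprod(x) / ncol(x)
  eig <- eigen(cov_ii, symmetric = TRUE)
  pos <- pmax(eig$values, 0)
  k <- min(n_components, nrow(x) - 1L, sum(pos > 1e-12))
  scores <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pos[seq_len(k)]), k, k)
  for (j in seq_len(k)) {
    load <- crossprod(x, eig$vectors[, j])
    if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- rownames(calls)
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(scores = scores,
                 explained_fraction = pos[seq_len(k)] / sum(pos),
                 breed_id = breed),
            class = "pca_result")
}

#' Per-breed centroids of the first two principal components
#'
#' The unweighted mean of each breed's individual scores on PC1 and PC2 --
#' the per-breed summary used to display population structure when
#' individual points would overplot.
#'
#' @param pca a [pca_genotypes()] result.
#' @param breed_id breed label per individual; defaults to the labels stored
#'   in the result.
#' @return Data frame with `breed_id`, `pc1`, `pc2`, `n_individuals`.
#' @export
breed_centroids <- function(pca, breed_id = pca$breed_id) {
  stopifnot(inherits(pca, "pca_result"))
  if (is.null(breed_id) || length(breed_id) != nrow(pca$scores))
    stop("every individual must carry a breed label")
  lv <- if (is.factor(breed_id)) levels(breed_id) else unique(as.character(breed_id))
  breed_id <- as.character(breed_id)
  counts <- table(factor(breed_id, levels = lv))
  if (any(counts == 0)) {
    warning("breeds with zero individuals excluded: ",
            paste(names(counts)[counts == 0], collapse = ", "))
    lv <- lv[counts[lv] > 0]
  }
  out <- do.call(rbind, lapply(lv, function(b) {
    s <- pca$scores[breed_id == b, 1:2, drop = FALSE]
    data.frame(breed_id = b, pc1 = mean(s[, 1]), pc2 = mean(s[, 2]),
               n_individuals = nrow(s), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
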