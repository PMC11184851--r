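#' Principal component analysis of the expression matrix
#'
#' Column-centered (per gene) SVD-based PCA on a gene subset, typically the
#' highly variable genes.  Uses a truncated SVD (irlba) when few components
#' are requested from a large matrix, exact SVD otherwise; signs are fixed
#' so each loading column's largest-magnitude entry is positive, making the
#' result deterministic up to that convention.
#'
#' @param expr an `scdens_expr` or numeric matrix, cells x genes.
#' @param genes gene subset to use (default: all columns).
#' @param n_components number of components.
#' @param seed seed for the truncated SVD initialisation.
#' @return object of class `scdens_pca`: list with `scores` (cells x K),
#'   `loadings` (genes x K, unit-norm columns), `variance_explained`
#'   (per-component variance, non-increasing) and `total_variance`.
#' @export
run_pca <- function(expr, genes = NULL, n_components = 20L, seed = 1L) {
  values <- if (inherits(expr, "scdens_expr")) expr$values else expr
  if (!is.null(genes)) {
    missing <- setdiff(genes, colnames(values))
    if (length(missing))
      stop("genes not present in the expression matrix: ",
           paste(utils::head(missing, 3), collapse = ", "))
    values <- values[, genes, drop = FALSE]
  }
  n <- nrow(values); g <- ncol(values)
  if (n_components > min(n, g))
    stop("n_components (", n_components, ") exceeds min(cells, genes) = ",
         min(n, g))
  X <- scale(values, center = TRUE, scale = FALSE)
  sv <- .truncated_svd(X, n_components, seed)
  flip <- vapply(seq_len(n_components), function(k) {
    v <- sv$v[, k]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, 1)
  loadings <- sweep(sv$v, 2, flip, `*`)
  scores <- sweep(sv$u %*% diag(sv$d, n_components), 2, flip, `*`)
  dimnames(scores) <- list(rownames(values),
                           paste0("PC", seq_len(n_components)))
  dimnames(loadings) <- list(colnames(values), colnames(scores))
  structure(list(scores = scores,
                 loadings = loadings,
                 variance_explained = sv$d^2 / max(1, n - 1),
                 total_variance = sum(.colVars(values))),
            class = "scdens_pca")
}

.truncated_svd <- function(X, k, seed = 1L) {
  if (k < 0.5 * min(dim(X)) && min(dim(X)) > 50) {
    set.seed(seed)
    sv <- irlba::irlba(X, nv = k)
  } else {
    sv <- svd(X, nu = k, nv = k)
    sv$d <- sv$d[seq_len(k)]
  }
  sv
}

#' @export
print.scdens_pca <- function(x, ...) {
  ve <- x$variance_explained
  cat("PCA:", nrow(x$scores), "cells,", ncol(x$scores), "components\n")
  cat("  variance explained (top 5):",
      paste(signif(utils::head(ve / max(x$total_variance, .Machine$double.eps)
                               * 100, 5), 3), collapse = "% "), "%\n")
  invisible(x)
}

#' Significant principal components by gene permutation
#'
#' A jackStraw-style permutation test.  In each of `n_reps` replicates a
#' random fraction `prop_permuted` of the genes has its values permuted
#' across cells and the PCA is re-fitted; the squared loadings of the
#' permuted genes form the null gene-PC association scores.  Observed
#' scores are taken from the same refit for an equally sized random
#' reference set of unpermuted genes, so both sides share the fit
#' conditions; a per-component p-value is then the exact binomial (sign)
#' test of how often, across replicates, the reference genes' mean squared
#' loading beats the permuted genes'.  Under the null the two sets are
#' exchangeable within a replicate, which keeps the test calibrated where
#' the classic full-fit-versus-refit comparison is anticonservative for
#' pure-noise components.  Components are declared significant when the
#' Bonferroni-adjusted p-value (across the tested components) is below
#' `alpha`.
#'
#' @param expr an `scdens_expr` or numeric matrix, cells x genes.
#' @param genes gene subset (default all).
#' @param n_test_pcs number of leading components tested (default 30).
#' @param n_reps number of permutation replicates (>= 50; default 200).
#' @param prop_permuted fraction of genes permuted per replicate
#'   (default 0.01).
#' @param alpha significance level after Bonferroni adjustment.
#' @param seed integer seed.
#' @return object of class `scdens_jackstraw`: list with `p` (per-PC raw
#'   p), `p_adjusted` (Bonferroni), `significant` (indices), and the
#'   parameters.
#' @export
jackstraw_significant_pcs <- function(expr, genes = NULL, n_test_pcs = 30L,
                                      n_reps = 200L, prop_permuted = 0.01,
                                      alpha = 0.05, seed = 1L) {
  if (n_reps < 50) stop("n_reps must be at least 50")
  values <- if (inherits(expr, "scdens_expr")) expr$values else expr
  if (!is.null(genes)) values <- values[, genes, drop = FALSE]
  G <- ncol(values)
  n_test_pcs <- min(n_test_pcs, min(dim(values)) - 1L)
  X <- scale(values, center = TRUE, scale = FALSE)
  if (all(abs(X) < 1e-12)) {
    return(structure(list(p = rep(1, n_test_pcs),
                          p_adjusted = rep(1, n_test_pcs),
                          significant = integer(0),
                          n_reps = n_reps, prop_permuted = prop_permuted,
                          alpha = alpha, seed = seed),
                     class = "scdens_jackstraw"))
  }
  m <- max(1L, round(prop_permuted * G))
  if (2 * m > G) stop("prop_permuted too large for the number of genes")
  set.seed(as.integer(seed))
  wins <- matrix(0L, n_reps, n_test_pcs)
  for (r in seq_len(n_reps)) {
    pick <- sample.int(G, 2L * m)
    perm_g <- pick[seq_len(m)]
    ref_g <- pick[m + seq_len(m)]
    Xp <- X
    for (g in perm_g) Xp[, g] <- sample(Xp[, g])
    v <- .truncated_svd(Xp, n_test_pcs, seed = seed + r)$v
    ref_sc <- colMeans(v[ref_g, , drop = FALSE]^2)
    perm_sc <- colMeans(v[perm_g, , drop = FALSE]^2)
    wins[r, ] <- as.integer(ref_sc > perm_sc)
  }
  p <- vapply(seq_len(n_test_pcs), function(k)
    stats::binom.test(sum(wins[, k]), n_reps, 0.5,
                      alternative = "greater")$p.value, 1)
  padj <- pmin(1, p * n_test_pcs)
  structure(list(p = p, p_adjusted = padj,
                 significant = which(padj < alpha),
                 n_reps = n_reps, prop_permuted = prop_permuted,
                 alpha = alpha, seed = seed),
            class = "scdens_jackstraw")
}

#' @export
print.scdens_jackstraw <- function(x, ...) {
  cat("jackStraw:", length(x$p), "components tested,",
      length(x$significant), "significant at Bonferroni alpha =",
      x$alpha, "\n")
  if (length(x$significant))
    cat("  significant:", paste(x$significant, collapse = ", "), "\n")
  invisible(x)
}
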