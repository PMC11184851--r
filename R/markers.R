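## Bimodal likelihood model for single-cell log expression: a point mass
## at zero (probability 1 - pi) and a normal on the positive values.  The
## log-likelihood of a group depends on the data only through (n, number
## of positives, sum and sum of squares of the positive values), which
## makes the likelihood-ratio test vectorizable over genes from cluster
## aggregates.  The positive-part sd is floored to keep likelihoods
## finite for (near-)constant positive values.
.bimod_ll <- function(n, n1, s, sq, sd_floor = 1e-3) {
  n0 <- n - n1
  pi_hat <- n1 / n
  ll <- ifelse(n0 > 0, n0 * log(pmax(1 - pi_hat, .Machine$double.xmin)), 0) +
    ifelse(n1 > 0, n1 * log(pmax(pi_hat, .Machine$double.xmin)), 0)
  mu <- ifelse(n1 > 0, s / pmax(n1, 1), 0)
  ss <- pmax(sq - n1 * mu^2, 0)
  v <- ifelse(n1 > 1, ss / (n1 - 1), 0)
  v <- pmax(v, sd_floor^2)
  ll + ifelse(n1 > 0, -n1 / 2 * log(2 * pi * v) - ss / (2 * v), 0)
}

.bimod_lrt_stats <- function(n_a, n1_a, s_a, sq_a,
                             n_b, n1_b, s_b, sq_b, sd_floor = 1e-3) {
  ll_a <- .bimod_ll(n_a, n1_a, s_a, sq_a, sd_floor)
  ll_b <- .bimod_ll(n_b, n1_b, s_b, sq_b, sd_floor)
  ll_p <- .bimod_ll(n_a + n_b, n1_a + n1_b, s_a + s_b, sq_a + sq_b, sd_floor)
  stat <- pmax(2 * (ll_a + ll_b - ll_p), 0)
  list(stat = stat,
       p = stats::pchisq(stat, df = 3, lower.tail = FALSE))
}

#' Bimodal likelihood-ratio test for two groups of expression values
#'
#' Models log-normalized expression as a mixture of a point mass at zero
#' and a normal distribution on the positive values (expression fraction,
#' positive-part mean and sd), and compares the two-group fit against the
#' pooled fit with a likelihood-ratio test on 3 degrees of freedom.
#'
#' @param values_a,values_b numeric vectors of log-normalized expression.
#' @param sd_floor lower bound on the positive-part sd (default 1e-3).
#' @return list with `statistic` (>= 0) and `p` (in (0, 1]); two all-zero
#'   groups give statistic 0 and p 1.
#' @export
bimod_lrt <- function(values_a, values_b, sd_floor = 1e-3) {
  if (!length(values_a) || !length(values_b))
    stop("both groups must be non-empty")
  r <- .bimod_lrt_stats(length(values_a), sum(values_a > 0),
                        sum(values_a[values_a > 0]),
                        sum(values_a[values_a > 0]^2),
                        length(values_b), sum(values_b > 0),
                        sum(values_b[values_b > 0]),
                        sum(values_b[values_b > 0]^2), sd_floor)
  list(statistic = r$stat, p = r$p)
}

## Per-cluster sufficient statistics of the log expression matrix:
## counts, positive counts, sums and sums of squares per gene.
.cluster_aggregates <- function(values, labels) {
  f <- factor(labels)
  list(levels = levels(f),
       n = as.integer(table(f)),
       n1 = rowsum(1 * (values > 0), f),
       s = rowsum(values, f),
       sq = rowsum(values^2, f))
}

.expr_values <- function(expr) {
  v <- if (inherits(expr, "scdens_expr")) expr$values else expr
  stopifnot(is.matrix(v))
  v
}

## Align expression rows to the retained cells of a clustering.
.retained <- function(values, clusters) {
  stopifnot(inherits(clusters, "scdens_clusters"))
  keep <- !is.na(clusters$final_label)
  idx <- match(clusters$cell_id[keep], rownames(values))
  if (any(is.na(idx)))
    stop("clustered cells missing from the expression matrix")
  list(values = values[idx, , drop = FALSE],
       labels = clusters$final_label[keep])
}

#' One-vs-rest differentially expressed genes per cluster
#'
#' For every cluster and gene, compares the cells of the cluster against
#' all other retained cells with the bimodal likelihood-ratio test.  The
#' record is kept when the average natural-log expression difference
#' strictly exceeds `min_log_diff` and the Benjamini-Hochberg q-value
#' (computed across all genes within the cluster's comparison) is below
#' `max_fdr`.
#'
#' @param expr `scdens_expr` or matrix of log-normalized values.
#' @param clusters an `scdens_clusters`.
#' @param min_log_diff effect-size floor in natural-log units
#'   (default 0.5, strict).
#' @param max_fdr BH q-value ceiling (default 0.01).
#' @param all_records return all (gene, cluster) records rather than only
#'   the ones passing the thresholds.
#' @return data.frame with `gene`, `cluster`, `avg_log_diff`, `p`, `q`,
#'   `direction` and (when `all_records`) `kept`.
#' @export
deg_one_vs_rest <- function(expr, clusters, min_log_diff = 0.5,
                            max_fdr = 0.01, all_records = FALSE) {
  values <- .expr_values(expr)
  r <- .retained(values, clusters)
  if (length(unique(r$labels)) < 2) {
    warning("fewer than 2 clusters; no differential expression computed")
    return(data.frame(gene = character(0), cluster = integer(0),
                      avg_log_diff = numeric(0), p = numeric(0),
                      q = numeric(0), direction = integer(0)))
  }
  ag <- .cluster_aggregates(r$values, r$labels)
  tot_n <- sum(ag$n)
  tot_n1 <- colSums(ag$n1); tot_s <- colSums(ag$s); tot_sq <- colSums(ag$sq)
  out <- vector("list", length(ag$levels))
  for (i in seq_along(ag$levels)) {
    n_a <- ag$n[i]; n_b <- tot_n - n_a
    lrt <- .bimod_lrt_stats(n_a, ag$n1[i, ], ag$s[i, ], ag$sq[i, ],
                            n_b, tot_n1 - ag$n1[i, ],
                            tot_s - ag$s[i, ], tot_sq - ag$sq[i, ])
    diff <- ag$s[i, ] / n_a - (tot_s - ag$s[i, ]) / n_b
    q <- stats::p.adjust(lrt$p, method = "BH")
    keep <- diff > min_log_diff & q < max_fdr
    rec <- data.frame(gene = colnames(r$values),
                      cluster = as.integer(ag$levels[i]),
                      avg_log_diff = unname(diff),
                      p = unname(lrt$p), q = unname(q),
                      direction = sign(unname(diff)),
                      stringsAsFactors = FALSE)
    if (all_records) rec$kept <- unname(keep)
    out[[i]] <- if (all_records) rec else rec[keep, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pairwise differentially expressed genes per cluster
#'
#' A gene enters a cluster's pairwise DEG set only when, against every
#' other cluster, its average natural-log expression difference strictly
#' exceeds `min_log_diff` and the (unadjusted) bimodal LRT p-value is
#' below `max_p`.
#'
#' @inheritParams deg_one_vs_rest
#' @param min_log_diff effect-size floor (default 0.25, strict).
#' @param max_p unadjusted p ceiling (default 0.05).
#' @return list with `sets` (named list: cluster -> character vector of
#'   genes) and `records` (per cluster-pair data.frame with
#'   `avg_log_diff` of the first cluster over the second, and `p`).
#' @export
deg_pairwise <- function(expr, clusters, min_log_diff = 0.25,
                         max_p = 0.05) {
  values <- .expr_values(expr)
  r <- .retained(values, clusters)
  lev <- sort(unique(r$labels))
  if (length(lev) < 2) {
    warning("fewer than 2 clusters; no differential expression computed")
    return(list(sets = list(), records = NULL))
  }
  ag <- .cluster_aggregates(r$values, r$labels)
  genes <- colnames(r$values)
  ok <- matrix(TRUE, length(genes), length(lev),
               dimnames = list(genes, ag$levels))
  records <- list()
  for (i in seq_along(lev)) for (j in seq_along(lev)) {
    if (j <= i) next
    lrt <- .bimod_lrt_stats(ag$n[i], ag$n1[i, ], ag$s[i, ], ag$sq[i, ],
                            ag$n[j], ag$n1[j, ], ag$s[j, ], ag$sq[j, ])
    diff <- ag$s[i, ] / ag$n[i] - ag$s[j, ] / ag$n[j]
    ok[, i] <- ok[, i] & (diff > min_log_diff & lrt$p < max_p)
    ok[, j] <- ok[, j] & (-diff > min_log_diff & lrt$p < max_p)
    records[[length(records) + 1L]] <-
      data.frame(cluster_a = lev[i], cluster_b = lev[j], gene = genes,
                 avg_log_diff = unname(diff), p = unname(lrt$p),
                 stringsAsFactors = FALSE)
  }
  sets <- lapply(seq_along(lev), function(i) genes[ok[, i]])
  names(sets) <- ag$levels
  list(sets = sets, records = do.call(rbind, records))
}

#' Overlap the two DEG stages into the marker table
#'
#' A gene is a marker of a cluster when it is in both the one-vs-rest DEG
#' set (stage 1) and the all-pairwise DEG set (stage 2) of that cluster.
#' Rows are sorted by cluster, then by decreasing average log difference.
#'
#' @param set1 data.frame from [deg_one_vs_rest()] (kept records).
#' @param set2 result of [deg_pairwise()] (or its `sets` element).
#' @return data.frame of class `scdens_markers`: stage-1 records plus
#'   logical `in_set1`, `in_set2`, `is_marker`.
#' @export
overlap_markers <- function(set1, set2) {
  sets2 <- if (is.list(set2) && !is.data.frame(set2) &&
                 !is.null(set2$sets)) set2$sets else set2
  out <- set1
  out$in_set1 <- TRUE
  out$in_set2 <- mapply(function(g, cl) {
    s <- sets2[[as.character(cl)]]
    !is.null(s) && g %in% s
  }, out$gene, out$cluster)
  out$is_marker <- out$in_set1 & out$in_set2
  out <- out[order(out$cluster, -out$avg_log_diff), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("scdens_markers", "data.frame")
  out
}

#' Post-hoc cluster-pair validity by pairwise DEG counts
#'
#' For every unordered pair of final clusters, counts the genes whose
#' absolute average natural-log expression difference strictly exceeds
#' `min_log_diff` with a Benjamini-Hochberg q-value (across genes within
#' the pair) below `max_fdr`.  A pair passes when the count strictly
#' exceeds `min_degs`; a well-separated clustering passes for every pair.
#'
#' @inheritParams deg_one_vs_rest
#' @param min_log_diff absolute effect floor (default 1.0).
#' @param max_fdr BH q ceiling (default 0.01).
#' @param min_degs required DEG count per pair (default 10, strict).
#' @return data.frame of class `scdens_validity` with `cluster_a`,
#'   `cluster_b`, `n_degs`, `pass`.
#' @export
posthoc_cluster_validity <- function(expr, clusters, min_log_diff = 1.0,
                                     max_fdr = 0.01, min_degs = 10L) {
  values <- .expr_values(expr)
  r <- .retained(values, clusters)
  lev <- sort(unique(r$labels))
  stopifnot(length(lev) >= 2)
  ag <- .cluster_aggregates(r$values, r$labels)
  rows <- list()
  for (i in seq_along(lev)) for (j in seq_along(lev)) {
    if (j <= i) next
    lrt <- .bimod_lrt_stats(ag$n[i], ag$n1[i, ], ag$s[i, ], ag$sq[i, ],
                            ag$n[j], ag$n1[j, ], ag$s[j, ], ag$sq[j, ])
    diff <- ag$s[i, ] / ag$n[i] - ag$s[j, ] / ag$n[j]
    q <- stats::p.adjust(lrt$p, method = "BH")
    n_degs <- sum(abs(diff) > min_log_diff & q < max_fdr)
    rows[[length(rows) + 1L]] <-
      data.frame(cluster_a = lev[i], cluster_b = lev[j],
                 n_degs = n_degs, pass = n_degs > min_degs)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("scdens_validity", "data.frame")
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment; a thin validating wrapper
#' around [stats::p.adjust()].
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return q-values, monotone in `pvals` and never smaller.
#' @export
bh_fdr <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Top markers per cluster
#'
#' The `n` strongest markers of each cluster by average log difference;
#' ties are broken by smaller q-value, then lexicographic gene id.
#'
#' @param markers an `scdens_markers` table.
#' @param n markers per cluster (default 10).
#' @return data.frame restricted to `is_marker` rows, at most `n` per
#'   cluster.  Clusters with fewer than `n` markers are reported in full
#'   with a message.
#' @export
top_markers <- function(markers, n = 10L) {
  stopifnot(nrow(markers) > 0)
  mk <- markers[markers$is_marker, , drop = FALSE]
  out <- list()
  for (cl in sort(unique(mk$cluster))) {
    sub <- mk[mk$cluster == cl, , drop = FALSE]
    ord <- order(-sub$avg_log_diff, sub$q, sub$gene)
    if (nrow(sub) < n)
      message("cluster ", cl, " has only ", nrow(sub), " markers")
    out[[length(out) + 1L]] <- sub[utils::head(ord, n), , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mean-expression matrix for a marker heatmap
#'
#' Genes x clusters matrix of mean log-normalized expression, suitable for
#' exporting a top-marker heatmap.
#'
#' @param expr `scdens_expr` or matrix.
#' @param clusters an `scdens_clusters`.
#' @param genes genes to include (e.g. `top_markers(...)$gene`).
#' @return numeric matrix, genes x clusters.
#' @export
marker_heatmap_matrix <- function(expr, clusters, genes) {
  values <- .expr_values(expr)
  r <- .retained(values, clusters)
  genes <- unique(genes)
  sub <- r$values[, genes, drop = FALSE]
  t(rowsum(sub, r$labels) / as.vector(table(r$labels)))
}
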