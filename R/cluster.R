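## Classic DBSCAN on 2-D coordinates.  Neighbourhoods are found with a
## grid of eps-sized buckets (only the 3x3 surrounding buckets can hold
## points within eps), so the usual O(n^2) scan is avoided; the labelling
## itself is the textbook core-point expansion.  A point's neighbourhood
## includes the point itself, so a core point has at least `min_pts`
## points within `eps` counting itself.
.dbscan <- function(coords, eps, min_pts) {
  n <- nrow(coords)
  if (n == 0) return(integer(0))
  gx <- floor(coords[, 1] / eps)
  gy <- floor(coords[, 2] / eps)
  key <- paste(gx, gy)
  bucket <- split(seq_len(n), key)
  bucket_of <- match(key, names(bucket))
  neighbours <- function(i) {
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      b <- bucket[[paste(gx[i] + dx, gy[i] + dy)]]
      if (!is.null(b)) cand <- c(cand, b)
    }
    d2 <- (coords[cand, 1] - coords[i, 1])^2 +
      (coords[cand, 2] - coords[i, 2])^2
    cand[d2 <= eps^2]
  }
  nb <- lapply(seq_len(n), neighbours)
  core <- lengths(nb) >= min_pts
  labels <- integer(n)      # 0 = unvisited/noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nb[[i]]
    while (length(queue)) {
      j <- queue[[1]]
      queue <- queue[-1]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) queue <- c(queue, nb[[j]])
      }
    }
  }
  labels
}

#' Two-pass DBSCAN clustering with size-based pruning
#'
#' Pass 1 runs DBSCAN with radius `eps1` on the embedding coordinates;
#' cells in clusters smaller than `min_size1` and pass-1 noise cells are
#' removed.  Pass 2 re-runs DBSCAN with radius `eps2` on the same
#' coordinates restricted to the surviving cells, after which clusters
#' smaller than `min_size2` and pass-2 noise are removed as well.  Final
#' labels are contiguous integers ordered by decreasing cluster size.
#' Every removal is accounted for in a per-cell ledger.
#'
#' @param embedding an `scdens_embedding` (or a cells x 2 coordinate
#'   matrix with row names).
#' @param eps1,eps2 DBSCAN radii of the two passes (defaults 0.5, 1.0).
#' @param min_size1,min_size2 cluster size floors (defaults 10, 20).
#' @param min_pts DBSCAN core-point neighbour floor, shared by both passes
#'   (default 10).
#' @return object of class `scdens_clusters`: data.frame with `cell_id`,
#'   `pass1_label` (0 = noise), `final_label` (NA when removed) and
#'   `removal_reason` (`none`, `noise_pass1`, `small_cluster_pass1`,
#'   `noise_pass2`, `small_cluster_pass2`).  The attribute `"sizes"` holds
#'   the final cluster sizes.
#' @export
dbscan_two_pass <- function(embedding, eps1 = 0.5, min_size1 = 10L,
                            eps2 = 1.0, min_size2 = 20L, min_pts = 10L) {
  coords <- if (inherits(embedding, "scdens_embedding"))
    embedding$coords else as.matrix(embedding)
  n <- nrow(coords)
  if (n < min_pts)
    stop("fewer cells (", n, ") than min_pts (", min_pts, ")")
  ids <- rownames(coords)
  if (is.null(ids)) ids <- as.character(seq_len(n))

  l1 <- .dbscan(coords, eps1, min_pts)
  reason <- rep("none", n)
  reason[l1 == 0L] <- "noise_pass1"
  sz1 <- table(l1[l1 > 0L])
  small1 <- as.integer(names(sz1)[sz1 < min_size1])
  reason[l1 %in% small1] <- "small_cluster_pass1"

  keep <- reason == "none"
  if (!any(keep))
    stop("degenerate output: all cells removed in pass 1")
  l2 <- integer(n)
  l2[keep] <- .dbscan(coords[keep, , drop = FALSE], eps2, min_pts)
  reason[keep & l2 == 0L] <- "noise_pass2"
  sz2 <- table(l2[keep & l2 > 0L])
  small2 <- as.integer(names(sz2)[sz2 < min_size2])
  reason[keep & l2 %in% small2] <- "small_cluster_pass2"
  keep2 <- reason == "none"
  if (!any(keep2))
    stop("degenerate output: all cells removed in pass 2")

  kept_sizes <- sort(table(l2[keep2]), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(kept_sizes),
                             names(kept_sizes))
  final <- rep(NA_integer_, n)
  final[keep2] <- relabel[as.character(l2[keep2])]

  out <- data.frame(cell_id = ids,
                    pass1_label = l1,
                    final_label = final,
                    removal_reason = factor(reason,
                      levels = c("none", "noise_pass1",
                                 "small_cluster_pass1", "noise_pass2",
                                 "small_cluster_pass2")),
                    stringsAsFactors = FALSE)
  class(out) <- c("scdens_clusters", "data.frame")
  attr(out, "sizes") <- as.integer(kept_sizes)
  attr(out, "params") <- list(eps1 = eps1, min_size1 = min_size1,
                              eps2 = eps2, min_size2 = min_size2,
                              min_pts = min_pts)
  out
}

#' @export
print.scdens_clusters <- function(x, ...) {
  removed <- sum(is.na(x$final_label))
  cat("Two-pass DBSCAN:", length(attr(x, "sizes")), "final clusters,",
      "sizes:", paste(attr(x, "sizes"), collapse = ", "), "\n")
  cat("  removed", removed, "cells (",
      removal_percent(removed, nrow(x)), "% of data)\n", sep = " ")
  invisible(x)
}

#' Cluster composition per experimental condition
#'
#' Tabulates, per final cluster and condition, the cell count and the
#' within-condition proportion, and tests each cluster's proportion between
#' every pair of conditions with a two-sided two-proportion test,
#' Benjamini-Hochberg corrected across clusters within each condition
#' pair.
#'
#' @param clusters an `scdens_clusters`.
#' @param meta data.frame with `cell_id` and `condition`.
#' @return list of class `scdens_composition` with `composition`
#'   (cluster, condition, n, proportion) and `tests` (cluster, cond_a,
#'   cond_b, p, q); `tests` is empty with fewer than two conditions.
#' @export
composition_by_group <- function(clusters, meta) {
  stopifnot(inherits(clusters, "scdens_clusters"))
  cond <- meta$condition[match(clusters$cell_id, meta$cell_id)]
  keep <- !is.na(clusters$final_label)
  if (any(is.na(cond[keep])))
    stop("retained cells without a condition label")
  lab <- clusters$final_label[keep]
  cond <- factor(cond[keep])
  tab <- table(cluster = lab, condition = cond)
  totals <- colSums(tab)
  if (any(totals == 0))
    stop("condition with zero retained cells: ",
         paste(names(totals)[totals == 0], collapse = ", "))
  comp <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(comp) <- c("cluster", "condition", "n")
  comp$cluster <- as.integer(comp$cluster)
  comp$proportion <- comp$n / totals[comp$condition]
  comp <- comp[order(comp$cluster, comp$condition), ]
  rownames(comp) <- NULL

  tests <- data.frame(cluster = integer(0), cond_a = character(0),
                      cond_b = character(0), p = numeric(0),
                      q = numeric(0), stringsAsFactors = FALSE)
  lvls <- levels(cond)
  if (length(lvls) >= 2) {
    rows <- list()
    for (a in seq_along(lvls)) for (b in seq_along(lvls)) {
      if (b <= a) next
      for (cl in rownames(tab)) {
        x <- c(tab[cl, lvls[a]], tab[cl, lvls[b]])
        nn <- c(totals[lvls[a]], totals[lvls[b]])
        p <- suppressWarnings(stats::prop.test(x, nn)$p.value)
        rows[[length(rows) + 1L]] <-
          data.frame(cluster = as.integer(cl), cond_a = lvls[a],
                     cond_b = lvls[b], p = p, stringsAsFactors = FALSE)
      }
    }
    tests <- do.call(rbind, rows)
    tests$q <- NA_real_
    for (pair in unique(paste(tests$cond_a, tests$cond_b))) {
      idx <- paste(tests$cond_a, tests$cond_b) == pair
      tests$q[idx] <- stats::p.adjust(tests$p[idx], method = "BH")
    }
  }
  structure(list(composition = comp, tests = tests),
            class = "scdens_composition")
}

#' @export
print.scdens_composition <- function(x, ...) {
  cat("Cluster composition:", length(unique(x$composition$cluster)),
      "clusters x", length(unique(x$composition$condition)),
      "conditions\n")
  if (nrow(x$tests))
    cat("  ", sum(x$tests$q < 0.05), "of", nrow(x$tests),
        "cluster/condition-pair tests at q < 0.05\n")
  invisible(x)
}

#' Re-cluster the cells of one cluster
#'
#' Repeats the embedding-and-clustering procedure (highly variable genes,
#' PCA, tSNE, two-pass DBSCAN) on the cells of a single cluster, with
#' overridable parameters.  Subcluster labels are namespaced under the
#' parent as `"<parent>.<child>"`.
#'
#' @param expr the `scdens_expr` used for the parent clustering (normalized
#'   values).
#' @param clusters the parent `scdens_clusters`.
#' @param target_cluster parent cluster to refine.
#' @param hvg,pca,tsne,dbscan named lists of parameter overrides for
#'   [select_hvg()], [run_pca()], [run_tsne()] and [dbscan_two_pass()].
#' @param seed seed for PCA/tSNE.
#' @return list of class `scdens_subclusters` with `assignment`
#'   (data.frame `cell_id`, `subcluster` of the form `"parent.child"`),
#'   the sub-`clusters` object and the parameters used.
#' @export
subcluster <- function(expr, clusters, target_cluster,
                       hvg = list(), pca = list(), tsne = list(),
                       dbscan = list(), seed = 1L) {
  stopifnot(inherits(clusters, "scdens_clusters"))
  cells <- clusters$cell_id[!is.na(clusters$final_label) &
                              clusters$final_label == target_cluster]
  if (!length(cells))
    stop("cluster ", target_cluster, " does not exist")
  min_pts <- if (!is.null(dbscan$min_pts)) dbscan$min_pts else 10L
  if (length(cells) < min_pts)
    stop("cluster ", target_cluster, " has fewer cells (", length(cells),
         ") than min_pts (", min_pts, ")")
  values <- expr$values[cells, , drop = FALSE]
  sub_expr <- structure(list(values = values,
                             total_umi = expr$total_umi[cells],
                             scale_factor = expr$scale_factor,
                             flags = expr$flags),
                        class = "scdens_expr")
  hv <- do.call(select_hvg, c(list(sub_expr), hvg))
  genes <- attr(hv, "genes")
  if (length(genes) < 2)
    stop("fewer than 2 variable genes in cluster ", target_cluster)
  pca_args <- c(list(sub_expr, genes = genes), pca)
  if (is.null(pca_args$n_components))
    pca_args$n_components <- min(20L, length(cells) - 1L, length(genes))
  if (is.null(pca_args$seed)) pca_args$seed <- seed
  pc <- do.call(run_pca, pca_args)
  tsne_args <- c(list(pc), tsne)
  if (is.null(tsne_args$n_pcs))
    tsne_args$n_pcs <- ncol(pc$scores)
  if (is.null(tsne_args$perplexity))
    tsne_args$perplexity <- min(30, floor((length(cells) - 2) / 3))
  if (is.null(tsne_args$seed)) tsne_args$seed <- seed
  emb <- do.call(run_tsne, tsne_args)
  cl <- do.call(dbscan_two_pass, c(list(emb), dbscan))
  sub_label <- ifelse(is.na(cl$final_label), NA_character_,
                      paste0(target_cluster, ".", cl$final_label))
  structure(list(assignment = data.frame(cell_id = cl$cell_id,
                                         subcluster = sub_label,
                                         stringsAsFactors = FALSE),
                 clusters = cl,
                 params = list(parent = target_cluster, hvg = hvg,
                               pca = pca, tsne = tsne, dbscan = dbscan,
                               seed = seed)),
            class = "scdens_subclusters")
}
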