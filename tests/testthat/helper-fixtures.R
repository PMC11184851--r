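## Shared fixtures and independent oracles for the test-suite.

## Small planted data set recovered perfectly by the pipeline: 4 equally
## weighted populations of ~225 cells with 40 markers each.
small_config <- function(seed = 42, ...) {
  sim_config(n_cells = 900L, n_genes = 500L, n_populations = 4L,
             markers_per_population = 40L, n_housekeeping = 40L,
             n_mito_genes = 10L,
             lr_programs = data.frame(ligand = "Lig1", receptor = "Rec1",
                                      sender = 2L, receiver = 4L,
                                      shift = 2.0),
             seed = seed, ...)
}

.fixture_cache <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.fixture_cache$sim))
    .fixture_cache$sim <- simulate_counts(small_config())
  .fixture_cache$sim
}

## Clustering object built from the ground-truth populations, to test the
## marker/crosstalk stages independently of DBSCAN.
truth_clusters <- function(sim, cells = NULL) {
  pop <- sim$truth$population
  if (!is.null(cells)) pop <- pop[cells]
  out <- data.frame(cell_id = names(pop),
                    pass1_label = unname(pop),
                    final_label = unname(pop),
                    removal_reason = factor("none",
                      levels = c("none", "noise_pass1",
                                 "small_cluster_pass1", "noise_pass2",
                                 "small_cluster_pass2")),
                    stringsAsFactors = FALSE)
  class(out) <- c("scdens_clusters", "data.frame")
  attr(out, "sizes") <- as.integer(sort(table(pop), decreasing = TRUE))
  out
}

## Normalized expression for the whole small fixture (no QC, no removal),
## restricted to cells with positive totals.
small_expr <- function() {
  if (is.null(.fixture_cache$expr)) {
    sim <- small_sim()
    keep <- rowSums(sim$counts) > 0
    .fixture_cache$expr <- normalize_log(sim$counts[keep, , drop = FALSE])
  }
  .fixture_cache$expr
}

## Independent O(n^2) DBSCAN: full distance matrix, textbook core-point
## expansion in index order (the same deterministic border-assignment rule
## as the package implementation, computed without the grid index).
dbscan_oracle <- function(coords, eps, min_pts) {
  n <- nrow(coords)
  D <- as.matrix(stats::dist(coords))
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- lengths(nb) >= min_pts
  labels <- integer(n)
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

## Canonical form of a partition: labels renumbered by first occurrence,
## noise (0 / NA) kept apart.
canon_partition <- function(labels) {
  labels <- ifelse(is.na(labels), 0L, labels)
  pos <- labels != 0L
  out <- integer(length(labels))
  out[pos] <- match(labels[pos], unique(labels[pos]))
  out
}

## Adjusted Rand index (independent of the package).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

## Hand-computed Benjamini-Hochberg step-up, as an oracle for bh_fdr().
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(n / (n:1) * p[o]))[ro]
  q
}
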