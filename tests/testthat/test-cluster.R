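## Deterministic blob coordinates: points on a small grid of spacing well
## below eps, blobs separated by `sep`.
blob_coords <- function(sizes, sep = 8, spacing = 0.1) {
  out <- NULL
  for (i in seq_along(sizes)) {
    k <- ceiling(sqrt(sizes[i]))
    g <- expand.grid(x = seq_len(k), y = seq_len(k))[seq_len(sizes[i]), ]
    out <- rbind(out, cbind(g$x * spacing + (i - 1) * sep, g$y * spacing))
  }
  rownames(out) <- paste0("c", seq_len(nrow(out)))
  colnames(out) <- c("tsne_1", "tsne_2")
  out
}

test_that("a single tight blob forms one cluster with nothing removed", {
  co <- blob_coords(30)
  cl <- dbscan_two_pass(co)
  expect_equal(attr(cl, "sizes"), 30L)
  expect_true(all(cl$removal_reason == "none"))
  expect_true(all(cl$final_label == 1L))
})

test_that("blobs of 100/50/5: the 5-cell blob is removed in pass 1", {
  co <- blob_coords(c(100, 50, 5))
  cl <- dbscan_two_pass(co)
  expect_equal(attr(cl, "sizes"), c(100L, 50L))
  removed <- is.na(cl$final_label)
  expect_equal(sum(removed), 5)
  ## the removed cells are exactly the third blob, taken out in pass 1
  expect_true(all(grepl("pass1", cl$removal_reason[removed])))
  expect_identical(which(removed), 151:155)
  ## final labels are ordered by decreasing size
  expect_equal(cl$final_label[1], 1L)
  expect_equal(cl$final_label[101], 2L)
})

test_that("the grid DBSCAN matches the brute-force oracle on random points", {
  for (seed in 1:3) {
    set.seed(seed)
    co <- matrix(runif(2 * 300, 0, 12), ncol = 2)
    for (eps in c(0.5, 1.0)) {
      got <- scdens:::.dbscan(co, eps, 10)
      want <- dbscan_oracle(co, eps, 10)
      expect_identical(canon_partition(got), canon_partition(want))
    }
  }
})

test_that("the removal ledger reconciles and final sizes respect the floor", {
  set.seed(9)
  co <- rbind(matrix(rnorm(2 * 120, sd = 0.4), ncol = 2),
              matrix(rnorm(2 * 60, sd = 0.4), ncol = 2) + 6,
              matrix(runif(2 * 40, -10, 16), ncol = 2))
  rownames(co) <- paste0("c", 1:220)
  cl <- dbscan_two_pass(co)
  removed <- sum(is.na(cl$final_label))
  expect_equal(removed + sum(!is.na(cl$final_label)), nrow(co))
  expect_equal(sum(cl$removal_reason != "none"), removed)
  expect_true(all(attr(cl, "sizes") >= 20))
  expect_equal(sort(unique(stats::na.omit(cl$final_label))),
               seq_along(attr(cl, "sizes")))
})

test_that("permuting the cell order yields the same partition", {
  set.seed(5)
  co <- blob_coords(c(80, 40, 30))
  co <- co + matrix(rnorm(length(co), sd = 0.02), nrow = nrow(co))
  cl1 <- dbscan_two_pass(co)
  perm <- sample(nrow(co))
  cl2 <- dbscan_two_pass(co[perm, ])
  m <- match(cl1$cell_id, cl2$cell_id)
  expect_equal(ari(cl1$final_label, cl2$final_label[m]), 1)
  expect_identical(attr(cl1, "sizes"), attr(cl2, "sizes"))
})

test_that("everything removed raises a degenerate-output error", {
  set.seed(1)
  co <- matrix(runif(2 * 30, 0, 100), ncol = 2)   # far too sparse
  expect_error(dbscan_two_pass(co), "all cells removed")
  expect_error(dbscan_two_pass(co[1:5, ]), "min_pts")
})

test_that("composition proportions and tests follow hand arithmetic", {
  cl <- data.frame(cell_id = paste0("c", 1:80),
                   pass1_label = 1L,
                   final_label = rep(c(1L, 2L, 1L, 2L), c(10, 30, 30, 10)),
                   removal_reason = factor("none",
                     levels = levels(factor("none"))),
                   stringsAsFactors = FALSE)
  class(cl) <- c("scdens_clusters", "data.frame")
  meta <- data.frame(cell_id = paste0("c", 1:80),
                     condition = rep(c("A", "B"), each = 40))
  comp <- composition_by_group(cl, meta)
  tab <- comp$composition
  expect_equal(tab$proportion[tab$cluster == 1 & tab$condition == "A"], 0.25)
  expect_equal(tab$proportion[tab$cluster == 1 & tab$condition == "B"], 0.75)
  expect_equal(tab$proportion[tab$cluster == 2 & tab$condition == "A"], 0.75)
  ## proportions sum to 1 within condition
  sums <- tapply(tab$proportion, tab$condition, sum)
  expect_equal(as.numeric(sums), c(1, 1))
  expect_true(all(comp$tests$p < 0.01))
})

test_that("identical composition across conditions gives q near 1", {
  cl <- data.frame(cell_id = paste0("c", 1:120),
                   pass1_label = 1L,
                   final_label = rep(rep(1:3, each = 20), 2),
                   removal_reason = factor("none"),
                   stringsAsFactors = FALSE)
  class(cl) <- c("scdens_clusters", "data.frame")
  meta <- data.frame(cell_id = paste0("c", 1:120),
                     condition = rep(c("A", "B"), each = 60))
  comp <- composition_by_group(cl, meta)
  expect_true(all(comp$tests$q > 0.99))
})

test_that("a single condition yields proportions but no tests", {
  cl <- data.frame(cell_id = paste0("c", 1:40), pass1_label = 1L,
                   final_label = rep(1:2, each = 20),
                   removal_reason = factor("none"), stringsAsFactors = FALSE)
  class(cl) <- c("scdens_clusters", "data.frame")
  meta <- data.frame(cell_id = paste0("c", 1:40), condition = "only")
  comp <- composition_by_group(cl, meta)
  expect_equal(nrow(comp$tests), 0)
  expect_equal(sum(comp$composition$proportion), 1)
})

test_that("subclustering splits planted substructure and keeps homogeneity", {
  ## two planted populations presented as a single parent cluster
  cfg <- sim_config(n_cells = 500, n_genes = 400, n_populations = 2,
                    markers_per_population = 40, n_housekeeping = 30,
                    n_mito_genes = 8, frac_low_quality = 0,
                    conditions = "only", n_batches = 1,
                    lr_programs = NULL, seed = 21)
  sim <- simulate_counts(cfg)
  expr <- normalize_log(sim$counts)
  parent <- truth_clusters(sim)
  parent$final_label[] <- 1L          # hide the substructure
  sub <- subcluster(expr, parent, 1, hvg = list(mean_high = 3),
                    seed = 21)
  lab <- sub$assignment$subcluster
  keep <- !is.na(lab)
  expect_equal(length(unique(lab[keep])), 2)
  expect_equal(ari(lab[keep],
                   sim$truth$population[sub$assignment$cell_id[keep]]), 1)
  expect_true(all(startsWith(lab[keep], "1.")))

  ## a homogeneous population stays a single subcluster
  one <- truth_clusters(sim)
  sub1 <- subcluster(expr, one, 1, hvg = list(mean_high = 3), seed = 3)
  l1 <- sub1$assignment$subcluster
  expect_equal(length(unique(na.omit(l1))), 1)

  ## parameter overrides are recorded
  sub2 <- subcluster(expr, one, 2, hvg = list(mean_high = 3),
                     dbscan = list(min_pts = 5L), seed = 4)
  expect_equal(sub2$params$dbscan$min_pts, 5L)
  expect_error(subcluster(expr, parent, 99), "does not exist")
})
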