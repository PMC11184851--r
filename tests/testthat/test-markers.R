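## Expression object around a plain matrix for the DE functions.
as_expr <- function(vals) {
  structure(list(values = vals,
                 total_umi = setNames(rep(100L, nrow(vals)),
                                      rownames(vals)),
                 scale_factor = 1e4,
                 flags = c(normalized = TRUE, umi_regressed = FALSE,
                           batch_corrected = FALSE)),
            class = "scdens_expr")
}

## Clustering object with given labels.
as_clusters <- function(labels, ids = names(labels)) {
  out <- data.frame(cell_id = ids, pass1_label = unname(labels),
                    final_label = unname(labels),
                    removal_reason = factor("none"),
                    stringsAsFactors = FALSE)
  class(out) <- c("scdens_clusters", "data.frame")
  out
}

## Draws from the bimodal model itself.
rbimod <- function(n, pi_expr, mu, sd) {
  x <- numeric(n)
  on <- runif(n) < pi_expr
  x[on] <- rnorm(sum(on), mu, sd)
  pmax(x, 0)
}

test_that("identical groups give statistic near 0 and p near 1", {
  set.seed(11)
  x <- rbimod(200, 0.7, 3, 0.5)
  r <- bimod_lrt(x[1:100], x[101:200])
  expect_lt(r$statistic, 12)
  expect_gt(r$p, 1e-3)
  rsame <- bimod_lrt(x, x)
  expect_equal(rsame$statistic, 0, tolerance = 1e-8)
  expect_equal(rsame$p, 1, tolerance = 1e-6)
})

test_that("all-zero groups give statistic 0 and p 1", {
  r <- bimod_lrt(rep(0, 20), rep(0, 30))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
})

test_that("a 3-log shift at high expression fraction is overwhelming", {
  set.seed(13)
  a <- rbimod(50, 0.9, 5, 0.6)
  b <- rbimod(50, 0.9, 2, 0.6)
  r <- bimod_lrt(a, b)
  expect_lt(r$p, 1e-6)
})

test_that("the scalar test agrees with the vectorized cluster path", {
  set.seed(17)
  vals <- cbind(g1 = rbimod(80, 0.6, 2, 0.7),
                g2 = rbimod(80, 0.8, 4, 0.5))
  rownames(vals) <- paste0("c", 1:80)
  labels <- setNames(rep(1:2, each = 40), rownames(vals))
  deg <- deg_one_vs_rest(as_expr(vals), as_clusters(labels),
                         min_log_diff = -Inf, max_fdr = 1.1,
                         all_records = TRUE)
  for (g in c("g1", "g2")) {
    want <- bimod_lrt(vals[1:40, g], vals[41:80, g])
    got <- deg$p[deg$gene == g & deg$cluster == 1]
    expect_equal(got, want$p, tolerance = 1e-12)
  }
})

test_that("one-vs-rest applies a strict effect-size boundary", {
  ## deterministic values: gene at exactly +0.5 excluded, +0.6 kept
  n <- 60
  base <- rep(c(1, 1.25), n / 2)          # nonconstant positives
  vals <- cbind(at = c(base + 0.5, base),
                above = c(base + 0.6, base),
                flat = rep(2, 2 * n))
  rownames(vals) <- paste0("c", seq_len(2 * n))
  labels <- setNames(rep(1:2, each = n), rownames(vals))
  deg <- deg_one_vs_rest(as_expr(vals), as_clusters(labels))
  d1 <- deg[deg$cluster == 1, ]
  expect_false("at" %in% d1$gene)        # diff exactly 0.5, strict >
  expect_true("above" %in% d1$gene)
  expect_false("flat" %in% d1$gene)
})

test_that("planted markers are recovered from the truth clustering", {
  sim <- small_sim()
  expr <- small_expr()
  cl <- truth_clusters(sim, rownames(expr$values))
  deg <- deg_one_vs_rest(expr, cl)
  recall <- sapply(1:4, function(p) {
    mk <- sim$truth$marker_genes[[p]]
    mean(mk %in% deg$gene[deg$cluster == p])
  })
  expect_true(all(recall >= 0.95))
  expect_true(all(deg$q < 0.01 & deg$avg_log_diff > 0.5))
})

test_that("pairwise sets demand significance against every other cluster", {
  ## 3 clusters; "shared" marks clusters 1 and 2 jointly, "unique" only 1
  n <- 50
  mk <- function(hi) c(rep(hi, n), rep(0.05, n), rep(0.05, n))
  base <- rep(c(2, 2.4), length.out = n)
  vals <- cbind(shared = c(base, base, rep(0.1, n)),
                unique = c(base, rep(0.1, n), rep(0.1, n)))
  rownames(vals) <- paste0("c", seq_len(3 * n))
  labels <- setNames(rep(1:3, each = n), rownames(vals))
  pw <- deg_pairwise(as_expr(vals), as_clusters(labels))
  expect_false("shared" %in% pw$sets[["1"]])   # fails 1 vs 2
  expect_true("unique" %in% pw$sets[["1"]])
  expect_false("unique" %in% pw$sets[["2"]])
})

test_that("with two clusters the pairwise set equals the single-pair DEGs", {
  sim <- small_sim()
  expr <- small_expr()
  cl <- truth_clusters(sim, rownames(expr$values))
  two <- cl[cl$final_label %in% 1:2, , drop = FALSE]
  class(two) <- class(cl)
  pw <- deg_pairwise(expr, two)
  rec <- pw$records
  direct1 <- rec$gene[rec$avg_log_diff > 0.25 & rec$p < 0.05]
  expect_setequal(pw$sets[["1"]], direct1)
})

test_that("marker overlap is set intersection with ordered output", {
  set1 <- data.frame(gene = c("a", "b", "c"), cluster = 1L,
                     avg_log_diff = c(2, 3, 1), p = 1e-5, q = 1e-4,
                     direction = 1, stringsAsFactors = FALSE)
  ## disjoint second set: no markers
  mk0 <- overlap_markers(set1, list(`1` = "zz"))
  expect_false(any(mk0$is_marker))
  ## subset second set: markers equal it
  mk1 <- overlap_markers(set1, list(`1` = c("b", "c")))
  expect_setequal(mk1$gene[mk1$is_marker], c("b", "c"))
  ## sorted by cluster then descending effect
  expect_equal(mk1$gene, c("b", "a", "c"))
})

test_that("markers on the planted fixture recover the planted genes", {
  sim <- small_sim()
  expr <- small_expr()
  cl <- truth_clusters(sim, rownames(expr$values))
  mk <- overlap_markers(deg_one_vs_rest(expr, cl),
                        deg_pairwise(expr, cl))
  called <- mk[mk$is_marker, ]
  planted <- unlist(sim$truth$marker_genes)
  recall <- mean(planted %in% called$gene)
  expect_gte(recall, 0.95)
  ## anything extra is a planted ligand-receptor program gene
  extra <- setdiff(called$gene, planted)
  expect_true(all(extra %in% c(sim$truth$lr_pairs$ligand,
                               sim$truth$lr_pairs$receptor)))
})

test_that("duplicated clusters fail the post-hoc validity check", {
  set.seed(23)
  vals <- matrix(rbimod(100 * 20, 0.6, 2, 0.5), 100, 20,
                 dimnames = list(paste0("c", 1:100), paste0("g", 1:20)))
  labels <- setNames(rep(1:2, 50), rownames(vals))  # interleaved halves
  v <- posthoc_cluster_validity(as_expr(vals), as_clusters(labels))
  expect_equal(v$n_degs, 0)
  expect_false(any(v$pass))
})

test_that("post-hoc DEG counts shrink as the effect threshold rises", {
  sim <- small_sim()
  expr <- small_expr()
  cl <- truth_clusters(sim, rownames(expr$values))
  v1 <- posthoc_cluster_validity(expr, cl, min_log_diff = 0.5)
  v2 <- posthoc_cluster_validity(expr, cl, min_log_diff = 1.0)
  v3 <- posthoc_cluster_validity(expr, cl, min_log_diff = 1.5)
  expect_true(all(v2$n_degs <= v1$n_degs))
  expect_true(all(v3$n_degs <= v2$n_degs))
  ## the planted fixture passes at the default thresholds
  expect_true(all(v2$pass))
})

test_that("BH q-values match the hand step-up", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(29)
  for (i in 1:5) {
    p <- runif(50)^2
    expect_equal(bh_fdr(p), bh_oracle(p))
    expect_true(all(bh_fdr(p) >= p))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("top markers use the effect/q/name tie-break and report shortfalls", {
  mk <- data.frame(gene = c("b", "a", "c", "d"), cluster = 1L,
                   avg_log_diff = c(2, 2, 2, 3),
                   p = 1e-6, q = c(1e-3, 1e-3, 1e-4, 1e-5),
                   direction = 1, in_set1 = TRUE, in_set2 = TRUE,
                   is_marker = TRUE, stringsAsFactors = FALSE)
  class(mk) <- c("scdens_markers", "data.frame")
  top <- top_markers(mk, 3)
  expect_equal(top$gene, c("d", "c", "a"))   # effect, then q, then name
  expect_message(full <- top_markers(mk, 10), "only 4")
  expect_equal(nrow(full), 4)
})

test_that("marker sets shrink monotonically as thresholds tighten", {
  sim <- small_sim()
  expr <- small_expr()
  cl <- truth_clusters(sim, rownames(expr$values))
  loose <- deg_one_vs_rest(expr, cl, min_log_diff = 0.25, max_fdr = 0.05)
  tight <- deg_one_vs_rest(expr, cl, min_log_diff = 0.75, max_fdr = 0.001)
  key <- function(d) paste(d$gene, d$cluster)
  expect_true(all(key(tight) %in% key(loose)))
  pw_loose <- deg_pairwise(expr, cl, min_log_diff = 0.1, max_p = 0.1)
  pw_tight <- deg_pairwise(expr, cl, min_log_diff = 0.5, max_p = 0.01)
  for (k in names(pw_loose$sets))
    expect_true(all(pw_tight$sets[[k]] %in% pw_loose$sets[[k]]))
})
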