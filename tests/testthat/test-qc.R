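test_that("cell filters use strict inequalities at the thresholds", {
  ## detected-gene boundaries with scaled-down thresholds
  n_genes <- 12
  counts <- rbind(
    below  = c(rep(1L, 3), rep(0L, 9)),   # 3 detected  (< 4: removed)
    at_min = c(rep(1L, 4), rep(0L, 8)),   # 4 detected  (= min: kept)
    at_max = c(rep(1L, 8), rep(0L, 4)),   # 8 detected  (= max: kept)
    above  = c(rep(1L, 9), rep(0L, 3)))   # 9 detected  (> 8: removed)
  colnames(counts) <- paste0("g", seq_len(n_genes))
  fl <- filter_cells_genes(counts, min_genes = 4, max_genes = 8,
                           min_cells_per_gene = 1, max_mito = 0.5)
  expect_setequal(fl$removed_cells, c("below", "above"))
  expect_equal(fl$report$removed_low_gene, 1)
  expect_equal(fl$report$removed_high_gene, 1)
})

test_that("mitochondrial fraction at exactly the ceiling is retained", {
  counts <- rbind(at   = c(5L, 5L, 2L, 2L, 2L),  # mito 10/16 > 0.5? no: 10/16
                  over = c(9L, 9L, 1L, 1L, 1L),  # mito 18/21 > 0.5: removed
                  low  = c(1L, 1L, 5L, 5L, 5L))
  colnames(counts) <- c("Mt-1", "Mt-2", "g1", "g2", "g3")
  ## make "at" exactly 0.5: mito 6 of 12
  counts["at", ] <- c(3L, 3L, 2L, 2L, 2L)
  md <- cell_metadata(counts)
  expect_equal(md$mito_fraction[md$cell_id == "at"], 0.5)
  fl <- filter_cells_genes(counts, min_genes = 1, max_genes = 10,
                           min_cells_per_gene = 1, max_mito = 0.5)
  expect_setequal(fl$removed_cells, "over")
})

test_that("high-mito toy cell is the only removal, verified by recount", {
  set.seed(1)
  counts <- matrix(rpois(6 * 20, 3), nrow = 6,
                   dimnames = list(paste0("c", 1:6),
                                   c(paste0("Mt-", 1:2), paste0("g", 1:18))))
  counts[3, ] <- c(30L, 30L, rep(1L, 18))        # mito fraction 60/78 = 0.77
  fl <- filter_cells_genes(counts, min_genes = 1, max_genes = 100,
                           min_cells_per_gene = 1, max_mito = 0.5)
  ## brute-force recount of the rule
  mito_frac <- rowSums(counts[, 1:2]) / rowSums(counts)
  expect_setequal(fl$removed_cells, rownames(counts)[mito_frac > 0.5])
  expect_equal(fl$removed_cells, "c3")
})

test_that("gene prevalence rule drops genes seen in too few cells", {
  counts <- matrix(1L, nrow = 12, ncol = 3,
                   dimnames = list(paste0("c", 1:12), c("a", "zero", "rare")))
  counts[, "zero"] <- 0L
  counts[, "rare"] <- c(rep(1L, 9), 0L, 0L, 0L)   # 9 cells < 10
  fl <- filter_cells_genes(counts, min_genes = 1, max_genes = 10,
                           min_cells_per_gene = 10)
  expect_identical(colnames(fl$counts), "a")
  expect_equal(fl$report$removed_low_prevalence_gene, 2)
})

test_that("QC report arithmetic reconciles and the filter is idempotent", {
  sim <- small_sim()
  fl <- filter_cells_genes(sim$counts)
  r <- fl$report
  expect_equal(r$n_cells_in - r$n_cells_out,
               r$removed_low_gene + r$removed_high_gene +
                 r$removed_high_mito)
  expect_equal(r$n_genes_in - r$n_genes_out,
               r$removed_low_prevalence_gene)
  fl2 <- filter_cells_genes(fl$counts)
  expect_identical(fl2$counts, fl$counts)
  expect_equal(fl2$report$n_cells_in, fl2$report$n_cells_out)
})

test_that("all cells removed raises a degenerate-output error", {
  counts <- matrix(1L, 2, 3, dimnames = list(c("a", "b"), c("x", "y", "z")))
  expect_error(filter_cells_genes(counts, min_genes = 5),
               "all cells removed")
})

test_that("normalization follows ln(1 + count * scale / total)", {
  counts <- matrix(c(1L, rep(0L, 4),
                     5L, 45L, 0L, 0L, 0L), nrow = 2, byrow = TRUE,
                   dimnames = list(c("single", "fifty"), paste0("g", 1:5)))
  ex <- normalize_log(counts)
  ## a cell with a single molecule of a single gene
  expect_equal(ex$values["single", "g1"], log(1 + 1e4))
  ## count 5 of total 50 at scale 1e4
  expect_equal(ex$values["fifty", "g1"], log(1 + 1000))
  ## conservation per cell
  back <- rowSums(exp(ex$values) - 1)
  expect_equal(back, c(single = 1e4, fifty = 1e4), tolerance = 1e-9)
})

test_that("normalization conservation holds on the simulated fixture", {
  ex <- small_expr()
  back <- rowSums(exp(ex$values) - 1)
  expect_equal(max(abs(back - 1e4) / 1e4), 0, tolerance = 1e-6)
})

test_that("zero-total cells make normalization fail with guidance", {
  counts <- matrix(c(1L, 0L, 0L, 0L), 2, 2,
                   dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(normalize_log(counts), "filter_cells_genes")
})

test_that("UMI regression leaves residuals orthogonal to the totals", {
  set.seed(7)
  ex <- small_expr()
  reg <- regress_out_umi(ex)
  expect_true(reg$flags["umi_regressed"])
  cors <- apply(reg$values[, 1:50], 2, function(v)
    if (sd(v) == 0) 0 else cor(v, ex$total_umi))
  expect_lt(max(abs(cors)), 1e-8)
  ## grand means are preserved
  expect_equal(colMeans(reg$values), colMeans(ex$values))
})

test_that("genes constant or exactly linear in the totals regress to flat", {
  tot <- as.integer(seq(100, 1000, length.out = 30))
  vals <- cbind(const = rep(2, 30),
                linear = 0.5 + 0.001 * tot)
  rownames(vals) <- paste0("c", 1:30)
  ex <- structure(list(values = vals, total_umi = setNames(tot,
                                                           rownames(vals)),
                       scale_factor = 1e4,
                       flags = c(normalized = TRUE, umi_regressed = FALSE,
                                 batch_corrected = FALSE)),
                  class = "scdens_expr")
  reg <- regress_out_umi(ex)
  expect_equal(reg$values[, "const"], vals[, "const"], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unname(reg$values[, "linear"]),
               rep(mean(vals[, "linear"]), 30), tolerance = 1e-10)
})

test_that("constant totals leave the matrix unchanged with a warning", {
  ex <- small_expr()
  ex$total_umi[] <- 500L
  expect_warning(reg <- regress_out_umi(ex), "constant")
  expect_equal(reg$values, ex$values)
})

test_that("batch correction equalizes per-gene batch means and is idempotent", {
  set.seed(3)
  vals <- matrix(rnorm(200 * 5), 200, 5,
                 dimnames = list(paste0("c", 1:200), paste0("g", 1:5)))
  batch <- rep(c("b1", "b2"), each = 100)
  delta <- 0.7
  vals[batch == "b2", "g1"] <- vals[batch == "b2", "g1"] + delta
  ex <- structure(list(values = vals,
                       total_umi = setNames(rep(100L, 200), rownames(vals)),
                       scale_factor = 1e4,
                       flags = c(normalized = TRUE, umi_regressed = FALSE,
                                 batch_corrected = FALSE)),
                  class = "scdens_expr")
  cor1 <- correct_batch(ex, batch)
  m1 <- colMeans(cor1$values[batch == "b1", ])
  m2 <- colMeans(cor1$values[batch == "b2", ])
  expect_equal(m1, m2, tolerance = 1e-12)
  ## grand mean preserved
  expect_equal(colMeans(cor1$values), colMeans(vals))
  ## idempotence
  cor2 <- correct_batch(cor1, batch)
  expect_equal(cor2$values, cor1$values, tolerance = 1e-12)
  ## single batch is the identity
  same <- correct_batch(ex, rep("b1", 200))
  expect_equal(same$values, ex$values)
})

test_that("removal percentage is truncated, not rounded", {
  expect_equal(removal_percent(320, 27744), 1.1)
  expect_equal(removal_percent(1, 3), 33.3)
  expect_equal(removal_percent(0, 10), 0)
})
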