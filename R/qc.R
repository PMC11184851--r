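#' Per-cell metadata computed from raw counts
#'
#' Computes the per-cell totals used by the QC filters and by UMI
#' regression: total UMI (row sum of raw counts), number of detected genes
#' and mitochondrial fraction (on raw counts).
#'
#' @param counts raw integer matrix, cells x genes.
#' @param mito_genes explicit mitochondrial gene set; if `NULL`, genes are
#'   matched by `mito_prefix`.
#' @param mito_prefix prefixes identifying mitochondrial genes.
#' @param meta optional data.frame with `cell_id` plus e.g. `condition`,
#'   `batch`; merged into the result.
#' @return data.frame with `cell_id`, `total_umi`, `n_genes_detected`,
#'   `mito_fraction` and any extra metadata columns.
#' @export
cell_metadata <- function(counts, mito_genes = NULL,
                          mito_prefix = c("Mt-", "mt-", "MT-"),
                          meta = NULL) {
  mito <- .mito_set(colnames(counts), mito_genes, mito_prefix)
  tot <- rowSums(counts)
  out <- data.frame(
    cell_id = rownames(counts),
    total_umi = as.integer(tot),
    n_genes_detected = as.integer(rowSums(counts > 0)),
    mito_fraction = if (length(mito))
      rowSums(counts[, mito, drop = FALSE]) / pmax(tot, 1) else 0,
    stringsAsFactors = FALSE)
  if (!is.null(meta)) {
    extra <- meta[match(out$cell_id, meta$cell_id),
                  setdiff(names(meta), names(out)), drop = FALSE]
    out <- cbind(out, extra)
  }
  rownames(out) <- NULL
  out
}

.mito_set <- function(gene_ids, mito_genes, mito_prefix) {
  if (!is.null(mito_genes)) {
    missing <- setdiff(mito_genes, gene_ids)
    if (length(missing))
      stop("mito_genes not present in the matrix: ",
           paste(utils::head(missing, 3), collapse = ", "))
    return(mito_genes)
  }
  gene_ids[startsWith(gene_ids, mito_prefix[1]) |
             Reduce(`|`, lapply(mito_prefix[-1],
                                function(p) startsWith(gene_ids, p)),
                    init = FALSE)]
}

#' Filter cells and genes on the raw count matrix
#'
#' Cell rules are evaluated on the raw matrix with strict inequalities: a
#' cell is removed when its number of detected genes is below `min_genes`
#' or above `max_genes`, or its mitochondrial fraction exceeds `max_mito`.
#' Cells at exactly the thresholds are retained.  The gene prevalence rule
#' (expressed in at least `min_cells_per_gene` cells) is then applied to the
#' surviving cells.  Re-applying the filter to its own output is a no-op.
#'
#' @param counts raw integer matrix, cells x genes.
#' @param min_genes,max_genes detected-gene window (default 200, 3000).
#' @param min_cells_per_gene gene prevalence floor (default 10).
#' @param max_mito mitochondrial fraction ceiling (default 0.5).
#' @param mito_genes,mito_prefix mitochondrial gene set, see
#'   [cell_metadata()].
#' @return list with `counts` (filtered matrix), `meta` (metadata of
#'   retained cells), `report` (an `scdens_qc_report`: in/out dimensions and
#'   per-rule removal counts; a cell failing several rules is attributed to
#'   the first in the order low-gene, high-gene, high-mito), and
#'   `removed_cells`.
#' @export
filter_cells_genes <- function(counts, min_genes = 200L, max_genes = 3000L,
                               min_cells_per_gene = 10L, max_mito = 0.5,
                               mito_genes = NULL,
                               mito_prefix = c("Mt-", "mt-", "MT-")) {
  stopifnot(min_genes > 0, max_genes > 0, min_cells_per_gene > 0,
            max_mito > 0)
  if (min_genes > max_genes)
    stop("min_genes must not exceed max_genes")
  md <- cell_metadata(counts, mito_genes, mito_prefix)
  low <- md$n_genes_detected < min_genes
  high <- !low & md$n_genes_detected > max_genes
  mito <- !low & !high & md$mito_fraction > max_mito
  drop_cell <- low | high | mito
  if (all(drop_cell))
    stop("degenerate output: all cells removed by the QC filters")
  kept <- counts[!drop_cell, , drop = FALSE]
  gene_keep <- colSums(kept > 0) >= min_cells_per_gene
  report <- structure(list(
    n_cells_in = nrow(counts), n_cells_out = sum(!drop_cell),
    n_genes_in = ncol(counts), n_genes_out = sum(gene_keep),
    removed_low_gene = sum(low),
    removed_high_gene = sum(high),
    removed_high_mito = sum(mito),
    removed_low_prevalence_gene = sum(!gene_keep),
    params = list(min_genes = min_genes, max_genes = max_genes,
                  min_cells_per_gene = min_cells_per_gene,
                  max_mito = max_mito)),
    class = "scdens_qc_report")
  list(counts = kept[, gene_keep, drop = FALSE],
       meta = md[!drop_cell, , drop = FALSE],
       report = report,
       removed_cells = md$cell_id[drop_cell])
}

#' @export
print.scdens_qc_report <- function(x, ...) {
  cat("QC report\n")
  cat("  cells:", x$n_cells_in, "->", x$n_cells_out,
      sprintf("(low-gene %d, high-gene %d, high-mito %d)\n",
              x$removed_low_gene, x$removed_high_gene, x$removed_high_mito))
  cat("  genes:", x$n_genes_in, "->", x$n_genes_out,
      sprintf("(low-prevalence %d)\n", x$removed_low_prevalence_gene))
  invisible(x)
}

#' Depth-normalize and natural-log transform counts
#'
#' Scales each cell to `scale_factor` total molecules and applies
#' `log(1 + x)`: `value(c,g) = ln(1 + count(c,g) * scale_factor /
#' total_umi(c))`.  Per cell, `sum(exp(value) - 1)` equals `scale_factor`
#' up to floating tolerance.
#'
#' @param counts raw integer matrix, cells x genes (filtered).
#' @param scale_factor target molecules per cell (default `1e4`).
#' @return an `scdens_expr` object: list with `values` (cells x genes,
#'   natural-log scale), `total_umi`, `scale_factor` and provenance `flags`
#'   (`normalized`, `umi_regressed`, `batch_corrected`).
#' @export
normalize_log <- function(counts, scale_factor = 1e4) {
  tot <- rowSums(counts)
  if (any(tot == 0))
    stop("cells with zero total counts present; run filter_cells_genes() ",
         "before normalizing")
  values <- log1p(counts * (scale_factor / tot))
  structure(list(values = values,
                 total_umi = stats::setNames(as.integer(tot),
                                             rownames(counts)),
                 scale_factor = scale_factor,
                 flags = c(normalized = TRUE, umi_regressed = FALSE,
                           batch_corrected = FALSE)),
            class = "scdens_expr")
}

#' @export
print.scdens_expr <- function(x, ...) {
  cat("Expression matrix:", nrow(x$values), "cells x", ncol(x$values),
      "genes\n  flags:",
      paste(names(x$flags)[x$flags], collapse = ", "), "\n")
  invisible(x)
}

#' Regress per-cell UMI totals out of the expression values
#'
#' Per gene, replaces the values by the residuals of an ordinary
#' least-squares fit of expression on the cell's total UMI count (with
#' intercept), with the gene's grand mean added back so values remain
#' comparable in sign.  Residuals are uncorrelated with the totals.
#'
#' @param expr an `scdens_expr` (normalized).
#' @param total_umi optional override of the totals stored in `expr`.
#' @return the modified `scdens_expr` with flag `umi_regressed` set.
#' @export
regress_out_umi <- function(expr, total_umi = NULL) {
  stopifnot(inherits(expr, "scdens_expr"))
  tot <- if (is.null(total_umi)) expr$total_umi else total_umi
  stopifnot(length(tot) == nrow(expr$values))
  if (stats::var(tot) == 0) {
    warning("total UMI constant across cells; returning input unchanged")
    expr$flags["umi_regressed"] <- TRUE
    return(expr)
  }
  X <- cbind(1, as.numeric(tot))
  fit <- stats::lm.fit(X, expr$values)
  gm <- colMeans(expr$values)
  expr$values <- fit$residuals + rep(gm, each = nrow(expr$values))
  expr$flags["umi_regressed"] <- TRUE
  expr
}

#' Remove linear batch offsets from the expression values
#'
#' Per gene, estimates batch-mean offsets by least squares on batch
#' indicators and subtracts them while preserving the gene's grand mean, so
#' per-gene batch means are equalized.  Applying the correction twice is a
#' no-op; a single batch returns the input unchanged.
#'
#' @param expr an `scdens_expr`.
#' @param batch batch label per cell (character or factor).
#' @return the modified `scdens_expr` with flag `batch_corrected` set.
#' @export
correct_batch <- function(expr, batch) {
  stopifnot(inherits(expr, "scdens_expr"),
            length(batch) == nrow(expr$values))
  batch <- as.factor(batch)
  if (nlevels(batch) < 2) {
    expr$flags["batch_corrected"] <- TRUE
    return(expr)
  }
  sizes <- table(batch)
  if (any(sizes < 2))
    warning("batch(es) with fewer than 2 cells: ",
            paste(names(sizes)[sizes < 2], collapse = ", "),
            "; offsets estimated anyway")
  gm <- colMeans(expr$values)
  for (b in levels(batch)) {
    idx <- which(batch == b)
    bm <- colMeans(expr$values[idx, , drop = FALSE])
    expr$values[idx, ] <- expr$values[idx, , drop = FALSE] -
      rep(bm - gm, each = length(idx))
  }
  expr$flags["batch_corrected"] <- TRUE
  expr
}

#' Truncated removal percentage
#'
#' Formats the share of removed cells the way the clustering report prints
#' it: the percentage truncated (not rounded) to `digits` decimals, so 320
#' removed of 27,744 cells reads as 1.1 (percent).
#'
#' @param n_removed,n_total cell counts.
#' @param digits decimals kept after truncation.
#' @return numeric percentage.
#' @export
removal_percent <- function(n_removed, n_total, digits = 1L) {
  stopifnot(n_total > 0, n_removed >= 0)
  trunc(100 * n_removed / n_total * 10^digits) / 10^digits
}
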