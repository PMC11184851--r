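#' Write a simulated data set to disk as plain-text fixtures
#'
#' Emits the counts as a Matrix-Market coordinate file (1-based indices)
#' plus gene/cell label files, the cell metadata and the ground truth as
#' TSVs, and the planted ligand-receptor pairs as a two-column TSV usable by
#' [load_lr_database()].
#'
#' @param sim an `scdens_sim` from [simulate_counts()], or a bare counts
#'   matrix (cells x genes with dimnames).
#' @param dir output directory, created if missing.
#' @return invisibly, a named character vector of the files written.
#' @export
write_fixture <- function(sim, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir))
      stop("cannot create output directory: ", dir)
  }
  counts <- if (inherits(sim, "scdens_sim")) sim$counts else sim
  stopifnot(is.matrix(counts) || methods::is(counts, "Matrix"))
  paths <- c(counts = file.path(dir, "counts.mtx"),
             genes = file.path(dir, "genes.tsv"),
             cells = file.path(dir, "cells.tsv"))
  m <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                               "generalMatrix"), "TsparseMatrix")
  Matrix::writeMM(m, paths["counts"])
  writeLines(as.character(colnames(counts)), paths["genes"])
  writeLines(as.character(rownames(counts)), paths["cells"])
  if (inherits(sim, "scdens_sim")) {
    paths["meta"] <- file.path(dir, "metadata.tsv")
    utils::write.table(sim$meta, paths["meta"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    tr <- sim$truth
    cell_truth <- data.frame(cell_id = rownames(counts),
                             population = unname(tr$population),
                             low_quality = unname(tr$low_quality),
                             stringsAsFactors = FALSE)
    paths["truth_cells"] <- file.path(dir, "truth_cells.tsv")
    utils::write.table(cell_truth, paths["truth_cells"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    marker_pop <- rep(seq_along(tr$marker_genes),
                      lengths(tr$marker_genes))
    gene_truth <- data.frame(gene_id = colnames(counts),
                             marker_of = NA_integer_,
                             mitochondrial = colnames(counts) %in%
                               tr$mito_genes,
                             stringsAsFactors = FALSE)
    gene_truth$marker_of[match(unlist(tr$marker_genes),
                               gene_truth$gene_id)] <- marker_pop
    paths["truth_genes"] <- file.path(dir, "truth_genes.tsv")
    utils::write.table(gene_truth, paths["truth_genes"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(tr$lr_pairs)) {
      paths["lr_pairs"] <- file.path(dir, "lr_pairs.tsv")
      utils::write.table(tr$lr_pairs[, c("ligand", "receptor")],
                         paths["lr_pairs"], sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
  }
  invisible(paths)
}

#' Read a count matrix from disk
#'
#' Reads either a Matrix-Market triplet file with companion gene/cell label
#' files (as written by [write_fixture()]) or a dense TSV with gene columns
#' and a `cell_id` first column.  The result is always oriented cells x
#' genes; if the on-disk matrix is genes x cells, say so with
#' `orientation = "genes_by_cells"`.
#'
#' @param path for `format = "mtx"`, the directory containing `counts.mtx`,
#'   `genes.tsv`, `cells.tsv` (or the path of the `.mtx` file itself, with
#'   the label files alongside); for `format = "tsv"`, the TSV file.
#' @param format `"mtx"` or `"tsv"`.
#' @param orientation orientation of the on-disk matrix.
#' @return a list with `counts` (dense integer matrix, cells x genes) and
#'   `meta` (data.frame skeleton with `cell_id`, `total_umi`,
#'   `n_genes_detected` computed from the raw counts).
#' @export
read_counts <- function(path, format = c("mtx", "tsv"),
                        orientation = c("cells_by_genes", "genes_by_cells")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (format == "mtx") {
    if (dir.exists(path)) {
      mtx <- file.path(path, "counts.mtx")
      gf <- file.path(path, "genes.tsv")
      cf <- file.path(path, "cells.tsv")
    } else {
      mtx <- path
      gf <- file.path(dirname(path), "genes.tsv")
      cf <- file.path(dirname(path), "cells.tsv")
    }
    if (!file.exists(mtx)) stop("counts file not found: ", mtx)
    if (!file.exists(gf)) stop("gene label file not found: ", gf)
    if (!file.exists(cf)) stop("cell label file not found: ", cf)
    m <- as.matrix(Matrix::readMM(mtx))
    genes <- readLines(gf)
    cells <- readLines(cf)
    if (orientation == "genes_by_cells") m <- t(m)
    if (nrow(m) != length(cells))
      stop("dimension mismatch: matrix has ", nrow(m), " rows but ",
           length(cells), " cell labels (", cf, ")")
    if (ncol(m) != length(genes))
      stop("dimension mismatch: matrix has ", ncol(m), " columns but ",
           length(genes), " gene labels (", gf, ")")
    dimnames(m) <- list(cells, genes)
  } else {
    if (!file.exists(path)) stop("counts file not found: ", path)
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE)
    ids <- df[[1]]
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- ids
    if (orientation == "genes_by_cells") m <- t(m)
  }
  if (any(m < 0) || any(m != round(m)))
    stop("count matrix must contain non-negative integers")
  if (anyDuplicated(rownames(m))) stop("duplicate cell identifiers")
  if (anyDuplicated(colnames(m))) stop("duplicate gene identifiers")
  storage.mode(m) <- "integer"
  list(counts = m,
       meta = data.frame(cell_id = rownames(m),
                         total_umi = as.integer(rowSums(m)),
                         n_genes_detected = as.integer(rowSums(m > 0)),
                         stringsAsFactors = FALSE))
}

#' Load a ligand-receptor pair table
#'
#' Reads a TSV with a header and at least two columns (ligand, receptor;
#' an optional third column is kept as annotation).  Duplicated pairs are
#' dropped with a warning.  Genes absent from an expression matrix are
#' flagged at scoring time, not here.
#'
#' @param path TSV file path.
#' @return data.frame of class `scdens_lr` with columns `ligand`,
#'   `receptor`, `annotation`.
#' @export
load_lr_database <- function(path) {
  if (!file.exists(path)) stop("ligand-receptor file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0) stop("ligand-receptor file is empty: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2)
  if (length(bad))
    stop("malformed ligand-receptor row (need >= 2 tab-separated fields) ",
         "at line ", bad[1], " of ", path)
  rows <- parts[-1]
  db <- data.frame(
    ligand = vapply(rows, `[[`, "", 1),
    receptor = vapply(rows, `[[`, "", 2),
    annotation = vapply(rows, function(p) if (length(p) >= 3) p[[3]] else "",
                        ""),
    stringsAsFactors = FALSE)
  if (any(!nzchar(db$ligand)) || any(!nzchar(db$receptor)))
    stop("empty gene identifier in ligand-receptor table: ", path)
  key <- paste(db$ligand, db$receptor, sep = "\r")
  if (anyDuplicated(key)) {
    warning("dropping ", sum(duplicated(key)),
            " duplicated ligand-receptor pair(s)")
    db <- db[!duplicated(key), , drop = FALSE]
    rownames(db) <- NULL
  }
  class(db) <- c("scdens_lr", "data.frame")
  db
}
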