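#' Ligand-receptor interaction score for one cluster pair
#'
#' The score of a (ligand, receptor, sender, receiver) quadruple is the
#' mean of the two average expression levels: mean ligand expression over
#' the sender cells averaged with mean receptor expression over the
#' receiver cells.
#'
#' @param expr `scdens_expr` or matrix of log-normalized values.
#' @param clusters an `scdens_clusters`.
#' @param ligand,receptor gene identifiers.
#' @param sender,receiver final cluster labels.
#' @return numeric score; `NA` with a warning when a gene is absent from
#'   the matrix.
#' @export
interaction_score <- function(expr, clusters, ligand, receptor,
                              sender, receiver) {
  values <- .expr_values(expr)
  r <- .retained(values, clusters)
  if (!(ligand %in% colnames(values)) || !(receptor %in% colnames(values))) {
    warning("gene absent from the expression matrix: ",
            paste(setdiff(c(ligand, receptor), colnames(values)),
                  collapse = ", "))
    return(NA_real_)
  }
  sc <- which(r$labels == sender)
  rc <- which(r$labels == receiver)
  if (!length(sc) || !length(rc))
    stop("empty sender or receiver cluster")
  (mean(r$values[sc, ligand]) + mean(r$values[rc, receptor])) / 2
}

#' Permutation p-values for ligand-receptor interactions
#'
#' Scores every ligand-receptor pair of the database for every ordered
#' (sender, receiver) cluster pair and attaches permutation p-values: each
#' permutation shuffles the cluster labels of all retained cells, and
#' `p = (1 + #\{permuted score >= observed\}) / (n_perm + 1)`.  Pairs where
#' the ligand is expressed (value > 0) in less than `min_frac` of the
#' sender cells, or the receptor in less than `min_frac` of the receiver
#' cells, are reported with `p = 1` and the `excluded` flag; pairs whose
#' genes are missing from the matrix carry `NA` scores.  q-values are
#' Benjamini-Hochberg across the tested (non-excluded) rows.
#'
#' @param expr `scdens_expr` or matrix of log-normalized values.
#' @param clusters an `scdens_clusters`.
#' @param db an `scdens_lr` table from [load_lr_database()] (or any
#'   data.frame with `ligand` and `receptor` columns).
#' @param n_perm number of label permutations (>= 100; default 1000).
#' @param min_frac expressing-cell fraction required in sender and
#'   receiver (default 0.1).
#' @param seed integer seed; the full table is deterministic given the
#'   seed.
#' @param directions `"both"` scores every ordered cluster pair
#'   (including sender == receiver); `"distinct"` skips autocrine pairs.
#' @return data.frame of class `scdens_interactions` with `ligand`,
#'   `receptor`, `sender`, `receiver`, `score`, `frac_ligand`,
#'   `frac_receptor`, `excluded`, `p`, `q`.
#' @export
permutation_pvalues <- function(expr, clusters, db, n_perm = 1000L,
                                min_frac = 0.1, seed = 1L,
                                directions = c("both", "distinct")) {
  directions <- match.arg(directions)
  if (n_perm < 100) stop("n_perm must be at least 100")
  if (!nrow(db)) stop("empty ligand-receptor database")
  values <- .expr_values(expr)
  r <- .retained(values, clusters)
  lev <- sort(unique(r$labels))
  if (length(lev) < 2) stop("need at least 2 clusters")

  genes <- unique(c(db$ligand, db$receptor))
  present <- genes[genes %in% colnames(r$values)]
  V <- r$values[, present, drop = FALSE]
  f <- factor(r$labels, levels = lev)
  nc <- as.vector(table(f))
  cl_mean <- rowsum(V, f) / nc              # clusters x genes
  cl_frac <- rowsum(1 * (V > 0), f) / nc

  grid <- expand.grid(pair = seq_len(nrow(db)),
                      sender = lev, receiver = lev,
                      KEEP.OUT.ATTRS = FALSE)
  if (directions == "distinct")
    grid <- grid[grid$sender != grid$receiver, , drop = FALSE]
  out <- data.frame(ligand = db$ligand[grid$pair],
                    receptor = db$receptor[grid$pair],
                    sender = grid$sender, receiver = grid$receiver,
                    stringsAsFactors = FALSE)
  li <- match(out$ligand, present)
  ri <- match(out$receptor, present)
  si <- match(out$sender, lev)
  vi <- match(out$receiver, lev)
  known <- !is.na(li) & !is.na(ri)
  out$score <- NA_real_
  out$frac_ligand <- NA_real_
  out$frac_receptor <- NA_real_
  out$score[known] <- (cl_mean[cbind(si, li)][known] +
                         cl_mean[cbind(vi, ri)][known]) / 2
  out$frac_ligand[known] <- cl_frac[cbind(si, li)][known]
  out$frac_receptor[known] <- cl_frac[cbind(vi, ri)][known]
  out$excluded <- !known | out$frac_ligand < min_frac |
    out$frac_receptor < min_frac
  tested <- which(!out$excluded)

  exceed <- integer(nrow(out))
  set.seed(as.integer(seed))
  for (b in seq_len(n_perm)) {
    fp <- sample(f)
    pm <- rowsum(V, fp) / as.vector(table(fp))
    ps <- (pm[cbind(si[tested], li[tested])] +
             pm[cbind(vi[tested], ri[tested])]) / 2
    exceed[tested] <- exceed[tested] + (ps >= out$score[tested])
  }
  out$p <- 1
  out$p[tested] <- (1 + exceed[tested]) / (n_perm + 1)
  out$q <- NA_real_
  out$q[tested] <- stats::p.adjust(out$p[tested], method = "BH")
  attr(out, "params") <- list(n_perm = n_perm, min_frac = min_frac,
                              seed = as.integer(seed))
  class(out) <- c("scdens_interactions", "data.frame")
  out
}

#' @export
print.scdens_interactions <- function(x, ...) {
  if (is.null(x$excluded)) return(print.data.frame(x, ...))
  cat("Ligand-receptor interactions:", nrow(x), "rows (",
      sum(x$excluded), "excluded by the expressing-fraction filter)\n")
  top <- x[!x$excluded, , drop = FALSE]
  if (nrow(top)) {
    top <- utils::head(top[order(top$p, -top$score), ], 5)
    print.data.frame(top, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Long-format export of the interaction table for a dot plot
#'
#' The quantities a ligand-receptor dot plot encodes: one row per
#' (pair, sender -> receiver) with the interaction score and permutation
#' p-value.
#'
#' @param table an `scdens_interactions`.
#' @param senders,receivers optional cluster filters.
#' @param path optional TSV output path.
#' @return data.frame with `pair`, `direction`, `score`, `p`.
#' @export
export_dotplot_table <- function(table, senders = NULL, receivers = NULL,
                                 path = NULL) {
  x <- table
  if (!is.null(senders)) x <- x[x$sender %in% senders, , drop = FALSE]
  if (!is.null(receivers)) x <- x[x$receiver %in% receivers, , drop = FALSE]
  if (nrow(x) == 0) {
    out <- data.frame(pair = character(0), direction = character(0),
                      score = numeric(0), p = numeric(0),
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(pair = paste(x$ligand, x$receptor, sep = "_"),
                      direction = paste0(x$sender, "->", x$receiver),
                      score = x$score, p = x$p,
                      stringsAsFactors = FALSE)
  }
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}
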