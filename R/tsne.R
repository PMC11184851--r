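#' tSNE embedding of the PC scores
#'
#' Embeds the leading principal-component scores in two dimensions with
#' Barnes-Hut tSNE.  By default the run is initialised from the first two
#' PC scores (scaled to the conventional 1e-4 spread), which stabilises the
#' global layout, and the resulting coordinates are standardised to a
#' constant point density: the tSNE objective fixes neighbourhoods but not
#' the coordinate scale, which grows with the number of cells, whereas the
#' downstream density clustering uses absolute radii.  Standardisation
#' rescales the embedding so that the central (1st-99th percentile)
#' bounding box provides `area_per_cell` square units per cell, making
#' radius parameters transferable across dataset sizes.
#'
#' @param pca an `scdens_pca` (or a bare score matrix).
#' @param n_pcs number of leading components to embed (default 20).
#' @param perplexity tSNE perplexity (default 30); must be below
#'   `(cells - 1)/3`.
#' @param seed integer seed.
#' @param max_iter tSNE iterations.
#' @param pca_init initialise from the first two PC scores (default TRUE);
#'   set to FALSE for the classic random initialisation.
#' @param density_standardize rescale coordinates to constant density
#'   (default TRUE).
#' @param area_per_cell target embedding area per cell in square units
#'   (default 0.15).
#' @return object of class `scdens_embedding`: list with `coords` (cells x
#'   2) and `params`.
#' @export
run_tsne <- function(pca, n_pcs = 20L, perplexity = 30, seed = 1L,
                     max_iter = 1000L, pca_init = TRUE,
                     density_standardize = TRUE, area_per_cell = 0.15) {
  scores <- if (inherits(pca, "scdens_pca")) pca$scores else pca
  if (n_pcs > ncol(scores))
    stop("n_pcs (", n_pcs, ") exceeds the available components (",
         ncol(scores), ")")
  S <- scores[, seq_len(n_pcs), drop = FALSE]
  n <- nrow(S)
  if (perplexity >= (n - 1) / 3)
    stop("perplexity must be below (cells - 1)/3 = ",
         signif((n - 1) / 3, 4),
         "; lower the perplexity for small data sets")
  y_init <- NULL
  if (pca_init && ncol(S) >= 2) {
    y_init <- S[, 1:2, drop = FALSE]
    s1 <- stats::sd(y_init[, 1])
    if (s1 > 0) y_init <- y_init / s1 * 1e-4
  }
  set.seed(as.integer(seed))
  fit <- Rtsne::Rtsne(S, dims = 2, pca = FALSE, perplexity = perplexity,
                      max_iter = max_iter, num_threads = 1,
                      check_duplicates = FALSE, Y_init = y_init)
  coords <- fit$Y
  scale_factor <- 1
  if (density_standardize && n >= 10) {
    bb <- apply(coords, 2, function(v)
      diff(stats::quantile(v, c(0.01, 0.99), names = FALSE)))
    if (all(bb > 0)) {
      scale_factor <- sqrt(area_per_cell * n / prod(bb))
      coords <- coords * scale_factor
    }
  }
  dimnames(coords) <- list(rownames(S), c("tsne_1", "tsne_2"))
  structure(list(coords = coords,
                 params = list(n_pcs = n_pcs, perplexity = perplexity,
                               seed = as.integer(seed), max_iter = max_iter,
                               pca_init = pca_init,
                               density_standardize = density_standardize,
                               area_per_cell = area_per_cell,
                               scale_factor = scale_factor)),
            class = "scdens_embedding")
}

#' @export
print.scdens_embedding <- function(x, ...) {
  cat("tSNE embedding:", nrow(x$coords), "cells (perplexity",
      x$params$perplexity, ",", x$params$n_pcs, "PCs)\n")
  invisible(x)
}

#' @export
plot.scdens_embedding <- function(x, labels = NULL, ...) {
  col <- if (is.null(labels)) 1 else as.integer(as.factor(labels))
  graphics::plot(x$coords, col = col, pch = 16, cex = 0.4,
                 xlab = "tSNE 1", ylab = "tSNE 2", ...)
  invisible(x)
}
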