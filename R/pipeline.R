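#' Default pipeline configuration
#'
#' All stage parameters of the end-to-end pipeline with their defaults:
#' QC window 200/3000 detected genes, gene prevalence 10 cells,
#' mitochondrial ceiling 50%, depth scale 1e4; 20 dispersion bins with
#' mean window 0.0125 to `hvg_mean_high` and z cutoff 0.5; 20 PCs; tSNE
#' perplexity 30; DBSCAN radii 0.5/1.0 with size floors 10/20 and
#' `min_pts` 10; DEG thresholds 0.5 natural log at FDR 0.01 (stage 1) and
#' 0.25 at p 0.05 (stage 2); post-hoc validity 1.0/0.01/10; top 10
#' markers; 1000 label permutations for the ligand-receptor test.
#'
#' `hvg_mean_high` defaults to 3: the source protocol prints 0.3, but at
#' that ceiling a marker program shifted by 2 natural-log units cannot
#' simultaneously pass the variable-gene window and the post-hoc
#' requirement of >1-log pairwise differences (see the methods vignette);
#' 3 is the upstream tool's historical default and keeps the procedure
#' self-consistent.  Set `hvg_mean_high = 0.3` to follow the printed value
#' verbatim.
#'
#' @param ... overrides of any default listed above (unknown names are
#'   rejected).
#' @return object of class `scdens_config` (a named list).
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    ## qc
    min_genes = 200L, max_genes = 3000L, min_cells_per_gene = 10L,
    max_mito = 0.5, scale_factor = 1e4,
    regress_umi = TRUE, batch_correct = TRUE,
    ## hvg
    hvg_bins = 20L, hvg_mean_low = 0.0125, hvg_mean_high = 3,
    hvg_z_cutoff = 0.5,
    ## reduction
    n_pcs = 20L, do_jackstraw = FALSE, jackstraw_pcs = 30L,
    jackstraw_reps = 200L, jackstraw_prop = 0.01, jackstraw_alpha = 0.05,
    perplexity = 30, tsne_iter = 1000L,
    ## clustering
    eps1 = 0.5, min_size1 = 10L, eps2 = 1.0, min_size2 = 20L,
    min_pts = 10L,
    ## markers
    deg1_log_diff = 0.5, deg1_fdr = 0.01,
    deg2_log_diff = 0.25, deg2_p = 0.05,
    posthoc_log_diff = 1.0, posthoc_fdr = 0.01, posthoc_min_degs = 10L,
    top_n = 10L,
    ## crosstalk
    n_perm = 1000L, min_frac = 0.1,
    ## global
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  .validate_pipeline_config(cfg)
  structure(cfg, class = "scdens_config")
}

.validate_pipeline_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("invalid configuration: ", msg,
                                         call. = FALSE)
  chk(cfg$min_genes <= cfg$max_genes, "min_genes exceeds max_genes")
  chk(cfg$max_mito > 0 && cfg$max_mito <= 1, "max_mito must be in (0, 1]")
  chk(cfg$scale_factor > 0, "scale_factor must be positive")
  chk(cfg$hvg_mean_low < cfg$hvg_mean_high,
      "hvg_mean_low must be below hvg_mean_high")
  chk(cfg$hvg_bins >= 2, "hvg_bins must be at least 2")
  chk(cfg$n_pcs >= 2, "n_pcs must be at least 2")
  chk(cfg$eps1 > 0 && cfg$eps2 > 0, "DBSCAN radii must be positive")
  chk(cfg$min_size1 >= 1 && cfg$min_size2 >= 1,
      "cluster size floors must be at least 1")
  chk(cfg$n_perm >= 100, "n_perm must be at least 100")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1,
      "seed must be a single integer")
  invisible(cfg)
}

#' Read and validate a pipeline configuration file
#'
#' Parses a flat `key = value` text file (one pair per line, `#` comments
#' allowed), fills unspecified keys with the [pipeline_config()] defaults
#' and rejects unknown keys or out-of-range values with the offending
#' field name.  An empty file yields the full default configuration.
#'
#' @param path configuration file.
#' @return an `scdens_config`.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  over <- list()
  template <- pipeline_config()
  for (i in seq_along(lines)) {
    kv <- strsplit(lines[[i]], "=", fixed = TRUE)[[1]]
    if (length(kv) != 2)
      stop("malformed configuration line ", i, ": ", lines[[i]])
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(template))
      stop("unknown configuration key: ", key)
    proto <- template[[key]]
    parsed <- if (is.logical(proto)) as.logical(val) else
      if (is.integer(proto)) suppressWarnings(as.integer(val)) else
        suppressWarnings(as.numeric(val))
    if (is.na(parsed))
      stop("cannot parse value for `", key, "`: ", val)
    over[[key]] <- parsed
  }
  do.call(pipeline_config, over)
}

## Deterministic per-stage seeds derived from the global seed; kept well
## below 2^31.
.stage_seed <- function(seed, k) {
  (as.integer(seed) %% 599479L) * 3581L + as.integer(k)
}

.checksum <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  v <- as.integer(raw)
  sprintf("%.0f", sum(v * rep_len(c(1, 17, 257, 4099), length(v))) %%
            2147483647)
}

#' Run the full pipeline on a count matrix
#'
#' Executes, in order: QC filtering, depth normalization, highly variable
#' gene selection, UMI regression and batch correction (on the variable
#' genes, which are the only ones entering PCA), PCA, optional jackStraw
#' PC selection, tSNE, two-pass DBSCAN with pruning, condition
#' composition statistics, two-stage marker calling with post-hoc
#' cluster-pair validity, and - when a ligand-receptor table is supplied -
#' the permutation interaction test.  Differential expression and
#' interaction scoring operate on the normalized (not regressed) values.
#' Per-stage seeds are derived deterministically from the global seed.
#'
#' @param counts raw integer count matrix, cells x genes.
#' @param meta data.frame with `cell_id` and optional `condition`,
#'   `batch` columns.
#' @param config an `scdens_config` from [pipeline_config()] /
#'   [validate_config()].
#' @param lr_db optional ligand-receptor table for the crosstalk stage.
#' @return object of class `scdens_run`: list with `qc`, `expr`
#'   (normalized), `hvg`, `pca`, `jackstraw` (or NULL), `embedding`,
#'   `clusters`, `composition` (or NULL), `markers`, `top_markers`,
#'   `validity`, `interactions` (or NULL) and a `manifest` recording
#'   stage order, parameters, cell/gene counts and content checksums.
#' @export
run_pipeline <- function(counts, meta = NULL,
                         config = pipeline_config(), lr_db = NULL) {
  stopifnot(inherits(config, "scdens_config"))
  t0 <- Sys.time()
  manifest <- list(params = unclass(config),
                   stages = list())
  log_stage <- function(name, n_cells, n_genes, obj) {
    manifest$stages[[name]] <<- list(n_cells = n_cells, n_genes = n_genes,
                                     checksum = .checksum(obj))
  }
  log_stage("input", nrow(counts), ncol(counts), dimnames(counts))

  ## --- QC ------------------------------------------------------------
  qc <- filter_cells_genes(counts,
                           min_genes = config$min_genes,
                           max_genes = config$max_genes,
                           min_cells_per_gene = config$min_cells_per_gene,
                           max_mito = config$max_mito)
  log_stage("qc", nrow(qc$counts), ncol(qc$counts), qc$report)

  ## --- normalization -------------------------------------------------
  expr <- normalize_log(qc$counts, scale_factor = config$scale_factor)
  log_stage("normalize", nrow(expr$values), ncol(expr$values),
            round(sum(expr$values), 6))

  ## --- HVG on the normalized values ----------------------------------
  hvg <- select_hvg(expr, n_bins = config$hvg_bins,
                    mean_low = config$hvg_mean_low,
                    mean_high = config$hvg_mean_high,
                    z_cutoff = config$hvg_z_cutoff)
  genes <- attr(hvg, "genes")
  if (length(genes) < config$n_pcs)
    stop("stage hvg: only ", length(genes), " variable genes selected, ",
         "fewer than n_pcs")
  log_stage("hvg", nrow(expr$values), length(genes), genes)

  ## --- UMI regression / batch correction on the variable genes -------
  red_expr <- structure(list(values = expr$values[, genes, drop = FALSE],
                             total_umi = expr$total_umi,
                             scale_factor = expr$scale_factor,
                             flags = expr$flags),
                        class = "scdens_expr")
  if (isTRUE(config$regress_umi))
    red_expr <- regress_out_umi(red_expr)
  batch <- if (!is.null(meta) && "batch" %in% names(meta))
    meta$batch[match(rownames(red_expr$values), meta$cell_id)] else NULL
  if (isTRUE(config$batch_correct) && !is.null(batch) &&
        length(unique(batch)) > 1)
    red_expr <- correct_batch(red_expr, batch)
  log_stage("residualize", nrow(red_expr$values), ncol(red_expr$values),
            round(sum(red_expr$values), 6))

  ## --- PCA / PC selection --------------------------------------------
  pca <- run_pca(red_expr, n_components = config$n_pcs,
                 seed = .stage_seed(config$seed, 1L))
  js <- NULL
  n_pcs_used <- config$n_pcs
  if (isTRUE(config$do_jackstraw)) {
    js <- jackstraw_significant_pcs(red_expr,
                                    n_test_pcs = config$jackstraw_pcs,
                                    n_reps = config$jackstraw_reps,
                                    prop_permuted = config$jackstraw_prop,
                                    alpha = config$jackstraw_alpha,
                                    seed = .stage_seed(config$seed, 2L))
    n_pcs_used <- min(config$n_pcs, max(js$significant, 2L))
  }
  log_stage("pca", nrow(pca$scores), ncol(pca$scores),
            round(pca$variance_explained, 6))

  ## --- tSNE + clustering ---------------------------------------------
  emb <- run_tsne(pca, n_pcs = n_pcs_used, perplexity = config$perplexity,
                  max_iter = config$tsne_iter,
                  seed = .stage_seed(config$seed, 3L))
  cl <- dbscan_two_pass(emb, eps1 = config$eps1,
                        min_size1 = config$min_size1, eps2 = config$eps2,
                        min_size2 = config$min_size2,
                        min_pts = config$min_pts)
  log_stage("cluster", sum(!is.na(cl$final_label)), ncol(expr$values),
            list(attr(cl, "sizes"), cl$final_label))

  comp <- NULL
  if (!is.null(meta) && "condition" %in% names(meta) &&
        length(unique(meta$condition)) >= 1)
    comp <- composition_by_group(cl, meta)

  ## --- markers (on normalized, non-regressed values) ------------------
  set1 <- deg_one_vs_rest(expr, cl, min_log_diff = config$deg1_log_diff,
                          max_fdr = config$deg1_fdr)
  set2 <- deg_pairwise(expr, cl, min_log_diff = config$deg2_log_diff,
                       max_p = config$deg2_p)
  markers <- overlap_markers(set1, set2)
  top <- if (any(markers$is_marker)) top_markers(markers, config$top_n)
         else markers[0, ]
  validity <- posthoc_cluster_validity(expr, cl,
                                       min_log_diff = config$posthoc_log_diff,
                                       max_fdr = config$posthoc_fdr,
                                       min_degs = config$posthoc_min_degs)
  log_stage("markers", length(unique(markers$cluster)),
            sum(markers$is_marker), markers)

  ## --- crosstalk ------------------------------------------------------
  inter <- NULL
  if (!is.null(lr_db)) {
    inter <- permutation_pvalues(expr, cl, lr_db, n_perm = config$n_perm,
                                 min_frac = config$min_frac,
                                 seed = .stage_seed(config$seed, 4L))
    log_stage("crosstalk", nrow(inter), sum(!inter$excluded), inter)
  }

  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  structure(list(qc = qc$report, expr = expr, hvg = hvg, pca = pca,
                 jackstraw = js, embedding = emb, clusters = cl,
                 composition = comp, markers = markers,
                 top_markers = top, validity = validity,
                 interactions = inter, manifest = manifest,
                 config = config),
            class = "scdens_run")
}

#' @export
print.scdens_run <- function(x, ...) {
  st <- x$manifest$stages
  cat("Pipeline run (", round(x$manifest$elapsed_s, 1), "s )\n", sep = "")
  for (nm in names(st))
    cat(sprintf("  %-11s cells %-6s genes/items %-6s\n", nm,
                st[[nm]]$n_cells, st[[nm]]$n_genes))
  cat("final clusters:", length(attr(x$clusters, "sizes")),
      "| markers:", sum(x$markers$is_marker),
      "| min pairwise DEGs:", min(x$validity$n_degs), "\n")
  invisible(x)
}
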