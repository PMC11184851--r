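#' Configuration for the synthetic count generator
#'
#' Builds and validates the parameter set used by [simulate_counts()].  The
#' generator draws gene-wise negative-binomial counts with a per-cell
#' multiplicative depth factor, plants disjoint marker programs for a set of
#' cell populations, adds gene-subset batch offsets, low-quality cells and
#' ligand-receptor co-expression programs, so that every downstream stage of
#' the pipeline has a testable ground truth.
#'
#' Gene space is organised in four tiers: population marker genes
#' (`n_populations * markers_per_population` of them, baseline NB mean
#' `marker_baseline_mean`, multiplied by `exp(marker_log_shift)` in the
#' population that owns them), background genes (log-normal means around
#' `baseline_mean`), a small set of high-expression housekeeping genes that
#' carry most of the sequencing depth, and mitochondrial genes (named with a
#' `Mt-` prefix).  Low-quality cells are produced by binomial thinning of all
#' non-mitochondrial counts plus inflation of the mitochondrial means, so
#' they violate both the detected-gene floor and the mitochondrial-fraction
#' ceiling of the QC stage.
#'
#' @param n_cells,n_genes dimensions of the simulated matrix.
#' @param n_populations number of planted cell populations.
#' @param population_weights base sampling probabilities of the populations
#'   (default equal); must sum to 1.
#' @param markers_per_population number of marker genes planted per
#'   population; marker sets are disjoint across populations.
#' @param marker_log_shift natural-log increase of a marker's NB mean in its
#'   own population.
#' @param marker_baseline_mean,marker_baseline_sigma log-normal location
#'   (median) and log-sd of marker baseline NB means.
#' @param baseline_mean,baseline_sigma log-normal median and log-sd of
#'   background gene NB means.
#' @param n_housekeeping,housekeeping_mean,housekeeping_sigma high-expression
#'   gene tier absorbing most sequencing depth.
#' @param n_mito_genes,mito_mean,mito_sigma mitochondrial gene tier.
#' @param nb_dispersion negative-binomial size parameter shared by all genes
#'   (variance `mu + mu^2/size`).
#' @param libsize_sigma log-normal sd of the per-cell depth factor.
#' @param frac_low_quality fraction of cells turned into low-quality cells;
#'   must be below 0.5.
#' @param lowq_keep_prob binomial thinning probability applied to
#'   non-mitochondrial counts of low-quality cells.
#' @param lowq_mito_factor multiplier on mitochondrial NB means of
#'   low-quality cells.
#' @param n_batches number of batches; cells are assigned uniformly.
#' @param batch_log_offset constant natural-log offset applied, in every
#'   batch after the first, to a random half of the genes.  A genuinely
#'   global offset would multiply every gene equally and be removed entirely
#'   by depth normalization, so the offset is planted on a gene subset to
#'   keep it visible to (and removable by) linear batch correction.
#' @param batch_gene_frac fraction of genes carrying the batch offset.
#' @param conditions character vector of condition labels.
#' @param condition_weight_mult matrix (`length(conditions)` x
#'   `n_populations`) of multiplicative tilts applied to
#'   `population_weights` per condition (rows are renormalized).  Default:
#'   the second population is expanded and the fifth depleted in the second
#'   condition, partially restored in the third, mimicking a
#'   disease/treatment composition shift.
#' @param lr_programs data.frame with columns `ligand`, `receptor`,
#'   `sender`, `receiver`, `shift`: dedicated ligand/receptor genes whose NB
#'   mean is raised by `exp(shift)` in the sender (ligand) and receiver
#'   (receptor) population respectively.  `NULL` for none; the default
#'   plants one program between populations 2 and 5.
#' @param lr_gene_mean baseline NB mean of the dedicated ligand/receptor
#'   genes.
#' @param seed integer seed; identical configurations and seeds give
#'   bit-identical output.
#'
#' @return an object of class `scdens_sim_config` (a validated list).
#' @seealso [simulate_counts()], [write_fixture()]
#' @export
sim_config <- function(n_cells = 3000L,
                       n_genes = 2000L,
                       n_populations = 12L,
                       population_weights = NULL,
                       markers_per_population = 50L,
                       marker_log_shift = 2.0,
                       marker_baseline_mean = 0.8,
                       marker_baseline_sigma = 0.4,
                       baseline_mean = 0.5,
                       baseline_sigma = 0.9,
                       n_housekeeping = 80L,
                       housekeeping_mean = 25,
                       housekeeping_sigma = 0.3,
                       n_mito_genes = 20L,
                       mito_mean = 6,
                       mito_sigma = 0.3,
                       nb_dispersion = 0.5,
                       libsize_sigma = 0.3,
                       frac_low_quality = 0.05,
                       lowq_keep_prob = 0.1,
                       lowq_mito_factor = 8,
                       n_batches = 2L,
                       batch_log_offset = 0.2,
                       batch_gene_frac = 0.5,
                       conditions = c("Normal", "DKD", "MSC-sEV"),
                       condition_weight_mult = NULL,
                       lr_programs = NULL,
                       lr_gene_mean = 2,
                       seed = 1L) {
  cfg <- as.list(environment())
  .chk <- function(ok, field, msg) {
    if (!ok) stop("invalid config: `", field, "` ", msg, call. = FALSE)
  }
  .chk(is.numeric(n_cells) && n_cells >= 1, "n_cells", "must be >= 1")
  .chk(is.numeric(n_genes) && n_genes >= 1, "n_genes", "must be >= 1")
  .chk(n_populations >= 1, "n_populations", "must be >= 1")
  if (is.null(population_weights)) {
    cfg$population_weights <- rep(1 / n_populations, n_populations)
  } else {
    .chk(length(population_weights) == n_populations, "population_weights",
         "must have one entry per population")
    .chk(all(population_weights > 0), "population_weights",
         "must be strictly positive")
    .chk(abs(sum(population_weights) - 1) < 1e-8, "population_weights",
         "must sum to 1")
  }
  for (f in c("marker_baseline_mean", "baseline_mean", "housekeeping_mean",
              "mito_mean", "nb_dispersion", "lr_gene_mean"))
    .chk(cfg[[f]] > 0, f, "must be strictly positive")
  .chk(marker_log_shift >= 0, "marker_log_shift", "must be >= 0")
  .chk(libsize_sigma >= 0, "libsize_sigma", "must be >= 0")
  .chk(frac_low_quality >= 0 && frac_low_quality < 0.5, "frac_low_quality",
       "must lie in [0, 0.5)")
  .chk(lowq_keep_prob > 0 && lowq_keep_prob <= 1, "lowq_keep_prob",
       "must lie in (0, 1]")
  .chk(n_batches >= 1, "n_batches", "must be >= 1")
  .chk(batch_gene_frac >= 0 && batch_gene_frac <= 1, "batch_gene_frac",
       "must lie in [0, 1]")
  .chk(length(conditions) >= 1 && !anyDuplicated(conditions), "conditions",
       "must be distinct labels")
  n_cond <- length(conditions)
  if (is.null(condition_weight_mult)) {
    m <- matrix(1, n_cond, n_populations)
    if (n_cond >= 2 && n_populations >= 5) {
      m[2, 2] <- 1.6; m[2, 5] <- 0.7
      if (n_cond >= 3) { m[3, 2] <- 1.3; m[3, 5] <- 0.85 }
    }
    cfg$condition_weight_mult <- m
  } else {
    .chk(is.matrix(condition_weight_mult) &&
           all(dim(condition_weight_mult) == c(n_cond, n_populations)),
         "condition_weight_mult", "must be a conditions x populations matrix")
    .chk(all(condition_weight_mult > 0), "condition_weight_mult",
         "must be strictly positive")
  }
  n_marker <- n_populations * markers_per_population
  n_special <- n_marker + n_housekeeping + n_mito_genes +
    if (is.null(lr_programs)) 2L else 0L
  .chk(n_genes > n_special, "n_genes",
       "too small for the marker/housekeeping/mito tiers")
  if (is.null(lr_programs) && n_populations >= 5) {
    cfg$lr_programs <- data.frame(
      ligand = "Lig1", receptor = "Rec1",
      sender = 2L, receiver = 5L, shift = 2.0,
      stringsAsFactors = FALSE)
  } else if (!is.null(lr_programs)) {
    .chk(is.data.frame(lr_programs) &&
           all(c("ligand", "receptor", "sender", "receiver", "shift") %in%
                 names(lr_programs)),
         "lr_programs",
         "needs columns ligand, receptor, sender, receiver, shift")
    .chk(all(lr_programs$sender %in% seq_len(n_populations)) &&
           all(lr_programs$receiver %in% seq_len(n_populations)),
         "lr_programs", "sender/receiver must be population indices")
  } else {
    cfg$lr_programs <- NULL
  }
  .chk(is.numeric(seed) && length(seed) == 1 && is.finite(seed), "seed",
       "must be a single integer")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "scdens_sim_config")
}

#' Simulate a single-cell count matrix with planted structure
#'
#' Draws the cell population, condition, batch and depth structure described
#' by a [sim_config()] and generates negative-binomial counts.  Returns the
#' raw counts (cells x genes), a per-cell metadata table and the full ground
#' truth used by the test-suite.
#'
#' @param config an `scdens_sim_config`.
#' @return an object of class `scdens_sim`: a list with elements
#'   \describe{
#'     \item{counts}{integer matrix, cells x genes, with cell/gene names.}
#'     \item{meta}{data.frame with `cell_id`, `condition`, `batch`.}
#'     \item{truth}{list: `population` (integer per cell), `low_quality`
#'       (logical per cell), `marker_genes` (list of gene-name vectors per
#'       population), `mito_genes`, `lr_pairs` (the planted programs with
#'       gene names), `gene_means` (baseline NB means), `batch_genes`
#'       (genes carrying the batch offset).}
#'   }
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "scdens_sim_config"))
  cf <- config
  set.seed(cf$seed)
  n_pops <- cf$n_populations
  n_cells <- as.integer(cf$n_cells)
  n_genes <- as.integer(cf$n_genes)
  n_cond <- length(cf$conditions)

  ## cell-level structure
  cond_id <- sample.int(n_cond, n_cells, replace = TRUE)
  w <- cf$condition_weight_mult * rep(cf$population_weights,
                                      each = n_cond)
  w <- w / rowSums(w)
  pop <- integer(n_cells)
  for (ci in seq_len(n_cond)) {
    idx <- which(cond_id == ci)
    pop[idx] <- sample.int(n_pops, length(idx), replace = TRUE, prob = w[ci, ])
  }
  batch <- sample.int(cf$n_batches, n_cells, replace = TRUE)

  ## gene tiers and names
  n_marker <- n_pops * cf$markers_per_population
  marker_idx <- seq_len(n_marker)
  marker_pop <- rep(seq_len(n_pops), each = cf$markers_per_population)
  n_lr <- if (is.null(cf$lr_programs)) 0L else
    length(unique(c(cf$lr_programs$ligand, cf$lr_programs$receptor)))
  hk_idx <- n_genes - cf$n_mito_genes - cf$n_housekeeping +
    seq_len(cf$n_housekeeping)
  mito_idx <- n_genes - cf$n_mito_genes + seq_len(cf$n_mito_genes)
  bg_idx <- setdiff(seq_len(n_genes), c(marker_idx, hk_idx, mito_idx))

  gene_ids <- character(n_genes)
  gene_ids[marker_idx] <- paste0("Mk", marker_pop, "-",
                                 sequence(rep(cf$markers_per_population,
                                              n_pops)))
  gene_ids[bg_idx] <- paste0("Gene", seq_along(bg_idx))
  gene_ids[hk_idx] <- paste0("Hk", seq_len(cf$n_housekeeping))
  gene_ids[mito_idx] <- paste0("Mt-", seq_len(cf$n_mito_genes))

  mu <- numeric(n_genes)
  mu[marker_idx] <- exp(stats::rnorm(n_marker, log(cf$marker_baseline_mean),
                                     cf$marker_baseline_sigma))
  mu[bg_idx] <- exp(stats::rnorm(length(bg_idx), log(cf$baseline_mean),
                                 cf$baseline_sigma))
  mu[hk_idx] <- exp(stats::rnorm(cf$n_housekeeping, log(cf$housekeeping_mean),
                                 cf$housekeeping_sigma))
  mu[mito_idx] <- exp(stats::rnorm(cf$n_mito_genes, log(cf$mito_mean),
                                   cf$mito_sigma))

  ## dedicated ligand/receptor genes live in the background tier
  lr <- cf$lr_programs
  if (!is.null(lr)) {
    lr_genes <- unique(c(lr$ligand, lr$receptor))
    stopifnot(length(lr_genes) <= length(bg_idx))
    lr_pos <- bg_idx[seq_along(lr_genes)]
    gene_ids[lr_pos] <- lr_genes
    mu[lr_pos] <- cf$lr_gene_mean
  }

  ## batch offset on a random gene subset, per non-reference batch
  batch_genes <- vector("list", cf$n_batches)
  if (cf$n_batches > 1) {
    for (b in 2:cf$n_batches)
      batch_genes[[b]] <- sort(sample.int(n_genes,
                                          round(cf$batch_gene_frac * n_genes)))
  }

  depth <- exp(stats::rnorm(n_cells, 0, cf$libsize_sigma))

  counts <- matrix(0L, n_cells, n_genes)
  for (p in seq_len(n_pops)) {
    for (b in seq_len(cf$n_batches)) {
      idx <- which(pop == p & batch == b)
      if (!length(idx)) next
      mup <- mu
      own <- marker_idx[marker_pop == p]
      mup[own] <- mup[own] * exp(cf$marker_log_shift)
      if (!is.null(lr)) {
        for (r in seq_len(nrow(lr))) {
          if (lr$sender[r] == p)
            mup[match(lr$ligand[r], gene_ids)] <-
              mup[match(lr$ligand[r], gene_ids)] * exp(lr$shift[r])
          if (lr$receiver[r] == p)
            mup[match(lr$receptor[r], gene_ids)] <-
              mup[match(lr$receptor[r], gene_ids)] * exp(lr$shift[r])
        }
      }
      if (b > 1)
        mup[batch_genes[[b]]] <- mup[batch_genes[[b]]] * exp(cf$batch_log_offset)
      lam <- outer(depth[idx], mup)
      counts[idx, ] <- matrix(stats::rnbinom(length(lam), mu = lam,
                                             size = cf$nb_dispersion),
                              nrow = length(idx))
    }
  }

  ## low-quality cells: thin non-mito counts, inflate mito draws
  lowq <- logical(n_cells)
  if (cf$frac_low_quality > 0) {
    lq <- sample.int(n_cells, round(cf$frac_low_quality * n_cells))
    lowq[lq] <- TRUE
    non_mito <- setdiff(seq_len(n_genes), mito_idx)
    for (i in lq) {
      counts[i, non_mito] <- stats::rbinom(length(non_mito),
                                           counts[i, non_mito],
                                           cf$lowq_keep_prob)
      counts[i, mito_idx] <- stats::rnbinom(cf$n_mito_genes,
                                            mu = depth[i] * mu[mito_idx] *
                                              cf$lowq_mito_factor,
                                            size = cf$nb_dispersion)
    }
  }

  cell_ids <- paste0("Cell", seq_len(n_cells))
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(cell_ids, gene_ids)
  meta <- data.frame(cell_id = cell_ids,
                     condition = cf$conditions[cond_id],
                     batch = paste0("B", batch),
                     stringsAsFactors = FALSE)
  truth <- list(
    population = stats::setNames(pop, cell_ids),
    low_quality = stats::setNames(lowq, cell_ids),
    marker_genes = split(gene_ids[marker_idx], marker_pop),
    mito_genes = gene_ids[mito_idx],
    lr_pairs = lr,
    gene_means = stats::setNames(mu, gene_ids),
    batch_genes = lapply(batch_genes, function(ix)
      if (is.null(ix)) NULL else gene_ids[ix]),
    depth_factor = stats::setNames(depth, cell_ids))
  structure(list(counts = counts, meta = meta, truth = truth,
                 config = cf),
            class = "scdens_sim")
}

#' Simulate counts with orthogonal expression programs
#'
#' A simpler generator used to calibrate the PC-significance test: a
#' negative-binomial background with per-cell depth variation, plus
#' `n_programs` programs, each raising the NB mean of a disjoint gene block
#' by `exp(program_log_shift)` inside a disjoint cell block.  Note that when
#' the cell blocks cover all cells the column-centered planted structure has
#' rank `n_programs - 1`: the centered program indicators are linearly
#' dependent.  With depth variation and depth normalization the library-size
#' component contributes one further structured dimension.
#'
#' @param n_cells,n_genes matrix dimensions.
#' @param n_programs number of planted programs (0 for pure noise).
#' @param genes_per_program,cells_per_program disjoint block sizes; requires
#'   `n_programs * genes_per_program <= n_genes` and similarly for cells.
#' @param program_log_shift natural-log mean shift inside a block.
#' @param baseline_mean,baseline_sigma log-normal NB mean distribution.
#' @param nb_dispersion NB size parameter.
#' @param libsize_sigma log-normal sd of per-cell depth (0 disables depth
#'   structure).
#' @param seed integer seed.
#' @return list with `counts` (cells x genes integer matrix) and `truth`
#'   (program cell/gene index lists).
#' @export
simulate_program_counts <- function(n_cells = 2000L, n_genes = 1500L,
                                    n_programs = 20L,
                                    genes_per_program = 50L,
                                    cells_per_program = 100L,
                                    program_log_shift = 2.0,
                                    baseline_mean = 0.5,
                                    baseline_sigma = 0.6,
                                    nb_dispersion = 0.5,
                                    libsize_sigma = 0.3,
                                    seed = 1L) {
  if (n_programs * genes_per_program > n_genes)
    stop("invalid config: `genes_per_program` blocks exceed `n_genes`")
  if (n_programs * cells_per_program > n_cells)
    stop("invalid config: `cells_per_program` blocks exceed `n_cells`")
  set.seed(as.integer(seed))
  mu <- exp(stats::rnorm(n_genes, log(baseline_mean), baseline_sigma))
  depth <- exp(stats::rnorm(n_cells, 0, libsize_sigma))
  lam <- outer(depth, mu)
  prog_cells <- prog_genes <- vector("list", n_programs)
  if (n_programs > 0) {
    for (k in seq_len(n_programs)) {
      cells <- (k - 1L) * cells_per_program + seq_len(cells_per_program)
      genes <- (k - 1L) * genes_per_program + seq_len(genes_per_program)
      lam[cells, genes] <- lam[cells, genes] * exp(program_log_shift)
      prog_cells[[k]] <- cells
      prog_genes[[k]] <- genes
    }
  }
  counts <- matrix(stats::rnbinom(length(lam), mu = lam, size = nb_dispersion),
                   nrow = n_cells,
                   dimnames = list(paste0("Cell", seq_len(n_cells)),
                                   paste0("Gene", seq_len(n_genes))))
  storage.mode(counts) <- "integer" 
  list(counts = counts,
       truth = list(program_cells = prog_cells, program_genes = prog_genes))
}

#' @export
print.scdens_sim <- function(x, ...) {
  cat("Synthetic single-cell data:", nrow(x$counts), "cells x",
      ncol(x$counts), "genes\n")
  cat("  populations:", x$config$n_populations,
      "| conditions:", paste(x$config$conditions, collapse = ", "),
      "| batches:", x$config$n_batches, "\n")
  cat("  low-quality cells:", sum(x$truth$low_quality), "\n")
  invisible(x)
}
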