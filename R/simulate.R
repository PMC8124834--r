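# Synthetic-data generator with planted ground truth. Emulates the study
# design: three liver cell types (E, I, K) under control and TME
# conditions, log2-scale microarray intensities with additive Gaussian
# noise, planted down/upregulated miRNAs (including geromiRs annotated to
# aging hallmarks) and planted upregulated target genes of downregulated
# miRNAs.

#' Simulation configuration
#'
#' Defaults emulate the study conditions: 600 miRNA features with a
#' 75-member on-platform geromiR catalog (fraction 0.125), 30 planted
#' downregulated miRNAs of which 10 are geromiRs concentrated on a
#' designated hallmark, 10 planted upregulated miRNAs, a planted
#' upregulated gene set targeted by downregulated miRNAs, a planted shift
#' of 3 log2 units against noise of 0.5 log2 units, and the study's
#' replicate layout (three biological replicates per miRNA group except
#' two for the E-control and K-TME groups; four per gene group).
#'
#' @param n_mirnas,n_genes Feature counts.
#' @param geromir_fraction Fraction of miRNAs in the on-platform geromiR
#'   catalog (default 0.125, i.e. 75 of 600).
#' @param n_planted_down,n_planted_down_geromirs,n_planted_up Planted
#'   miRNA set sizes; `n_planted_down_geromirs` of the downregulated
#'   miRNAs are geromiRs.
#' @param n_planted_up_genes Number of planted upregulated target genes.
#' @param effect_log2 Magnitude of the planted shift (log2 units, > 0 for
#'   a non-null scenario; 0 gives the null case).
#' @param noise_sd Additive Gaussian noise standard deviation (log2
#'   units).
#' @param mirna_replicates Named integer vector of per-group replicate
#'   counts for the miRNA arrays, names like `"E.C"`.
#' @param gene_replicates Single replicate count per gene-array group.
#' @param baseline_mean,baseline_sd Per-feature baseline distribution
#'   (log2 units).
#' @param celltype_sd SD of the per-cell-type baseline offset (drawn once
#'   per cell type) so pooled testing is exercised under heterogeneity.
#' @param designated_hallmark Hallmark on which planted downregulated
#'   geromiRs are concentrated.
#' @param seed Integer seed driving a single documented stream of draws.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(
    n_mirnas = 600L, n_genes = 1000L,
    geromir_fraction = 0.125,
    n_planted_down = 30L, n_planted_down_geromirs = 10L,
    n_planted_up = 10L, n_planted_up_genes = 5L,
    effect_log2 = 3, noise_sd = 0.5,
    mirna_replicates = c(E.C = 2L, E.T = 3L, I.C = 3L, I.T = 3L,
                         K.C = 3L, K.T = 2L),
    gene_replicates = 4L,
    baseline_mean = 8, baseline_sd = 2,
    celltype_sd = 0.25,
    designated_hallmark = "histone modifications",
    seed = 1L) {
  cfg <- list(n_mirnas = as.integer(n_mirnas),
              n_genes = as.integer(n_genes),
              geromir_fraction = geromir_fraction,
              n_planted_down = as.integer(n_planted_down),
              n_planted_down_geromirs = as.integer(n_planted_down_geromirs),
              n_planted_up = as.integer(n_planted_up),
              n_planted_up_genes = as.integer(n_planted_up_genes),
              effect_log2 = effect_log2, noise_sd = noise_sd,
              mirna_replicates = mirna_replicates,
              gene_replicates = as.integer(gene_replicates),
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              celltype_sd = celltype_sd,
              designated_hallmark = designated_hallmark,
              seed = as.integer(seed))
  n_gero <- round(cfg$n_mirnas * cfg$geromir_fraction)
  if (cfg$noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  if (cfg$effect_log2 < 0) stop("effect_log2 must be >= 0", call. = FALSE)
  if (cfg$n_planted_down_geromirs > min(cfg$n_planted_down, n_gero)) {
    stop("more planted downregulated geromiRs than available", call. = FALSE)
  }
  if (cfg$n_planted_down + cfg$n_planted_up > cfg$n_mirnas) {
    stop("planted sets exceed the miRNA universe", call. = FALSE)
  }
  if (any(cfg$mirna_replicates < 2L) || cfg$gene_replicates < 2L) {
    stop("at least two replicates per (cell type, condition) group",
         call. = FALSE)
  }
  assert_hallmarks(cfg$designated_hallmark)
  structure(cfg, class = "simulation_config")
}

sim_annotation <- function(replicates) {
  rows <- do.call(rbind, lapply(names(replicates), function(key) {
    ct <- sub("\\..*$", "", key); cond <- sub("^.*\\.", "", key)
    r <- seq_len(replicates[[key]])
    data.frame(sample_id = sprintf("%s_%s_%d", ct, cond, r),
               cell_type = ct, condition = cond, replicate = r,
               stringsAsFactors = FALSE)
  }))
  validate_annotation(rows)
}

sim_matrix <- function(ids, annot, baseline, ct_offset, effect) {
  n <- length(ids)
  x <- matrix(0, nrow = n, ncol = nrow(annot),
              dimnames = list(ids, annot$sample_id))
  for (j in seq_len(nrow(annot))) {
    shift <- if (annot$condition[j] == "T") effect else 0
    x[, j] <- baseline + ct_offset[[annot$cell_type[j]]] + shift +
      stats::rnorm(n, 0, 1) * attr(effect, "noise_sd")
  }
  x
}

#' Simulate a study-shaped dataset with planted ground truth
#'
#' Draws, in a fixed documented order under the configured seed:
#' per-feature baselines, per-cell-type offsets, the geromiR catalog with
#' hallmark annotations (planted downregulated geromiRs concentrated on
#' the designated hallmark), planted miRNA and gene sets, the interaction
#' table linking planted downregulated miRNAs to planted upregulated
#' genes (plus background edges), and the noisy sample values. Output is
#' bit-identical for a fixed seed.
#'
#' @param config A [simulation_config()].
#' @return A `simulated_dataset` list: `mirna_matrix`, `gene_matrix`,
#'   `mirna_annotation`, `gene_annotation`, `catalog` (a
#'   `geromir_catalog`), `interactions`, `truth` (planted sets and effect
#'   size) and `config`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  withr_seed(config$seed, {
    mirna_ids <- sprintf("miR-s%04d", seq_len(config$n_mirnas))
    gene_ids <- sprintf("Gene%04d", seq_len(config$n_genes))
    n_gero <- round(config$n_mirnas * config$geromir_fraction)
    geromirs <- sort(sample(mirna_ids, n_gero))

    down_gero <- sort(sample(geromirs, config$n_planted_down_geromirs))
    non_gero <- setdiff(mirna_ids, geromirs)
    down_other <- sort(sample(non_gero,
                              config$n_planted_down -
                                config$n_planted_down_geromirs))
    planted_down <- sort(c(down_gero, down_other))
    up_pool <- setdiff(non_gero, down_other)
    planted_up <- sort(sample(up_pool, config$n_planted_up))
    planted_up_genes <- sort(sample(gene_ids, config$n_planted_up_genes))

    # catalog: every geromiR gets 1-3 hallmarks; planted downregulated
    # geromiRs always carry the designated hallmark
    vocab <- aging_hallmarks()$name
    rows <- do.call(rbind, lapply(geromirs, function(mir) {
      k <- sample(1:3, 1L)
      hms <- sample(vocab, k)
      if (mir %in% down_gero) hms <- unique(c(config$designated_hallmark, hms))
      data.frame(canonical_name = mir, hallmark = hms,
                 source = "simulated", stringsAsFactors = FALSE)
    }))
    rows$on_platform <- TRUE
    rows$downregulated_flag <- FALSE
    catalog <- validate_catalog(new_catalog(
      rows[order(rows$canonical_name, rows$hallmark), , drop = FALSE]))

    # interactions: each planted upregulated gene targeted by 1-3 planted
    # downregulated miRNAs, plus background edges
    planted_edges <- do.call(rbind, lapply(planted_up_genes, function(g) {
      data.frame(mirna = sample(planted_down, sample(1:3, 1L)), gene = g,
                 evidence = "simulated", stringsAsFactors = FALSE)
    }))
    bg_genes <- setdiff(gene_ids, planted_up_genes)
    background <- data.frame(mirna = sample(mirna_ids, 40L, replace = TRUE),
                             gene = sample(bg_genes, 40L, replace = TRUE),
                             evidence = "simulated",
                             stringsAsFactors = FALSE)
    interactions <- rbind(planted_edges, background)
    interactions <- interactions[!duplicated(
      interactions[, c("mirna", "gene")]), , drop = FALSE]
    rownames(interactions) <- NULL

    mirna_annot <- sim_annotation(config$mirna_replicates)
    gene_annot <- sim_annotation(stats::setNames(
      rep(config$gene_replicates, 6L),
      c("E.C", "E.T", "I.C", "I.T", "K.C", "K.T")))

    ct_offset <- stats::setNames(
      as.list(stats::rnorm(3L, 0, config$celltype_sd)), c("E", "I", "K"))

    mirna_effect <- numeric(config$n_mirnas)
    names(mirna_effect) <- mirna_ids
    mirna_effect[planted_down] <- -config$effect_log2
    mirna_effect[planted_up] <- config$effect_log2
    attr(mirna_effect, "noise_sd") <- config$noise_sd
    mirna_base <- stats::rnorm(config$n_mirnas, config$baseline_mean,
                               config$baseline_sd)
    mirna_matrix <- sim_matrix(mirna_ids, mirna_annot, mirna_base,
                               ct_offset, mirna_effect)

    gene_effect <- numeric(config$n_genes)
    names(gene_effect) <- gene_ids
    gene_effect[planted_up_genes] <- config$effect_log2
    attr(gene_effect, "noise_sd") <- config$noise_sd
    gene_base <- stats::rnorm(config$n_genes, config$baseline_mean,
                              config$baseline_sd)
    gene_matrix <- sim_matrix(gene_ids, gene_annot, gene_base,
                              ct_offset, gene_effect)

    structure(list(
      mirna_matrix = mirna_matrix,
      gene_matrix = gene_matrix,
      mirna_annotation = mirna_annot,
      gene_annotation = gene_annot,
      catalog = catalog,
      interactions = interactions,
      truth = list(geromirs = geromirs,
                   planted_down = planted_down,
                   planted_down_geromirs = down_gero,
                   planted_up = planted_up,
                   planted_up_genes = planted_up_genes,
                   effect_log2 = config$effect_log2,
                   designated_hallmark = config$designated_hallmark),
      config = config), class = "simulated_dataset")
  })
}

#' Precision and recall of a DEM call against planted truth
#'
#' @param dataset A `simulated_dataset`.
#' @param dem_table A `dem_table` produced from the dataset's miRNA matrix.
#' @return Data.frame with one row per direction (`down`, `up`) and
#'   columns `tp`, `fp`, `fn`, `precision`, `recall`. An empty call has
#'   precision 1 by convention (no false positives); an empty truth set
#'   has recall 1.
#' @export
evaluate_recovery <- function(dataset, dem_table) {
  stopifnot(inherits(dataset, "simulated_dataset"))
  if (!all(dem_table$feature_id %in% rownames(dataset$mirna_matrix))) {
    stop("DEM table features are not from this dataset", call. = FALSE)
  }
  one <- function(dir, truth) {
    called <- dem_features(dem_table, dir)
    tp <- length(intersect(called, truth))
    fp <- length(setdiff(called, truth))
    fn <- length(setdiff(truth, called))
    data.frame(direction = dir, tp = tp, fp = fp, fn = fn,
               precision = if (tp + fp == 0L) 1 else tp / (tp + fp),
               recall = if (tp + fn == 0L) 1 else tp / (tp + fn),
               stringsAsFactors = FALSE)
  }
  rbind(one("down", dataset$truth$planted_down),
        one("up", dataset$truth$planted_up))
}

#' Write a simulated dataset as pipeline input files
#'
#' Writes the miRNA and gene matrices with annotations, the catalog and
#' the interaction table as TSV under `dir`, in the formats the pipeline
#' reads.
#'
#' @param dataset A `simulated_dataset`.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "simulated_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    mirna_matrix = file.path(dir, "mirna_matrix.tsv"),
    mirna_annotation = file.path(dir, "mirna_annotation.tsv"),
    gene_matrix = file.path(dir, "gene_matrix.tsv"),
    gene_annotation = file.path(dir, "gene_annotation.tsv"),
    catalog = file.path(dir, "catalog.tsv"),
    interactions = file.path(dir, "interactions.tsv"))
  write_expression_matrix(dataset$mirna_matrix, paths["mirna_matrix"])
  write_sample_annotation(dataset$mirna_annotation,
                          paths["mirna_annotation"])
  write_expression_matrix(dataset$gene_matrix, paths["gene_matrix"])
  write_sample_annotation(dataset$gene_annotation, paths["gene_annotation"])
  write_catalog(dataset$catalog, paths["catalog"])
  utils::write.table(dataset$interactions, paths["interactions"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
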