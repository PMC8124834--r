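# End-to-end pipeline: normalize -> DEM calling -> catalog intersection ->
# over-representation -> target network -> reverse-expression screen ->
# machine-readable summary. Every intermediate is written as TSV; reruns
# with identical inputs and config are byte-identical.

pipeline_defaults <- function() {
  list(
    mirna_matrix = NULL, mirna_annotation = NULL,
    gene_matrix = NULL, gene_annotation = NULL,
    catalog = "packaged",        # path to a catalog TSV, or "packaged"
    interactions = NULL,          # path to an interaction TSV, or NULL
    out_dir = "geromir_out",
    cell_types = c("E", "I", "K"),
    linear_scale = FALSE,
    theta = 4, alpha = 0.001, test = "welch",
    gene_theta = NULL, gene_alpha = NULL,  # default: same as miRNA layer
    hallmark_population = "platform")      # "platform" or "catalog"
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are an error; omitted keys take the documented defaults
#' (see [run_pipeline()]). Referenced input paths are resolved relative to
#' the YAML file's directory and must exist.
#'
#' @param path YAML file path.
#' @return A validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, raw)
  base <- dirname(normalizePath(path))
  for (key in c("mirna_matrix", "mirna_annotation", "gene_matrix",
                "gene_annotation", "interactions")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      cand <- file.path(base, cfg[[key]])
      if (file.exists(cand)) cfg[[key]] <- cand
    }
  }
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (is.null(cfg$mirna_matrix) || is.null(cfg$mirna_annotation)) {
    stop("config must name mirna_matrix and mirna_annotation files",
         call. = FALSE)
  }
  for (key in c("mirna_matrix", "mirna_annotation", "gene_matrix",
                "gene_annotation", "interactions")) {
    p <- cfg[[key]]
    if (!is.null(p) && !file.exists(p)) {
      stop("config path for ", key, " does not exist: ", p, call. = FALSE)
    }
  }
  if (!identical(cfg$catalog, "packaged") && !file.exists(cfg$catalog)) {
    stop("config path for catalog does not exist: ", cfg$catalog,
         call. = FALSE)
  }
  if (!cfg$hallmark_population %in% c("platform", "catalog")) {
    stop("hallmark_population must be 'platform' or 'catalog'",
         call. = FALSE)
  }
  structure(cfg, class = c("run_config", "list"))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage [", name, "]: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full geromiR analysis pipeline
#'
#' Stages, in order: read and quantile-normalize the miRNA matrix; call
#' DEMs; load the geromiR catalog and restrict it to the measured
#' platform; intersect DEMs with the catalog; hypergeometric
#' over-representation of geromiRs among downregulated and upregulated
#' DEMs and of aging hallmarks among downregulated geromiRs; build the
#' miRNA-target network (if an interaction table is configured) and screen
#' its targets for reversed expression (if a gene matrix is configured).
#' Every intermediate is written as TSV under `out_dir`; a machine-readable
#' JSON summary is written last. Any stage error aborts with a
#' stage-labelled message.
#'
#' @param config A `run_config` from [read_run_config()], or a list of
#'   the same shape.
#' @return The run summary (named list), invisibly; also written as
#'   `summary.json`.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_run_config(utils::modifyList(pipeline_defaults(),
                                               unclass(config)))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(...) file.path(cfg$out_dir, ...)

  mirna <- stage("read_mirna", read_expression_matrix(
    cfg$mirna_matrix, cfg$mirna_annotation,
    linear_scale = cfg$linear_scale))
  xq <- stage("normalize", quantile_normalize(mirna$matrix))
  stage("normalize", write_expression_matrix(xq, outfile("mirna_qnorm.tsv")))

  params <- dem_params(cfg$theta, cfg$alpha, cfg$test)
  dems <- stage("dem", call_dems(xq, mirna$annotation, params,
                                 cell_types = cfg$cell_types))
  stage("dem", {
    utils::write.table(as.data.frame(dems), outfile("dems.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      volcano_points(xq, mirna$annotation, params, cfg$cell_types),
      outfile("volcano.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  })

  catalog <- stage("catalog", {
    if (identical(cfg$catalog, "packaged")) geromir_catalog()
    else read_catalog(cfg$catalog)
  })
  platform_cat <- stage("catalog",
                        restrict_to_platform(catalog, rownames(xq)))
  stage("catalog", write_catalog(platform_cat,
                                 outfile("catalog_on_platform.tsv")))

  down_dems <- dem_features(dems, "down")
  up_dems <- dem_features(dems, "up")
  gero_on_platform <- catalog_names(platform_cat)
  down_geromirs <- intersect(down_dems, gero_on_platform)
  up_geromirs <- intersect(up_dems, gero_on_platform)

  population <- rownames(xq)
  enr <- stage("enrichment", rbind(
    set_enrichment(down_dems, gero_on_platform, population,
                   category_id = "geromiRs_among_down_DEMs"),
    set_enrichment(up_dems, gero_on_platform, population,
                   category_id = "geromiRs_among_up_DEMs")))
  stage("enrichment", utils::write.table(
    as.data.frame(enr), outfile("geromir_enrichment.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE))

  hm <- stage("enrichment", {
    pop_size <- if (cfg$hallmark_population == "platform") {
      attr(dems, "population_size")
    } else NULL
    hallmark_enrichment(down_geromirs, platform_cat,
                        population_size = pop_size)
  })
  stage("enrichment", utils::write.table(
    hm, outfile("hallmark_enrichment.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE))

  hits <- data.frame(gene = character(), linked_mirnas = character())
  network <- NULL
  if (!is.null(cfg$interactions)) {
    interactions <- stage("network", read_interactions(cfg$interactions))
    network <- stage("network", build_network(down_geromirs, interactions))
    stage("network", export_network(network, outfile("network.graphml"),
                                    outfile("network_edges.tsv")))
    if (!is.null(cfg$gene_matrix)) {
      if (is.null(cfg$gene_annotation)) {
        stop("stage [network]: gene_matrix configured without ",
             "gene_annotation", call. = FALSE)
      }
      genes <- stage("network", read_expression_matrix(
        cfg$gene_matrix, cfg$gene_annotation,
        linear_scale = cfg$linear_scale))
      gq <- stage("network", quantile_normalize(genes$matrix))
      gene_params <- dem_params(
        theta = if (is.null(cfg$gene_theta)) cfg$theta else cfg$gene_theta,
        alpha = if (is.null(cfg$gene_alpha)) cfg$alpha else cfg$gene_alpha,
        test = cfg$test)
      hits <- stage("screen", reverse_expression_screen(
        network, gq, genes$annotation, gene_params,
        cell_types = cfg$cell_types))
      stage("screen", utils::write.table(
        hits, outfile("reverse_expression_hits.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE))
    }
  }

  summary <- stage("summary", {
    s <- list(
      package_version = as.character(utils::packageVersion("geromir")),
      features_tested = attr(dems, "population_size"),
      dems_down = length(down_dems),
      dems_up = length(up_dems),
      catalog_size = length(catalog_names(catalog)),
      geromirs_on_platform = length(gero_on_platform),
      geromirs_down = length(down_geromirs),
      geromirs_up = length(up_geromirs),
      geromir_down_enrichment_p = enr$p_value[1L],
      top_hallmarks = utils::head(hm$category_id, 2L),
      reverse_expression_hits = hits$gene,
      config = cfg[setdiff(names(cfg), NULL)])
    stopifnot(s$geromirs_down <= s$dems_down,
              s$geromirs_up <= s$dems_up,
              s$geromirs_on_platform <= s$catalog_size,
              s$geromirs_on_platform <= s$features_tested)
    jsonlite::write_json(s, outfile("summary.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA, null = "null")
    s
  })
  invisible(summary)
}
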