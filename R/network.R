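# Bipartite miRNA-target network from a local interaction table, and the
# reverse-expression screen for targets upregulated despite (because of)
# the downregulation of their miRNA regulators.

#' Read a miRNA-target interaction table
#'
#' Tab-separated with header columns `mirna`, `gene`, `evidence` (a
#' MirTarBase-export-like layout). MiRNA names are harmonized with
#' [normalize_mirna_name()]; duplicate (mirna, gene) pairs are collapsed to
#' their first occurrence. An optional evidence filter keeps rows whose
#' evidence matches a regular expression.
#'
#' @param path Interaction TSV path.
#' @param evidence_pattern Optional regular expression; rows whose
#'   `evidence` does not match are dropped. Default keeps everything.
#' @return Data.frame (`mirna`, `gene`, `evidence`), unique pairs.
#' @export
read_interactions <- function(path, evidence_pattern = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("mirna", "gene")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("interaction table lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (is.null(df$evidence)) df$evidence <- ""
  df$mirna <- normalize_mirna_name(df$mirna)
  if (!is.null(evidence_pattern)) {
    df <- df[grepl(evidence_pattern, df$evidence), , drop = FALSE]
  }
  df <- df[!duplicated(df[, c("mirna", "gene")]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' The packaged synthetic miRNA-target interaction fixture
#'
#' A small, versioned stand-in for a MirTarBase export (synthetic: hand
#' assembled for testing, not a database extract), encoding the curated
#' target neighborhoods of the downregulated geromiRs plus background
#' edges. Users should supply their own interaction table for real
#' analyses.
#'
#' @return Data.frame as from [read_interactions()].
#' @export
synthetic_interactions <- function() {
  read_interactions(system.file("extdata", "mirtarbase_synthetic.tsv",
                                package = "geromir", mustWork = TRUE))
}

#' Build the bipartite miRNA-target network
#'
#' Edges are exactly the interaction rows whose miRNA is in
#' `down_geromirs`; node sets are derived from the retained edges, so no
#' isolated miRNA nodes occur. The graph is strictly bipartite with a
#' logical `type` vertex attribute (`FALSE` miRNA, `TRUE` gene) and a
#' `node_kind` attribute in `{"mirna", "gene"}`.
#'
#' @param down_geromirs Character vector of (downregulated) miRNA names.
#' @param interactions Interaction data.frame from [read_interactions()].
#' @return An igraph graph (possibly empty).
#' @export
build_network <- function(down_geromirs, interactions) {
  keep <- interactions$mirna %in% unique(down_geromirs)
  edges <- interactions[keep, , drop = FALSE]
  mirnas <- sort(unique(edges$mirna))
  genes <- sort(unique(edges$gene))
  clash <- intersect(mirnas, genes)
  if (length(clash) > 0L) {
    stop("identifier(s) appear as both miRNA and gene: ",
         paste(clash, collapse = ", "), call. = FALSE)
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("mirna", "gene"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(
      name = c(mirnas, genes),
      type = c(rep(FALSE, length(mirnas)), rep(TRUE, length(genes))),
      node_kind = c(rep("mirna", length(mirnas)),
                    rep("gene", length(genes))),
      stringsAsFactors = FALSE))
  assert_bipartite(g)
  g
}

assert_bipartite <- function(g) {
  stopifnot(igraph::is_igraph(g))
  if (is.null(igraph::V(g)$type)) {
    stop("network lacks the bipartite 'type' vertex attribute",
         call. = FALSE)
  }
  if (igraph::ecount(g) > 0L) {
    ends <- igraph::ends(g, igraph::E(g), names = FALSE)
    tp <- igraph::V(g)$type
    if (any(tp[ends[, 1L]] == tp[ends[, 2L]])) {
      stop("network is not bipartite: an edge joins two nodes of one kind",
           call. = FALSE)
    }
  }
  invisible(g)
}

#' Node and edge accessors for a bipartite miRNA-target network
#'
#' @param network An igraph graph from [build_network()].
#' @return Character vectors of node names, or a data.frame of edges.
#' @export
mirna_nodes <- function(network) {
  sort(igraph::V(network)$name[!igraph::V(network)$type])
}

#' @rdname mirna_nodes
#' @export
gene_nodes <- function(network) {
  sort(igraph::V(network)$name[igraph::V(network)$type])
}

#' @rdname mirna_nodes
#' @export
network_edges <- function(network) {
  if (igraph::ecount(network) == 0L) {
    return(data.frame(mirna = character(), gene = character(),
                      stringsAsFactors = FALSE))
  }
  e <- igraph::as_data_frame(network, what = "edges")
  tp <- stats::setNames(igraph::V(network)$type, igraph::V(network)$name)
  mir <- ifelse(tp[e$from], e$to, e$from)
  gen <- ifelse(tp[e$from], e$from, e$to)
  out <- data.frame(mirna = unname(mir), gene = unname(gen),
                    stringsAsFactors = FALSE)
  out[order(out$mirna, out$gene), , drop = FALSE]
}

#' MiRNA regulators of one gene in the network
#'
#' Gene symbols are matched case-insensitively (mouse/human capitalization
#' both accepted).
#'
#' @param network An igraph graph from [build_network()].
#' @param gene A gene symbol.
#' @return Sorted character vector of miRNA neighbors (empty if the gene
#'   is not a node).
#' @export
gene_regulators <- function(network, gene) {
  nm <- igraph::V(network)$name
  hit <- which(igraph::V(network)$type & tolower(nm) == tolower(gene))
  if (length(hit) == 0L) return(character())
  sort(igraph::neighbors(network, hit[1L])$name)
}

#' Screen network targets for reversed (upregulated) expression
#'
#' Applies the differential-expression rule of [call_dems()] to the gene
#' expression matrix and keeps the network's gene nodes that are selected
#' as upregulated in the TME: the reverse-expression signature expected
#' when their miRNA repressors are lost. Gene symbols are matched
#' case-insensitively; capitalization is taken from the expression matrix.
#'
#' @param network An igraph graph from [build_network()].
#' @param gene_matrix Quantile-normalized log2 gene expression matrix.
#' @param annot Sample annotation for `gene_matrix`.
#' @param params [dem_params()] used for the screen (by default the same
#'   thresholds as the miRNA layer).
#' @param cell_types Cell types pooled in the contrast.
#' @return Data.frame of hits (`gene`, `mean_C`, `mean_T`, `log2_fc`,
#'   `p_value`, `linked_mirnas` with `;`-joined regulators), sorted by
#'   ascending p-value. Empty (with a warning) if no network gene is
#'   measured in the matrix.
#' @export
reverse_expression_screen <- function(network, gene_matrix, annot,
                                      params = dem_params(),
                                      cell_types = TME_CELL_TYPES) {
  genes <- gene_nodes(network)
  empty <- data.frame(gene = character(), mean_C = numeric(),
                      mean_T = numeric(), log2_fc = numeric(),
                      p_value = numeric(), linked_mirnas = character(),
                      stringsAsFactors = FALSE)
  if (length(genes) == 0L) return(empty)
  present <- tolower(rownames(gene_matrix)) %in% tolower(genes)
  if (!any(present)) {
    warning("no network gene is measured in the expression matrix",
            call. = FALSE)
    return(empty)
  }
  st <- dem_stats(gene_matrix, annot, params, cell_types)
  st <- st[st$selected & st$direction == "up" &
             tolower(st$feature_id) %in% tolower(genes), , drop = FALSE]
  if (nrow(st) == 0L) return(empty)
  linked <- vapply(st$feature_id, function(g) {
    paste(gene_regulators(network, g), collapse = ";")
  }, character(1L))
  out <- data.frame(gene = st$feature_id, mean_C = st$mean_C,
                    mean_T = st$mean_T, log2_fc = st$log2_fc,
                    p_value = st$p_value, linked_mirnas = unname(linked),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export / import a bipartite network
#'
#' Writes GraphML (with the bipartite `type` and `node_kind` vertex
#' attributes) and, optionally, a plain edge-list TSV. Re-importing the
#' GraphML reproduces the network exactly (same node sets and edges).
#'
#' @param network An igraph graph from [build_network()].
#' @param graphml_path Output GraphML path.
#' @param edgelist_path Optional output TSV path (`mirna`, `gene`).
#' @return `graphml_path`, invisibly.
#' @export
export_network <- function(network, graphml_path, edgelist_path = NULL) {
  assert_bipartite(network)
  igraph::write_graph(network, graphml_path, format = "graphml")
  if (!is.null(edgelist_path)) {
    utils::write.table(network_edges(network), edgelist_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(graphml_path)
}

#' @rdname export_network
#' @param path GraphML path written by [export_network()].
#' @export
import_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  igraph::V(g)$type <- as.logical(igraph::V(g)$type)
  assert_bipartite(g)
  g
}
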