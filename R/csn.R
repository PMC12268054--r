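# Chemical space networks: similarity-thresholded graphs over the most
# potent compounds, with pIC50-annotated nodes.

#' Select the most potent compounds
#'
#' The `n` active records with the smallest IC50; ties at the cutoff are
#' broken by canonical SMILES order so the selection is deterministic.
#'
#' @param records Curated compound data frame.
#' @param n Number of compounds to keep (default 500). If fewer are
#'   available, all are returned with a warning.
#' @param active_only Restrict to records labeled active (default TRUE).
#' @return Subset of `records`, ordered by increasing IC50.
#' @export
select_top_actives <- function(records, n = 500, active_only = TRUE) {
  sub <- if (active_only)
    records[records$label == "active", , drop = FALSE] else records
  sub <- sub[order(sub$ic50_nM, sub$canonical_smiles), , drop = FALSE]
  if (n > nrow(sub)) {
    warning("requested ", n, " compounds but only ", nrow(sub),
            " available")
    n <- nrow(sub)
  }
  out <- sub[seq_len(n), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a chemical space network
#'
#' Nodes are compounds (annotated with canonical SMILES and pIC50); an
#' edge joins every pair whose fingerprint Tanimoto similarity passes the
#' threshold (inclusive by default, matching the ">= 0.6" edge rule; set
#' `strict = TRUE` for a strict cut). All C(n,2) pairs are evaluated.
#'
#' @param records Compound data frame (e.g. from [select_top_actives()]).
#' @param threshold Similarity threshold in (0, 1] (default 0.6).
#' @param strict Use `>` instead of `>=` for the edge rule.
#' @param drop_isolated Remove nodes with no edge (default TRUE; network
#'   metrics are then computed over the retained node set).
#' @param fps Optional precomputed fingerprint matrix aligned with
#'   `records`.
#' @return An `igraph` graph with vertex attributes `name` (compound id),
#'   `smiles`, `pic50`, edge attribute `tanimoto`, and graph attributes
#'   `threshold`, `strict`.
#' @export
build_csn <- function(records, threshold = 0.6, strict = FALSE,
                      drop_isolated = TRUE, fps = NULL) {
  if (nrow(records) == 0) stop("empty compound set")
  if (is.null(fps)) fps <- fingerprint_matrix(records$canonical_smiles)
  tm <- tanimoto_matrix(fps)
  n <- nrow(records)
  pass <- if (strict) tm > threshold else tm >= threshold
  pass[lower.tri(pass, diag = TRUE)] <- FALSE
  idx <- which(pass, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  ids <- as.character(records$compound_id)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  g <- igraph::set_vertex_attr(g, "smiles", value = records$canonical_smiles)
  g <- igraph::set_vertex_attr(g, "pic50", value = records$pic50)
  if (nrow(idx)) {
    g <- igraph::add_edges(g, t(idx))
    g <- igraph::set_edge_attr(g, "tanimoto", value = tm[idx])
  }
  if (drop_isolated) {
    iso <- which(igraph::degree(g) == 0)
    if (length(iso)) g <- igraph::delete_vertices(g, iso)
  }
  g <- igraph::set_graph_attr(g, "threshold", threshold)
  g <- igraph::set_graph_attr(g, "strict", strict)
  g
}

#' Metrics of a chemical space network
#'
#' Node/edge counts, edge density `2E / (N (N - 1))` over the graph's node
#' set, connected components with their sizes, and the pIC50 range within
#' each component.
#'
#' @param network An `igraph` graph from [build_csn()].
#' @return List of class `"csn_metrics"`: `n_nodes`, `n_edges`, `density`,
#'   `n_components`, `component_sizes` (decreasing), `components` (data
#'   frame with size and pIC50 range per component).
#' @export
csn_metrics <- function(network) {
  n <- igraph::vcount(network)
  e <- igraph::ecount(network)
  density <- if (n < 2) 0 else 2 * e / (n * (n - 1))
  comp <- igraph::components(network)
  pic50 <- igraph::vertex_attr(network, "pic50")
  comp_df <- do.call(rbind, lapply(seq_len(comp$no), function(i) {
    v <- which(comp$membership == i)
    data.frame(component = i, size = length(v),
               pic50_min = if (!is.null(pic50)) min(pic50[v]) else NA_real_,
               pic50_max = if (!is.null(pic50)) max(pic50[v]) else NA_real_)
  }))
  structure(list(n_nodes = n, n_edges = e, density = density,
                 n_components = comp$no,
                 component_sizes = sort(comp$csize, decreasing = TRUE),
                 components = comp_df),
            class = "csn_metrics")
}

#' @export
print.csn_metrics <- function(x, ...) {
  cat(sprintf(
    "CSN: %d nodes, %d edges, density %.4f, %d connected component%s\n",
    x$n_nodes, x$n_edges, x$density, x$n_components,
    if (x$n_components == 1) "" else "s"))
  cat("component sizes:", paste(utils::head(x$component_sizes, 10),
                                collapse = ", "),
      if (x$n_components > 10) "..." else "", "\n")
  invisible(x)
}

#' Export / import a chemical space network
#'
#' `"graphml"` writes a single GraphML file carrying all node and edge
#' attributes. `"edge_csv"` writes an edge list (`id_a`, `id_b`,
#' `tanimoto` to 4 decimals) plus a companion `*_nodes.csv` with the node
#' attributes, so the round trip `import_graph(export_graph(g))`
#' reproduces node and edge sets with attributes.
#'
#' @param network An `igraph` graph.
#' @param path Output file path.
#' @param format `"graphml"` or `"edge_csv"`.
#' @return `path`, invisibly (`export_graph`); an `igraph` graph
#'   (`import_graph`).
#' @export
export_graph <- function(network, path, format = c("graphml", "edge_csv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(network, names = TRUE)
    edges <- data.frame(
      id_a = if (nrow(el)) el[, 1] else character(0),
      id_b = if (nrow(el)) el[, 2] else character(0),
      tanimoto = sprintf("%.4f", igraph::edge_attr(network, "tanimoto") %||%
                           numeric(0)))
    if (!nrow(el)) edges <- edges[0, ]
    utils::write.csv(edges, path, row.names = FALSE, quote = FALSE)
    nodes <- data.frame(id = igraph::vertex_attr(network, "name"),
                        smiles = igraph::vertex_attr(network, "smiles") %||% NA,
                        pic50 = igraph::vertex_attr(network, "pic50") %||% NA)
    utils::write.csv(nodes, .nodes_path(path), row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}

.nodes_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), "_nodes.csv")
}

#' @rdname export_graph
#' @export
import_graph <- function(path, format = c("graphml", "edge_csv")) {
  format <- match.arg(format)
  if (format == "graphml") return(igraph::read_graph(path, format = "graphml"))
  edges <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = c(id_a = "character",
                                          id_b = "character"))
  nodes <- utils::read.csv(.nodes_path(path), stringsAsFactors = FALSE,
                           colClasses = c(id = "character"))
  g <- igraph::make_empty_graph(n = nrow(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes$id)
  if ("smiles" %in% names(nodes))
    g <- igraph::set_vertex_attr(g, "smiles", value = nodes$smiles)
  if ("pic50" %in% names(nodes))
    g <- igraph::set_vertex_attr(g, "pic50", value = nodes$pic50)
  if (nrow(edges)) {
    g <- igraph::add_edges(g, rbind(match(edges$id_a, nodes$id),
                                    match(edges$id_b, nodes$id)))
    g <- igraph::set_edge_attr(g, "tanimoto", value = as.numeric(edges$tanimoto))
  }
  g
}
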