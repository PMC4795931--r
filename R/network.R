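# Composite typed interaction network: merge PPI, miRNA-target, protein-
# compound and TF-target edges around a query gene list and export to
# standard graph formats.

.tn_node_df <- function(id, kind) {
  data.frame(node_id = id, node_kind = kind, stringsAsFactors = FALSE)
}

#' Build a composite typed interaction network
#'
#' Merges the one-hop neighbourhood of the query genes across four edge
#' families into a single heterogeneous network: protein-protein
#' interactions (restricted to the high-confidence direct-physical class
#' for reliability), miRNA-target interactions (directed miRNA to gene),
#' protein-compound interactions (gene to compound group), and TF-target
#' interactions (directed TF to target). Edges are deduplicated per
#' (pair, type); the same gene pair may carry edges of several types.
#' Query genes are always nodes, even when isolated.
#'
#' @param genes Query [gene_list()]; must be non-empty.
#' @param ppi Optional classified pairs from [classify_ppi()].
#' @param mti Optional miRNA-target records (schema `"mti"`).
#' @param pci Optional protein-compound edges from [build_pci_edges()].
#' @param tf Optional TF-target records (schema `"tf"`).
#' @return An object of class `typed_network`: list with `nodes`
#'   (data.frame `node_id`, `node_kind`), `edges` (data.frame `from`,
#'   `to`, `edge_type`, `directed`, plus per-type attribute columns) and
#'   `query` (the query gene ids).
#' @export
build_network <- function(genes, ppi = NULL, mti = NULL, pci = NULL,
                          tf = NULL) {
  stopifnot(inherits(genes, "gene_list"))
  if (length(genes$members) == 0L) stop("empty query gene list")
  q <- genes$members
  edges <- list()
  nodes <- list(.tn_node_df(q, "gene"))

  if (!is.null(ppi) && nrow(ppi) > 0) {
    p <- ppi[ppi$direct_physical &
               (ppi$gene_a %in% q | ppi$gene_b %in% q), , drop = FALSE]
    if (nrow(p) > 0) {
      edges$ppi <- data.frame(from = pmin(p$gene_a, p$gene_b),
                              to = pmax(p$gene_a, p$gene_b),
                              edge_type = "ppi", directed = FALSE,
                              confidence = "direct_physical",
                              stringsAsFactors = FALSE)
      nodes$ppi <- .tn_node_df(unique(c(p$gene_a, p$gene_b)), "gene")
    }
  }
  if (!is.null(mti) && nrow(mti) > 0) {
    m <- mti[mti$gene_id %in% q | mti$mirna_id %in% q, , drop = FALSE]
    if (nrow(m) > 0) {
      m <- m[!duplicated(m[c("mirna_id", "gene_id")]), , drop = FALSE]
      edges$mti <- data.frame(from = m$mirna_id, to = m$gene_id,
                              edge_type = "mti", directed = TRUE,
                              evidence_class = m$evidence_class,
                              stringsAsFactors = FALSE)
      nodes$mti <- rbind(.tn_node_df(unique(m$mirna_id), "mirna"),
                         .tn_node_df(unique(m$gene_id), "gene"))
    }
  }
  if (!is.null(pci) && nrow(pci) > 0) {
    pc <- pci[pci$protein_id %in% q, , drop = FALSE]
    if (nrow(pc) > 0) {
      edges$pci <- data.frame(from = pc$protein_id, to = pc$skeleton,
                              edge_type = "pci", directed = FALSE,
                              best_activity_nM = pc$best_activity_nM,
                              annotation_edge = pc$has_annotation,
                              stringsAsFactors = FALSE)
      nodes$pci <- rbind(.tn_node_df(unique(pc$protein_id), "gene"),
                         .tn_node_df(unique(pc$skeleton),
                                     "compound_group"))
    }
  }
  if (!is.null(tf) && nrow(tf) > 0) {
    t_ <- tf[tf$tf_gene_id %in% q | tf$target_gene_id %in% q, ,
             drop = FALSE]
    t_ <- t_[t_$tf_gene_id != t_$target_gene_id, , drop = FALSE]
    if (nrow(t_) > 0) {
      t_ <- t_[!duplicated(t_[c("tf_gene_id", "target_gene_id")]), ,
               drop = FALSE]
      edges$tf <- data.frame(from = t_$tf_gene_id, to = t_$target_gene_id,
                             edge_type = "tf_target", directed = TRUE,
                             source_db = t_$source_db,
                             stringsAsFactors = FALSE)
      nodes$tf <- .tn_node_df(unique(c(t_$tf_gene_id, t_$target_gene_id)),
                              "gene")
    }
  }

  all_edges <- if (length(edges) > 0) {
    cols <- c("from", "to", "edge_type", "directed", "confidence",
              "evidence_class", "best_activity_nM", "annotation_edge",
              "source_db")
    filled <- lapply(edges, function(e) {
      for (cl in setdiff(cols, names(e))) e[[cl]] <- NA
      e[cols]
    })
    do.call(rbind, filled)
  } else {
    data.frame(from = character(0), to = character(0),
               edge_type = character(0), directed = logical(0),
               stringsAsFactors = FALSE)
  }
  key <- ifelse(all_edges$directed,
                paste(all_edges$from, all_edges$to, all_edges$edge_type),
                paste(pmin(all_edges$from, all_edges$to),
                      pmax(all_edges$from, all_edges$to),
                      all_edges$edge_type))
  all_edges <- all_edges[!duplicated(key), , drop = FALSE]
  all_nodes <- do.call(rbind, nodes)
  all_nodes <- all_nodes[!duplicated(all_nodes$node_id), , drop = FALSE]
  all_nodes <- all_nodes[order(all_nodes$node_id), , drop = FALSE]
  all_edges <- all_edges[order(all_edges$edge_type, all_edges$from,
                               all_edges$to), , drop = FALSE]
  rownames(all_nodes) <- rownames(all_edges) <- NULL
  structure(list(nodes = all_nodes, edges = all_edges, query = q),
            class = "typed_network")
}

#' @export
print.typed_network <- function(x, ...) {
  cat(sprintf("<typed_network> %d node(s), %d edge(s)\n",
              nrow(x$nodes), nrow(x$edges)))
  if (nrow(x$edges) > 0) print(table(x$edges$edge_type))
  invisible(x)
}

#' Filter protein-compound edges by activity threshold
#'
#' Removes PCI edges whose best assay activity exceeds `max_nM`, and
#' assay-less PCI edges unless they are drug-annotation edges (pairs from
#' curated drug-target sources, which carry no assay value by design).
#' Other edge types are untouched. Nodes orphaned by the removal are
#' pruned, except query genes, which anchor the display and are always
#' retained.
#'
#' @param net A [build_network()] result.
#' @param max_nM Maximum activity kept, in nM (inclusive).
#' @return A filtered `typed_network`.
#' @export
filter_activity <- function(net, max_nM) {
  stopifnot(inherits(net, "typed_network"), max_nM > 0)
  e <- net$edges
  is_pci <- e$edge_type == "pci"
  keep_pci <- !is_pci |
    (!is.na(e$best_activity_nM) & e$best_activity_nM <= max_nM) |
    (is_pci & !is.na(e$annotation_edge) & e$annotation_edge)
  e <- e[keep_pci, , drop = FALSE]
  used <- unique(c(e$from, e$to, net$query))
  nodes <- net$nodes[net$nodes$node_id %in% used, , drop = FALSE]
  rownames(e) <- rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = e, query = net$query),
            class = "typed_network")
}

#' Export a typed network
#'
#' Writes the network as GraphML (node kind and edge attributes
#' preserved; importable with [igraph::read_graph()]), SIF (one line per
#' edge, the edge type as the relation), or Cytoscape-compatible JSON
#' (an `elements` object with `nodes` and `edges` arrays). Directed edge
#' types (miRNA-target, TF-target) carry their direction.
#'
#' @param net A [build_network()] result.
#' @param path Output file path.
#' @param format One of `"graphml"`, `"sif"`, `"json"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "sif", "json")) {
  stopifnot(inherits(net, "typed_network"))
  format <- match.arg(format)
  if (format == "sif") {
    lines <- sprintf("%s\t%s\t%s", net$edges$from, net$edges$edge_type,
                     net$edges$to)
    writeLines(lines, path)
  } else if (format == "graphml") {
    vertices <- data.frame(name = net$nodes$node_id,
                           node_kind = net$nodes$node_kind,
                           is_query = net$nodes$node_id %in% net$query,
                           stringsAsFactors = FALSE)
    e <- net$edges
    # GraphML attributes: blank out non-applicable fields
    for (cl in names(e)) {
      if (is.character(e[[cl]])) e[[cl]][is.na(e[[cl]])] <- ""
      if (is.logical(e[[cl]])) e[[cl]][is.na(e[[cl]])] <- FALSE
    }
    g <- igraph::graph_from_data_frame(e, directed = TRUE,
                                       vertices = vertices)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    nodes <- lapply(seq_len(nrow(net$nodes)), function(i) {
      list(data = list(id = net$nodes$node_id[i],
                       node_kind = net$nodes$node_kind[i],
                       is_query = net$nodes$node_id[i] %in% net$query))
    })
    edges <- lapply(seq_len(nrow(net$edges)), function(i) {
      d <- list(id = paste0("e", i),
                source = net$edges$from[i],
                target = net$edges$to[i],
                edge_type = net$edges$edge_type[i],
                directed = net$edges$directed[i])
      if (!is.na(net$edges$best_activity_nM[i])) {
        d$best_activity_nM <- net$edges$best_activity_nM[i]
      }
      list(data = d)
    })
    jsonlite::write_json(list(elements = list(nodes = nodes, edges = edges)),
                         path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
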