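# End-to-end workflow: list -> (extend) -> (convert) -> enrich ->
# heatmap matrix -> composite network -> topology, with provenance
# headers on every artifact.

.tn_version <- function() {
  as.character(utils::packageVersion("themenet"))
}

.tn_provenance <- function(stage, params, inputs) {
  sums <- vapply(inputs, function(p) unname(tools::md5sum(p)), character(1))
  c(paste0("themenet ", .tn_version(), " stage=", stage),
    paste0("params: ", paste(names(params), unlist(params), sep = "=",
                             collapse = " ")),
    paste0("input ", basename(inputs), " md5=", sums))
}

#' Run the full list-analysis workflow
#'
#' Executes, in order: optional extension of the query list by PPI
#' partners, optional orthologue conversion to a target organism, theme
#' enrichment, construction of the binary gene-by-theme matrix with UPGMA
#' ordering, assembly of the composite typed interaction network, and
#' topology analysis of the high-confidence direct-physical PPI graph.
#' Every table written carries a provenance header (tool version,
#' parameters, input checksums). Outputs are byte-identical across runs
#' with identical inputs and configuration.
#'
#' @param config A list (or path to a JSON file) with elements:
#'   `genes` (gene list path), `taxon`, `annotation`, `ppi`, and
#'   optionally `mti`, `tf`, `compound`, `activity`, `drug_pairs`,
#'   `hits`; parameters `extend_mode` (`"none"`/`"high_confidence"`/
#'   `"direct_physical"`), `convert_to` (target taxon or `NULL`),
#'   `method`, `alpha`, `max_nm`, `hub_fraction`; and `outdir`.
#' @return A named list of written artifact paths, invisibly.
#' @export
run_workflow <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config)
  cfg <- utils::modifyList(
    list(taxon = "human", extend_mode = "none", convert_to = NULL,
         method = "bh", alpha = 0.05, max_nm = NULL, hub_fraction = 0.10),
    config)
  for (f in c("genes", "annotation")) {
    if (is.null(cfg[[f]])) stop("workflow config is missing '", f, "'")
  }
  if (cfg$extend_mode != "none" && is.null(cfg$ppi)) {
    stop("list extension (extend_mode = '", cfg$extend_mode,
         "') requires a 'ppi' table")
  }
  if (!is.null(cfg$convert_to) && is.null(cfg$hits)) {
    stop("orthologue conversion requires a 'hits' table")
  }
  inputs <- unlist(cfg[intersect(names(cfg),
                                 c("genes", "annotation", "ppi", "mti",
                                   "tf", "compound", "activity",
                                   "drug_pairs", "hits"))])
  for (p in inputs) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  params <- cfg[c("taxon", "extend_mode", "method", "alpha",
                  "hub_fraction")]
  params$convert_to <- cfg$convert_to %||% "none"
  params$max_nm <- cfg$max_nm %||% "none"
  prov <- function(stage) .tn_provenance(stage, params, inputs)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("workflow stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  art <- list()

  genes <- stage("read", read_gene_list(cfg$genes, taxon = cfg$taxon))
  ann <- stage("read", annotation_set(read_table(cfg$annotation,
                                                 "annotation")))
  ppi_cls <- NULL
  if (!is.null(cfg$ppi)) {
    ppi_cls <- stage("ppi-classify", classify_ppi(read_table(cfg$ppi,
                                                             "ppi")))
    art$ppi_classified <- file.path(cfg$outdir, "ppi_classified.tsv")
    write_table(ppi_cls, art$ppi_classified, prov("ppi-classify"))
  }

  if (cfg$extend_mode != "none") {
    genes <- stage("extend",
                   extend_with_partners(genes, ppi_cls, cfg$extend_mode))
  }
  if (!is.null(cfg$convert_to)) {
    pairs <- stage("orthology", {
      mutual_best_hits(read_table(cfg$hits, "hits"))
    })
    art$orthologues <- file.path(cfg$outdir, "orthologues.tsv")
    write_table(pairs, art$orthologues, prov("orthology"))
    genes <- stage("convert", convert_list(genes, pairs, cfg$convert_to))
  }

  enr <- stage("enrich",
               run_enrichment(genes, ann, method = cfg$method,
                              alpha = cfg$alpha))
  art$enrichment <- file.path(cfg$outdir, "enrichment.tsv")
  write_table(as.data.frame(enr), art$enrichment, prov("enrich"))

  sig <- enr[enr$significant, , drop = FALSE]
  if (nrow(sig) >= 1) {
    assoc <- do.call(rbind, lapply(seq_len(nrow(sig)), function(i) {
      data.frame(gene_id = strsplit(sig$genes[i], ";")[[1]],
                 theme_id = sig$theme_id[i], stringsAsFactors = FALSE)
    }))
    m <- stage("thememap", build_binary_matrix(assoc))
    art$matrix <- file.path(cfg$outdir, "association_matrix.tsv")
    if (nrow(m) >= 2) {
      dg <- stage("thememap", upgma(euclidean_distances(m)))
      export_matrix(m, dg, sort = "cluster", path = art$matrix)
      art$dendrogram <- file.path(cfg$outdir, "dendrogram.nwk")
      writeLines(dendrogram_newick(dg), art$dendrogram)
    } else {
      export_matrix(m, sort = "none", path = art$matrix)
    }
  }

  pci <- NULL
  if (!is.null(cfg$compound) && !is.null(cfg$activity)) {
    pci <- stage("compounds", {
      groups <- group_compounds(read_table(cfg$compound, "compound"))
      acts <- filter_binding_activities(read_table(cfg$activity,
                                                   "activity"))
      extra <- if (!is.null(cfg$drug_pairs)) {
        read.delim(cfg$drug_pairs, sep = "\t", stringsAsFactors = FALSE)
      } else NULL
      build_pci_edges(groups, acts, extra)
    })
    art$pci_edges <- file.path(cfg$outdir, "pci_edges.tsv")
    write_table(pci, art$pci_edges, prov("compounds"))
  }
  mti <- if (!is.null(cfg$mti)) read_table(cfg$mti, "mti") else NULL
  tf <- if (!is.null(cfg$tf)) read_table(cfg$tf, "tf") else NULL
  net <- stage("network", {
    n <- build_network(genes, ppi = ppi_cls, mti = mti, pci = pci, tf = tf)
    if (!is.null(cfg$max_nm)) n <- filter_activity(n, cfg$max_nm) else n
  })
  art$network_sif <- file.path(cfg$outdir, "network.sif")
  export_network(net, art$network_sif, "sif")
  art$network_graphml <- file.path(cfg$outdir, "network.graphml")
  export_network(net, art$network_graphml, "graphml")
  art$network_json <- file.path(cfg$outdir, "network.json")
  export_network(net, art$network_json, "json")

  topo <- stage("topology", {
    dp <- if (is.null(ppi_cls)) NULL else
      ppi_cls[ppi_cls$direct_physical, c("gene_a", "gene_b")]
    if (is.null(dp) || nrow(dp) == 0) NULL else {
      centrality_table(largest_component(simple_graph(dp)),
                       fraction = cfg$hub_fraction)
    }
  })
  if (!is.null(topo)) {
    art$centrality <- file.path(cfg$outdir, "centrality.tsv")
    write_table(topo, art$centrality, prov("topology"))
  }
  invisible(art)
}
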