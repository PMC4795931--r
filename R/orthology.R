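# Orthologue derivation by mutual best hits and cross-species list
# conversion.

#' Mutual best hits from reciprocal similarity searches
#'
#' Two sequences are called orthologues when each is the other's uniquely
#' best similarity hit (minimum e-value) and both hits pass the e-value
#' threshold (1e-3 by default, inclusive). A query whose minimal e-value
#' is achieved by more than one subject has no defined best hit and is
#' disqualified. Hits where only one direction is best are reported as
#' near-misses.
#'
#' @param hits Alignment hits (schema `"hits"` of [read_table()]); both
#'   query directions for the taxon pair must be present. Optional columns
#'   `query_taxon` / `subject_taxon` are carried through to the output.
#' @param max_evalue E-value threshold; hits above it are ignored.
#' @return A data.frame of pairs `id_a`, `id_b` (with `taxon_a`/`taxon_b`
#'   when taxa were supplied), one row per orthologue pair, attribute
#'   `"near_misses"` listing one-directional best hits.
#' @export
mutual_best_hits <- function(hits, max_evalue = 1e-3) {
  h <- hits[hits$evalue <= max_evalue, , drop = FALSE]
  if (nrow(h) == 0L) {
    out <- data.frame(id_a = character(0), id_b = character(0),
                      stringsAsFactors = FALSE)
    attr(out, "near_misses") <- out
    return(out)
  }
  # unique-minimum best subject per query
  best_of <- new.env(parent = emptyenv())
  for (q in unique(h$query_id)) {
    rows <- h[h$query_id == q, , drop = FALSE]
    m <- min(rows$evalue)
    subj <- unique(rows$subject_id[rows$evalue == m])
    if (length(subj) == 1L) assign(q, subj, envir = best_of)
  }
  taxon_of <- NULL
  if (all(c("query_taxon", "subject_taxon") %in% names(hits))) {
    taxon_of <- setNames(c(hits$query_taxon, hits$subject_taxon),
                         c(hits$query_id, hits$subject_id))
  }
  qs <- ls(best_of)
  pairs <- list()
  near <- list()
  for (q in qs) {
    b <- get(q, envir = best_of)
    back <- if (exists(b, envir = best_of)) get(b, envir = best_of) else NA
    if (identical(back, q)) {
      if (q < b) {  # emit each unordered pair once
        pairs[[q]] <- data.frame(id_a = q, id_b = b,
                                 stringsAsFactors = FALSE)
      }
    } else {
      near[[q]] <- data.frame(id_a = q, id_b = b, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(pairs) > 0) do.call(rbind, pairs) else
    data.frame(id_a = character(0), id_b = character(0),
               stringsAsFactors = FALSE)
  nm <- if (length(near) > 0) do.call(rbind, near) else
    data.frame(id_a = character(0), id_b = character(0),
               stringsAsFactors = FALSE)
  if (!is.null(taxon_of)) {
    out$taxon_a <- unname(taxon_of[out$id_a])
    out$taxon_b <- unname(taxon_of[out$id_b])
  }
  out <- out[order(out$id_a), , drop = FALSE]
  rownames(out) <- NULL
  rownames(nm) <- NULL
  attr(out, "near_misses") <- nm
  out
}

#' Convert a gene list to another organism via orthologue pairs
#'
#' Maps each member to its orthologue in the target organism. Because
#' mutual-best-hit pairs form a one-to-one matching, distinct input genes
#' never collapse onto one target gene. Unmapped members are reported.
#'
#' @param genes A [gene_list()].
#' @param pairs Orthologue pairs from [mutual_best_hits()] with
#'   `taxon_a`/`taxon_b` columns, or any data.frame with columns `id_a`,
#'   `id_b`, `taxon_a`, `taxon_b`.
#' @param target_taxon Organism tag to convert to.
#' @return A [gene_list()] in the target organism with attribute
#'   `"unmapped"` (input gene ids without an orthologue).
#' @export
convert_list <- function(genes, pairs, target_taxon) {
  stopifnot(inherits(genes, "gene_list"))
  if (!all(c("taxon_a", "taxon_b") %in% names(pairs))) {
    stop("orthologue pairs need taxon_a/taxon_b columns for conversion")
  }
  fwd <- pairs$taxon_a == genes$taxon & pairs$taxon_b == target_taxon
  rev <- pairs$taxon_b == genes$taxon & pairs$taxon_a == target_taxon
  from <- c(pairs$id_a[fwd], pairs$id_b[rev])
  to <- c(pairs$id_b[fwd], pairs$id_a[rev])
  if (length(from) == 0L) {
    stop("no orthologue pairs connect '", genes$taxon, "' to '",
         target_taxon, "'")
  }
  map <- setNames(to, from)
  if (anyDuplicated(from) || anyDuplicated(to)) {
    stop("orthologue pairs are not one-to-one for this taxon pair")
  }
  mapped <- unname(map[genes$members])
  unmapped <- genes$members[is.na(mapped)]
  mapped <- mapped[!is.na(mapped)]
  if (length(mapped) == 0L) stop("no genes could be converted")
  out <- gene_list(mapped, name = paste0(genes$name, ".", target_taxon),
                   taxon = target_taxon)
  if (length(unmapped) > 0) {
    message(length(unmapped), " gene(s) had no orthologue in ", target_taxon)
  }
  attr(out, "unmapped") <- unmapped
  out
}
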