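# Multi-source PPI evidence aggregation and confidence classification.
#
# An interaction is "high-confidence" when supported by at least two
# distinct experimental methods or two independent publications, and
# "direct physical" when, in addition, at least one piece of evidence is
# annotated as a direct physical interaction by its source or comes from a
# method capable of detecting direct physical contact (yeast two-hybrid,
# FRET, AFM, ...).

.canonical_pair <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Default whitelist of direct-physical-capable detection methods
#'
#' Reads the method whitelist shipped with the package (PSI-MI detection
#' method accessions for assays that can demonstrate direct physical
#' contact, such as two-hybrid and FRET). Users may supply their own file
#' with columns `method_id` and `method_name`.
#'
#' @param path Path to a whitelist TSV; defaults to the packaged file.
#' @return Character vector of method ids.
#' @export
load_direct_methods <- function(path = system.file("extdata",
                                                   "direct_methods.tsv",
                                                   package = "themenet")) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  df$method_id
}

#' Aggregate PPI evidence records onto canonical gene pairs
#'
#' Orders each gene pair lexicographically so that `(b, a)` and `(a, b)`
#' are one pair, quarantines self-interactions, deduplicates evidence on
#' (pair, method, publication, source database), and tags each evidence
#' item with whether its method is on the direct-physical-capable
#' whitelist.
#'
#' @param ev PPI evidence records (schema `"ppi"` of [read_table()]).
#' @param direct_methods Character vector of method ids capable of
#'   detecting direct physical contact; see [load_direct_methods()].
#' @return A data.frame of deduplicated evidence with columns `pair_key`,
#'   `gene_a`, `gene_b` (canonical order), `method_id`, `pmid`,
#'   `source_db`, `direct_flag`, `method_direct_capable`; attribute
#'   `"self_loops"` holds the quarantined rows.
#' @export
aggregate_evidence <- function(ev, direct_methods = load_direct_methods()) {
  self <- ev$gene_a == ev$gene_b
  quarantined <- ev[self, , drop = FALSE]
  if (nrow(quarantined) > 0) {
    message(nrow(quarantined), " self-interaction record(s) quarantined")
  }
  ev <- ev[!self, , drop = FALSE]
  a <- pmin(ev$gene_a, ev$gene_b)
  b <- pmax(ev$gene_a, ev$gene_b)
  out <- data.frame(pair_key = paste(a, b, sep = "\r"),
                    gene_a = a, gene_b = b,
                    method_id = ev$method_id, pmid = as.character(ev$pmid),
                    source_db = ev$source_db,
                    direct_flag = as.logical(ev$direct_flag),
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(out[c("pair_key", "method_id", "pmid",
                               "source_db")]), , drop = FALSE]
  out$method_direct_capable <- out$method_id %in% direct_methods
  rownames(out) <- NULL
  attr(out, "self_loops") <- quarantined
  out
}

#' Classify pairs as high-confidence
#'
#' A pair is high-confidence when supported by at least two distinct
#' detection methods or at least two independent publications (distinct
#' method-id and PMID strings respectively).
#'
#' @param agg Aggregated evidence from [aggregate_evidence()].
#' @return One row per pair: `gene_a`, `gene_b`, `n_methods`, `n_pubs`,
#'   `high_confidence`.
#' @export
classify_high_confidence <- function(agg) {
  sp <- split(seq_len(nrow(agg)), agg$pair_key)
  out <- do.call(rbind, lapply(sp, function(ix) {
    data.frame(gene_a = agg$gene_a[ix[1]], gene_b = agg$gene_b[ix[1]],
               n_methods = length(unique(agg$method_id[ix])),
               n_pubs = length(unique(agg$pmid[ix])),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(gene_a = character(0), gene_b = character(0),
                      n_methods = integer(0), n_pubs = integer(0))
  }
  out$high_confidence <- out$n_methods >= 2 | out$n_pubs >= 2
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify high-confidence pairs as direct physical
#'
#' The direct-physical subset of the high-confidence pairs: those with at
#' least one evidence item annotated as a direct physical interaction by
#' its source, or detected by a whitelisted direct-capable method. A pair
#' that is not high-confidence is never direct-physical, whatever its
#' evidence.
#'
#' @param cls Output of [classify_high_confidence()].
#' @param agg The aggregated evidence the classification came from.
#' @return `cls` with an added logical column `direct_physical`.
#' @export
classify_direct_physical <- function(cls, agg) {
  key <- paste(cls$gene_a, cls$gene_b, sep = "\r")
  direct_pairs <- unique(agg$pair_key[agg$direct_flag |
                                        agg$method_direct_capable])
  cls$direct_physical <- cls$high_confidence & key %in% direct_pairs
  cls
}

#' Aggregate and classify PPI evidence in one step
#'
#' Convenience wrapper: [aggregate_evidence()] then
#' [classify_high_confidence()] then [classify_direct_physical()].
#'
#' @inheritParams aggregate_evidence
#' @return A classified pair table (see [classify_direct_physical()]).
#' @export
classify_ppi <- function(ev, direct_methods = load_direct_methods()) {
  agg <- aggregate_evidence(ev, direct_methods)
  classify_direct_physical(classify_high_confidence(agg), agg)
}
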