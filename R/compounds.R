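# Compound unification by InChIKey skeleton and binding-activity filtering.

#' Validate InChIKeys and extract the molecular skeleton
#'
#' An InChIKey is a 27-character hashed structure identifier in three
#' hyphen-separated blocks: 14 uppercase letters encoding the molecular
#' skeleton (connectivity), 10 uppercase letters (8 for the remaining
#' structural layers plus a 2-letter flag area), and a final 1-letter
#' protonation block. Only the shape is validated; the second and third
#' blocks are never interpreted.
#'
#' @param x Character vector of putative InChIKeys.
#' @return A data.frame with columns `inchikey`, `valid` (logical),
#'   `skeleton` (first 14-character block, `NA` when invalid) and `reason`
#'   (`NA` when valid; otherwise one of `"block count"`, `"block length"`,
#'   `"case"`, `"invalid characters"`).
#' @export
#' @examples
#' parse_inchikey(c("BSYNRYMUTXBXSQ-UHFFFAOYSA-N", "AAAA-BB-N"))
parse_inchikey <- function(x) {
  x <- as.character(x)
  n <- length(x)
  valid <- rep(FALSE, n)
  skeleton <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  parts <- strsplit(x, "-", fixed = TRUE)
  for (i in seq_len(n)) {
    p <- parts[[i]]
    if (is.na(x[i]) || length(p) != 3L) {
      reason[i] <- "block count"
    } else if (nchar(p[1]) != 14L || nchar(p[2]) != 10L ||
               nchar(p[3]) != 1L) {
      reason[i] <- "block length"
    } else if (grepl("[a-z]", x[i])) {
      reason[i] <- "case"
    } else if (!all(grepl("^[A-Z]+$", p))) {
      reason[i] <- "invalid characters"
    } else {
      valid[i] <- TRUE
      skeleton[i] <- p[1]
    }
  }
  data.frame(inchikey = x, valid = valid, skeleton = skeleton,
             reason = reason, stringsAsFactors = FALSE)
}

#' Unify compound records into groups by InChIKey skeleton
#'
#' Compounds from different sources that share the first 14-character
#' InChIKey block describe the same molecular skeleton and are collated
#' into one group — the unified chemical entity. Records with invalid
#' InChIKeys are rejected first and reported.
#'
#' @param records Compound records (schema `"compound"` of [read_table()]).
#' @return An object of class `compound_groups`: a list with `records`
#'   (the valid records plus a `skeleton` column), `skeletons` (distinct
#'   skeleton keys, one per group) and `rejected` (invalid records with
#'   reasons).
#' @export
group_compounds <- function(records) {
  if (nrow(records) == 0L) {
    return(structure(list(records = cbind(records,
                                          skeleton = character(0)),
                          skeletons = character(0),
                          rejected = records),
                     class = "compound_groups"))
  }
  pk <- parse_inchikey(records$inchikey)
  rejected <- records[!pk$valid, , drop = FALSE]
  if (nrow(rejected) > 0) {
    rejected$reason <- pk$reason[!pk$valid]
    message(nrow(rejected), " compound record(s) with invalid InChIKey rejected")
  }
  recs <- records[pk$valid, , drop = FALSE]
  recs$skeleton <- pk$skeleton[pk$valid]
  rownames(recs) <- NULL
  structure(list(records = recs,
                 skeletons = unique(recs$skeleton),
                 rejected = rejected),
            class = "compound_groups")
}

#' @export
print.compound_groups <- function(x, ...) {
  cat(sprintf("<compound_groups> %d group(s) from %d record(s) (%d rejected)\n",
              length(x$skeletons), nrow(x$records), nrow(x$rejected)))
  invisible(x)
}

#' Filter bioactivity records to reliable single-protein binding assays
#'
#' Keeps activity records satisfying all of: assay-to-target mapping
#' confidence score at least 4, assay type `"B"` (binding), target type
#' `"SINGLE PROTEIN"`, measurement type one of IC50 / Kd / Ki, and
#' activity value at or below `max_value_nM` (10 000 nM by default; the
#' comparison is inclusive). Values must already be in nM. Rejected counts
#' are tallied by the first unmet condition.
#'
#' @param acts Activity records (schema `"activity"` of [read_table()]).
#' @param max_value_nM Maximum activity value kept, in nM.
#' @return The surviving records, with attribute `"rejected_by_reason"`
#'   (named integer vector of counts).
#' @export
filter_binding_activities <- function(acts, max_value_nM = 10000) {
  reason <- rep(NA_character_, nrow(acts))
  reason[is.na(reason) & !(acts$confidence_score >= 4)] <- "confidence_score"
  reason[is.na(reason) & acts$assay_type != "B"] <- "assay_type"
  reason[is.na(reason) & acts$target_type != "SINGLE PROTEIN"] <- "target_type"
  reason[is.na(reason) &
           !acts$standard_type %in% c("IC50", "Kd", "Ki")] <- "standard_type"
  reason[is.na(reason) &
           !(acts$standard_value_nM <= max_value_nM)] <- "standard_value"
  keep <- is.na(reason)
  out <- acts[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected_by_reason") <-
    table(factor(reason[!keep],
                 levels = c("confidence_score", "assay_type", "target_type",
                            "standard_type", "standard_value")))
  out
}

#' Build protein-compound interaction edges
#'
#' Collapses filtered activity records and annotation-style compound-protein
#' pairs (e.g. approved-drug target annotations carrying no assay value)
#' onto compound groups, yielding one edge per (skeleton, protein). The
#' edge activity is the minimum (most potent) surviving assay value across
#' all group members; edges supported only by annotation pairs have no
#' activity value. Compound identifiers that resolve to no group are
#' reported as orphans.
#'
#' @param groups A [group_compounds()] result.
#' @param acts Filtered activity records (see [filter_binding_activities()]);
#'   an optional `source_db` column is honoured, otherwise `"ChEMBL"` is
#'   assumed.
#' @param extra_pairs Optional data.frame with columns `compound_id`,
#'   `protein_id`, `source_db` of annotation-only pairs.
#' @return A data.frame of edges with columns `skeleton`, `protein_id`,
#'   `best_activity_nM` (`NA` for annotation-only edges), `annotation_only`
#'   (logical) and `source_dbs` (semicolon-joined), plus attribute
#'   `"orphans"` (unresolvable compound ids).
#' @export
build_pci_edges <- function(groups, acts, extra_pairs = NULL) {
  stopifnot(inherits(groups, "compound_groups"))
  skel_of <- setNames(groups$records$skeleton, groups$records$compound_id)

  rows <- list()
  orphans <- character(0)
  if (nrow(acts) > 0) {
    src <- if ("source_db" %in% names(acts)) acts$source_db else
      rep("ChEMBL", nrow(acts))
    sk <- unname(skel_of[acts$compound_id])
    orphans <- c(orphans, unique(acts$compound_id[is.na(sk)]))
    ok <- !is.na(sk)
    rows$assay <- data.frame(skeleton = sk[ok],
                             protein_id = acts$protein_id[ok],
                             activity = acts$standard_value_nM[ok],
                             source_db = src[ok],
                             stringsAsFactors = FALSE)
  }
  if (!is.null(extra_pairs) && nrow(extra_pairs) > 0) {
    sk <- unname(skel_of[extra_pairs$compound_id])
    orphans <- c(orphans, unique(extra_pairs$compound_id[is.na(sk)]))
    ok <- !is.na(sk)
    rows$annot <- data.frame(skeleton = sk[ok],
                             protein_id = extra_pairs$protein_id[ok],
                             activity = NA_real_,
                             source_db = extra_pairs$source_db[ok],
                             stringsAsFactors = FALSE)
  }
  all_rows <- do.call(rbind, rows)
  if (is.null(all_rows) || nrow(all_rows) == 0L) {
    out <- data.frame(skeleton = character(0), protein_id = character(0),
                      best_activity_nM = numeric(0),
                      annotation_only = logical(0),
                      has_annotation = logical(0),
                      source_dbs = character(0), stringsAsFactors = FALSE)
    attr(out, "orphans") <- unique(orphans)
    return(out)
  }
  key <- paste(all_rows$skeleton, all_rows$protein_id, sep = "\r")
  sp <- split(seq_len(nrow(all_rows)), key)
  out <- do.call(rbind, lapply(sp, function(ix) {
    act <- all_rows$activity[ix]
    best <- if (all(is.na(act))) NA_real_ else min(act, na.rm = TRUE)
    data.frame(skeleton = all_rows$skeleton[ix[1]],
               protein_id = all_rows$protein_id[ix[1]],
               best_activity_nM = best,
               annotation_only = all(is.na(act)),
               has_annotation = any(is.na(act)),
               source_dbs = paste(sort(unique(all_rows$source_db[ix])),
                                  collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$skeleton, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  orphans <- unique(orphans)
  if (length(orphans) > 0) {
    message(length(orphans), " compound id(s) did not resolve to any group")
  }
  attr(out, "orphans") <- orphans
  out
}
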