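# Readers/writers for the delimited input tables, the gene-list container
# and the Barcode expression filter.

#' Construct a gene list
#'
#' A `gene_list` is an ordered, duplicate-free set of gene identifiers with
#' a name and an organism tag. Duplicates are removed keeping the first
#' occurrence; the number dropped is recorded.
#'
#' @param ids Character vector of gene identifiers (non-empty strings).
#' @param name Name of the list.
#' @param taxon Organism tag, e.g. `"human"`, `"mouse"`, `"rat"`.
#' @return An object of class `gene_list` with elements `name`, `members`,
#'   `taxon` and `n_duplicates_dropped`.
#' @export
#' @examples
#' gene_list(c("g1", "g2", "g1"), name = "demo")
gene_list <- function(ids, name = "gene_list", taxon = "human") {
  ids <- as.character(ids)
  if (any(is.na(ids) | !nzchar(ids))) {
    stop("gene identifiers must be non-empty strings")
  }
  dup <- duplicated(ids)
  structure(
    list(name = name, members = ids[!dup], taxon = taxon,
         n_duplicates_dropped = sum(dup)),
    class = "gene_list"
  )
}

#' @export
print.gene_list <- function(x, ...) {
  cat(sprintf("<gene_list> '%s' (%s): %d genes\n",
              x$name, x$taxon, length(x$members)))
  cat(" ", paste(head(x$members, 8), collapse = ", "),
      if (length(x$members) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.gene_list <- function(x) length(x$members)

#' Read a gene list from a plain-text file
#'
#' One identifier per line; lines starting with `#` are comments and blank
#' lines are skipped. Duplicates are dropped (first occurrence kept) and
#' reported via a message.
#'
#' @param path Path to the file.
#' @param taxon Organism tag attached to the list.
#' @param name List name; defaults to the file name.
#' @return A [gene_list()].
#' @export
read_gene_list <- function(path, taxon = "human", name = basename(path)) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty gene list: ", path)
  gl <- gene_list(lines, name = name, taxon = taxon)
  if (gl$n_duplicates_dropped > 0) {
    message(gl$n_duplicates_dropped, " duplicate identifier(s) dropped from ",
            name)
  }
  gl
}

# Table schemas: required columns and per-column coercers. A coercer
# returns NA where a value cannot be represented, which rejects the row.
.tn_schemas <- list(
  annotation = list(
    required = c("theme_id", "theme_name", "gene_id"),
    numeric = character()
  ),
  ppi = list(
    required = c("gene_a", "gene_b", "method_id", "pmid", "source_db",
                 "direct_flag"),
    numeric = character(),
    logical = "direct_flag"
  ),
  mti = list(
    required = c("mirna_id", "gene_id", "evidence_class", "pmid"),
    numeric = character()
  ),
  tf = list(
    required = c("tf_gene_id", "target_gene_id", "source_db"),
    numeric = character()
  ),
  compound = list(
    required = c("compound_id", "source_db", "inchikey", "name"),
    numeric = character()
  ),
  activity = list(
    required = c("compound_id", "protein_id", "confidence_score",
                 "assay_type", "target_type", "standard_type",
                 "standard_value_nM"),
    numeric = c("confidence_score", "standard_value_nM")
  ),
  expression = list(
    required = c("gene_id", "tissue", "platform", "barcode_score"),
    numeric = "barcode_score"
  ),
  hits = list(
    required = c("query_id", "subject_id", "evalue"),
    numeric = "evalue"
  )
)

.tn_coerce_logical <- function(x) {
  lx <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[lx %in% c("true", "t", "1", "yes")] <- TRUE
  out[lx %in% c("false", "f", "0", "no")] <- FALSE
  out
}

# Range/invariant checks per schema; returns a reason string or NA per row.
.tn_row_check <- function(schema, df) {
  reason <- rep(NA_character_, nrow(df))
  if (schema == "expression") {
    bad <- is.na(df$barcode_score) | df$barcode_score < 0 |
      df$barcode_score > 1
    reason[bad] <- "barcode_score outside [0,1]"
  } else if (schema == "activity") {
    bad <- !is.na(df$standard_value_nM) & df$standard_value_nM < 0
    reason[bad] <- "negative standard_value_nM"
  } else if (schema == "hits") {
    bad <- is.na(df$evalue) | df$evalue < 0
    reason[bad] <- "negative or missing evalue"
  }
  reason
}

#' Read a typed delimited table
#'
#' Reads one of the toolkit's input tables. The header row must contain the
#' schema's required column names (extra columns are kept). Rows failing
#' type coercion or a schema invariant (for example a Barcode score outside
#' `[0, 1]`) are rejected; the rejected rows and their file row numbers are
#' attached as attribute `"rejected"` and reported via a message.
#'
#' @param path Path to the table.
#' @param schema One of `"annotation"`, `"ppi"`, `"mti"`, `"tf"`,
#'   `"compound"`, `"activity"`, `"expression"`, `"hits"`.
#' @param sep Field separator, tab by default; pass `","` for CSV.
#' @return A `data.frame` of typed records with attribute `"rejected"`
#'   (a data.frame with columns `row` and `reason`, possibly empty).
#' @export
read_table <- function(path, schema, sep = "\t") {
  schema <- match.arg(schema, names(.tn_schemas))
  stopifnot(file.exists(path))
  sc <- .tn_schemas[[schema]]
  df <- read.delim(path, sep = sep, header = TRUE, comment.char = "#",
                   colClasses = "character", check.names = FALSE,
                   stringsAsFactors = FALSE, quote = "")
  missing <- setdiff(sc$required, names(df))
  if (length(missing) > 0) {
    stop("table '", basename(path), "' (schema ", schema,
         ") is missing required column(s): ", paste(missing, collapse = ", "))
  }
  reason <- rep(NA_character_, nrow(df))
  for (col in sc$numeric) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    reason[is.na(v) & is.na(reason)] <- paste0("non-numeric ", col)
    df[[col]] <- v
  }
  for (col in sc$logical %||% character()) {
    v <- .tn_coerce_logical(df[[col]])
    reason[is.na(v) & is.na(reason)] <- paste0("non-logical ", col)
    df[[col]] <- v
  }
  chk <- .tn_row_check(schema, df)
  reason[is.na(reason) & !is.na(chk)] <- chk[is.na(reason) & !is.na(chk)]
  bad <- !is.na(reason)
  rejected <- data.frame(row = which(bad) + 1L,  # +1 for the header line
                         reason = reason[bad],
                         stringsAsFactors = FALSE)
  if (nrow(rejected) > 0) {
    message(nrow(rejected), " row(s) rejected reading ", basename(path),
            " (rows ", paste(rejected$row, collapse = ","), ")")
  }
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  attr(out, "schema") <- schema
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a table as tab-delimited text
#'
#' Writes a data.frame with a header row, tab separators, no quoting and no
#' row names — the inverse of [read_table()] up to column order and float
#' formatting. Optional provenance lines are written first, each prefixed
#' with `#`.
#'
#' @param df A data.frame.
#' @param path Output path.
#' @param header_lines Optional character vector of comment lines (written
#'   with a leading `"# "`).
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, header_lines = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(header_lines) > 0) {
    writeLines(paste0("# ", header_lines), con)
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Filter a gene list to reliably expressed genes
#'
#' Keeps the genes that have at least one expression record in the given
#' tissue with a Barcode score at or above `threshold` (0.5 by default, the
#' conventional "reliably expressed" cutoff: the gene is called expressed
#' in at least half of the tissue's samples). A gene with records on
#' several platforms passes if any platform's record passes; disagreements
#' between platforms are reported. Genes with no record at all in the
#' tissue are reported separately from genes whose records all fall below
#' the threshold.
#'
#' @param genes A [gene_list()].
#' @param expr Expression records (schema `"expression"` of [read_table()]).
#' @param tissue Tissue/cell-type name to filter on.
#' @param threshold Barcode score cutoff in `[0, 1]`; comparison is
#'   inclusive (`>=`).
#' @return A [gene_list()] of the retained genes, with attributes
#'   `"no_data"` (genes lacking any record in the tissue),
#'   `"below_threshold"` (genes whose records all fail) and
#'   `"platform_disagreement"` (genes where platforms disagree).
#' @export
filter_reliably_expressed <- function(genes, expr, tissue, threshold = 0.5) {
  stopifnot(inherits(genes, "gene_list"),
            threshold >= 0, threshold <= 1)
  tissues <- unique(expr$tissue)
  if (!tissue %in% tissues) {
    stop("tissue '", tissue, "' not present in expression table; available: ",
         paste(sort(tissues), collapse = ", "))
  }
  e <- expr[expr$tissue == tissue, , drop = FALSE]
  has_data <- genes$members %in% e$gene_id
  pass_ids <- unique(e$gene_id[e$barcode_score >= threshold])
  fail_ids <- unique(e$gene_id[e$barcode_score < threshold])
  kept <- genes$members[has_data & genes$members %in% pass_ids]
  below <- genes$members[has_data & !genes$members %in% pass_ids]
  no_data <- genes$members[!has_data]
  disagree <- intersect(kept, fail_ids)
  if (length(disagree) > 0) {
    message("platform disagreement (kept by the ANY-record rule) for: ",
            paste(disagree, collapse = ", "))
  }
  if (length(kept) == 0L) {
    out <- structure(list(name = paste0(genes$name, ".", tissue),
                          members = character(0), taxon = genes$taxon,
                          n_duplicates_dropped = 0L),
                     class = "gene_list")
  } else {
    out <- gene_list(kept, name = paste0(genes$name, ".", tissue),
                     taxon = genes$taxon)
  }
  attr(out, "no_data") <- no_data
  attr(out, "below_threshold") <- below
  attr(out, "platform_disagreement") <- disagree
  out
}
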