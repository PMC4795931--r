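# Fisher's exact theme enrichment with multiple-testing correction and
# optional gene-list extension by PPI partners.

#' Construct an annotation set
#'
#' Maps biological themes (pathways, GO / GO-slim terms, integrated
#' pathway clusters, or custom vocabularies) to gene sets. The union of
#' all annotated genes is the default enrichment background ("annotation
#' universe").
#'
#' @param df Data.frame with columns `theme_id`, `theme_name`, `gene_id`
#'   and optionally `category` (one of `pathway`, `go`, `go_slim`, `ipc`,
#'   `custom`; defaults to `custom`).
#' @return An object of class `annotation_set` (a normalized data.frame
#'   with one row per theme-gene association).
#' @export
annotation_set <- function(df) {
  stopifnot(all(c("theme_id", "theme_name", "gene_id") %in% names(df)))
  if (!"category" %in% names(df)) df$category <- "custom"
  df <- df[!duplicated(df[c("theme_id", "gene_id")]), , drop = FALSE]
  if (nrow(df) == 0L) stop("annotation set is empty")
  # theme_name must be constant within a theme_id
  nm <- tapply(df$theme_name, df$theme_id, function(x) length(unique(x)))
  if (any(nm > 1)) {
    stop("conflicting theme_name for theme_id(s): ",
         paste(names(nm)[nm > 1], collapse = ", "))
  }
  rownames(df) <- NULL
  class(df) <- c("annotation_set", "data.frame")
  df
}

#' Annotation universe
#'
#' @param ann An [annotation_set()].
#' @return Character vector of all genes carrying at least one theme.
#' @export
annotation_universe <- function(ann) unique(ann$gene_id)

#' One-sided Fisher's exact test for over-representation
#'
#' The probability, under the hypergeometric null, of drawing at least `k`
#' theme-annotated genes when sampling `n` genes from a background of `N`
#' genes of which `K` are annotated:
#' `p = sum_{j=k}^{min(n,K)} C(K,j) C(N-K,n-j) / C(N,n)`.
#' Evaluated via the stably computed hypergeometric upper tail. All
#' arguments are vectorized.
#'
#' @param k Foreground genes annotated to the theme.
#' @param n Foreground size.
#' @param K Background genes annotated to the theme.
#' @param N Background size.
#' @return P-value(s) in `[0, 1]`.
#' @export
#' @examples
#' fisher_one_sided(3, 5, 5, 20)  # 1126/15504
fisher_one_sided <- function(k, n, K, N) {
  if (any(k < 0 | K < 0 | n < 0 | N < 0 | k > n | k > K | n > N | K > N)) {
    stop("invalid contingency counts: need 0 <= k <= min(n, K), n <= N, K <= N")
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Adjust p-values for multiple testing
#'
#' Bonferroni (`min(1, m p)`), Holm step-down, or Benjamini-Hochberg
#' step-up adjusted p-values, in the input order.
#'
#' @param ps Numeric vector of raw p-values in `[0, 1]`.
#' @param method One of `"bh"` (default), `"bonferroni"`, `"holm"`.
#' @return Adjusted p-values, same length and order as `ps`.
#' @export
adjust_pvalues <- function(ps, method = c("bh", "bonferroni", "holm")) {
  method <- match.arg(method)
  if (length(ps) == 0L) return(numeric(0))
  stopifnot(all(ps >= 0 & ps <= 1))
  p.adjust(ps, method = c(bh = "BH", bonferroni = "bonferroni",
                          holm = "holm")[[method]])
}

#' Extend a gene list with its PPI partners
#'
#' Adds to the list every partner of a member gene among pairs of the
#' selected confidence class. Each output gene carries a provenance flag
#' (`seed` or `partner`).
#'
#' @param genes A [gene_list()].
#' @param ppi Classified pairs from [classify_ppi()].
#' @param mode `"none"` (identity), `"high_confidence"`, or
#'   `"direct_physical"`.
#' @return A [gene_list()] with attribute `"provenance"` (data.frame of
#'   `gene_id`, `provenance`).
#' @export
extend_with_partners <- function(genes, ppi,
                                 mode = c("none", "high_confidence",
                                          "direct_physical")) {
  mode <- match.arg(mode)
  stopifnot(inherits(genes, "gene_list"))
  if (mode == "none") {
    prov <- data.frame(gene_id = genes$members, provenance = "seed",
                       stringsAsFactors = FALSE)
    attr(genes, "provenance") <- prov
    return(genes)
  }
  sel <- if (mode == "high_confidence") ppi$high_confidence else
    ppi$direct_physical
  p <- ppi[sel, , drop = FALSE]
  touch_a <- p$gene_a %in% genes$members
  touch_b <- p$gene_b %in% genes$members
  partners <- sort(unique(c(p$gene_b[touch_a], p$gene_a[touch_b])))
  partners <- setdiff(partners, genes$members)
  out <- gene_list(c(genes$members, partners),
                   name = paste0(genes$name, "+partners"),
                   taxon = genes$taxon)
  attr(out, "provenance") <- data.frame(
    gene_id = out$members,
    provenance = c(rep("seed", length(genes$members)),
                   rep("partner", length(partners))),
    stringsAsFactors = FALSE)
  out
}

#' Theme enrichment of a gene list
#'
#' Tests each biological theme for over-representation in the foreground
#' list against the background with a one-sided Fisher's exact test, then
#' adjusts across the tested themes. Only themes with at least one
#' annotated foreground gene are tested; `m` for the correction is the
#' number of tested themes. Foreground genes absent from the background
#' (after intersecting with the annotation universe) are dropped and
#' reported, shrinking `n`.
#'
#' @param genes Foreground [gene_list()].
#' @param ann An [annotation_set()].
#' @param background Optional [gene_list()] or character vector; defaults
#'   to the annotation universe. An explicit background is intersected
#'   with the universe.
#' @param method Correction method, see [adjust_pvalues()]; default
#'   Benjamini-Hochberg.
#' @param alpha Significance level on the adjusted p-value (inclusive);
#'   default 0.05.
#' @param correct_m Whether the correction's `m` counts only the tested
#'   themes (`"tested"`, default) or every theme in the annotation set
#'   (`"all"`), which is more conservative.
#' @return A data.frame of class `enrichment_result`, one row per tested
#'   theme, sorted by adjusted p (ties by theme id): `theme_id`,
#'   `theme_name`, `k`, `n`, `K`, `N`, `p_raw`, `p_adj`, `method`,
#'   `significant`, `genes` (semicolon-joined annotated foreground genes).
#'   Attribute `"dropped_foreground"` lists foreground genes outside the
#'   background.
#' @export
run_enrichment <- function(genes, ann, background = NULL,
                           method = c("bh", "bonferroni", "holm"),
                           alpha = 0.05,
                           correct_m = c("tested", "all")) {
  method <- match.arg(method)
  correct_m <- match.arg(correct_m)
  stopifnot(inherits(genes, "gene_list"), inherits(ann, "annotation_set"))
  universe <- annotation_universe(ann)
  bg <- if (is.null(background)) universe else {
    b <- if (inherits(background, "gene_list")) background$members else
      as.character(background)
    intersect(b, universe)
  }
  fg <- intersect(genes$members, bg)
  dropped <- setdiff(genes$members, fg)
  if (length(fg) == 0L) {
    stop("no foreground genes remain after intersection with the background")
  }
  if (length(dropped) > 0) {
    message(length(dropped),
            " foreground gene(s) outside the background were dropped")
  }
  n <- length(fg); N <- length(bg)
  a <- ann[ann$gene_id %in% bg, , drop = FALSE]
  themes <- split(a$gene_id, a$theme_id)
  theme_names <- tapply(a$theme_name, a$theme_id, `[`, 1)
  k <- vapply(themes, function(gs) sum(fg %in% gs), integer(1))
  K <- lengths(themes)
  tested <- k >= 1L
  res <- data.frame(theme_id = names(themes)[tested],
                    theme_name = unname(theme_names[names(themes)[tested]]),
                    k = unname(k[tested]), n = n,
                    K = unname(K[tested]), N = N,
                    stringsAsFactors = FALSE)
  res$p_raw <- fisher_one_sided(res$k, res$n, res$K, res$N)
  m <- if (correct_m == "all") length(themes) else nrow(res)
  res$p_adj <- p.adjust(res$p_raw,
                        method = c(bh = "BH", bonferroni = "bonferroni",
                                   holm = "holm")[[method]],
                        n = m)
  res$method <- method
  res$significant <- res$p_adj <= alpha
  res$genes <- vapply(res$theme_id, function(t) {
    paste(fg[fg %in% themes[[t]]], collapse = ";")
  }, character(1))
  res <- res[order(res$p_adj, res$theme_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "dropped_foreground") <- dropped
  attr(res, "alpha") <- alpha
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> %d theme(s) tested, %d significant (%s, alpha = %g)\n",
              nrow(x), sum(x$significant), x$method[1] %||% "?",
              attr(x, "alpha") %||% NA))
  print.data.frame(head(as.data.frame(x)[c("theme_id", "theme_name", "k",
                                           "K", "p_raw", "p_adj",
                                           "significant")], 10))
  invisible(x)
}
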