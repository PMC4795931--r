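# Binary gene-by-theme association matrices, UPGMA clustering with
# deterministic tie-breaking, and heatmap-ready exports.

#' Build a binary gene-by-theme association matrix
#'
#' Cell (gene, theme) is 1 iff the association is present; rows and
#' columns are ordered by first appearance in the input. Duplicate pairs
#' collapse silently. A gene never associated with any theme does not
#' appear.
#'
#' @param assoc Data.frame with columns `gene_id` and `theme_id` (extra
#'   columns ignored).
#' @return Integer 0/1 matrix, genes as rows, themes as columns.
#' @export
build_binary_matrix <- function(assoc) {
  stopifnot(all(c("gene_id", "theme_id") %in% names(assoc)))
  genes <- unique(assoc$gene_id)
  themes <- unique(assoc$theme_id)
  m <- matrix(0L, nrow = length(genes), ncol = length(themes),
              dimnames = list(genes, themes))
  m[cbind(match(assoc$gene_id, genes), match(assoc$theme_id, themes))] <- 1L
  m
}

#' Read a user-supplied binary association matrix
#'
#' First row holds theme ids, first column gene ids. Nonzero entries are
#' coerced to 1 with a warning; all-zero rows are dropped and reported.
#'
#' @param path Path to the matrix TSV.
#' @param sep Field separator.
#' @return Integer 0/1 matrix with attribute `"dropped_rows"`.
#' @export
read_binary_matrix <- function(path, sep = "\t") {
  df <- read.delim(path, sep = sep, header = TRUE, row.names = 1,
                   check.names = FALSE, comment.char = "#")
  m <- as.matrix(df)
  storage.mode(m) <- "numeric"
  if (any(is.na(m))) stop("matrix contains non-numeric cells")
  if (any(!m %in% c(0, 1))) {
    warning("nonzero entries coerced to 1")
    m <- (m != 0) * 1
  }
  storage.mode(m) <- "integer"
  zero <- rowSums(m) == 0
  dropped <- rownames(m)[zero]
  if (length(dropped) > 0) {
    message(length(dropped), " all-zero row(s) dropped")
  }
  m <- m[!zero, , drop = FALSE]
  attr(m, "dropped_rows") <- dropped
  m
}

#' Euclidean distances between binary association profiles
#'
#' For 0/1 rows the Euclidean distance is the square root of the number
#' of themes on which two genes disagree (Hamming count).
#'
#' @param m Binary matrix from [build_binary_matrix()].
#' @return Symmetric numeric distance matrix over the rows.
#' @export
euclidean_distances <- function(m) {
  if (nrow(m) < 2L) stop("need at least 2 rows to compute distances")
  as.matrix(dist(m, method = "euclidean"))
}

#' UPGMA (unweighted average-linkage) hierarchical clustering
#'
#' Iteratively merges the pair of clusters with the smallest average
#' inter-cluster distance, where the average is the unweighted mean over
#' all original cross-cluster pairs (maintained by the size-weighted
#' Lance-Williams update). Ties are broken deterministically by the
#' smallest pair of original row indices; at each merge the cluster
#' containing the lower original index is kept on the left, so the leaf
#' order is reproducible across runs and platforms.
#'
#' @param d Symmetric distance matrix with zero diagonal (e.g. from
#'   [euclidean_distances()]).
#' @return An object of class `hclust` (merge, height, order, labels;
#'   method `"average"`), usable with [stats::cutree()], `plot()` or
#'   [ape::as.phylo()].
#' @export
upgma <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(n >= 2L, isTRUE(all.equal(unname(d), unname(t(d)))),
            all(diag(d) == 0))
  labels <- rownames(d) %||% as.character(seq_len(n))

  # active clusters: id (merge-tree index; -i for leaf i), size,
  # rep = smallest original row index (tie-break key), members' left-to-
  # right leaf order
  act <- seq_len(n)              # positions into bookkeeping vectors
  id <- -seq_len(n)
  size <- rep(1L, n)
  rep_ <- seq_len(n)
  ord <- lapply(seq_len(n), identity)
  D <- d
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    na <- length(act)
    # find min off-diagonal; tie-break by smallest (rep_i, rep_j) with i<j
    best <- NULL
    best_val <- Inf
    for (ii in seq_len(na - 1L)) {
      for (jj in (ii + 1L):na) {
        v <- D[ii, jj]
        lo <- min(rep_[ii], rep_[jj]); hi <- max(rep_[ii], rep_[jj])
        if (v < best_val - 1e-15 ||
            (abs(v - best_val) <= 1e-15 &&
             (is.null(best) || lo < best[3] ||
              (lo == best[3] && hi < best[4])))) {
          best_val <- v
          best <- c(ii, jj, lo, hi)
        }
      }
    }
    i <- best[1]; j <- best[2]
    merge[step, ] <- c(id[i], id[j])
    height[step] <- D[i, j]
    # lower original index goes left
    left_first <- rep_[i] <= rep_[j]
    new_ord <- if (left_first) c(ord[[i]], ord[[j]]) else
      c(ord[[j]], ord[[i]])
    # Lance-Williams UPGMA update against every other cluster
    new_row <- (size[i] * D[i, ] + size[j] * D[j, ]) / (size[i] + size[j])
    keep <- setdiff(seq_len(na), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], new_row[keep]),
               c(new_row[keep], 0))
    id <- c(id[keep], step)
    size <- c(size[keep], size[i] + size[j])
    rep_ <- c(rep_[keep], min(rep_[i], rep_[j]))
    ord <- c(ord[keep], list(new_ord))
    act <- seq_len(length(keep) + 1L)
  }
  structure(list(merge = merge, height = height, order = ord[[1]],
                 labels = labels, method = "average",
                 dist.method = "euclidean",
                 call = match.call()),
            class = "hclust")
}

#' Dendrogram in Newick format
#'
#' @param dg An `hclust` object (e.g. from [upgma()]).
#' @return Newick string (branch lengths from merge heights).
#' @export
dendrogram_newick <- function(dg) {
  ape::write.tree(ape::as.phylo(dg))
}

#' Export an ordered association matrix
#'
#' Writes the binary matrix as TSV with rows ordered by dendrogram leaf
#' order (`sort = "cluster"`), lexicographic gene name (`"name"`), or
#' input order (`"none"`). Optionally renders a heatmap image when the
#' pheatmap package is installed.
#'
#' @param m Binary matrix from [build_binary_matrix()].
#' @param dg `hclust` from [upgma()] (required for `sort = "cluster"`).
#' @param sort Row ordering mode.
#' @param path Output TSV path.
#' @param image Optional PNG path for a heatmap rendering.
#' @return The row-ordered matrix, invisibly.
#' @export
export_matrix <- function(m, dg = NULL,
                          sort = c("cluster", "name", "none"),
                          path, image = NULL) {
  sort <- match.arg(sort)
  ord <- switch(sort,
                cluster = {
                  if (is.null(dg)) stop("sort = 'cluster' needs a dendrogram")
                  dg$order
                },
                name = order(rownames(m)),
                none = seq_len(nrow(m)))
  mo <- m[ord, , drop = FALSE]
  df <- data.frame(gene_id = rownames(mo), mo, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_table(df, path, header_lines = paste0("sort=", sort,
                                              " linkage=UPGMA"))
  if (!is.null(image)) {
    if (requireNamespace("pheatmap", quietly = TRUE)) {
      grDevices::png(image, width = 800, height = 600)
      pheatmap::pheatmap(mo, cluster_rows = FALSE, cluster_cols = FALSE,
                         legend = FALSE)
      grDevices::dev.off()
    } else {
      message("pheatmap not installed; image skipped")
    }
  }
  invisible(mo)
}
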