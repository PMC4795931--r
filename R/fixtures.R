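# Deterministic synthetic input bundles with planted structure, so every
# stage of the toolkit can be exercised and scored without downloads.

#' Specify a synthetic fixture bundle
#'
#' Parameters of the generator. Boundary records (activity confidence
#' score exactly 4, value exactly 10 000 nM, Barcode score exactly 0.5,
#' e-value exactly 1e-3) are always planted so that inclusive/exclusive
#' threshold semantics are pinned by construction.
#'
#' @param seed Integer seed driving the single pseudo-random stream.
#' @param n_genes Genes per organism.
#' @param n_themes Biological themes in the annotation set.
#' @param n_foreground Size of the planted foreground list.
#' @param n_mirnas miRNAs in the miRNA-target table.
#' @param n_compounds Valid compound records.
#' @param planted_theme List with `theme_id` and `intensity` in `(0, 1]`:
#'   the fraction of the foreground drawn from the planted theme's genes.
#' @param planted_orthologues Number of planted mutual-best-hit pairs.
#' @param ppi_density Fraction of possible gene pairs given PPI evidence.
#' @param fraction_direct Fraction of high-confidence pairs that also get
#'   direct-physical support.
#' @param preset `"small"` (defaults) or `"medium"` (larger tables).
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1, n_genes = 200, n_themes = 20,
                         n_foreground = 30, n_mirnas = 10,
                         n_compounds = 30,
                         planted_theme = list(theme_id = "TH01",
                                              intensity = 0.6),
                         planted_orthologues = 10,
                         ppi_density = 0.02, fraction_direct = 0.5,
                         preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("small", "medium"))
    if (preset == "medium") {
      n_genes <- 600; n_themes <- 40; n_foreground <- 50
      n_mirnas <- 20; n_compounds <- 80; planted_orthologues <- 25
      ppi_density <- 0.005
    }
  }
  stopifnot(n_genes > 0, n_themes > 0, n_foreground > 0,
            planted_theme$intensity > 0, planted_theme$intensity <= 1,
            ppi_density >= 0, ppi_density <= 1,
            fraction_direct >= 0, fraction_direct <= 1)
  structure(list(seed = as.integer(seed), n_genes = n_genes,
                 n_themes = n_themes, n_foreground = n_foreground,
                 n_mirnas = n_mirnas, n_compounds = n_compounds,
                 planted_theme = planted_theme,
                 planted_orthologues = planted_orthologues,
                 ppi_density = ppi_density,
                 fraction_direct = fraction_direct),
            class = "fixture_spec")
}

.tn_rand_letters <- function(n, k) {
  vapply(seq_len(n), function(i) {
    paste(sample(LETTERS, k, replace = TRUE), collapse = "")
  }, character(1))
}

.tn_with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic input bundle
#'
#' Writes every input table the toolkit consumes, with planted, known
#' structure: a foreground list over-sampling one theme at a stated
#' intensity; PPI evidence with known high-confidence and direct-physical
#' counts (plus a planted self-loop and a reversed duplicate to exercise
#' canonicalization); reciprocal alignment hits whose mutual best hits are
#' exactly the planted orthologue pairs (plus a tie decoy and an
#' over-threshold pair); compound records spanning a known number of
#' InChIKey skeletons (plus invalid keys); activity records straddling
#' every binding-filter boundary; and Barcode expression scores straddling
#' 0.5. The ground truth is recorded in `manifest.json`.
#'
#' @param spec A [fixture_spec()].
#' @param outdir Output directory (created if needed).
#' @return The manifest, invisibly (also written as JSON).
#' @export
generate_bundle <- function(spec, outdir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  .tn_with_seed(spec$seed, {
    genes <- sprintf("G%04d", seq_len(spec$n_genes))
    mgenes <- sprintf("M%04d", seq_len(spec$n_genes))

    ## annotation set with one planted theme -----------------------------
    theme_ids <- sprintf("TH%02d", seq_len(spec$n_themes))
    planted_id <- spec$planted_theme$theme_id
    if (!planted_id %in% theme_ids) theme_ids[1] <- planted_id
    ann_rows <- lapply(seq_along(theme_ids), function(i) {
      size <- if (theme_ids[i] == planted_id) 20L else sample(8:25, 1)
      data.frame(theme_id = theme_ids[i],
                 theme_name = paste("theme", theme_ids[i]),
                 category = sample(c("pathway", "go_slim", "ipc"), 1),
                 gene_id = sample(genes, size),
                 stringsAsFactors = FALSE)
    })
    ann <- do.call(rbind, ann_rows)
    planted_genes <- ann$gene_id[ann$theme_id == planted_id]

    ## foreground list over-sampling the planted theme --------------------
    n_sig <- min(length(planted_genes),
                 round(spec$planted_theme$intensity * spec$n_foreground))
    fg <- c(sample(planted_genes, n_sig),
            sample(setdiff(genes, planted_genes),
                   spec$n_foreground - n_sig))
    fg <- sample(fg)  # shuffle order

    ## PPI evidence with known confidence profiles ------------------------
    npairs <- max(40L, round(spec$ppi_density * choose(spec$n_genes, 2)))
    npairs <- min(npairs, 400L)
    pool <- genes[seq_len(min(spec$n_genes, 120L))]
    all_pairs <- t(combn(pool, 2))
    sel <- all_pairs[sample(nrow(all_pairs), npairs), , drop = FALSE]
    profiles <- sample(c("single", "two_methods", "two_pubs"), npairs,
                       replace = TRUE, prob = c(0.3, 0.35, 0.35))
    hc <- profiles != "single"
    direct <- hc & (runif(npairs) < spec$fraction_direct)
    plain_methods <- c("MI:0006", "MI:0007", "MI:0096", "MI:0676")
    direct_method <- "MI:0018"  # whitelisted (two hybrid)
    ppi_rows <- list()
    for (i in seq_len(npairs)) {
      a <- sel[i, 1]; b <- sel[i, 2]
      pm <- sample.int(8000000L, 2) + 1000000L
      ms <- sample(plain_methods, 2)
      rows <- switch(profiles[i],
        single = data.frame(gene_a = a, gene_b = b, method_id = ms[1],
                            pmid = pm[1], source_db = "dbA",
                            direct_flag = FALSE),
        two_methods = data.frame(gene_a = a, gene_b = b,
                                 method_id = ms, pmid = pm[1],
                                 source_db = c("dbA", "dbB"),
                                 direct_flag = FALSE),
        two_pubs = data.frame(gene_a = a, gene_b = b, method_id = ms[1],
                              pmid = pm, source_db = "dbA",
                              direct_flag = FALSE))
      if (direct[i]) {
        if (runif(1) < 0.5) {
          rows$direct_flag[1] <- TRUE            # condition (i)
        } else {
          rows$method_id[1] <- direct_method     # condition (ii)
        }
      }
      ppi_rows[[i]] <- rows
    }
    ppi <- do.call(rbind, ppi_rows)
    # planted canonicalization probes: one self-loop, one reversed duplicate
    ppi <- rbind(ppi,
                 data.frame(gene_a = pool[1], gene_b = pool[1],
                            method_id = "MI:0006", pmid = 999,
                            source_db = "dbA", direct_flag = FALSE),
                 data.frame(gene_a = ppi$gene_b[1], gene_b = ppi$gene_a[1],
                            method_id = ppi$method_id[1],
                            pmid = ppi$pmid[1], source_db = ppi$source_db[1],
                            direct_flag = ppi$direct_flag[1]))
    hc_keys <- paste(pmin(sel[hc, 1], sel[hc, 2]),
                     pmax(sel[hc, 1], sel[hc, 2]), sep = "|")
    direct_keys <- paste(pmin(sel[direct, 1], sel[direct, 2]),
                         pmax(sel[direct, 1], sel[direct, 2]), sep = "|")

    ## miRNA-target and TF-target tables ----------------------------------
    mirnas <- sprintf("mir-%03d", seq_len(spec$n_mirnas))
    mti <- do.call(rbind, lapply(mirnas, function(m) {
      tg <- c(sample(fg, min(2, length(fg))),
              sample(genes, sample(1:3, 1)))
      data.frame(mirna_id = m, gene_id = unique(tg),
                 evidence_class = sample(c("Functional MTI",
                                           "Functional MTI (Weak)"),
                                         length(unique(tg)), TRUE),
                 pmid = sample.int(8000000L, length(unique(tg))) + 1000000L,
                 stringsAsFactors = FALSE)
    }))
    tfs <- sample(genes, 5)
    tf <- do.call(rbind, lapply(tfs, function(t_) {
      tg <- setdiff(unique(c(sample(fg, 2), sample(genes, 2))), t_)
      data.frame(tf_gene_id = t_, target_gene_id = tg,
                 source_db = "tfdb", stringsAsFactors = FALSE)
    }))

    ## compounds: known number of skeletons + invalid keys ----------------
    n_skel <- max(1L, ceiling(spec$n_compounds * 0.7))
    skeletons <- unique(.tn_rand_letters(n_skel * 2L, 14L))[seq_len(n_skel)]
    assign_skel <- c(skeletons,
                     sample(skeletons, spec$n_compounds - n_skel,
                            replace = TRUE))
    compound <- data.frame(
      compound_id = sprintf("CPD%04d", seq_len(spec$n_compounds)),
      source_db = sample(c("ChEMBL", "PubChem", "DrugBank"),
                         spec$n_compounds, TRUE),
      inchikey = paste0(assign_skel, "-",
                        .tn_rand_letters(spec$n_compounds, 8L), "SA-N"),
      name = paste0("compound ", seq_len(spec$n_compounds)),
      stringsAsFactors = FALSE)
    compound <- rbind(compound,
                      data.frame(compound_id = c("BAD1", "BAD2"),
                                 source_db = "ChEMBL",
                                 inchikey = c("AAAA-BB-N",
                                              "aaaaaaaaaaaaaa-BBBBBBBBSA-N"),
                                 name = c("bad key 1", "bad key 2"),
                                 stringsAsFactors = FALSE))

    ## activities: boundary rows + records with predetermined fate --------
    prot <- fg[seq_len(min(10, length(fg)))]
    boundary <- data.frame(
      compound_id = compound$compound_id[1:7],
      protein_id = prot[1],
      confidence_score = c(4, 3, 5, 5, 5, 5, 4),
      assay_type = c("B", "B", "F", "B", "B", "B", "B"),
      target_type = c("SINGLE PROTEIN", "SINGLE PROTEIN", "SINGLE PROTEIN",
                      "PROTEIN COMPLEX", "SINGLE PROTEIN", "SINGLE PROTEIN",
                      "SINGLE PROTEIN"),
      standard_type = c("IC50", "Kd", "Ki", "Ki", "other", "Ki", "Ki"),
      standard_value_nM = c(10000, 10, 10, 10, 10, 10001, 10000),
      stringsAsFactors = FALSE)
    boundary_pass <- c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)
    n_rand <- 40L
    fate <- runif(n_rand) < 0.5
    rand_rows <- lapply(seq_len(n_rand), function(i) {
      r <- data.frame(compound_id = sample(compound$compound_id[
                        seq_len(spec$n_compounds)], 1),
                      protein_id = sample(prot, 1),
                      confidence_score = sample(4:9, 1),
                      assay_type = "B",
                      target_type = "SINGLE PROTEIN",
                      standard_type = sample(c("IC50", "Kd", "Ki"), 1),
                      standard_value_nM = round(10^runif(1, 0, 4), 2),
                      stringsAsFactors = FALSE)
      if (!fate[i]) {  # break exactly one condition
        how <- sample(4, 1)
        if (how == 1) r$confidence_score <- sample(0:3, 1)
        if (how == 2) r$assay_type <- sample(c("F", "A"), 1)
        if (how == 3) r$target_type <- "PROTEIN COMPLEX"
        if (how == 4) r$standard_value_nM <- round(10^runif(1, 4.1, 7), 2)
      }
      r
    })
    activity <- rbind(boundary, do.call(rbind, rand_rows))
    n_survivors <- sum(boundary_pass) + sum(fate)
    drug_pairs <- data.frame(
      compound_id = sample(compound$compound_id[seq_len(spec$n_compounds)],
                           5),
      protein_id = sample(prot, 5, replace = TRUE),
      source_db = "DrugBank", stringsAsFactors = FALSE)

    ## expression: scores straddling 0.5 ----------------------------------
    expr <- data.frame(
      gene_id = fg,
      tissue = "liver", platform = "GPL570",
      barcode_score = round(runif(length(fg)), 3),
      stringsAsFactors = FALSE)
    expr$barcode_score[1:3] <- c(0.5, 0.49, 0.51)  # pin the boundary
    expr <- rbind(expr,
                  data.frame(gene_id = fg[2], tissue = "liver",
                             platform = "GPL96", barcode_score = 0.8,
                             stringsAsFactors = FALSE),
                  data.frame(gene_id = fg[1:5], tissue = "kidney",
                             platform = "GPL570",
                             barcode_score = round(runif(5), 3),
                             stringsAsFactors = FALSE))
    reliably <- unique(expr$gene_id[expr$tissue == "liver" &
                                      expr$barcode_score >= 0.5])

    ## reciprocal hits with planted mutual best hits ----------------------
    p <- spec$planted_orthologues
    hq <- sample(genes, p)
    ms <- sample(mgenes, p)
    best_e <- 10^runif(p, -20, -6)
    best_e[p] <- 1e-3  # inclusive-boundary pair
    hit_rows <- list(
      data.frame(query_id = hq, subject_id = ms, evalue = best_e,
                 query_taxon = "human", subject_taxon = "mouse",
                 stringsAsFactors = FALSE),
      data.frame(query_id = ms, subject_id = hq, evalue = pmin(best_e * 2, 1e-3),
                 query_taxon = "mouse", subject_taxon = "human",
                 stringsAsFactors = FALSE))
    # decoys: worse hits from other human genes onto planted mouse genes
    dq <- sample(setdiff(genes, hq), p)
    hit_rows$decoy <- data.frame(query_id = dq, subject_id = ms,
                                 evalue = pmin(best_e * 50, 2e-3),
                                 query_taxon = "human",
                                 subject_taxon = "mouse",
                                 stringsAsFactors = FALSE)
    # tie decoy: a gene whose two best hits have equal e-values
    tie_q <- setdiff(genes, c(hq, dq))[1]
    tie_s <- setdiff(mgenes, ms)[1:2]
    hit_rows$tie <- data.frame(
      query_id = c(tie_q, tie_q, tie_s),
      subject_id = c(tie_s, tie_q, tie_q),
      evalue = c(1e-8, 1e-8, 1e-7, 1e-7),
      query_taxon = c("human", "human", "mouse", "mouse"),
      subject_taxon = c("mouse", "mouse", "human", "human"),
      stringsAsFactors = FALSE)
    # over-threshold reciprocal pair: mutually best but e-value 2e-3
    ot_q <- setdiff(genes, c(hq, dq, tie_q))[1]
    ot_s <- setdiff(mgenes, c(ms, tie_s))[1]
    hit_rows$over <- data.frame(
      query_id = c(ot_q, ot_s), subject_id = c(ot_s, ot_q),
      evalue = 2e-3, query_taxon = c("human", "mouse"),
      subject_taxon = c("mouse", "human"), stringsAsFactors = FALSE)
    hits <- do.call(rbind, hit_rows)

    ## write the bundle ----------------------------------------------------
    paths <- list(
      genes = file.path(outdir, "genes.txt"),
      annotation = file.path(outdir, "annotation.tsv"),
      ppi = file.path(outdir, "ppi.tsv"),
      mti = file.path(outdir, "mti.tsv"),
      tf = file.path(outdir, "tf.tsv"),
      compound = file.path(outdir, "compound.tsv"),
      activity = file.path(outdir, "activity.tsv"),
      drug_pairs = file.path(outdir, "drug_pairs.tsv"),
      expression = file.path(outdir, "expression.tsv"),
      hits = file.path(outdir, "hits.tsv"),
      manifest = file.path(outdir, "manifest.json"))
    writeLines(c("# synthetic foreground gene list", fg), paths$genes)
    write_table(ann, paths$annotation)
    write_table(ppi, paths$ppi)
    write_table(mti, paths$mti)
    write_table(tf, paths$tf)
    write_table(compound, paths$compound)
    write_table(activity, paths$activity)
    write_table(drug_pairs, paths$drug_pairs)
    write_table(expr, paths$expression)
    write_table(hits, paths$hits)

    manifest <- list(
      seed = spec$seed,
      parameters = unclass(spec),
      planted_theme_id = planted_id,
      planted_theme_genes = sort(planted_genes),
      foreground = fg,
      n_hc_pairs = length(hc_keys),
      hc_pairs = sort(hc_keys),
      n_direct_pairs = length(direct_keys),
      direct_pairs = sort(direct_keys),
      n_self_loops = 1L,
      n_skeletons = n_skel,
      n_valid_compounds = spec$n_compounds,
      n_invalid_compounds = 2L,
      n_activity_records = nrow(activity),
      n_activity_survivors = n_survivors,
      planted_orthologues = data.frame(id_a = sort(hq),
                                       id_b = ms[order(hq)],
                                       stringsAsFactors = FALSE),
      reliably_expressed = sort(reliably),
      files = lapply(paths, basename))
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(manifest)
  })
}

#' Generate a random simple graph (Erdos-Renyi)
#'
#' Each of the `choose(n, 2)` possible edges is included independently
#' with probability `p`. Deterministic under `seed`.
#'
#' @param n Number of nodes (labelled `n01`, `n02`, ...).
#' @param p Edge probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return A [simple_graph()].
#' @export
generate_random_graph <- function(n, p, seed = 1) {
  stopifnot(n >= 1, p >= 0, p <= 1)
  .tn_with_seed(seed, {
    nodes <- sprintf("n%02d", seq_len(n))
    if (n == 1L || p == 0) return(simple_graph(nodes = nodes))
    pairs <- t(combn(nodes, 2))
    keep <- runif(nrow(pairs)) < p
    simple_graph(as.data.frame(pairs[keep, , drop = FALSE]),
                 nodes = nodes)
  })
}
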