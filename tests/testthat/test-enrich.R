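test_that("one-sided Fisher p matches the hypergeometric tail", {
  expect_equal(fisher_one_sided(3, 5, 5, 20), 1126 / 15504,
               tolerance = 1e-12)
  expect_equal(fisher_one_sided(0, 5, 5, 20), 1)
  expect_equal(fisher_one_sided(5, 5, 20, 20), 1)  # K = N forces k = n
  expect_error(fisher_one_sided(6, 5, 5, 20), "invalid contingency")
  # spot-check against stats::fisher.test's one-sided alternative
  ft <- stats::fisher.test(matrix(c(3, 2, 2, 13), 2),
                           alternative = "greater")$p.value
  expect_equal(fisher_one_sided(3, 5, 5, 20), ft, tolerance = 1e-12)
})

test_that("p-value adjustment reproduces textbook step formulas", {
  expect_equal(adjust_pvalues(c(0.01, 0.6), "bonferroni"), c(0.02, 1.0))
  expect_equal(adjust_pvalues(c(0.01, 0.04, 0.03), "holm"),
               c(0.03, 0.06, 0.06))
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "bh"),
               rep(0.04, 4))
  expect_equal(adjust_pvalues(numeric(0), "bh"), numeric(0))
  set.seed(21)
  for (i in 1:50) {
    p <- runif(sample(1:30, 1))
    for (m in c("bonferroni", "holm", "bh")) {
      got <- adjust_pvalues(p, m)
      expect_equal(got, oracle_adjust(p, m), tolerance = 1e-12)
      expect_true(all(got >= p - 1e-15 & got <= 1))
    }
    expect_true(all(adjust_pvalues(p, "bonferroni") >=
                      adjust_pvalues(p, "holm") - 1e-15))
  }
})

test_that("PPI-partner extension respects the confidence class", {
  ppi <- data.frame(gene_a = c("a", "a", "a"),
                    gene_b = c("b", "c", "d"),
                    n_methods = c(2L, 2L, 1L), n_pubs = c(1L, 1L, 1L),
                    high_confidence = c(TRUE, TRUE, FALSE),
                    direct_physical = c(TRUE, FALSE, FALSE),
                    stringsAsFactors = FALSE)
  seed <- gene_list("a")
  expect_equal(extend_with_partners(seed, ppi, "none")$members, "a")
  hc <- extend_with_partners(seed, ppi, "high_confidence")
  expect_setequal(hc$members, c("a", "b", "c"))
  prov <- attr(hc, "provenance")
  expect_equal(prov$provenance[prov$gene_id == "a"], "seed")
  expect_equal(prov$provenance[prov$gene_id == "b"], "partner")
  dp <- extend_with_partners(seed, ppi, "direct_physical")
  expect_setequal(dp$members, c("a", "b"))
})

test_that("enrichment ranks a planted theme first and flags it", {
  d <- withr::local_tempdir()
  man <- suppressMessages(generate_bundle(fixture_spec(seed = 3), d))
  ann <- annotation_set(suppressMessages(
    read_table(file.path(d, "annotation.tsv"), "annotation")))
  gl <- suppressMessages(read_gene_list(file.path(d, "genes.txt")))
  res <- suppressMessages(run_enrichment(gl, ann))
  expect_s3_class(res, "enrichment_result")
  expect_equal(res$theme_id[1], man$planted_theme_id)
  expect_true(res$significant[1])
  expect_true(all(res$p_adj >= res$p_raw - 1e-15))
  expect_true(all(res$k >= 1))
  # foreground = background gives p = 1 everywhere
  bg_list <- gene_list(annotation_universe(ann))
  res_all <- run_enrichment(bg_list, ann)
  expect_true(all(res_all$p_raw == 1))
  # alpha = 0 flags nothing
  res0 <- suppressMessages(run_enrichment(gl, ann, alpha = 0))
  expect_false(any(res0$significant))
})

test_that("foreground genes outside the background shrink n and are reported", {
  ann <- annotation_set(data.frame(
    theme_id = "T1", theme_name = "t", category = "custom",
    gene_id = c("g1", "g2", "g3", "g4"), stringsAsFactors = FALSE))
  gl <- gene_list(c("g1", "g2", "nope"))
  res <- suppressMessages(run_enrichment(gl, ann))
  expect_equal(res$n[1], 2L)
  expect_equal(attr(res, "dropped_foreground"), "nope")
  expect_error(run_enrichment(gene_list("zzz"), ann), "no foreground")
})
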