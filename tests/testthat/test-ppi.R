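mk_ev <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(gene_a = r[[1]], gene_b = r[[2]], method_id = r[[3]],
               pmid = r[[4]], source_db = r[[5]],
               direct_flag = as.logical(r[[6]]), stringsAsFactors = FALSE)
  }))
}

test_that("evidence aggregation canonicalizes pairs and deduplicates", {
  ev <- mk_ev(list("g2", "g1", "M1", "111", "dbA", FALSE),
              list("g1", "g2", "M1", "111", "dbA", FALSE),  # reversed dup
              list("g1", "g2", "M1", "111", "dbB", FALSE),  # new source
              list("g3", "g3", "M1", "222", "dbA", FALSE))  # self-loop
  agg <- suppressMessages(aggregate_evidence(ev, direct_methods = "MI:0018"))
  expect_equal(nrow(agg), 2L)                 # dedup kept the dbB copy
  expect_equal(unique(agg$gene_a), "g1")      # canonical order
  expect_equal(nrow(attr(agg, "self_loops")), 1L)
})

test_that("high-confidence needs two methods or two publications", {
  ev <- mk_ev(list("a", "b", "M1", "P1", "db", FALSE),
              list("a", "b", "M2", "P1", "db", FALSE),   # 2 methods
              list("c", "d", "M1", "P1", "db", FALSE),
              list("c", "d", "M1", "P2", "db", FALSE),   # 2 pubs
              list("e", "f", "M1", "P1", "db", FALSE))   # single support
  cls <- classify_high_confidence(aggregate_evidence(ev,
                                                     direct_methods = "X"))
  got <- setNames(cls$high_confidence, cls$gene_a)
  expect_true(got[["a"]]); expect_true(got[["c"]]); expect_false(got[["e"]])
  expect_equal(cls$n_methods[cls$gene_a == "a"], 2L)
  expect_equal(cls$n_pubs[cls$gene_a == "c"], 2L)
})

test_that("direct-physical requires high confidence plus direct evidence", {
  ev <- mk_ev(list("a", "b", "M1", "P1", "db", TRUE),    # hc + source flag
              list("a", "b", "M2", "P1", "db", FALSE),
              list("c", "d", "MI:0018", "P1", "db", FALSE),  # hc + method
              list("c", "d", "M2", "P1", "db", FALSE),
              list("e", "f", "M1", "P1", "db", TRUE),    # direct, NOT hc
              list("g", "h", "M1", "P1", "db", FALSE),   # hc, no direct
              list("g", "h", "M2", "P1", "db", FALSE))
  cls <- classify_ppi(ev, direct_methods = "MI:0018")
  got <- setNames(cls$direct_physical, cls$gene_a)
  expect_true(got[["a"]])   # condition (i): source annotation
  expect_true(got[["c"]])   # condition (ii): capable method
  expect_false(got[["e"]])  # subset rule: not high-confidence
  expect_false(got[["g"]])
  expect_true(all(cls$direct_physical <= cls$high_confidence))
})

test_that("classification is order-independent and monotone in evidence", {
  d <- withr::local_tempdir()
  man <- suppressMessages(generate_bundle(fixture_spec(seed = 5), d))
  ev <- suppressMessages(read_table(file.path(d, "ppi.tsv"), "ppi"))
  cls1 <- suppressMessages(classify_ppi(ev))
  cls2 <- suppressMessages(classify_ppi(ev[rev(seq_len(nrow(ev))), ]))
  expect_equal(cls1, cls2)
  # counts nest: direct subset of high-confidence subset of all pairs
  expect_lte(sum(cls1$direct_physical), sum(cls1$high_confidence))
  expect_lte(sum(cls1$high_confidence), nrow(cls1))
  # adding a publication to a single-support pair can only promote it
  single <- cls1[!cls1$high_confidence, ][1, ]
  extra <- data.frame(gene_a = single$gene_a, gene_b = single$gene_b,
                      method_id = "M_new", pmid = "99999999",
                      source_db = "dbC", direct_flag = FALSE)
  cls3 <- suppressMessages(classify_ppi(rbind(ev, extra)))
  expect_true(cls3$high_confidence[cls3$gene_a == single$gene_a &
                                     cls3$gene_b == single$gene_b])
  before <- cls1[cls1$high_confidence, c("gene_a", "gene_b")]
  after <- cls3[cls3$high_confidence, c("gene_a", "gene_b")]
  expect_true(all(paste(before$gene_a, before$gene_b) %in%
                    paste(after$gene_a, after$gene_b)))
})
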