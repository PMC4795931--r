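test_that("InChIKey validation accepts the pattern and names the defect", {
  pk <- parse_inchikey(c("AAAAAAAAAAAAAA-BBBBBBBBSA-N",
                         "AAAA-BB-N",
                         "aaaaaaaaaaaaaa-BBBBBBBBSA-N",
                         "AAAAAAAAAAAAAABBBBBBBBSA-N",
                         "AAAAAAAAAAAAA1-BBBBBBBBSA-N"))
  expect_identical(pk$valid, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_identical(pk$skeleton[1], "AAAAAAAAAAAAAA")
  expect_identical(pk$reason, c(NA, "block length", "case", "block count",
                                "invalid characters"))
})

test_that("compound grouping partitions valid records by skeleton", {
  rec <- data.frame(
    compound_id = c("c1", "c2", "c3", "c4"),
    source_db = "ChEMBL",
    inchikey = c("AAAAAAAAAAAAAA-BBBBBBBBSA-N",
                 "AAAAAAAAAAAAAA-CCCCCCCCSA-N",  # same skeleton as c1
                 "DDDDDDDDDDDDDD-BBBBBBBBSA-N",
                 "bad-key-x"),
    name = "", stringsAsFactors = FALSE)
  gr <- suppressMessages(group_compounds(rec))
  expect_equal(length(gr$skeletons), 2L)
  expect_equal(nrow(gr$records), 3L)
  expect_equal(nrow(gr$rejected), 1L)
  # partition: sizes sum to valid records, groups disjoint
  expect_equal(sum(table(gr$records$skeleton)), 3)
  expect_equal(sort(unique(gr$records$skeleton)), sort(gr$skeletons))
  expect_equal(nrow(group_compounds(rec[0, ])$records), 0L)
})

test_that("binding-activity filter applies all conditions with inclusive bounds", {
  acts <- data.frame(
    compound_id = "c", protein_id = "p",
    confidence_score = c(4, 3, 5, 5, 5, 5),
    assay_type = c("B", "B", "F", "B", "B", "B"),
    target_type = c("SINGLE PROTEIN", "SINGLE PROTEIN", "SINGLE PROTEIN",
                    "PROTEIN COMPLEX", "SINGLE PROTEIN", "SINGLE PROTEIN"),
    standard_type = c("IC50", "Kd", "Ki", "Ki", "Ki", "other"),
    standard_value_nM = c(5000, 10, 10, 10, 10000, 10),
    stringsAsFactors = FALSE)
  kept <- filter_binding_activities(acts)
  expect_equal(which(seq_len(nrow(acts)) %in% which(
    acts$confidence_score >= 4 & acts$assay_type == "B" &
      acts$target_type == "SINGLE PROTEIN" &
      acts$standard_type %in% c("IC50", "Kd", "Ki") &
      acts$standard_value_nM <= 10000)), c(1L, 5L))
  expect_equal(nrow(kept), 2L)
  expect_equal(kept$standard_value_nM, c(5000, 10000))
  rej <- attr(kept, "rejected_by_reason")
  expect_equal(sum(rej), 4)
  # order-independent and idempotent
  shuf <- acts[sample(nrow(acts)), ]
  kept2 <- filter_binding_activities(shuf)
  expect_setequal(paste(kept2$confidence_score, kept2$standard_value_nM),
                  paste(kept$confidence_score, kept$standard_value_nM))
  expect_equal(nrow(filter_binding_activities(kept)), nrow(kept))
})

test_that("PCI edges take the minimum activity across group members", {
  rec <- data.frame(
    compound_id = c("c1", "c2", "c3"),
    source_db = "ChEMBL",
    inchikey = c("AAAAAAAAAAAAAA-BBBBBBBBSA-N",
                 "AAAAAAAAAAAAAA-CCCCCCCCSA-N",
                 "DDDDDDDDDDDDDD-BBBBBBBBSA-N"),
    name = "", stringsAsFactors = FALSE)
  gr <- group_compounds(rec)
  acts <- data.frame(compound_id = c("c1", "c2"), protein_id = "P1",
                     confidence_score = 5, assay_type = "B",
                     target_type = "SINGLE PROTEIN", standard_type = "Ki",
                     standard_value_nM = c(200, 50),
                     stringsAsFactors = FALSE)
  extra <- data.frame(compound_id = c("c3", "ghost"), protein_id = "P2",
                      source_db = "DrugBank", stringsAsFactors = FALSE)
  edges <- suppressMessages(build_pci_edges(gr, acts, extra))
  expect_equal(nrow(edges), 2L)
  e1 <- edges[edges$protein_id == "P1", ]
  expect_equal(e1$best_activity_nM, 50)   # min over the two group members
  expect_false(e1$annotation_only)
  e2 <- edges[edges$protein_id == "P2", ]
  expect_true(is.na(e2$best_activity_nM))
  expect_true(e2$annotation_only)
  expect_equal(attr(edges, "orphans"), "ghost")
  # one edge per (skeleton, protein)
  expect_false(any(duplicated(edges[c("skeleton", "protein_id")])))
})

test_that("fixture compound tables yield exactly the planted skeleton count", {
  d <- withr::local_tempdir()
  man <- suppressMessages(generate_bundle(fixture_spec(seed = 42), d))
  comp <- suppressMessages(read_table(file.path(d, "compound.tsv"),
                                      "compound"))
  gr <- suppressMessages(group_compounds(comp))
  expect_equal(length(gr$skeletons), man$n_skeletons)
  expect_equal(nrow(gr$records), man$n_valid_compounds)
  expect_equal(nrow(gr$rejected), man$n_invalid_compounds)
})
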