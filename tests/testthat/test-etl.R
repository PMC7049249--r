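maf_text <- function(rows) {
  header <- paste("tumor_aliquot_id", "hugo_symbol", "ensembl_gene",
                  "chromosome", "start", "reference_allele",
                  "alternate_allele", "callers", sep = "\t")
  c(header, rows)
}

write_tmp <- function(lines, ext = ".tsv") {
  p <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, p)
  p
}

count_labels <- function(el) {
  table(vapply(el$vertices, `[[`, character(1), "label"))
}

count_edge_labels <- function(el) {
  table(vapply(el$edges, `[[`, character(1), "label"))
}

test_that("MAF loading deduplicates alleles and keeps per-edge annotations", {
  p <- write_tmp(maf_text(c(
    "a1\tTP53\tENSG1\t17\t7675000\tC\tT\tMUTECT|MUSE",
    "a2\tTP53\tENSG1\t17\t7675000\tC\tT\tMUTECT",
    "a1\tPIK3CA\tENSG2\t3\t179218000\tG\tA\tMUSE"
  )))
  el <- load_maf(p)
  labs <- count_labels(el)
  expect_equal(unname(labs[["Allele"]]), 2)         # shared variant dedup
  expect_equal(unname(labs[["SomaticCallset"]]), 2)
  expect_equal(unname(labs[["Aliquot"]]), 2)
  elabs <- count_edge_labels(el)
  expect_equal(unname(elabs[["alleles"]]), 3)
  expect_equal(unname(elabs[["somatic_callsets"]]), 2)

  # caller list parsing onto the edge payload
  allele_edges <- Filter(function(e) e$label == "alleles", el$edges)
  expect_equal(allele_edges[[1]]$data$methods, list("MUTECT", "MUSE"))
  expect_equal(allele_edges[[1]]$data$ensembl_gene, "ENSG1")

  # allele gid encodes the variant key, 1-based coordinates
  g <- elements_to_graph(el)
  expect_false(is.null(evigraph:::get_vertex(g, "Allele:17:7675000:C:T")))
  expect_equal(nrow(validate_against_schema(g)), 0)
})

test_that("MAF loading is order-independent for dedup and errors usefully", {
  rows <- c(
    "a1\tTP53\tENSG1\t17\t7675000\tC\tT\tMUTECT",
    "a2\tTP53\tENSG1\t17\t7675000\tC\tT\tMUSE",
    "a1\tKRAS\tENSG3\t12\t25245350\tC\tA\tVARSCAN"
  )
  el1 <- load_maf(write_tmp(maf_text(rows)))
  el2 <- load_maf(write_tmp(maf_text(rev(rows))))
  alleles <- function(el) sort(names(Filter(function(v) v$label == "Allele",
                                            el$vertices)))
  expect_equal(alleles(el1), alleles(el2))

  # idempotence: same file loads to identical element sets
  p <- write_tmp(maf_text(rows))
  expect_identical(load_maf(p), load_maf(p))

  # header-only file yields nothing
  expect_length(load_maf(write_tmp(maf_text(character(0))))$vertices, 0)

  expect_error(load_maf(write_tmp(c("a\tb", "1\t2"))), "required column")
  expect_error(load_maf(write_tmp(maf_text(
    "a1\tTP53\tENSG1\t17\t0\tC\tT\tMUTECT"
  ))), "line 2.*start")
  expect_error(load_maf(write_tmp(maf_text(
    "a1\tTP53\tENSG1\t17\t10\tC\tZ\tMUTECT"
  ))), "line 2.*allele")
})

test_that("GMT loading emits membership edges in both directions", {
  p <- write_tmp(c("PW1\tfirst pathway\tENSG1\tENSG2\tENSG3\tENSG4"),
                 ext = ".gmt")
  el <- load_pathways_gmt(p)
  labs <- count_labels(el)
  expect_equal(unname(labs[["Pathway"]]), 1)
  expect_equal(unname(labs[["Gene"]]), 4)
  elabs <- count_edge_labels(el)
  expect_equal(unname(elabs[["genes"]]), 4)
  expect_equal(unname(elabs[["pathways"]]), 4)
  expect_equal(nrow(validate_against_schema(elements_to_graph(el))), 0)

  # duplicate member in one set contributes a single edge pair
  el2 <- load_pathways_gmt(write_tmp("PW1\td\tENSG1\tENSG1", ext = ".gmt"))
  expect_equal(length(el2$edges), 2)

  expect_error(load_pathways_gmt(write_tmp(c("PW1\tdesc-only"), ext = ".gmt")),
               "line 1")
})

test_that("shared pathway membership is traversable from the gene side", {
  p <- write_tmp(c("PW1\td\tENSG1\tENSG2", "PW2\td\tENSG1"), ext = ".gmt")
  g <- elements_to_graph(load_pathways_gmt(p))
  r <- execute(g, list(
    list(op = "V", args = list("ENSG1")),
    list(op = "as", args = "gene"),
    list(op = "out", args = list("pathways")),
    list(op = "render", args = list("$gene._gid", "$._gid"))
  ))
  expect_equal(r$rows, list(list("ENSG1", "Pathway:PW1"),
                            list("ENSG1", "Pathway:PW2")))
})

test_that("expression matrices round-trip through the graph and engine", {
  p <- write_tmp(c("aliquot\tENSG1\tENSG2\tENSG3",
                   "a1\t1.5\t0.0\t7.25",
                   "a2\t3\t2.5\t0.75"))
  el <- load_expression_matrix(p)
  labs <- count_labels(el)
  expect_equal(unname(labs[["GeneExpression"]]), 2)
  ge <- Filter(function(v) v$label == "GeneExpression", el$vertices)
  expect_length(ge[[1]]$data$values, 3)
  expect_identical(ge[[1]]$data$values$ENSG2, 0)      # zero retained
  expect_equal(ge[[1]]$data$metric, "TPM")

  g <- elements_to_graph(el)
  expect_equal(nrow(validate_against_schema(g)), 0)
  r <- execute(g, list(
    list(op = "V"),
    list(op = "hasLabel", args = list("Aliquot")),
    list(op = "as", args = "sample"),
    list(op = "out", args = list("gene_expressions")),
    list(op = "as", args = "exp"),
    list(op = "render", args = list("$sample._gid", "$exp._data.values"))
  ))
  m <- expression_to_matrix(r)
  expect_equal(m$sample, c("Aliquot:a1", "Aliquot:a2"))
  expect_equal(m$ENSG1, c(1.5, 3))
  expect_equal(m$ENSG3, c(7.25, 0.75))

  expect_error(load_expression_matrix(write_tmp(
    c("aliquot\tENSG1", "a1\t-2"))), "negative")
  expect_error(load_expression_matrix(write_tmp(
    c("aliquot\tENSG1", "a1\t5")), graph = graph_new(),
    create_missing = FALSE), "unknown aliquot")
})

test_that("drug-response loading derives compound-project links", {
  p <- write_tmp(c("sample_id,compound_id,submitter_compound_id,ec50,auc",
                   "ACH-1,CID104741,fulvestrant,0.3075,0.51"), ext = ".csv")
  el <- load_drug_response(p, "Project:CTRP-X")
  labs <- count_labels(el)
  expect_equal(unname(labs[["DrugResponse"]]), 1)
  expect_equal(unname(labs[["Compound"]]), 1)
  elabs <- count_edge_labels(el)
  expect_equal(unname(elabs[["drug_response"]]), 1)
  expect_equal(unname(elabs[["compounds"]]), 1)
  expect_equal(unname(elabs[["projects"]]), 1)
  expect_equal(nrow(validate_against_schema(elements_to_graph(el))), 0)

  # dedup across rows of the same compound
  p2 <- write_tmp(c("sample_id,compound_id,submitter_compound_id,ec50",
                    "ACH-1,CID1,drugx,0.5",
                    "ACH-2,CID1,drugx,1.5"), ext = ".csv")
  el2 <- load_drug_response(p2, "Project:CTRP-X")
  labs2 <- count_labels(el2)
  expect_equal(unname(labs2[["Compound"]]), 1)
  expect_equal(unname(labs2[["DrugResponse"]]), 2)

  expect_error(load_drug_response(write_tmp(
    c("sample_id,compound_id,submitter_compound_id,ec50",
      "ACH-1,CID1,drugx,strong"), ext = ".csv"), "Project:P"),
    "line 2.*ec50")
})

test_that("the sensitivity traversal reproduces the drug-response table", {
  p <- write_tmp(c("sample_id,compound_id,submitter_compound_id,ec50",
                   "ACH-1,CID7,fulvestrant,0.3075",
                   "ACH-2,CID7,fulvestrant,0.0231",
                   "ACH-2,CID9,otherdrug,1.25"), ext = ".csv")
  g <- graph_new()
  add_vertex(g, "Program:CTRP", "Program")
  add_edge(g, "Program:CTRP", "projects", "Project:CTRP-X")
  for (s in c("ACH-1", "ACH-2")) {
    add_vertex(g, paste0("Case:", s), "Case")
    add_edge(g, "Project:CTRP-X", "cases", paste0("Case:", s))
    add_vertex(g, paste0("Sample:", s), "Sample")
    add_edge(g, paste0("Case:", s), "samples", paste0("Sample:", s))
    add_edge(g, paste0("Sample:", s), "aliquots", paste0("Aliquot:", s))
  }
  add_elements(g, load_drug_response(p, "Project:CTRP-X"))
  finalize(g)
  r <- q7_ec50_for_compound(g, "Program:CTRP", "Compound:CID7")
  expect_equal(r$rows$rows, list(
    list("Sample:ACH-1", "fulvestrant", 0.3075),
    list("Sample:ACH-2", "fulvestrant", 0.0231)
  ))
})

test_that("association records wire alleles to publications and compounds", {
  maf <- write_tmp(maf_text("a1\tCTNNB1\tENSG5\t3\t41224610\tA\tG\tMUTECT"))
  g <- elements_to_graph(load_maf(maf))
  rec <- list(association_id = "A1", allele_key = "3:41224610:A:G",
              compound_ids = list("CID1"),
              publication_urls = list("pubmed/1", "pubmed/2"),
              phenotype = "drug_sensitivity", description = "toy")
  p <- write_tmp(as.character(jsonlite::toJSON(rec, auto_unbox = TRUE)),
                 ext = ".jsonl")
  el <- load_g2p(p, g)
  elabs <- count_edge_labels(el)
  expect_equal(unname(elabs[["publications"]]), 2)
  expect_equal(unname(elabs[["g2p_associations"]]), 1)
  expect_equal(unname(elabs[["compounds"]]), 1)
  expect_equal(unname(elabs[["phenotypes"]]), 1)
  add_elements(g, el)
  finalize(g)
  expect_equal(nrow(validate_against_schema(g)), 0)

  # unmatched allele key: skip with warning, no new association edges
  rec2 <- rec
  rec2$allele_key <- "9:999:T:C"
  p2 <- write_tmp(as.character(jsonlite::toJSON(rec2, auto_unbox = TRUE)),
                  ext = ".jsonl")
  expect_warning(el2 <- load_g2p(p2, g), "matches no Allele")
  expect_length(el2$edges, 0)
  expect_equal(attr(el2, "skipped"), "9:999:T:C")
})

test_that("duplicate association routes collapse to one case-compound pair", {
  # one case, one allele, two associations (different publications) naming
  # the same compound: the distinct step credits the compound once
  g <- graph_new()
  add_vertex(g, "Project:P1", "Project")
  add_vertex(g, "Case:C1", "Case")
  add_edge(g, "Project:P1", "cases", "Case:C1")
  add_vertex(g, "Sample:S1", "Sample",
             list(gdc_attributes = list(sample_type = "Primary Tumor")))
  add_edge(g, "Case:C1", "samples", "Sample:S1")
  add_edge(g, "Sample:S1", "aliquots", "Aliquot:A1")
  maf_el <- load_maf(write_tmp(maf_text(
    "A1\tCTNNB1\tENSG5\t3\t41224610\tA\tG\tMUTECT")))
  add_elements(g, maf_el)
  recs <- lapply(1:2, function(i) {
    list(association_id = sprintf("A%d", i), allele_key = "3:41224610:A:G",
         compound_ids = list("CID1"),
         publication_urls = list(sprintf("pubmed/%d", i)),
         phenotype = "drug_sensitivity", description = "toy")
  })
  p <- write_tmp(vapply(recs, function(r) {
    as.character(jsonlite::toJSON(r, auto_unbox = TRUE))
  }, character(1)), ext = ".jsonl")
  add_elements(g, load_g2p(p, g))
  finalize(g)
  r5 <- q5_compound_case_counts(g, "Project:P1")
  tb <- as_tibble(r5)
  expect_equal(tb$key, "Compound:CID1")
  expect_equal(tb$count, 1L)

  # without distinct the same compound is credited twice
  doc <- Filter(function(s) s$op != "distinct", r5$query_doc)
  tb2 <- as_tibble(execute(g, parse_query(doc)))
  expect_equal(tb2$count, 2L)
})
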