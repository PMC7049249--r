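test_that("query documents parse to validated step lists", {
  q <- parse_query(list(list(op = "V", args = list()),
                        list(op = "hasLabel", args = list("Pathway"))))
  expect_s3_class(q, "gq_query")
  expect_length(q$steps, 2)

  expect_error(parse_query(list(list(op = "frobnicate"))), "unknown step")
  expect_error(parse_query(list(list(op = "hasLabel", args = list("A")))),
               "first step.*V")
  expect_error(parse_query(list(list(op = "V"), list(op = "V"))),
               "only as the first")
})

test_that("the mutation-count traversal parses as a 9-step plan ending in aggregate", {
  doc <- list(
    list(op = "V", args = list("Project:TCGA-BRCA")),
    list(op = "out", args = list("cases")),
    list(op = "out", args = list("samples")),
    list(op = "has", args = list(op = "eq",
                                 field = "gdc_attributes.sample_type",
                                 value = "Primary Tumor")),
    list(op = "out", args = list("aliquots")),
    list(op = "out", args = list("somatic_callsets")),
    list(op = "outE", args = list("alleles")),
    list(op = "has", args = list(op = "contains", field = "methods",
                                 value = "MUTECT")),
    list(op = "aggregate", args = list(name = "geneCount",
                                       field = "ensembl_gene"))
  )
  q <- parse_query(doc)
  expect_length(q$steps, 9)
  expect_equal(q$steps[[9]]$op, "aggregate")
  expect_equal(q$steps[[9]]$aggs[[1]]$name, "geneCount")
  expect_s3_class(compile_query(q), "gq_query")
})

test_that("compilation catches undefined marks, steps after terminals, bad limits", {
  ok <- parse_query(list(list(op = "V"), list(op = "as", args = "x"),
                         list(op = "out", args = list("cases")),
                         list(op = "select", args = "x")))
  expect_true(compile_query(ok)$compiled)

  expect_error(compile_query(parse_query(list(
    list(op = "V"), list(op = "select", args = "x")
  ))), "undefined mark 'x'")

  expect_error(compile_query(parse_query(list(
    list(op = "V"), list(op = "count"), list(op = "out", args = list("c"))
  ))), "after terminal")

  expect_error(compile_query(parse_query(list(
    list(op = "V"), list(op = "limit", args = -1)
  ))), "non-negative")

  expect_error(compile_query(parse_query(list(
    list(op = "V"),
    list(op = "render", args = list("$ghost._gid"))
  ))), "undefined mark")
})

test_that("query documents round-trip through serialization", {
  doc <- list(
    list(op = "V", args = list("a", "b")),
    list(op = "as", args = "m"),
    list(op = "out", args = list("x")),
    list(op = "has", args = list(op = "and", children = list(
      list(op = "eq", field = "p", value = "red"),
      list(op = "not", children = list(
        list(op = "within", field = "$m.p", value = list("u", "v"))
      ))
    ))),
    list(op = "distinct", args = list("$m._gid", "_gid")),
    list(op = "limit", args = 5),
    list(op = "render", args = list("_gid", "$m.nested.k"))
  )
  q1 <- parse_query(doc)
  q2 <- parse_query(query_to_doc(q1))
  expect_equal(query_to_doc(q1), query_to_doc(q2))
  # and through JSON text
  q3 <- parse_query(as.character(jsonlite::toJSON(query_to_doc(q1),
                                                  auto_unbox = TRUE,
                                                  digits = NA)))
  expect_equal(query_to_doc(q3), query_to_doc(q1))
})

test_that("field paths parse marks, reserved keys and data prefixes", {
  fp <- parse_field_path("$sample._gid")
  expect_equal(fp$mark, "sample")
  expect_equal(fp$components, "_gid")

  fp2 <- parse_field_path("$exp._data.values")
  expect_equal(fp2$mark, "exp")
  expect_equal(as.character(fp2$components), "values")

  fp3 <- parse_field_path("gdc_attributes.sample_type")
  expect_equal(fp3$mark, "")
  expect_equal(fp3$components, c("gdc_attributes", "sample_type"))

  expect_equal(parse_field_path("$._gid")$mark, "")
  expect_error(parse_field_path("a._gid"), "reserved")
  expect_error(parse_field_path(""), "non-empty")
})

test_that("field resolution walks nested maps and yields null for misses", {
  g <- graph_new()
  add_vertex(g, "Gene:E1", "Gene", list(
    gdc_attributes = list(sample_type = "Primary Tumor"),
    num = 4
  ))
  finalize(g)
  t <- list(cur = list(kind = "vertex", gid = "Gene:E1"), marks = list())
  expect_equal(resolve_field(t, "_gid", g), "Gene:E1")
  expect_equal(resolve_field(t, "_label", g), "Gene")
  expect_equal(resolve_field(t, "gdc_attributes.sample_type", g),
               "Primary Tumor")
  expect_null(resolve_field(t, "nonexistent.key", g))
  expect_null(resolve_field(t, "gdc_attributes.sample_type.deeper", g))
  expect_equal(resolve_field(t, "_data.num", g), 4)
  expect_error(resolve_field(t, "$ghost._gid", g), "never set")
})

test_that("condition evaluation is total over heterogeneous values", {
  g <- graph_new()
  add_vertex(g, "v", "A", list(
    methods = list("MUTECT", "MUSE"),
    project_id = "CTRP_Breast_Cancer",
    ec50 = "high",
    num = 2,
    flag = FALSE
  ))
  finalize(g)
  t <- list(cur = list(kind = "vertex", gid = "v"), marks = list())
  ev <- function(op, field, value) {
    eval_condition(cond_leaf(op, field, value), t, g)
  }
  expect_true(ev("contains", "methods", "MUTECT"))
  expect_false(ev("contains", "methods", "VARSCAN"))
  expect_false(ev("contains", "project_id", "CTRP"))  # scalar, not a list
  expect_true(ev("eq", "project_id", "CTRP_Breast_Cancer"))
  expect_false(ev("gt", "ec50", 1.0))                 # non-numeric -> false
  expect_true(ev("gt", "num", 1))
  expect_true(ev("within", "num", list(1, 2, 3)))
  expect_false(ev("within", "missing", list(1, 2)))
  expect_false(ev("eq", "missing", "x"))              # null field
  expect_true(ev("neq", "missing", "x"))              # except neq
  expect_true(ev("eq", "missing", NULL))              # explicit null literal
  expect_false(ev("eq", "flag", TRUE))
  expect_true(eval_condition(cond_node("and",
    cond_leaf("eq", "num", 2),
    cond_node("not", cond_leaf("eq", "project_id", "other"))), t, g))
  expect_false(eval_condition(cond_node("or",
    cond_leaf("eq", "num", 3),
    cond_leaf("contains", "methods", "NOPE")), t, g))
})
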