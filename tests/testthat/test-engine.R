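test_that("traversal steps fan out along edges in insertion order", {
  g <- mini_cohort()
  # out from the project reaches each case
  r <- execute(g, list(list(op = "V", args = list("Project:P1")),
                       list(op = "out", args = list("cases"))))
  expect_equal(as_tibble(r)$gid, c("Case:C1", "Case:C2", "Case:C3"))

  # tumor filter then count: 2 of 3 samples are primary tumor
  r2 <- execute(g, list(
    list(op = "V", args = list("Project:P1")),
    list(op = "out", args = list("cases")),
    list(op = "out", args = list("samples")),
    list(op = "has", args = list(op = "eq",
                                 field = "gdc_attributes.sample_type",
                                 value = "Primary Tumor")),
    list(op = "count")
  ))
  expect_equal(as_tibble(r2)$n, 2L)

  # V of a missing gid yields no travelers, not an error
  r3 <- execute(g, list(list(op = "V", args = list("Project:NOPE")),
                        list(op = "count")))
  expect_equal(as_tibble(r3)$n, 0L)
})

test_that("outE lands on the edge so edge payloads are aggregable", {
  g <- mini_cohort()
  r <- execute(g, list(
    list(op = "V", args = list("SomaticCallset:A1")),
    list(op = "outE", args = list("alleles")),
    list(op = "aggregate", args = list(name = "geneCount",
                                       field = "ensembl_gene"))
  ))
  tb <- as_tibble(r)
  expect_equal(tb$key, c("ENSG1", "ENSG2"))
  expect_equal(tb$count, c(1L, 1L))

  # out (not outE) lands on the allele vertex instead
  r2 <- execute(g, list(
    list(op = "V", args = list("SomaticCallset:A1")),
    list(op = "out", args = list("alleles"))
  ))
  expect_equal(as_tibble(r2)$label, c("Allele", "Allele"))

  # traversal from an edge position is an error naming the step
  expect_error(execute(g, list(
    list(op = "V", args = list("SomaticCallset:A1")),
    list(op = "outE", args = list("alleles")),
    list(op = "out", args = list("x"))
  )), "out.*vertex")
})

test_that("marks snapshot elements; select recalls them for all travelers", {
  g <- pathway_toy()
  r <- execute(g, list(
    list(op = "V", args = list("Pathway:P")),
    list(op = "as", args = "pathway"),
    list(op = "out", args = list("genes")),
    list(op = "select", args = "pathway")
  ))
  expect_equal(as_tibble(r)$gid, rep("Pathway:P", 3))

  # select twice is the same as once
  r2 <- execute(g, list(
    list(op = "V", args = list("Pathway:P")),
    list(op = "as", args = "pathway"),
    list(op = "out", args = list("genes")),
    list(op = "select", args = "pathway"),
    list(op = "select", args = "pathway")
  ))
  expect_identical(r, r2)

  # per-pathway membership counts via select + aggregate
  r3 <- execute(g, list(
    list(op = "V"),
    list(op = "hasLabel", args = list("Pathway")),
    list(op = "as", args = "pathway"),
    list(op = "out", args = list("genes")),
    list(op = "select", args = "pathway"),
    list(op = "aggregate", args = list(name = "pathwayGeneCount",
                                       field = "_gid"))
  ))
  tb <- as_tibble(r3)
  expect_equal(tb$key, c("Pathway:P", "Pathway:Q"))
  expect_equal(tb$count, c(3L, 1L))
})

test_that("aggregation skips nulls, sorts by count then key", {
  g <- graph_new()
  vals <- list("g1", "g1", "g2", NULL)
  for (i in seq_along(vals)) {
    d <- if (is.null(vals[[i]])) list() else list(f = vals[[i]])
    add_vertex(g, sprintf("v%d", i), "A", d)
  }
  finalize(g)
  r <- execute(g, list(list(op = "V"),
                       list(op = "aggregate",
                            args = list(name = "t", field = "f"))))
  tb <- as_tibble(r)
  expect_equal(tb$key, c("g1", "g2"))
  expect_equal(tb$count, c(2L, 1L))
  expect_lte(sum(tb$count), n_vertices(g))

  # all-distinct values tie-break by ascending key
  g2 <- graph_new()
  for (k in c("zeta", "alpha", "mid")) {
    add_vertex(g2, k, "A", list(f = k))
  }
  finalize(g2)
  tb2 <- as_tibble(execute(g2, list(
    list(op = "V"),
    list(op = "aggregate", args = list(name = "t", field = "f"))
  )))
  expect_equal(tb2$key, c("alpha", "mid", "zeta"))
  expect_equal(tb2$count, rep(1L, 3))

  # zero travelers produce an empty bucket list
  tb3 <- as_tibble(execute(g2, list(
    list(op = "V", args = list("NOPE")),
    list(op = "aggregate", args = list(name = "t", field = "f"))
  )))
  expect_equal(nrow(tb3), 0)
})

test_that("render resolves marks and passes nested values through", {
  g <- graph_new()
  add_vertex(g, "Compound:X", "Compound", list(synonym = "FULVESTRANT"))
  add_vertex(g, "GeneExpression:1", "GeneExpression",
             list(values = list(ENSG1 = 1.5, ENSG2 = 0)))
  finalize(g)
  r <- execute(g, list(
    list(op = "V", args = list("Compound:X")),
    list(op = "render", args = list("_gid", "synonym", "missing"))
  ))
  expect_equal(r$rows[[1]], list("Compound:X", "FULVESTRANT", NULL))

  r2 <- execute(g, list(
    list(op = "V", args = list("GeneExpression:1")),
    list(op = "as", args = "exp"),
    list(op = "render", args = list("$exp._data.values"))
  ))
  expect_equal(r2$rows[[1]][[1]], list(ENSG1 = 1.5, ENSG2 = 0))
})

test_that("distinct keeps the first traveler per value tuple and is idempotent", {
  g <- mini_cohort()
  base <- list(
    list(op = "V"),
    list(op = "hasLabel", args = list("SomaticCallset")),
    list(op = "as", args = "cs"),
    list(op = "out", args = list("alleles"))
  )
  once <- execute(g, c(base, list(
    list(op = "distinct", args = list("_gid")))))
  twice <- execute(g, c(base, list(
    list(op = "distinct", args = list("_gid")),
    list(op = "distinct", args = list("_gid")))))
  expect_identical(once, twice)
  expect_equal(as_tibble(once)$gid, c("Allele:1:100:A:T", "Allele:2:200:C:G"))

  # distinct over a (mark, current) pair
  pairs <- execute(g, c(base, list(
    list(op = "distinct", args = list("$cs._gid", "_gid")),
    list(op = "count"))))
  expect_equal(as_tibble(pairs)$n, 3L)
})

test_that("limit truncates the traveler stream; empty labels traverse any edge", {
  g <- mini_cohort()
  r <- execute(g, list(list(op = "V"), list(op = "limit", args = 2),
                       list(op = "count")))
  expect_equal(as_tibble(r)$n, 2L)
  r0 <- execute(g, list(list(op = "V"), list(op = "limit", args = 0),
                        list(op = "count")))
  expect_equal(as_tibble(r0)$n, 0L)

  # out() with no labels follows every out edge of the sample
  r2 <- execute(g, list(list(op = "V", args = list("Sample:S1")),
                        list(op = "out", args = list()),
                        list(op = "count")))
  expect_equal(as_tibble(r2)$n, 2L)  # case + aliquot
})

test_that("a query with no terminal step emits element rows", {
  g <- pathway_toy()
  r <- execute(g, list(list(op = "V"),
                       list(op = "hasLabel", args = list("Gene"))))
  expect_equal(r$kind, "elements")
  tb <- as_tibble(r)
  expect_equal(tb$label, rep("Gene", 3))
  expect_named(tb, c("gid", "label", "data"))
})
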