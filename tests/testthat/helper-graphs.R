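# Hand-built fixture graphs and the random (graph, query) generator used by
# the differential tests against the brute-force oracle.

# Minimal cohort: one project, three cases each with one sample
# (2 primary tumor + 1 normal), aliquots and callsets, two alleles.
mini_cohort <- function() {
  g <- graph_new()
  add_vertex(g, "Program:P", "Program")
  add_vertex(g, "Project:P1", "Project", list(project_id = "P1"))
  add_edge(g, "Program:P", "projects", "Project:P1")
  types <- c("Primary Tumor", "Primary Tumor", "Solid Tissue Normal")
  for (i in 1:3) {
    cgid <- sprintf("Case:C%d", i)
    sgid <- sprintf("Sample:S%d", i)
    agid <- sprintf("Aliquot:A%d", i)
    add_vertex(g, cgid, "Case")
    add_edge(g, "Project:P1", "cases", cgid)
    add_vertex(g, sgid, "Sample",
               list(gdc_attributes = list(sample_type = types[[i]])))
    add_edge(g, cgid, "samples", sgid)
    add_edge(g, sgid, "case", cgid)
    add_vertex(g, agid, "Aliquot")
    add_edge(g, sgid, "aliquots", agid)
  }
  add_vertex(g, "Allele:1:100:A:T", "Allele")
  add_vertex(g, "Allele:2:200:C:G", "Allele")
  for (i in 1:2) {
    csgid <- sprintf("SomaticCallset:A%d", i)
    add_vertex(g, csgid, "SomaticCallset")
    add_edge(g, sprintf("Aliquot:A%d", i), "somatic_callsets", csgid)
  }
  add_edge(g, "SomaticCallset:A1", "alleles", "Allele:1:100:A:T",
           list(methods = list("MUTECT", "MUSE"), ensembl_gene = "ENSG1"))
  add_edge(g, "SomaticCallset:A1", "alleles", "Allele:2:200:C:G",
           list(methods = list("MUSE"), ensembl_gene = "ENSG2"))
  add_edge(g, "SomaticCallset:A2", "alleles", "Allele:1:100:A:T",
           list(methods = list("MUTECT"), ensembl_gene = "ENSG1"))
  finalize(g)
  g
}

# Pathway membership toy: P holds 3 genes, Q holds 1 (shared with P).
pathway_toy <- function() {
  g <- graph_new()
  add_vertex(g, "Pathway:P", "Pathway")
  add_vertex(g, "Pathway:Q", "Pathway")
  for (i in 1:3) add_vertex(g, sprintf("ENSG%d", i), "Gene")
  for (i in 1:3) {
    add_edge(g, "Pathway:P", "genes", sprintf("ENSG%d", i))
    add_edge(g, sprintf("ENSG%d", i), "pathways", "Pathway:P")
  }
  add_edge(g, "Pathway:Q", "genes", "ENSG1")
  add_edge(g, "ENSG1", "pathways", "Pathway:Q")
  finalize(g)
  g
}

# --- random property graphs and queries ------------------------------------

random_pg <- function(max_v = 40, max_e = 120) {
  nv <- sample(2:max_v, 1)
  g <- graph_new()
  gids <- sprintf("V%02d", seq_len(nv))
  for (i in seq_len(nv)) {
    data <- list()
    if (stats::runif(1) < 0.7) data$p <- sample(c("red", "green", "blue"), 1)
    if (stats::runif(1) < 0.5) data$n <- sample(1:5, 1)
    if (stats::runif(1) < 0.4) data$nested <- list(k = sample(c("u", "v"), 1))
    if (stats::runif(1) < 0.4) {
      data$tags <- as.list(sample(c("s", "t", "u"), sample(1:3, 1)))
    }
    add_vertex(g, gids[[i]], sample(c("A", "B", "C"), 1), data)
  }
  ne <- sample(0:max_e, 1)
  for (j in seq_len(ne)) {
    data <- list()
    if (stats::runif(1) < 0.5) data$w <- sample(1:9, 1)
    if (stats::runif(1) < 0.3) {
      data$tags <- as.list(sample(c("s", "t"), sample(1:2, 1)))
    }
    add_edge(g, sample(gids, 1), sample(c("x", "y", "z"), 1),
             sample(gids, 1), data)
  }
  finalize(g)
  g
}

random_fields <- function(marks, n = 1) {
  pool <- c("_gid", "_label", "p", "n", "nested.k", "tags", "q.missing",
            "_data.p")
  for (m in marks) pool <- c(pool, paste0("$", m, "._gid"),
                             paste0("$", m, ".p"))
  as.list(sample(pool, n, replace = TRUE))
}

random_condition <- function(marks, depth = 1) {
  if (depth > 0 && stats::runif(1) < 0.3) {
    op <- sample(c("and", "or", "not"), 1)
    kids <- if (op == "not") 1 else 2
    return(list(op = op, children = lapply(seq_len(kids), function(i) {
      random_condition(marks, depth - 1)
    })))
  }
  op <- sample(c("eq", "neq", "gt", "gte", "lt", "lte", "contains",
                 "within"), 1)
  field <- random_fields(marks, 1)[[1]]
  value <- switch(op,
    eq = , neq = sample(list("red", "green", 3, TRUE), 1)[[1]],
    gt = , gte = , lt = , lte = sample(1:5, 1),
    contains = sample(c("s", "t", "u"), 1),
    within = as.list(sample(c("red", "green", "blue"), 2))
  )
  list(op = op, field = field, value = value)
}

# Random valid query document over a graph: tracks traveler position so
# traversal steps are only emitted on vertices, and marks before use.
random_query_doc <- function(g, max_depth = 6) {
  steps <- list()
  if (stats::runif(1) < 0.4) {
    steps[[1]] <- list(op = "V")
  } else {
    pool <- c(g$v_order, "NO-SUCH-GID")
    steps[[1]] <- list(op = "V",
                       args = as.list(sample(pool, sample(1:3, 1))))
  }
  pos <- "vertex"
  marks <- character(0)
  markpos <- list()
  for (d in seq_len(sample(0:max_depth, 1))) {
    choices <- c("hasLabel", "hasId", "has", "as", "distinct", "limit")
    if (pos == "vertex") choices <- c(choices, "out", "in", "outE", "inE")
    if (length(marks) > 0) choices <- c(choices, "select")
    op <- sample(choices, 1)
    steps[[length(steps) + 1L]] <- switch(op,
      hasLabel = list(op = "hasLabel", args = as.list(
        sample(c("A", "B", "C", "x", "y"), sample(1:2, 1)))),
      hasId = list(op = "hasId", args = as.list(
        sample(c(g$v_order, "NO"), sample(1:2, 1)))),
      has = list(op = "has", args = random_condition(marks)),
      out = , `in` = , outE = , inE = {
        labs <- if (stats::runif(1) < 0.25) list() else {
          as.list(sample(c("x", "y", "z"), sample(1:2, 1)))
        }
        list(op = op, args = labs)
      },
      as = {
        nm <- sample(c("m1", "m2"), 1)
        marks <- union(marks, nm)
        markpos[[nm]] <- pos
        list(op = "as", args = nm)
      },
      select = {
        nm <- sample(marks, 1)
        pos <- markpos[[nm]]
        list(op = "select", args = nm)
      },
      distinct = list(op = "distinct",
                      args = random_fields(marks, sample(1:2, 1))),
      limit = list(op = "limit", args = sample(0:10, 1))
    )
    if (op %in% c("out", "in")) pos <- "vertex"
    if (op %in% c("outE", "inE")) pos <- "edge"
  }
  term <- sample(c("none", "count", "aggregate", "render"), 1,
                 prob = c(0.25, 0.2, 0.3, 0.25))
  if (term == "count") {
    steps[[length(steps) + 1L]] <- list(op = "count")
  } else if (term == "aggregate") {
    n_aggs <- sample(1:2, 1)
    steps[[length(steps) + 1L]] <- list(op = "aggregate", args = lapply(
      seq_len(n_aggs), function(i) {
        list(name = paste0("agg", i), field = random_fields(marks, 1)[[1]])
      }))
  } else if (term == "render") {
    steps[[length(steps) + 1L]] <- list(op = "render",
                                        args = random_fields(marks,
                                                             sample(1:3, 1)))
  }
  steps
}

# n differential cases: returns number of agreeing cases.
run_differential <- function(n, max_v = 40, max_e = 120, max_depth = 6) {
  agree <- 0L
  for (i in seq_len(n)) {
    g <- random_pg(max_v, max_e)
    q <- compile_query(parse_query(random_query_doc(g, max_depth)))
    a <- execute(g, q)
    b <- brute_force_execute(g, q)
    if (identical(a, b)) {
      agree <- agree + 1L
    } else {
      info <- paste(vapply(query_to_doc(q), function(s) s$op, character(1)),
                    collapse = ".")
      warning(sprintf("differential mismatch on case %d (%s)", i, info))
    }
  }
  agree
}
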