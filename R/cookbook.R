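# The eight cookbook analyses. Each is implemented by constructing a query
# document and handing it to execute() — never by bespoke graph walking —
# so every cookbook run exercises the full engine. Defaults are the
# conventional gids of the default synthetic fixture, so a zero-argument
# run works out of the box.

step <- function(op, args = NULL) {
  if (is.null(args)) list(op = op) else list(op = op, args = args)
}

cookbook_result <- function(query_id, rows, query_doc) {
  structure(list(query_id = query_id, rows = rows, query_doc = query_doc),
            class = "cookbook_result")
}

run_doc <- function(graph, query_id, doc) {
  cookbook_result(query_id, execute(graph, parse_query(doc)), doc)
}

# V() with no gids means "all vertices", so an empty chained input list
# must not fall through to a full scan: start from a gid no vertex carries.
v_step_for <- function(gids) {
  if (length(gids) == 0) {
    step("V", list("\x01no-such-vertex"))
  } else {
    step("V", as.list(gids))
  }
}

#' @export
print.cookbook_result <- function(x, ...) {
  cat(sprintf("<cookbook %s>\n", x$query_id))
  print(x$rows, ...)
  invisible(x)
}

#' @method tidy cookbook_result
#' @export
tidy.cookbook_result <- function(x, ...) as_tibble(x$rows, ...)

#' @method as_tibble cookbook_result
#' @export
as_tibble.cookbook_result <- function(x, ...) as_tibble(x$rows, ...)

#' @method glance cookbook_result
#' @export
glance.cookbook_result <- function(x, ...) {
  dplyr::mutate(glance(x$rows), query_id = x$query_id, .before = 1)
}

#' @method autoplot cookbook_result
#' @export
autoplot.cookbook_result <- function(object, ...) autoplot(object$rows, ...)

#' Count somatic mutations per gene in a cohort
#'
#' Walks project, cases, primary-tumor samples, aliquots and somatic
#' callsets, lands on the callset-to-allele *edges* (whose payload carries
#' the caller method list and gene annotation), keeps edges called by
#' MUTECT, and term-aggregates the per-edge `ensembl_gene` field.
#'
#' @param graph A finalized [`evigraph`][graph_new].
#' @param project_gid Project to count in (an unknown gid yields an empty
#'   aggregation).
#' @param method Caller that must appear in the edge's `methods` list.
#' @return A `cookbook_result` whose `rows` is an aggregation result.
#' @export
q1_mutation_counts <- function(graph,
                               project_gid = "Project:TCGA-SYN-BRCA",
                               method = "MUTECT") {
  doc <- list(
    step("V", list(project_gid)),
    step("out", list("cases")),
    step("out", list("samples")),
    step("has", list(op = "eq", field = "gdc_attributes.sample_type",
                     value = "Primary Tumor")),
    step("out", list("aliquots")),
    step("out", list("somatic_callsets")),
    step("outE", list("alleles")),
    step("has", list(op = "contains", field = "methods", value = method)),
    step("aggregate", list(name = "geneCount", field = "ensembl_gene"))
  )
  run_doc(graph, "q1", doc)
}

#' Gene-to-pathway membership pairs
#'
#' Marks each starting gene, moves to its pathways, and renders
#' (gene gid, pathway gid) tuples, one per membership edge.
#'
#' @inheritParams q1_mutation_counts
#' @param gene_gids Genes to start from; defaults to the genes found
#'   mutated by [q1_mutation_counts()] (in bucket order), mirroring how the
#'   analyses chain.
#' @export
q2_gene_pathway_pairs <- function(graph, gene_gids = NULL) {
  if (is.null(gene_gids)) {
    q1 <- q1_mutation_counts(graph)
    gene_gids <- q1$rows$rows$key
  }
  doc <- list(
    v_step_for(gene_gids),
    step("as", "gene"),
    step("out", list("pathways")),
    step("render", list("$gene._gid", "$._gid"))
  )
  run_doc(graph, "q2", doc)
}

#' Gene-membership counts per pathway
#'
#' Marks each pathway, fans out to its member genes, selects the marked
#' pathway back, and counts travelers per pathway gid — i.e. each pathway's
#' out-degree under `genes`. Pathways with no members produce no travelers
#' and are absent from the buckets.
#'
#' @inheritParams q1_mutation_counts
#' @export
q3_pathway_gene_counts <- function(graph) {
  doc <- list(
    step("V"),
    step("hasLabel", list("Pathway")),
    step("as", "pathway"),
    step("out", list("genes")),
    step("select", "pathway"),
    step("aggregate", list(name = "pathwayGeneCount", field = "_gid"))
  )
  run_doc(graph, "q3", doc)
}

#' Publications linked to a cohort's mutations
#'
#' Follows tumor mutations to their alleles, then literature-curated
#' associations and their publications, counting travelers per publication
#' gid.
#'
#' @inheritParams q1_mutation_counts
#' @export
q4_publication_counts <- function(graph,
                                  project_gid = "Project:TCGA-SYN-BRCA") {
  doc <- list(
    step("V", list(project_gid)),
    step("out", list("cases")),
    step("out", list("samples")),
    step("has", list(op = "eq", field = "gdc_attributes.sample_type",
                     value = "Primary Tumor")),
    step("out", list("aliquots")),
    step("out", list("somatic_callsets")),
    step("out", list("alleles")),
    step("out", list("g2p_associations")),
    step("out", list("publications")),
    step("aggregate", list(name = "pub", field = "_gid"))
  )
  run_doc(graph, "q4", doc)
}

#' Compounds linked to a cohort's mutations, one count per case
#'
#' Like [q4_publication_counts()] but continuing to compounds, with a
#' `distinct` on the (case, compound) pair so a case contributes at most 1
#' to each compound regardless of how many alleles, associations, or
#' publications link them.
#'
#' @inheritParams q1_mutation_counts
#' @export
q5_compound_case_counts <- function(graph,
                                    project_gid = "Project:TCGA-SYN-BRCA") {
  doc <- list(
    step("V", list(project_gid)),
    step("out", list("cases")),
    step("as", "case"),
    step("out", list("samples")),
    step("has", list(op = "eq", field = "gdc_attributes.sample_type",
                     value = "Primary Tumor")),
    step("out", list("aliquots")),
    step("out", list("somatic_callsets")),
    step("out", list("alleles")),
    step("out", list("g2p_associations")),
    step("out", list("compounds")),
    step("distinct", list("$case._gid", "_gid")),
    step("aggregate", list(name = "compound", field = "_gid"))
  )
  run_doc(graph, "q5", doc)
}

#' Which of a set of compounds were tested in a given project
#'
#' Marks each compound, moves along its derived `projects` edges, filters
#' on the project's `project_id`, recalls the compound, and renders
#' (gid, synonym) tuples.
#'
#' @inheritParams q1_mutation_counts
#' @param compound_gids Compounds to check; defaults to the compounds found
#'   by [q5_compound_case_counts()], in bucket order.
#' @param project_id `project_id` property of the screening project.
#' @export
q6_compounds_in_project <- function(graph, compound_gids = NULL,
                                    project_id = "CTRP-SYN-Breast_Screen") {
  if (is.null(compound_gids)) {
    q5 <- q5_compound_case_counts(graph)
    compound_gids <- q5$rows$rows$key
  }
  doc <- list(
    v_step_for(compound_gids),
    step("as", "compound"),
    step("out", list("projects")),
    step("has", list(op = "eq", field = "project_id", value = project_id)),
    step("select", "compound"),
    step("render", list("_gid", "synonym"))
  )
  run_doc(graph, "q6", doc)
}

#' EC50 of each cell line in a program for one compound
#'
#' Walks the program's projects down to samples (marked), aliquots and
#' drug-response vertices (marked), then to the compound, keeps the target
#' compound by id, and renders (sample gid, submitter compound id, EC50).
#'
#' @inheritParams q1_mutation_counts
#' @param program_gid Cell-line program.
#' @param compound_gid Target compound.
#' @export
q7_ec50_for_compound <- function(graph,
                                 program_gid = "Program:CTRP-SYN",
                                 compound_gid = "Compound:CID0000001") {
  doc <- list(
    step("V", list(program_gid)),
    step("out", list("projects")),
    step("out", list("cases")),
    step("out", list("samples")),
    step("as", "sample"),
    step("out", list("aliquots")),
    step("out", list("drug_response")),
    step("as", "response"),
    step("out", list("compounds")),
    step("hasId", list(compound_gid)),
    step("render", list("$sample._gid", "$response.submitter_compound_id",
                        "$response.ec50"))
  )
  run_doc(graph, "q7", doc)
}

#' Expression vectors for screened cell lines via cross-project links
#'
#' From each screened sample (marked), climbs to its case, hops the
#' `same_as` link to the matching case in the expression project, descends
#' to that case's aliquots and gene-expression payloads, and renders
#' (originating sample gid, expression values map). Samples whose case has
#' no `same_as` partner produce no row.
#'
#' @inheritParams q1_mutation_counts
#' @param sample_gids Starting samples; defaults to the samples returned by
#'   [q7_ec50_for_compound()], in order.
#' @export
q8_expression_matrix <- function(graph, sample_gids = NULL) {
  if (is.null(sample_gids)) {
    q7 <- q7_ec50_for_compound(graph)
    sample_gids <- unique(vapply(q7$rows$rows, function(r) {
      r[[1]]
    }, character(1)))
  }
  doc <- list(
    v_step_for(sample_gids),
    step("as", "sample"),
    step("out", list("case")),
    step("out", list("same_as")),
    step("out", list("samples")),
    step("out", list("aliquots")),
    step("out", list("gene_expressions")),
    step("as", "exp"),
    step("render", list("$sample._gid", "$exp._data.values"))
  )
  run_doc(graph, "q8", doc)
}

#' Run all eight cookbook analyses
#'
#' @inheritParams q1_mutation_counts
#' @return Named list `q1`...`q8` of `cookbook_result` objects.
#' @export
cookbook_all <- function(graph) {
  list(
    q1 = q1_mutation_counts(graph),
    q2 = q2_gene_pathway_pairs(graph),
    q3 = q3_pathway_gene_counts(graph),
    q4 = q4_publication_counts(graph),
    q5 = q5_compound_case_counts(graph),
    q6 = q6_compounds_in_project(graph),
    q7 = q7_ec50_for_compound(graph),
    q8 = q8_expression_matrix(graph)
  )
}

#' Assemble expression render rows into a samples-by-genes tibble
#'
#' Post-processing helper for [q8_expression_matrix()]: one row per sample,
#' one numeric column per gene.
#'
#' @param result A `cookbook_result` (or render [`gq_result`]) whose tuples
#'   are (sample gid, values map).
#' @return A tibble with a `sample` column and one column per gene.
#' @export
expression_to_matrix <- function(result) {
  rows <- if (inherits(result, "cookbook_result")) result$rows$rows else result$rows
  samples <- vapply(rows, function(r) r[[1]], character(1))
  genes <- if (length(rows) > 0) names(rows[[1]][[2]]) else character(0)
  cols <- lapply(genes, function(gn) {
    vapply(rows, function(r) as.numeric(r[[2]][[gn]] %||% NA_real_),
           numeric(1))
  })
  names(cols) <- genes
  tibble::as_tibble(c(list(sample = samples), cols))
}
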