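# ETL loaders: convert standard bioinformatics source formats (MAF-like
# somatic variant TSV, GMT gene sets, TSV expression matrices, drug-response
# CSV, association JSON Lines) into schema-conformant graph elements.
#
# Loaders are pure: they read a file and return an element set (vertices +
# edges) without touching any graph, so loading the same file twice yields
# identical element sets. add_elements() merges an element set into a graph,
# skipping vertices that already exist (shared anchors such as Aliquot or
# Gene vertices may be created by several loaders).

elements_new <- function() {
  structure(list(vertices = list(), edges = list()),
            class = "evigraph_elements")
}

el_vertex <- function(el, gid, label, data = list()) {
  if (is.null(el$vertices[[gid]])) {
    el$vertices[[gid]] <- list(gid = gid, label = label,
                               data = as_data_map(data))
  }
  el
}

el_edge <- function(el, from, label, to, data = list(), gid = NULL) {
  el$edges[[length(el$edges) + 1L]] <-
    list(gid = gid, from = from, label = label, to = to,
         data = as_data_map(data))
  el
}

#' @export
print.evigraph_elements <- function(x, ...) {
  cat(sprintf("<evigraph elements: %d vertices, %d edges>\n",
              length(x$vertices), length(x$edges)))
  invisible(x)
}

#' Merge an element set into a graph
#'
#' Vertices whose gid already exists in the graph are skipped (loaders may
#' independently create shared anchor vertices); edges are always added,
#' with deterministic synthesized gids when absent.
#'
#' @param graph An [`evigraph`][graph_new].
#' @param elements An element set returned by one of the `load_*()` loaders.
#' @return The graph, invisibly.
#' @export
add_elements <- function(graph, elements) {
  stopifnot(inherits(graph, "evigraph"),
            inherits(elements, "evigraph_elements"))
  for (v in elements$vertices) {
    if (is.null(get_vertex(graph, v$gid))) {
      add_vertex(graph, v$gid, v$label, v$data)
    }
  }
  for (e in elements$edges) {
    add_edge(graph, e$from, e$label, e$to, e$data, gid = e$gid)
  }
  invisible(graph)
}

#' Turn an element set into a finalized standalone graph
#'
#' @param elements An element set.
#' @return A finalized [`evigraph`][graph_new].
#' @export
elements_to_graph <- function(elements) {
  g <- graph_new()
  add_elements(g, elements)
  finalize(g)
  g
}

prefixed_gid <- function(id, label) {
  pre <- paste0(label, ":")
  ifelse(startsWith(id, pre), id, paste0(pre, id))
}

#' Load a MAF-like somatic variant table
#'
#' Builds one `SomaticCallset` per tumor aliquot, `Allele` vertices
#' deduplicated by their `(chromosome, start, ref, alt)` key so repeated
#' variants across samples share one vertex, and
#' `SomaticCallset-[alleles]->Allele` edges carrying the caller method list
#' and the Ensembl gene id (the gene annotation lives on the edge, which is
#' what a traversal landing on the edge with `outE` aggregates over).
#'
#' @param path TSV file with columns `tumor_aliquot_id`, `hugo_symbol`,
#'   `ensembl_gene`, `chromosome`, `start`, `reference_allele`,
#'   `alternate_allele`, `callers` (pipe- or comma-separated list).
#' @param project_gid Unused anchor, kept for symmetry with sibling loaders.
#' @param col_map Optional named character vector mapping the standard
#'   column names above to the file's actual header names.
#' @return An element set (see [add_elements()]).
#' @export
load_maf <- function(path, project_gid = NULL, col_map = NULL) {
  required <- c("tumor_aliquot_id", "hugo_symbol", "ensembl_gene",
                "chromosome", "start", "reference_allele",
                "alternate_allele", "callers")
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  for (std in required) {
    actual <- if (!is.null(col_map) && std %in% names(col_map)) {
      col_map[[std]]
    } else {
      std
    }
    if (!(actual %in% names(df))) {
      stop(sprintf("MAF file lacks required column '%s'", actual),
           call. = FALSE)
    }
    names(df)[names(df) == actual] <- std
  }
  el <- elements_new()
  callsets <- character(0)
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    lineno <- i + 1L   # header is line 1
    start <- suppressWarnings(as.numeric(row$start))
    if (is.na(start) || start < 1 || start != floor(start)) {
      stop(sprintf("%s line %d: malformed start position '%s'", path, lineno,
                   row$start), call. = FALSE)
    }
    if (!grepl("^[ACGT-]+$", row$reference_allele) ||
        !grepl("^[ACGT-]+$", row$alternate_allele)) {
      stop(sprintf("%s line %d: malformed allele", path, lineno),
           call. = FALSE)
    }
    aliquot_gid <- prefixed_gid(row$tumor_aliquot_id, "Aliquot")
    callset_gid <- prefixed_gid(row$tumor_aliquot_id, "SomaticCallset")
    allele_gid <- sprintf("Allele:%s:%d:%s:%s", row$chromosome, start,
                          row$reference_allele, row$alternate_allele)
    el <- el_vertex(el, aliquot_gid, "Aliquot")
    if (!(callset_gid %in% callsets)) {
      callsets <- c(callsets, callset_gid)
      el <- el_vertex(el, callset_gid, "SomaticCallset",
                      list(tumor_aliquot_id = row$tumor_aliquot_id))
      el <- el_edge(el, aliquot_gid, "somatic_callsets", callset_gid)
    }
    el <- el_vertex(el, allele_gid, "Allele", list(
      chromosome = row$chromosome, start = start,
      reference_bases = row$reference_allele,
      alternate_bases = row$alternate_allele,
      hugo_symbol = row$hugo_symbol
    ))
    methods <- strsplit(row$callers, "[|,]")[[1]]
    el <- el_edge(el, callset_gid, "alleles", allele_gid, list(
      methods = as.list(methods), ensembl_gene = row$ensembl_gene
    ))
  }
  el
}

#' Load a GMT gene-set file as pathway memberships
#'
#' One `Pathway` vertex per line; `Gene` vertices are created for members
#' not yet seen; membership is emitted in both directions
#' (`Pathway-[genes]->Gene` and `Gene-[pathways]->Pathway`) since the
#' cookbook traverses both. Duplicate members within a line contribute one
#' edge pair.
#'
#' @param path GMT file: tab-separated `name`, `description`, then member
#'   gene identifiers (used as gene gids unchanged).
#' @return An element set.
#' @export
load_pathways_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  el <- elements_new()
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[[i]]))) next
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("%s line %d: GMT line needs name, description and members",
                   path, i), call. = FALSE)
    }
    pathway_gid <- prefixed_gid(fields[[1]], "Pathway")
    el <- el_vertex(el, pathway_gid, "Pathway",
                    list(name = fields[[1]], description = fields[[2]]))
    for (gene in unique(fields[-(1:2)])) {
      if (!nzchar(gene)) next
      el <- el_vertex(el, gene, "Gene", list(ensembl_gene = gene))
      el <- el_edge(el, pathway_gid, "genes", gene)
      el <- el_edge(el, gene, "pathways", pathway_gid)
    }
  }
  el
}

#' Load a samples-by-genes TPM expression matrix
#'
#' One `GeneExpression` vertex per row, holding the full row as a dense
#' `values` map (gene gid -> TPM), attached to its aliquot.
#'
#' @param path TSV matrix: first column aliquot identifiers, remaining
#'   columns gene gids, cells non-negative TPM values.
#' @param graph Optional existing graph used to check aliquots when
#'   `create_missing = FALSE`.
#' @param create_missing Create `Aliquot` vertices for unknown aliquots
#'   (default) or fail.
#' @return An element set.
#' @export
load_expression_matrix <- function(path, graph = NULL, create_missing = TRUE) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    readr::col_character(), .default = "d"), progress = FALSE)
  gene_cols <- names(df)[-1]
  el <- elements_new()
  for (i in seq_len(nrow(df))) {
    aid <- df[[1]][[i]]
    vals <- as.numeric(unlist(df[i, -1], use.names = FALSE))
    if (any(is.na(vals)) || any(vals < 0)) {
      stop(sprintf("%s line %d: negative or non-numeric expression value",
                   path, i + 1L), call. = FALSE)
    }
    aliquot_gid <- prefixed_gid(aid, "Aliquot")
    if (!create_missing &&
        (is.null(graph) || is.null(get_vertex(graph, aliquot_gid)))) {
      stop(sprintf("%s line %d: unknown aliquot '%s'", path, i + 1L, aid),
           call. = FALSE)
    }
    el <- el_vertex(el, aliquot_gid, "Aliquot")
    ge_gid <- prefixed_gid(aid, "GeneExpression")
    el <- el_vertex(el, ge_gid, "GeneExpression", list(
      values = stats::setNames(as.list(vals), gene_cols),
      metric = "TPM"
    ))
    el <- el_edge(el, aliquot_gid, "gene_expressions", ge_gid)
  }
  el
}

#' Load a drug-response CSV
#'
#' `Compound` vertices are deduplicated by compound id; each row becomes a
#' `DrugResponse` vertex with `ec50`, `auc`, and `submitter_compound_id`
#' payload, wired `Aliquot-[drug_response]->DrugResponse-[compounds]->
#' Compound`. A derived `Compound-[projects]->Project` edge (one per
#' compound) records that the project's samples tested the compound, which
#' is what the cookbook's project-restricted compound query traverses.
#'
#' @param path CSV with columns `sample_id`, `compound_id`,
#'   `submitter_compound_id`, `ec50`, and optionally `auc` and `synonym`.
#' @param project_gid gid of the project whose screen this file records.
#' @return An element set.
#' @export
load_drug_response <- function(path, project_gid) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  for (col in c("sample_id", "compound_id", "submitter_compound_id", "ec50")) {
    if (!(col %in% names(df))) {
      stop(sprintf("drug-response file lacks required column '%s'", col),
           call. = FALSE)
    }
  }
  el <- elements_new()
  el <- el_vertex(el, project_gid, "Project",
                  list(project_id = sub("^Project:", "", project_gid)))
  linked <- character(0)
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    lineno <- i + 1L
    ec50 <- suppressWarnings(as.numeric(row$ec50))
    if (is.na(ec50)) {
      stop(sprintf("%s line %d: non-numeric ec50 '%s'", path, lineno,
                   row$ec50), call. = FALSE)
    }
    auc <- if ("auc" %in% names(df) && !is.na(row$auc) && nzchar(row$auc)) {
      suppressWarnings(as.numeric(row$auc))
    } else {
      NULL
    }
    compound_gid <- prefixed_gid(row$compound_id, "Compound")
    synonym <- if ("synonym" %in% names(df) && !is.na(row$synonym)) {
      row$synonym
    } else {
      toupper(row$submitter_compound_id)
    }
    aliquot_gid <- prefixed_gid(row$sample_id, "Aliquot")
    dr_gid <- sprintf("DrugResponse:%s:%s", row$sample_id, row$compound_id)
    el <- el_vertex(el, aliquot_gid, "Aliquot")
    el <- el_vertex(el, compound_gid, "Compound", list(synonym = synonym))
    dr_data <- list(ec50 = ec50,
                    submitter_compound_id = row$submitter_compound_id)
    if (!is.null(auc)) dr_data$auc <- auc
    el <- el_vertex(el, dr_gid, "DrugResponse", dr_data)
    el <- el_edge(el, aliquot_gid, "drug_response", dr_gid)
    el <- el_edge(el, dr_gid, "compounds", compound_gid)
    if (!(compound_gid %in% linked)) {
      linked <- c(linked, compound_gid)
      el <- el_edge(el, compound_gid, "projects", project_gid)
    }
  }
  el
}

#' Load genotype-to-phenotype association records (JSON Lines)
#'
#' Each record wires an existing `Allele` (matched via its
#' `chromosome:start:ref:alt` key) to a `G2PAssociation` vertex with edges
#' to `Publication`, `Compound`, and `Phenotype` vertices. A record whose
#' allele key matches no allele in `graph` is skipped with a warning rather
#' than an error.
#'
#' @param path JSON Lines file; each record has `association_id`,
#'   `allele_key`, `compound_ids`, `publication_urls`, `phenotype`,
#'   `description`.
#' @param graph The graph holding already-loaded `Allele` vertices.
#' @return An element set; skipped allele keys are in attribute `"skipped"`.
#' @export
load_g2p <- function(path, graph) {
  stopifnot(inherits(graph, "evigraph"))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  el <- elements_new()
  skipped <- character(0)
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[[i]]))) next
    rec <- parse_jsonl_line(lines[[i]], path, i)
    if (is.null(rec$association_id) || is.null(rec$allele_key)) {
      stop(sprintf("%s line %d: record needs association_id and allele_key",
                   path, i), call. = FALSE)
    }
    compounds <- unlist(rec$compound_ids %||% list())
    pubs <- unlist(rec$publication_urls %||% list())
    if (length(compounds) == 0 && length(pubs) == 0) {
      stop(sprintf(
        "%s line %d: record needs compound_ids or publication_urls", path, i),
        call. = FALSE)
    }
    allele_gid <- paste0("Allele:", rec$allele_key)
    if (is.null(get_vertex(graph, allele_gid))) {
      warning(sprintf("%s line %d: allele_key '%s' matches no Allele; skipped",
                      path, i, rec$allele_key), call. = FALSE)
      skipped <- c(skipped, rec$allele_key)
      next
    }
    assoc_gid <- prefixed_gid(rec$association_id, "G2PAssociation")
    el <- el_vertex(el, assoc_gid, "G2PAssociation", list(
      description = rec$description %||% "",
      phenotype = rec$phenotype %||% ""
    ))
    el <- el_edge(el, allele_gid, "g2p_associations", assoc_gid)
    for (url in pubs) {
      pub_gid <- prefixed_gid(url, "Publication")
      el <- el_vertex(el, pub_gid, "Publication", list(url = url))
      el <- el_edge(el, assoc_gid, "publications", pub_gid)
    }
    for (cid in compounds) {
      compound_gid <- prefixed_gid(cid, "Compound")
      el <- el_vertex(el, compound_gid, "Compound")
      el <- el_edge(el, assoc_gid, "compounds", compound_gid)
    }
    if (!is.null(rec$phenotype) && nzchar(rec$phenotype)) {
      ph_gid <- prefixed_gid(rec$phenotype, "Phenotype")
      el <- el_vertex(el, ph_gid, "Phenotype", list(term = rec$phenotype))
      el <- el_edge(el, assoc_gid, "phenotypes", ph_gid)
    }
  }
  attr(el, "skipped") <- skipped
  el
}
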