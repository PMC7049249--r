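#' Graph schemas: allowed vertex labels and edge triples
#'
#' A schema declares the set of legal vertex labels and the set of legal
#' `(from_label, edge_label, to_label)` triples, optionally with required
#' property fields per label. The built-in cancer-genomics evidence-graph
#' schema models a cohort tree (Program, Project, Case, Sample, Aliquot)
#' connected to somatic callsets and alleles, gene and pathway annotations,
#' compounds and drug-response experiments, gene-expression payloads, and
#' literature-curated genotype-to-phenotype associations.
#'
#' @param vertex_labels Character vector of vertex type names.
#' @param edge_triples A data frame (or tibble) with columns `from`, `label`,
#'   `to`, or a list of 3-element character vectors.
#' @param required_fields Named list: label -> character vector of required
#'   field paths (dotted). May be empty.
#' @return An object of class `evigraph_schema`.
#' @export
schema_def <- function(vertex_labels = character(0),
                       edge_triples = NULL,
                       required_fields = list()) {
  vertex_labels <- as.character(vertex_labels)
  if (is.null(edge_triples)) {
    edge_triples <- tibble::tibble(from = character(0), label = character(0),
                                   to = character(0))
  } else if (is.list(edge_triples) && !is.data.frame(edge_triples)) {
    edge_triples <- tibble::tibble(
      from = vapply(edge_triples, function(t) as.character(t[[1]]), character(1)),
      label = vapply(edge_triples, function(t) as.character(t[[2]]), character(1)),
      to = vapply(edge_triples, function(t) as.character(t[[3]]), character(1))
    )
  } else {
    edge_triples <- tibble::as_tibble(edge_triples)[, c("from", "label", "to")]
  }
  bad <- setdiff(unique(c(edge_triples$from, edge_triples$to)), vertex_labels)
  if (length(bad) > 0) {
    stop(sprintf("edge triples reference undeclared vertex label(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  structure(list(vertex_labels = vertex_labels, edge_triples = edge_triples,
                 required_fields = required_fields),
            class = "evigraph_schema")
}

#' @export
print.evigraph_schema <- function(x, ...) {
  cat(sprintf("<evigraph schema: %d vertex labels, %d edge triples>\n",
              length(x$vertex_labels), nrow(x$edge_triples)))
  invisible(x)
}

#' The built-in evidence-graph schema
#'
#' @return The packaged [`schema_def()`] covering the cohort tree and all
#'   edge labels used by the cookbook traversals.
#' @export
#' @examples
#' s <- bmeg_schema()
#' has_triple(s, "SomaticCallset", "alleles", "Allele")
bmeg_schema <- function() {
  path <- system.file("extdata", "bmeg_schema.yaml", package = "evigraph",
                      mustWork = TRUE)
  load_schema(path)
}

#' Load / write a schema file (YAML or JSON)
#'
#' @param path File path; format chosen by extension (`.json` vs YAML).
#' @return `load_schema()`: an `evigraph_schema`. `write_schema()`: the path,
#'   invisibly.
#' @export
load_schema <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  raw <- raw %||% list()
  triples <- raw$edge_triples %||% list()
  schema_def(
    vertex_labels = unlist(raw$vertex_labels %||% character(0)),
    edge_triples = lapply(triples, unlist),
    required_fields = lapply(raw$required_fields %||% list(), unlist)
  )
}

#' @rdname load_schema
#' @param schema An `evigraph_schema`.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "evigraph_schema"))
  doc <- list(
    vertex_labels = as.list(schema$vertex_labels),
    edge_triples = lapply(seq_len(nrow(schema$edge_triples)), function(i) {
      list(schema$edge_triples$from[[i]], schema$edge_triples$label[[i]],
           schema$edge_triples$to[[i]])
    }),
    required_fields = lapply(schema$required_fields, as.list)
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(doc, path)
  }
  invisible(path)
}

#' @rdname bmeg_schema
#' @param schema An `evigraph_schema`.
#' @param from,label,to Labels of a candidate edge triple.
#' @export
has_triple <- function(schema, from, label, to) {
  any(schema$edge_triples$from == from &
        schema$edge_triples$label == label &
        schema$edge_triples$to == to)
}

#' Validate a graph against a schema
#'
#' Violations are data, not errors: the return value is a tibble with one
#' row per violation and columns `kind` (one of `unknown_vertex_label`,
#' `dangling_edge`, `illegal_edge_triple`, `duplicate_gid`,
#' `missing_required_field`), `subject_gid`, and `message`. Vertices are
#' checked first, then edges, each in insertion order, so the report is
#' deterministic. A schema-clean graph yields a zero-row tibble.
#'
#' @param graph An [`evigraph`][graph_new] (finalized or not: dangling edges
#'   are reported as violations rather than refused).
#' @param schema An [`evigraph_schema`][schema_def].
#' @return A tibble of violations (zero rows if conformant).
#' @export
validate_against_schema <- function(graph, schema = bmeg_schema()) {
  stopifnot(inherits(graph, "evigraph"), inherits(schema, "evigraph_schema"))
  kinds <- character(0); subjects <- character(0); messages <- character(0)
  note <- function(kind, gid, msg) {
    kinds <<- c(kinds, kind); subjects <<- c(subjects, gid)
    messages <<- c(messages, msg)
  }
  check_required <- function(label, gid, data) {
    req <- schema$required_fields[[label]]
    for (fp in req %||% character(0)) {
      if (is.null(resolve_in_map(data, strsplit(fp, ".", fixed = TRUE)[[1]]))) {
        note("missing_required_field", gid,
             sprintf("%s '%s' lacks required field '%s'", label, gid, fp))
      }
    }
  }
  for (gid in graph$v_order) {
    v <- get(gid, envir = graph$v)
    if (!(v$label %in% schema$vertex_labels)) {
      note("unknown_vertex_label", gid,
           sprintf("vertex '%s' has unknown label '%s'", gid, v$label))
    } else {
      check_required(v$label, gid, v$data)
    }
    if (exists(gid, envir = graph$e, inherits = FALSE)) {
      note("duplicate_gid", gid,
           sprintf("gid '%s' names both a vertex and an edge", gid))
    }
  }
  for (gid in graph$e_order) {
    e <- get(gid, envir = graph$e)
    vf <- get_vertex(graph, e$from)
    vt <- get_vertex(graph, e$to)
    if (is.null(vf) || is.null(vt)) {
      note("dangling_edge", gid,
           sprintf("edge '%s' references missing vertex '%s'", gid,
                   if (is.null(vf)) e$from else e$to))
      next
    }
    if (!has_triple(schema, vf$label, e$label, vt$label)) {
      note("illegal_edge_triple", gid,
           sprintf("edge '%s': (%s)-[%s]->(%s) is not a legal triple", gid,
                   vf$label, e$label, vt$label))
    }
  }
  tibble::tibble(kind = kinds, subject_gid = subjects, message = messages)
}
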