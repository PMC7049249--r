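# JSON Lines persistence. One JSON object per line, UTF-8, "\n"-terminated.
# Vertices and edges live in separate files; a single-file dialect carrying a
# "type" discriminator per record is accepted on read.

value_to_json <- function(x) {
  jsonlite::toJSON(x, auto_unbox = TRUE, null = "null", na = "null",
                   digits = NA)
}

#' Write a graph to vertex/edge JSON Lines files
#'
#' Records are written in insertion order, so the same graph always produces
#' byte-identical files and re-loading reproduces the graph exactly.
#'
#' @param graph A finalized [`evigraph`][graph_new].
#' @param vertex_path,edge_path Output file paths.
#' @return Invisibly, `c(vertices = n, edges = n)`.
#' @export
write_graph_jsonl <- function(graph, vertex_path, edge_path) {
  stopifnot(inherits(graph, "evigraph"))
  vcon <- file(vertex_path, open = "wb")
  on.exit(close(vcon), add = TRUE)
  for (gid in graph$v_order) {
    v <- get(gid, envir = graph$v)
    line <- value_to_json(list(gid = v$gid, label = v$label, data = v$data))
    writeLines(line, vcon, useBytes = TRUE)
  }
  econ <- file(edge_path, open = "wb")
  on.exit(close(econ), add = TRUE)
  for (gid in graph$e_order) {
    e <- get(gid, envir = graph$e)
    line <- value_to_json(list(gid = e$gid, from = e$from, to = e$to,
                               label = e$label, data = e$data))
    writeLines(line, econ, useBytes = TRUE)
  }
  invisible(c(vertices = n_vertices(graph), edges = n_edges(graph)))
}

parse_jsonl_line <- function(line, path, lineno) {
  rec <- tryCatch(
    jsonlite::fromJSON(line, simplifyVector = FALSE),
    error = function(e) {
      stop(sprintf("%s line %d: malformed JSON (%s)", path, lineno,
                   conditionMessage(e)), call. = FALSE)
    }
  )
  if (!is.list(rec) || is.null(names(rec))) {
    stop(sprintf("%s line %d: record is not a JSON object", path, lineno),
         call. = FALSE)
  }
  rec
}

ingest_record <- function(graph, rec, kind, path, lineno) {
  if (!is.null(rec$type)) kind <- rec$type
  if (identical(kind, "vertex")) {
    if (is.null(rec$gid) || is.null(rec$label)) {
      stop(sprintf("%s line %d: vertex record needs gid and label",
                   path, lineno), call. = FALSE)
    }
    add_vertex(graph, rec$gid, rec$label, rec$data %||% list())
  } else if (identical(kind, "edge")) {
    if (is.null(rec$from) || is.null(rec$to) || is.null(rec$label)) {
      stop(sprintf("%s line %d: edge record needs from, to and label",
                   path, lineno), call. = FALSE)
    }
    add_edge(graph, rec$from, rec$label, rec$to, rec$data %||% list(),
             gid = rec$gid)
  } else {
    stop(sprintf("%s line %d: unknown record type '%s'", path, lineno, kind),
         call. = FALSE)
  }
  invisible(graph)
}

#' Load a graph from vertex/edge JSON Lines files
#'
#' Line order defines insertion order. Duplicate gids and edges whose
#' endpoints never appear are errors (the graph is [finalize()]d before
#' return); a malformed line errors with its line number.
#'
#' @param vertex_path,edge_path Input file paths. Either file may also use
#'   the single-file dialect where each record carries a `"type"` field.
#' @return A finalized [`evigraph`][graph_new].
#' @export
load_graph_jsonl <- function(vertex_path, edge_path) {
  graph <- graph_new()
  for (spec in list(list(path = vertex_path, kind = "vertex"),
                    list(path = edge_path, kind = "edge"))) {
    if (!file.exists(spec$path)) {
      stop(sprintf("file not found: %s", spec$path), call. = FALSE)
    }
    lines <- readLines(spec$path, encoding = "UTF-8", warn = FALSE)
    for (i in seq_along(lines)) {
      if (!nzchar(trimws(lines[[i]]))) next
      rec <- parse_jsonl_line(lines[[i]], spec$path, i)
      tryCatch(
        ingest_record(graph, rec, spec$kind, spec$path, i),
        error = function(e) {
          msg <- conditionMessage(e)
          if (grepl("^.* line [0-9]+:", msg)) stop(e)
          stop(sprintf("%s line %d: %s", spec$path, i, msg), call. = FALSE)
        }
      )
    }
  }
  finalize(graph)
  graph
}

`%||%` <- function(a, b) if (is.null(a)) b else a
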