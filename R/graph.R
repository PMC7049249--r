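#' Create an empty property graph
#'
#' An `evigraph` is an in-memory directed property graph: vertices and edges
#' carry arbitrarily nested property maps (`data`), and iteration over
#' vertices, edges, and per-vertex adjacency lists always follows insertion
#' order, so every downstream computation is reproducible. The object has
#' reference semantics (it is an environment, like a connection or an R6
#' object): `add_vertex()` and `add_edge()` modify it in place and return it
#' invisibly, so calls can still be chained with the pipe.
#'
#' Property values follow the JSON data model: scalars (character, numeric,
#' logical, `NULL`), ordered unnamed lists (arrays), and named lists (maps),
#' nested to any depth. Dense payloads — e.g. a per-aliquot map of thousands
#' of gene-expression values — are ordinary property values.
#'
#' @return An object of class `evigraph`.
#' @seealso [add_vertex()], [add_edge()], [finalize()], [load_graph_jsonl()]
#' @export
#' @examples
#' g <- graph_new()
#' add_vertex(g, "Gene:ENSG1", "Gene")
#' n_vertices(g)
graph_new <- function() {
  g <- new.env(parent = emptyenv())
  g$v <- new.env(parent = emptyenv())        # gid -> vertex record
  g$e <- new.env(parent = emptyenv())        # gid -> edge record
  g$v_order <- character(0)
  g$e_order <- character(0)
  g$e_ord <- new.env(parent = emptyenv())    # gid -> insertion ordinal
  g$out_idx <- new.env(parent = emptyenv())  # "gid\x1flabel" -> edge gids
  g$in_idx <- new.env(parent = emptyenv())
  g$out_all <- new.env(parent = emptyenv())  # gid -> edge gids (any label)
  g$in_all <- new.env(parent = emptyenv())
  g$finalized <- FALSE
  class(g) <- "evigraph"
  g
}

idx_key <- function(gid, label) paste(gid, label, sep = "\x1f")

as_data_map <- function(data) {
  if (is.null(data) || length(data) == 0) {
    return(structure(list(), names = character(0)))
  }
  if (!is.list(data) || is.null(names(data)) || any(names(data) == "")) {
    stop("property data must be a named list (a JSON object)", call. = FALSE)
  }
  canon_value(data)
}

# Canonical in-memory form of a property value: all numbers are doubles
# (JSON does not distinguish 12 from 12.0, so write-then-load must not
# either), lists and maps recurse.
canon_value <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.integer(x)) return(as.numeric(x))
  if (is.list(x)) return(lapply(x, canon_value))
  x
}

#' Add a vertex to a graph
#'
#' @param graph An [`evigraph`][graph_new] object.
#' @param gid Non-empty global identifier, unique among vertices.
#' @param label Non-empty vertex type name (e.g. `"Case"`).
#' @param data Named list of property values (may be nested).
#' @return The graph, invisibly (modified in place).
#' @export
add_vertex <- function(graph, gid, label, data = list()) {
  stopifnot(inherits(graph, "evigraph"))
  if (!is.character(gid) || length(gid) != 1 || is.na(gid) || !nzchar(gid)) {
    stop("vertex gid must be a non-empty string", call. = FALSE)
  }
  if (!is.character(label) || length(label) != 1 || !nzchar(label)) {
    stop("vertex label must be a non-empty string", call. = FALSE)
  }
  if (exists(gid, envir = graph$v, inherits = FALSE)) {
    stop(sprintf("duplicate vertex gid: '%s'", gid), call. = FALSE)
  }
  assign(gid, list(gid = gid, label = label, data = as_data_map(data)),
         envir = graph$v)
  graph$v_order <- c(graph$v_order, gid)
  graph$finalized <- FALSE
  invisible(graph)
}

#' Add an edge to a graph
#'
#' Endpoints need not exist yet; [finalize()] verifies them. The edge is
#' entered into the out-index of `from` and the in-index of `to` under its
#' label, preserving insertion order.
#'
#' @inheritParams add_vertex
#' @param from,to Endpoint vertex gids.
#' @param gid Edge gid; if `NULL`, synthesized as
#'   `"(from)--(label)->(to)#(ordinal)"` for determinism.
#' @export
add_edge <- function(graph, from, label, to, data = list(), gid = NULL) {
  stopifnot(inherits(graph, "evigraph"))
  if (is.null(gid)) {
    gid <- sprintf("(%s)--(%s)->(%s)#%d", from, label, to,
                   length(graph$e_order) + 1L)
  }
  if (!is.character(gid) || length(gid) != 1 || !nzchar(gid)) {
    stop("edge gid must be a non-empty string", call. = FALSE)
  }
  for (fld in list(from = from, to = to, label = label)) {
    if (!is.character(fld) || length(fld) != 1 || !nzchar(fld)) {
      stop("edge from/to/label must be non-empty strings", call. = FALSE)
    }
  }
  if (exists(gid, envir = graph$e, inherits = FALSE)) {
    stop(sprintf("duplicate edge gid: '%s'", gid), call. = FALSE)
  }
  assign(gid, list(gid = gid, from = from, to = to, label = label,
                   data = as_data_map(data)), envir = graph$e)
  ord <- length(graph$e_order) + 1L
  graph$e_order <- c(graph$e_order, gid)
  assign(gid, ord, envir = graph$e_ord)
  append_idx(graph$out_idx, idx_key(from, label), gid)
  append_idx(graph$in_idx, idx_key(to, label), gid)
  append_idx(graph$out_all, from, gid)
  append_idx(graph$in_all, to, gid)
  graph$finalized <- FALSE
  invisible(graph)
}

append_idx <- function(env, key, gid) {
  cur <- if (exists(key, envir = env, inherits = FALSE)) {
    get(key, envir = env, inherits = FALSE)
  } else {
    character(0)
  }
  assign(key, c(cur, gid), envir = env)
}

#' Verify edge endpoints and mark the graph queryable
#'
#' @inheritParams add_vertex
#' @return The graph, invisibly. Errors listing the offending edge gids if
#'   any edge endpoint does not resolve to a vertex.
#' @export
finalize <- function(graph) {
  stopifnot(inherits(graph, "evigraph"))
  dangling <- character(0)
  for (gid in graph$e_order) {
    e <- get(gid, envir = graph$e, inherits = FALSE)
    if (!exists(e$from, envir = graph$v, inherits = FALSE) ||
        !exists(e$to, envir = graph$v, inherits = FALSE)) {
      dangling <- c(dangling, gid)
    }
  }
  if (length(dangling) > 0) {
    stop(sprintf("dangling edge endpoint(s) in: %s",
                 paste(dangling, collapse = ", ")), call. = FALSE)
  }
  graph$finalized <- TRUE
  invisible(graph)
}

get_vertex <- function(graph, gid) {
  if (exists(gid, envir = graph$v, inherits = FALSE)) {
    get(gid, envir = graph$v, inherits = FALSE)
  } else {
    NULL
  }
}

get_edge <- function(graph, gid) {
  if (exists(gid, envir = graph$e, inherits = FALSE)) {
    get(gid, envir = graph$e, inherits = FALSE)
  } else {
    NULL
  }
}

#' @export
#' @rdname graph_new
#' @param graph An `evigraph` object.
n_vertices <- function(graph) length(graph$v_order)

#' @export
#' @rdname graph_new
n_edges <- function(graph) length(graph$e_order)

# Edge gids out of / into a vertex, restricted to `labels` (character(0) =
# any label), in global edge-insertion order.
adjacent_edges <- function(graph, gid, labels, direction = c("out", "in")) {
  direction <- match.arg(direction)
  if (length(labels) == 0) {
    env <- if (direction == "out") graph$out_all else graph$in_all
    if (exists(gid, envir = env, inherits = FALSE)) {
      get(gid, envir = env, inherits = FALSE)
    } else {
      character(0)
    }
  } else {
    env <- if (direction == "out") graph$out_idx else graph$in_idx
    hits <- lapply(labels, function(l) {
      k <- idx_key(gid, l)
      if (exists(k, envir = env, inherits = FALSE)) {
        get(k, envir = env, inherits = FALSE)
      } else {
        character(0)
      }
    })
    hits <- unlist(hits, use.names = FALSE)
    if (length(hits) > 1) {
      ords <- vapply(hits, function(x) get(x, envir = graph$e_ord), integer(1))
      hits[order(ords)]
    } else {
      hits
    }
  }
}

#' Vertex and edge tables of a graph
#'
#' @param graph An [`evigraph`][graph_new] object.
#' @return A tibble in insertion order: `vertices()` with columns `gid`,
#'   `label`, `data` (list column of property maps); `edges()` additionally
#'   with `from` and `to`.
#' @export
vertices <- function(graph) {
  recs <- lapply(graph$v_order, function(gid) get(gid, envir = graph$v))
  tibble::tibble(
    gid = vapply(recs, `[[`, character(1), "gid"),
    label = vapply(recs, `[[`, character(1), "label"),
    data = lapply(recs, `[[`, "data")
  )
}

#' @rdname vertices
#' @export
edges <- function(graph) {
  recs <- lapply(graph$e_order, function(gid) get(gid, envir = graph$e))
  tibble::tibble(
    gid = vapply(recs, `[[`, character(1), "gid"),
    from = vapply(recs, `[[`, character(1), "from"),
    label = vapply(recs, `[[`, character(1), "label"),
    to = vapply(recs, `[[`, character(1), "to"),
    data = lapply(recs, `[[`, "data")
  )
}

#' @export
print.evigraph <- function(x, ...) {
  cat(sprintf("<evigraph: %d vertices, %d edges%s>\n",
              n_vertices(x), n_edges(x),
              if (x$finalized) ", finalized" else ""))
  labs <- table(vapply(x$v_order, function(g) get(g, envir = x$v)$label,
                       character(1)))
  if (length(labs) > 0) {
    cat("  vertex labels:",
        paste(sprintf("%s (%d)", names(labs), as.integer(labs)),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
format.evigraph <- function(x, ...) {
  sprintf("<evigraph: %d vertices, %d edges>", n_vertices(x), n_edges(x))
}
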