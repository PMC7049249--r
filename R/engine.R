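# Traversal execution. A traveler is a cursor on one element (vertex or
# edge) plus named mark snapshots taken by as(); out()/outE()/in()/inE()
# fan travelers out along matching edges in edge-insertion order, so the
# whole traversal is deterministic for a fixed graph.

new_traveler <- function(kind, gid, marks = list()) {
  list(cur = list(kind = kind, gid = gid), marks = marks)
}

#' Query result container
#'
#' A single query yields rows of exactly one kind: element rows (the final
#' travelers' elements), render tuples, a count, or a term-aggregation
#' result. `as_tibble()` / `tidy()` convert any kind to a tibble.
#'
#' @name gq_result
NULL

new_result <- function(kind, rows) {
  structure(list(kind = kind, rows = rows), class = "gq_result")
}

result_elements <- function(elems) {
  new_result("elements", tibble::tibble(
    gid = vapply(elems, `[[`, character(1), "gid"),
    label = vapply(elems, `[[`, character(1), "label"),
    data = lapply(elems, `[[`, "data")
  ))
}

result_render <- function(tuples, template = NULL) {
  r <- new_result("render", tuples)
  r$template <- template
  r
}

result_count <- function(n) new_result("count", as.integer(n))

# buckets: named list agg name -> list of list(key=, count=)
result_aggregation <- function(buckets) {
  nm <- rep(names(buckets), vapply(buckets, length, integer(1)))
  keys <- unlist(lapply(buckets, function(b) {
    vapply(b, `[[`, character(1), "key")
  }), use.names = FALSE)
  counts <- unlist(lapply(buckets, function(b) {
    vapply(b, function(x) as.integer(x$count), integer(1))
  }), use.names = FALSE)
  new_result("aggregation", tibble::tibble(
    name = as.character(nm %||% character(0)),
    key = as.character(keys %||% character(0)),
    count = as.integer(counts %||% integer(0))
  ))
}

# Multiset counts of non-null values, keys as text, sorted by count
# descending then key ascending (radix: byte order, locale-independent).
sort_buckets <- function(keys) {
  if (length(keys) == 0) {
    return(list())
  }
  tab <- table(keys)
  k <- names(tab)
  n <- as.integer(tab)
  ord <- order(-n, k, method = "radix")
  lapply(ord, function(i) list(key = k[[i]], count = n[[i]]))
}

#' Apply one traversal step to a stream of travelers
#'
#' Non-terminal step semantics: `V(gids)` emits one traveler per named
#' vertex in the given order (all vertices in insertion order when empty);
#' `hasLabel`/`hasId`/`has` filter, preserving order; `out(labels)` replaces
#' each traveler with one per matching out-edge positioned on the
#' destination vertex, ordered by edge insertion (`outE` lands on the edge
#' itself; `in`/`inE` mirror via the in-index; an empty label set matches
#' any label); `as(name)` snapshots the current element; `select(name)`
#' repositions to the marked element; `distinct(fields)` keeps the first
#' traveler per distinct tuple of resolved values; `limit(n)` truncates.
#'
#' @param graph A finalized [`evigraph`][graph_new].
#' @param travelers List of travelers.
#' @param step A step from a compiled [`gq_query`][parse_query].
#' @return The resulting list of travelers.
#' @export
apply_step <- function(graph, travelers, step) {
  switch(step$op,
    V = {
      gids <- if (length(step$args) == 0) graph$v_order else step$args
      gids <- gids[vapply(gids, function(g) {
        !is.null(get_vertex(graph, g))
      }, logical(1))]
      lapply(gids, function(g) new_traveler("vertex", g))
    },
    hasLabel = Filter(function(t) {
      element_of(graph, t$cur)$label %in% step$args
    }, travelers),
    hasId = Filter(function(t) t$cur$gid %in% step$args, travelers),
    has = Filter(function(t) {
      isTRUE(eval_condition(step$cond, t, graph))
    }, travelers),
    out = traverse(graph, travelers, step, "out", land_on = "vertex"),
    `in` = traverse(graph, travelers, step, "in", land_on = "vertex"),
    outE = traverse(graph, travelers, step, "out", land_on = "edge"),
    inE = traverse(graph, travelers, step, "in", land_on = "edge"),
    as = lapply(travelers, function(t) {
      t$marks[[step$name]] <- t$cur
      t
    }),
    select = lapply(travelers, function(t) {
      m <- t$marks[[step$name]]
      if (is.null(m)) {
        stop(sprintf("select('%s'): mark never set", step$name), call. = FALSE)
      }
      t$cur <- m
      t
    }),
    distinct = {
      seen <- new.env(parent = emptyenv())
      Filter(function(t) {
        key <- distinct_key(t, step$fields, graph)
        if (exists(key, envir = seen, inherits = FALSE)) {
          FALSE
        } else {
          assign(key, TRUE, envir = seen)
          TRUE
        }
      }, travelers)
    },
    limit = utils::head(travelers, n = step$n),
    stop(sprintf("step '%s' is terminal and cannot be applied mid-stream",
                 step$op), call. = FALSE)
  )
}

traverse <- function(graph, travelers, step, direction, land_on) {
  out <- lapply(travelers, function(t) {
    if (t$cur$kind != "vertex") {
      stop(sprintf(
        "step '%s%s' requires travelers positioned on a vertex, not an edge",
        if (direction == "out") "out" else "in",
        if (land_on == "edge") "E" else ""), call. = FALSE)
    }
    egids <- adjacent_edges(graph, t$cur$gid, step$args, direction)
    lapply(egids, function(eg) {
      if (land_on == "edge") {
        list(cur = list(kind = "edge", gid = eg), marks = t$marks)
      } else {
        e <- get_edge(graph, eg)
        dest <- if (direction == "out") e$to else e$from
        list(cur = list(kind = "vertex", gid = dest), marks = t$marks)
      }
    })
  })
  unlist(out, recursive = FALSE) %||% list()
}

distinct_key <- function(traveler, fields, graph) {
  parts <- vapply(fields, function(fp) {
    v <- resolve_field(traveler, fp, graph)
    if (is.null(v)) "\x01null" else term_key(v)
  }, character(1))
  paste(parts, collapse = "\x1f")
}

#' Terminal term aggregation over a traveler stream
#'
#' For each named aggregation, buckets are the multiset counts of the
#' non-null resolved values of its field, converted to text keys, sorted by
#' count descending with ties broken by key ascending. Travelers whose field
#' resolves to null are skipped, so bucket counts sum to at most the
#' traveler count.
#'
#' @param travelers List of travelers at the terminal position.
#' @param aggs List of `list(name, field)` term aggregations.
#' @param graph The graph.
#' @return An aggregation [`gq_result`].
#' @export
aggregate_terms <- function(travelers, aggs, graph) {
  buckets <- lapply(aggs, function(a) {
    keys <- vapply(travelers, function(t) {
      term_key(resolve_field(t, a$field, graph))
    }, character(1))
    sort_buckets(keys[!is.na(keys)])
  })
  names(buckets) <- vapply(aggs, `[[`, character(1), "name")
  result_aggregation(buckets)
}

#' Terminal render over a traveler stream
#'
#' One tuple per traveler in stream order; each position holds the resolved
#' value of the corresponding template path, or `NULL` if missing. Nested
#' values (e.g. a dense expression-values map) pass through unflattened.
#'
#' @param travelers List of travelers.
#' @param template List of parsed field paths (or path strings).
#' @param graph The graph.
#' @return A render [`gq_result`]; `$rows` is a list of unnamed tuples.
#' @export
render_rows <- function(travelers, template, graph) {
  template <- lapply(template, function(fp) {
    if (is.character(fp)) parse_field_path(fp) else fp
  })
  tuples <- lapply(travelers, function(t) {
    lapply(template, function(fp) resolve_field(t, fp, graph))
  })
  result_render(tuples, vapply(template, `[[`, character(1), "text"))
}

#' Execute a query against a graph
#'
#' Folds [apply_step()] over the step list starting from `V`; a terminal
#' `render`/`aggregate`/`count` shapes the output, and a query with no
#' terminal step emits element rows for the final travelers. Output is
#' deterministic for a fixed graph.
#'
#' @param graph A finalized [`evigraph`][graph_new].
#' @param query A [`parse_query()`] result (compiled on the fly if needed),
#'   or a raw query document.
#' @return A [`gq_result`].
#' @export
#' @examples
#' g <- graph_new()
#' add_vertex(g, "Pathway:P1", "Pathway")
#' add_vertex(g, "ENSG1", "Gene")
#' add_edge(g, "Pathway:P1", "genes", "ENSG1")
#' finalize(g)
#' execute(g, list(list(op = "V"), list(op = "count")))
execute <- function(graph, query) {
  stopifnot(inherits(graph, "evigraph"))
  if (!inherits(query, "gq_query")) query <- parse_query(query)
  if (!isTRUE(query$compiled)) query <- compile_query(query)
  if (!isTRUE(graph$finalized)) {
    stop("graph must be finalized before querying", call. = FALSE)
  }
  travelers <- list()
  for (step in query$steps) {
    if (step$op == "count") {
      return(result_count(length(travelers)))
    } else if (step$op == "aggregate") {
      return(aggregate_terms(travelers, step$aggs, graph))
    } else if (step$op == "render") {
      return(render_rows(travelers, step$fields, graph))
    }
    travelers <- apply_step(graph, travelers, step)
  }
  result_elements(lapply(travelers, function(t) element_of(graph, t$cur)))
}

#' @export
print.gq_result <- function(x, ...) {
  cat(sprintf("<gq_result: %s>\n", x$kind))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}
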