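# Brute-force reference interpreter: enumerates all root-to-end paths by
# naive recursion over materialized traveler lists, scanning the full edge
# table for every hop instead of using adjacency indices. It exists purely
# as a differential-test oracle for execute() on small graphs (<= ~100
# vertices); filtering, distinct, aggregation and ordering are re-derived
# here from first principles.

bf_edges_touching <- function(graph, vgid, labels, direction) {
  # full scan of the edge table in insertion order, no indices
  hits <- character(0)
  for (eg in graph$e_order) {
    e <- get(eg, envir = graph$e)
    anchor <- if (direction == "out") e$from else e$to
    if (anchor == vgid && (length(labels) == 0 || e$label %in% labels)) {
      hits <- c(hits, eg)
    }
  }
  hits
}

bf_eval <- function(cond, traveler, graph) {
  if (cond$op %in% c("and", "or", "not")) {
    vals <- vapply(cond$children, bf_eval, logical(1), traveler = traveler,
                   graph = graph)
    if (cond$op == "and") return(all(vals))
    if (cond$op == "or") return(any(vals))
    return(!vals[[1]])
  }
  v <- resolve_field(traveler, cond$field, graph)
  lit <- cond$value
  num <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x)
  same <- function(a, b) {
    if (is.null(a) && is.null(b)) return(TRUE)
    if (is.null(a) || is.null(b)) return(FALSE)
    if (num(a) && num(b)) return(a == b)
    identical(unclass(a), unclass(b))
  }
  if (cond$op == "eq") return(same(v, lit))
  if (cond$op == "neq") return(!same(v, lit))
  if (cond$op %in% c("gt", "gte", "lt", "lte")) {
    if (!num(v) || !num(lit)) return(FALSE)
    return(switch(cond$op, gt = v > lit, gte = v >= lit,
                  lt = v < lit, lte = v <= lit))
  }
  if (cond$op == "contains") {
    if (!is.list(v) || !is.null(names(v))) return(FALSE)
    for (el in v) if (same(el, lit)) return(TRUE)
    return(FALSE)
  }
  if (cond$op == "within") {
    if (is.null(v) || !is.list(lit)) return(FALSE)
    for (el in lit) if (same(el, v)) return(TRUE)
    return(FALSE)
  }
  stop(sprintf("unknown condition op '%s'", cond$op), call. = FALSE)
}

bf_step <- function(graph, travelers, step) {
  op <- step$op
  if (op == "V") {
    gids <- if (length(step$args) == 0) graph$v_order else step$args
    out <- list()
    for (g in gids) {
      if (!is.null(get_vertex(graph, g))) {
        out[[length(out) + 1L]] <- new_traveler("vertex", g)
      }
    }
    return(out)
  }
  if (op %in% c("out", "in", "outE", "inE")) {
    direction <- if (op %in% c("out", "outE")) "out" else "in"
    land_edge <- op %in% c("outE", "inE")
    out <- list()
    for (t in travelers) {
      if (t$cur$kind != "vertex") {
        stop(sprintf(
          "step '%s' requires travelers positioned on a vertex, not an edge",
          op), call. = FALSE)
      }
      for (eg in bf_edges_touching(graph, t$cur$gid, step$args, direction)) {
        nt <- t
        if (land_edge) {
          nt$cur <- list(kind = "edge", gid = eg)
        } else {
          e <- get_edge(graph, eg)
          dest <- if (direction == "out") e$to else e$from
          nt$cur <- list(kind = "vertex", gid = dest)
        }
        out[[length(out) + 1L]] <- nt
      }
    }
    return(out)
  }
  out <- list()
  for (t in travelers) {
    keep <- switch(op,
      hasLabel = element_of(graph, t$cur)$label %in% step$args,
      hasId = t$cur$gid %in% step$args,
      has = isTRUE(bf_eval(step$cond, t, graph)),
      as = { t$marks[[step$name]] <- t$cur; TRUE },
      select = {
        m <- t$marks[[step$name]]
        if (is.null(m)) {
          stop(sprintf("select('%s'): mark never set", step$name),
               call. = FALSE)
        }
        t$cur <- m
        TRUE
      },
      TRUE)
    if (keep) out[[length(out) + 1L]] <- t
  }
  if (op == "distinct") {
    kept <- list()
    seen <- character(0)
    for (t in out) {
      parts <- vapply(step$fields, function(fp) {
        v <- resolve_field(t, fp, graph)
        if (is.null(v)) "\x01null" else term_key(v)
      }, character(1))
      key <- paste(parts, collapse = "\x1f")
      if (!(key %in% seen)) {
        seen <- c(seen, key)
        kept[[length(kept) + 1L]] <- t
      }
    }
    return(kept)
  }
  if (op == "limit") {
    n <- min(length(out), step$n)
    return(if (n == 0) list() else out[seq_len(n)])
  }
  out
}

#' Brute-force reference execution of a query
#'
#' A second, index-free interpreter of the same query language, intended as
#' a differential-test oracle on small graphs: every hop scans the whole
#' edge table, every intermediate traveler list is materialized, and
#' filtering, distinct, aggregation sorting and output shaping are
#' re-implemented independently of [execute()]'s streaming path. For any
#' graph and compiled query the two must return identical results, row
#' order included.
#'
#' @inheritParams execute
#' @return A [`gq_result`], elementwise-identical to `execute(graph, query)`.
#' @export
brute_force_execute <- function(graph, query) {
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
    }
    if (step$op == "aggregate") {
      out <- list()
      for (a in step$aggs) {
        keys <- character(0)
        for (t in travelers) {
          v <- resolve_field(t, a$field, graph)
          if (!is.null(v)) keys <- c(keys, term_key(v))
        }
        # multiset count then sort: count desc, key asc, byte order
        uk <- unique(keys)
        cnt <- vapply(uk, function(k) sum(keys == k), integer(1))
        ord <- order(-cnt, uk, method = "radix")
        buckets <- lapply(ord, function(i) {
          list(key = uk[[i]], count = cnt[[i]])
        })
        out <- c(out, stats::setNames(list(buckets), a$name))
      }
      return(result_aggregation(out))
    }
    if (step$op == "render") {
      tuples <- list()
      for (t in travelers) {
        tuples[[length(tuples) + 1L]] <-
          lapply(step$fields, function(fp) resolve_field(t, fp, graph))
      }
      return(result_render(tuples,
                           vapply(step$fields, `[[`, character(1), "text")))
    }
    travelers <- bf_step(graph, travelers, step)
  }
  result_elements(lapply(travelers, function(t) element_of(graph, t$cur)))
}
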