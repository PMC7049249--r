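# Query documents are ordered lists of step records {"op": name, "args": ...}.
# parse_query() turns a document (R list, JSON text, or a .json file path)
# into a Query; compile_query() validates the plan (V first, marks defined
# before use, nothing after a terminal step).

step_ops <- c("V", "hasLabel", "hasId", "has", "out", "in", "outE", "inE",
              "as", "select", "render", "distinct", "aggregate", "count",
              "limit")
terminal_ops <- c("render", "aggregate", "count")

as_chr_args <- function(args) {
  if (is.null(args)) return(character(0))
  out <- unlist(args, use.names = FALSE)
  if (is.null(out)) character(0) else as.character(out)
}

new_step <- function(op, args = NULL) {
  if (!(op %in% step_ops)) {
    stop(sprintf("unknown step '%s'", op), call. = FALSE)
  }
  step <- list(op = op)
  if (op %in% c("V", "hasLabel", "hasId", "out", "in", "outE", "inE")) {
    step$args <- as_chr_args(args)
    if (op %in% c("hasLabel", "hasId") && length(step$args) == 0) {
      stop(sprintf("step '%s' needs at least one argument", op), call. = FALSE)
    }
  } else if (op == "has") {
    step$cond <- parse_condition(args)
  } else if (op %in% c("as", "select")) {
    nm <- as_chr_args(args)
    if (length(nm) != 1 || !nzchar(nm)) {
      stop(sprintf("step '%s' takes exactly one mark name", op), call. = FALSE)
    }
    step$name <- nm
  } else if (op %in% c("render", "distinct")) {
    fields <- as_chr_args(args)
    if (length(fields) == 0) {
      stop(sprintf("step '%s' needs at least one field path", op),
           call. = FALSE)
    }
    step$fields <- lapply(fields, parse_field_path)
  } else if (op == "aggregate") {
    aggs <- args
    if (!is.null(aggs$name)) aggs <- list(aggs)   # single aggregation record
    if (length(aggs) == 0) {
      stop("step 'aggregate' needs at least one term aggregation",
           call. = FALSE)
    }
    step$aggs <- lapply(aggs, function(a) {
      if (is.null(a$name) || is.null(a$field)) {
        stop("term aggregation needs 'name' and 'field'", call. = FALSE)
      }
      list(name = as.character(a$name), field = parse_field_path(a$field))
    })
    nms <- vapply(step$aggs, `[[`, character(1), "name")
    if (anyDuplicated(nms)) {
      stop("aggregation names must be unique within one aggregate step",
           call. = FALSE)
    }
  } else if (op == "limit") {
    n <- unlist(args, use.names = FALSE)
    if (length(n) != 1 || !is.numeric(n) || is.na(n)) {
      stop("step 'limit' takes one number", call. = FALSE)
    }
    step$n <- as.numeric(n)
  }
  step
}

#' Parse a query document
#'
#' @param document One of: an R list of step records (each
#'   `list(op = ..., args = ...)`), a JSON string, or a path to a JSON file.
#' @return A `gq_query` object (ordered list of validated steps).
#' @export
#' @examples
#' q <- parse_query(list(
#'   list(op = "V", args = list()),
#'   list(op = "hasLabel", args = list("Pathway"))
#' ))
parse_query <- function(document) {
  if (is.character(document) && length(document) == 1) {
    # jsonlite reads a file path and parses literal JSON text alike
    document <- jsonlite::fromJSON(document, simplifyVector = FALSE)
  }
  if (!is.list(document) || length(document) == 0) {
    stop("query document must be a non-empty list of steps", call. = FALSE)
  }
  steps <- lapply(document, function(rec) {
    if (!is.list(rec) || is.null(rec$op)) {
      stop("each step record needs an 'op'", call. = FALSE)
    }
    new_step(rec$op, rec$args)
  })
  if (steps[[1]]$op != "V") {
    stop("the first step of a query must be V", call. = FALSE)
  }
  if (any(vapply(steps[-1], `[[`, character(1), "op") == "V")) {
    stop("V may appear only as the first step", call. = FALSE)
  }
  structure(list(steps = steps, compiled = FALSE), class = "gq_query")
}

collect_mark_refs <- function(step) {
  fps <- switch(step$op,
    render = step$fields,
    distinct = step$fields,
    aggregate = lapply(step$aggs, `[[`, "field"),
    has = condition_fields(step$cond),
    list()
  )
  marks <- vapply(fps, `[[`, character(1), "mark")
  unique(marks[nzchar(marks)])
}

condition_fields <- function(cond) {
  if (cond$op %in% node_ops) {
    unlist(lapply(cond$children, condition_fields), recursive = FALSE)
  } else {
    list(cond$field)
  }
}

#' Validate a parsed query plan
#'
#' Checks that mark references in `select`, `render`, `distinct`,
#' `aggregate`, and `has` are defined by a preceding `as`, that terminal
#' steps (`render`, `aggregate`, `count`) are not followed by further steps,
#' and that `limit` is non-negative.
#'
#' @param query A [`parse_query()`] result.
#' @return The query, annotated as compiled.
#' @export
compile_query <- function(query) {
  stopifnot(inherits(query, "gq_query"))
  defined <- character(0)
  n <- length(query$steps)
  for (i in seq_len(n)) {
    step <- query$steps[[i]]
    if (step$op %in% terminal_ops && i < n) {
      stop(sprintf("step '%s' after terminal step '%s'",
                   query$steps[[i + 1]]$op, step$op), call. = FALSE)
    }
    if (step$op == "as") defined <- union(defined, step$name)
    if (step$op == "select" && !(step$name %in% defined)) {
      stop(sprintf("select references undefined mark '%s'", step$name),
           call. = FALSE)
    }
    missing <- setdiff(collect_mark_refs(step), defined)
    if (length(missing) > 0) {
      stop(sprintf("step '%s' references undefined mark(s): %s", step$op,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    if (step$op == "limit" && step$n < 0) {
      stop("limit must be non-negative", call. = FALSE)
    }
  }
  query$compiled <- TRUE
  query
}

#' Serialize a query back to a step-record document
#'
#' @param query A `gq_query`.
#' @return A list of step records that round-trips through [parse_query()].
#' @export
query_to_doc <- function(query) {
  lapply(query$steps, function(step) {
    switch(step$op,
      V = , hasLabel = , hasId = , out = , `in` = , outE = , inE =
        list(op = step$op, args = as.list(step$args)),
      has = list(op = "has", args = condition_to_doc(step$cond)),
      as = , select = list(op = step$op, args = step$name),
      render = , distinct = list(op = step$op,
        args = lapply(step$fields, `[[`, "text")),
      aggregate = list(op = "aggregate", args = lapply(step$aggs, function(a) {
        list(name = a$name, field = a$field$text)
      })),
      count = list(op = "count"),
      limit = list(op = "limit", args = step$n)
    )
  })
}

#' @export
print.gq_query <- function(x, ...) {
  ops <- vapply(x$steps, function(s) {
    extra <- switch(s$op,
      V = , hasLabel = , hasId = , out = , `in` = , outE = , inE =
        paste(s$args, collapse = ", "),
      as = , select = s$name,
      render = , distinct = paste(vapply(s$fields, `[[`, character(1),
                                         "text"), collapse = ", "),
      aggregate = paste(vapply(s$aggs, `[[`, character(1), "name"),
                        collapse = ", "),
      limit = format(s$n),
      "")
    sprintf("%s(%s)", s$op, extra)
  }, character(1))
  cat("<gq_query> ", paste(ops, collapse = "."),
      if (x$compiled) " [compiled]" else "", "\n", sep = "")
  invisible(x)
}
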