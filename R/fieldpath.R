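# Field paths address values on the element a traveler currently occupies or
# on a marked element: "$mark.rest" starts from a mark, "$.rest" and bare
# paths from the current element. The first component may be the reserved
# "_gid" or "_label"; a leading "_data" addresses the property map
# explicitly; any other bare first key addresses the property map implicitly.

#' Parse a field path string
#'
#' @param text A path such as `"_gid"`, `"gdc_attributes.sample_type"`,
#'   `"$sample._gid"`, or `"$exp._data.values"`.
#' @return A list with `mark` (`""` = current element), `components`
#'   (character vector of keys), and `text` (the original string).
#' @export
parse_field_path <- function(text) {
  if (!is.character(text) || length(text) != 1 || !nzchar(text)) {
    stop("field path must be a non-empty string", call. = FALSE)
  }
  mark <- ""
  rest <- text
  if (startsWith(text, "$")) {
    dot <- regexpr(".", text, fixed = TRUE)
    if (dot == -1) {
      # "$mark" alone: the marked element itself (treated as its data map)
      mark <- substring(text, 2)
      rest <- "_data"
    } else {
      mark <- substring(text, 2, dot - 1)
      rest <- substring(text, dot + 1)
    }
  }
  comps <- strsplit(rest, ".", fixed = TRUE)[[1]]
  if (length(comps) == 0 || any(!nzchar(comps))) {
    stop(sprintf("malformed field path: '%s'", text), call. = FALSE)
  }
  reserved <- c("_gid", "_label", "_data")
  if (any(comps[-1] %in% c("_gid", "_label"))) {
    stop(sprintf("reserved key in non-leading position: '%s'", text),
         call. = FALSE)
  }
  if (comps[[1]] == "_data") {
    comps <- comps[-1]           # explicit property-map prefix
    attr(comps, "data") <- TRUE
  }
  structure(list(mark = mark, components = as.character(comps), text = text),
            class = "gq_field_path")
}

# Walk a property map by a vector of keys; any miss yields NULL.
resolve_in_map <- function(data, keys) {
  cur <- data
  for (k in keys) {
    if (!is.list(cur) || is.null(names(cur)) ||
        !(k %in% names(cur))) {
      return(NULL)
    }
    cur <- cur[[k]]
  }
  cur
}

#' Resolve a field path against a traveler
#'
#' `"_gid"` and `"_label"` resolve to the element's identifier and type; any
#' other components walk the element's property map. A missing key resolves
#' to `NULL`, never an error. A reference to a mark that was never set is an
#' error (normally caught at compile time).
#'
#' @param traveler A traveler (as produced during [execute()]).
#' @param path A [`parse_field_path()`] result or path string.
#' @param graph The graph the traveler walks.
#' @return The resolved property value, or `NULL`.
#' @export
resolve_field <- function(traveler, path, graph) {
  if (is.character(path)) path <- parse_field_path(path)
  ref <- if (identical(path$mark, "")) {
    traveler$cur
  } else {
    m <- traveler$marks[[path$mark]]
    if (is.null(m)) {
      stop(sprintf("reference to mark '%s' that was never set", path$mark),
           call. = FALSE)
    }
    m
  }
  elem <- element_of(graph, ref)
  comps <- path$components
  if (length(comps) == 0) return(elem$data)
  if (comps[[1]] == "_gid" && is.null(attr(comps, "data"))) {
    if (length(comps) > 1) return(NULL)
    return(elem$gid)
  }
  if (comps[[1]] == "_label" && is.null(attr(comps, "data"))) {
    if (length(comps) > 1) return(NULL)
    return(elem$label)
  }
  resolve_in_map(elem$data, comps)
}

element_of <- function(graph, ref) {
  if (ref$kind == "vertex") get_vertex(graph, ref$gid) else get_edge(graph, ref$gid)
}

# --- Conditions -------------------------------------------------------------

leaf_ops <- c("eq", "neq", "gt", "gte", "lt", "lte", "contains", "within")
node_ops <- c("and", "or", "not")

#' Build a filter condition
#'
#' Leaf conditions compare a resolved field to a literal; `and`, `or`, `not`
#' combine conditions. See [eval_condition()] for the exact semantics.
#'
#' @param op For `cond_leaf()`: one of `eq`, `neq`, `gt`, `gte`, `lt`, `lte`,
#'   `contains`, `within`. For `cond_node()`: `and`, `or`, or `not`.
#' @param field Field path string.
#' @param value Literal property value (for `within`: a list of candidates).
#' @return A condition object of class `gq_condition`.
#' @export
cond_leaf <- function(op, field, value) {
  if (!(op %in% leaf_ops)) stop(sprintf("unknown condition op '%s'", op),
                                call. = FALSE)
  structure(list(op = op, field = parse_field_path(field), value = value),
            class = "gq_condition")
}

#' @rdname cond_leaf
#' @param ... Child conditions.
#' @export
cond_node <- function(op, ...) {
  children <- list(...)
  if (length(children) == 1 && is.list(children[[1]]) &&
      !inherits(children[[1]], "gq_condition")) {
    children <- children[[1]]
  }
  if (!(op %in% node_ops)) stop(sprintf("unknown condition op '%s'", op),
                                call. = FALSE)
  if (op == "not" && length(children) != 1) {
    stop("'not' takes exactly one child condition", call. = FALSE)
  }
  if (op %in% c("and", "or") && length(children) < 1) {
    stop(sprintf("'%s' needs at least one child condition", op), call. = FALSE)
  }
  structure(list(op = op, children = children), class = "gq_condition")
}

parse_condition <- function(x) {
  if (inherits(x, "gq_condition")) return(x)
  if (!is.list(x) || is.null(x$op)) {
    stop("malformed condition document", call. = FALSE)
  }
  if (x$op %in% node_ops) {
    cond_node(x$op, lapply(x$children %||% list(), parse_condition))
  } else {
    if (is.null(x$field)) stop("leaf condition lacks a field", call. = FALSE)
    if (!("value" %in% names(x))) {
      stop("leaf condition lacks a value", call. = FALSE)
    }
    cond_leaf(x$op, x$field, x$value)
  }
}

condition_to_doc <- function(cond) {
  if (cond$op %in% node_ops) {
    list(op = cond$op, children = lapply(cond$children, condition_to_doc))
  } else {
    list(op = cond$op, field = cond$field$text, value = cond$value)
  }
}

is_num_scalar <- function(x) {
  (is.numeric(x) || is.integer(x)) && length(x) == 1 && !is.na(x)
}

value_equal <- function(a, b) {
  if (is.null(a) && is.null(b)) return(TRUE)
  if (is.null(a) || is.null(b)) return(FALSE)
  if (is_num_scalar(a) && is_num_scalar(b)) return(a == b)
  isTRUE(identical(unclass(a), unclass(b)))
}

#' Evaluate a condition for a traveler
#'
#' Total over heterogeneous property values: `eq`/`neq` compare the resolved
#' value to the literal (`eq` against an explicit `NULL` literal is true only
#' when the field is null); the order comparisons require both sides numeric
#' and are false otherwise; `contains` is true iff the value is a list (JSON
#' array) containing the literal — a scalar field yields false; `within` is
#' true iff the value is a member of the literal list. A null field makes
#' every leaf except `neq` false.
#'
#' @param cond A [`cond_leaf()`]/[`cond_node()`] condition.
#' @param traveler A traveler.
#' @param graph The graph.
#' @return `TRUE` or `FALSE`.
#' @export
eval_condition <- function(cond, traveler, graph) {
  if (cond$op %in% node_ops) {
    vals <- vapply(cond$children, eval_condition, logical(1),
                   traveler = traveler, graph = graph)
    return(switch(cond$op, and = all(vals), or = any(vals), not = !vals[[1]]))
  }
  v <- resolve_field(traveler, cond$field, graph)
  lit <- cond$value
  switch(cond$op,
    eq = value_equal(v, lit),
    neq = !value_equal(v, lit),
    gt = is_num_scalar(v) && is_num_scalar(lit) && v > lit,
    gte = is_num_scalar(v) && is_num_scalar(lit) && v >= lit,
    lt = is_num_scalar(v) && is_num_scalar(lit) && v < lit,
    lte = is_num_scalar(v) && is_num_scalar(lit) && v <= lit,
    contains = is.list(v) && is.null(names(v)) &&
      any(vapply(v, value_equal, logical(1), b = lit)),
    within = !is.null(v) && is.list(lit) &&
      any(vapply(lit, value_equal, logical(1), b = v))
  )
}

# Text key for term aggregation and distinct tuples: scalars by their
# canonical string form, composite values by compact JSON.
term_key <- function(v) {
  if (is.null(v)) return(NA_character_)
  if (is.character(v) && length(v) == 1) return(v)
  if (is.logical(v) && length(v) == 1) return(if (v) "true" else "false")
  if (is_num_scalar(v)) return(as.character(v))
  as.character(value_to_json(v))
}
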