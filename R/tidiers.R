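# Tidy interfaces: every result type converts to a tibble, and aggregation
# results plot as ranked bar charts.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Convert a query result to a tibble
#'
#' Element results give `gid`/`label`/`data` columns; render results one
#' column per template path (list columns where values are nested, unpacked
#' to atomic vectors where every value is a scalar of one type); count
#' results a single `n`; aggregation results `name`/`key`/`count`.
#'
#' @param x A [`gq_result`].
#' @param ... Unused.
#' @return A tibble.
#' @method as_tibble gq_result
#' @export
as_tibble.gq_result <- function(x, ...) {
  switch(x$kind,
    elements = x$rows,
    count = tibble::tibble(n = x$rows),
    aggregation = x$rows,
    render = render_to_tibble(x)
  )
}

render_to_tibble <- function(x) {
  k <- if (!is.null(x$template)) length(x$template) else {
    if (length(x$rows) > 0) length(x$rows[[1]]) else 0L
  }
  nms <- if (!is.null(x$template)) make.unique(x$template) else {
    paste0("value", seq_len(k))
  }
  cols <- lapply(seq_len(k), function(j) {
    col <- lapply(x$rows, `[[`, j)
    scalar <- vapply(col, function(v) {
      is.null(v) || (is.atomic(v) && length(v) == 1)
    }, logical(1))
    if (all(scalar)) {
      types <- unique(unlist(lapply(col, class)))
      if (length(types) <= 1 || identical(sort(types), c("integer", "numeric"))) {
        return(unlist(lapply(col, function(v) {
          if (is.null(v)) NA else v
        }), use.names = FALSE) %||% logical(0))
      }
    }
    col
  })
  names(cols) <- nms
  tibble::as_tibble(cols)
}

#' @method tidy gq_result
#' @export
tidy.gq_result <- function(x, ...) as_tibble(x, ...)

#' @method glance gq_result
#' @export
glance.gq_result <- function(x, ...) {
  tibble::tibble(
    kind = x$kind,
    n_rows = switch(x$kind,
      count = 1L,
      render = length(x$rows),
      nrow(x$rows))
  )
}

#' Plot a term-aggregation result as a ranked bar chart
#'
#' @param object An aggregation [`gq_result`].
#' @param top_n Keep at most this many buckets per aggregation.
#' @param ... Unused.
#' @return A ggplot object, faceted by aggregation name.
#' @method autoplot gq_result
#' @export
autoplot.gq_result <- function(object, top_n = 20, ...) {
  if (object$kind != "aggregation") {
    stop("autoplot is defined for aggregation results", call. = FALSE)
  }
  df <- object$rows |>
    dplyr::group_by(.data$name) |>
    dplyr::slice_head(n = top_n) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$count,
    y = stats::reorder(.data$key, .data$count)
  )) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~name, scales = "free") +
    ggplot2::labs(x = "travelers", y = NULL)
}

#' @importFrom rlang .data
NULL
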