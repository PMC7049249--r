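# On-disk fixtures: graph (v.jsonl / e.jsonl), recorded ground truth
# (groundtruth.json) and generator configuration (config.json), all
# plain-text and byte-stable for a fixed seed.

result_to_doc <- function(r) {
  switch(r$kind,
    count = list(kind = "count", value = r$rows),
    aggregation = {
      aggs <- list()
      for (nm in unique(r$rows$name)) {
        sub <- r$rows[r$rows$name == nm, ]
        aggs[[nm]] <- lapply(seq_len(nrow(sub)), function(i) {
          list(key = sub$key[[i]], count = sub$count[[i]])
        })
      }
      list(kind = "aggregation", names = as.list(unique(r$rows$name)),
           aggs = aggs)
    },
    render = list(kind = "render", template = as.list(r$template %||% list()),
                  rows = r$rows),
    elements = list(kind = "elements", rows = lapply(
      seq_len(nrow(r$rows)), function(i) {
        list(gid = r$rows$gid[[i]], label = r$rows$label[[i]],
             data = r$rows$data[[i]])
      }))
  )
}

doc_to_result <- function(d) {
  switch(d$kind,
    count = result_count(d$value),
    aggregation = {
      buckets <- lapply(d$aggs, function(b) {
        lapply(b, function(x) list(key = x$key, count = as.integer(x$count)))
      })
      # empty bucket lists drop out of JSON objects; restore declared names
      nms <- unlist(d$names %||% names(d$aggs))
      out <- stats::setNames(vector("list", length(nms)), nms)
      for (nm in nms) out[[nm]] <- buckets[[nm]] %||% list()
      result_aggregation(out)
    },
    render = result_render(
      lapply(d$rows, function(row) lapply(row, canon_value)),
      unlist(d$template) %||% NULL
    ),
    elements = result_elements(lapply(d$rows, function(x) {
      list(gid = x$gid, label = x$label, data = as_data_map(x$data))
    }))
  )
}

#' Serialize / read recorded ground truth
#'
#' @param gt An `evigraph_groundtruth` object.
#' @param path JSON file path.
#' @return `read_groundtruth()` returns the reconstructed object; values
#'   survive the round trip exactly (the generator emits JSON-stable
#'   numbers).
#' @export
write_groundtruth <- function(gt, path) {
  doc <- list(
    queries = lapply(unclass(gt), result_to_doc),
    inputs = attr(gt, "inputs"),
    stats = attr(gt, "stats")
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(as.character(value_to_json(doc)), con, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_groundtruth
#' @export
read_groundtruth <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  gt <- structure(lapply(doc$queries, doc_to_result),
                  class = "evigraph_groundtruth")
  attr(gt, "inputs") <- doc$inputs
  attr(gt, "stats") <- doc$stats
  gt
}

#' Write a complete synthetic fixture to a directory
#'
#' Generates the graph and ground truth for `config` and writes `v.jsonl`,
#' `e.jsonl`, `groundtruth.json`, and `config.json`. Two runs with the same
#' config produce byte-identical files.
#'
#' @param config A [synthetic_config()].
#' @param directory Output directory (created if needed).
#' @return Invisibly, the generated fixture (list with `graph`,
#'   `ground_truth`, `config`).
#' @export
write_fixture <- function(config = synthetic_config(), directory) {
  fx <- generate_bmeg(config)
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  write_graph_jsonl(fx$graph, file.path(directory, "v.jsonl"),
                    file.path(directory, "e.jsonl"))
  write_groundtruth(fx$ground_truth, file.path(directory, "groundtruth.json"))
  con <- file(file.path(directory, "config.json"), open = "wb")
  writeLines(as.character(value_to_json(unclass(config))), con,
             useBytes = TRUE)
  close(con)
  invisible(fx)
}

#' Load a fixture directory written by [write_fixture()]
#'
#' @param directory Fixture directory.
#' @return List with `graph` (finalized), `ground_truth`, and `config`.
#' @export
read_fixture <- function(directory) {
  cfgdoc <- jsonlite::fromJSON(file.path(directory, "config.json"),
                               simplifyVector = TRUE)
  cfg <- do.call(synthetic_config, cfgdoc)
  list(
    graph = load_graph_jsonl(file.path(directory, "v.jsonl"),
                             file.path(directory, "e.jsonl")),
    ground_truth = read_groundtruth(file.path(directory, "groundtruth.json")),
    config = cfg
  )
}
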