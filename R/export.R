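#' Write alignment solutions to TSV, SIF or GraphML
#'
#' TSV: one row per solution (rank, score, p-value, vertex list, typed
#' edge list).  SIF and GraphML (Cytoscape-readable) encode vertices as
#' `queryID|targetID` nodes with the edge type as relation/attribute.
#' Ordering is deterministic: decreasing score, ties by the
#' lexicographic vertex list.
#'
#' @param result A `netalign_result`.
#' @param path Output file path.
#' @param format `"tsv"`, `"sif"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_solutions <- function(result, path, format = c("tsv", "sif", "graphml")) {
  if (!format[1] %in% c("tsv", "sif", "graphml")) {
    abort(sprintf("unknown solutions format '%s'", format[1]))
  }
  format <- match.arg(format)
  res <- as_tibble(result)
  vname <- function(v) paste(v$query_protein, v$target_protein, sep = "|")
  edge_rows <- function(sol) {
    v <- sol$vertices[[1]]
    e <- sol$edges[[1]]
    idx <- match(c(e$from, e$to), v$vertex_id)
    tibble(
      from = vname(v)[idx[seq_len(nrow(e))]],
      to = vname(v)[idx[nrow(e) + seq_len(nrow(e))]],
      edge_type = e$edge_type,
      probability = e$probability
    )
  }
  if (format == "tsv") {
    rows <- map(seq_len(nrow(res)), function(i) {
      sol <- res[i, ]
      er <- edge_rows(sol)
      tibble(
        rank = sol$solution_id, score = sol$score, p_value = sol$p_value,
        vertices = paste(sort(vname(sol$vertices[[1]])), collapse = ","),
        edges = paste(
          sprintf("%s--%s[%s]", er$from, er$to, er$edge_type),
          collapse = ","
        )
      )
    })
    out <- bind_rows(rows)
    if (nrow(res) == 0) {
      out <- tibble(
        rank = integer(), score = double(), p_value = double(),
        vertices = character(), edges = character()
      )
    }
    readr::write_tsv(out, path)
    return(invisible(path))
  }
  # node-and-edge formats pool all solutions into one network
  all_edges <- bind_rows(map(seq_len(nrow(res)), \(i) edge_rows(res[i, ])))
  all_nodes <- unique(unlist(map(res$vertices, vname)))
  if (format == "sif") {
    lines <- if (nrow(all_edges) > 0) {
      paste(all_edges$from, all_edges$edge_type, all_edges$to, sep = "\t")
    } else {
      character(0)
    }
    readr::write_lines(c(lines, setdiff(all_nodes, c(all_edges$from, all_edges$to))), path)
  } else {
    g <- igraph::graph_from_data_frame(
      all_edges,
      directed = FALSE,
      vertices = data.frame(name = all_nodes %||% character(0))
    )
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Write a performance report to TSV
#'
#' @param report [evaluate_alignment()] output.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  readr::write_tsv(report, path)
  invisible(path)
}
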