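# run an expression with a private, seeded RNG stream, restoring the
# caller's .Random.seed afterwards so alignment runs are reproducible and
# side-effect free
with_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  )
  set.seed(seed)
  force(expr)
}

#' Align two protein interaction networks
#'
#' The full pipeline: build the initial alignment graph (conserved and,
#' optionally, likely-conserved edges over homolog-pair vertices), find
#' alignment seeds as connected components, extend the graph with gap and
#' mismatch edges between seeds, take the components of the extended
#' graph as alignment solutions, score them, and attach Monte-Carlo
#' permutation p-values.  Solution vertex sets are pairwise disjoint by
#' construction — no homolog pair belongs to two solutions.
#'
#' @param query_net,target_net [interactome()]s.
#' @param pairs Homolog pairs with `vertex_probability` (see
#'   [assign_vertex_probabilities()]) and, for likely-conserved
#'   prediction, `distance` (see [assign_distances()]).
#' @param cons_model Optional [fit_conservation_model()] fit.
#' @param params [align_params()].
#' @param seed Integer seed for the permutation backgrounds.
#' @param keep_insignificant Keep solutions with `p > p_threshold`
#'   (flagged, default `FALSE`).
#' @return A `netalign_result`: tibble with one row per solution (rank
#'   order by decreasing score), columns `solution_id`, `score`,
#'   `p_value`, `significant`, `n_vertices`, `n_edges` and list-columns
#'   `vertices`, `edges`.
#' @export
align_networks <- function(query_net, target_net, pairs, cons_model = NULL,
                           params = align_params(), seed = 1L,
                           keep_insignificant = FALSE) {
  stopifnot(inherits(query_net, "interactome"), inherits(target_net, "interactome"))
  graph <- build_initial_graph(query_net, target_net, pairs, cons_model, params)
  seeds <- alignment_components(graph)
  graph <- extend_graph(graph, seeds, query_net, target_net, params)
  comps <- alignment_components(graph)

  sols <- with_rng(seed, {
    pools <- probability_pools(
      query_net, target_net,
      pairs[pairs$query_protein %in% interactome_proteins(query_net) &
        pairs$target_protein %in% interactome_proteins(target_net), ],
      cons_model
    )
    map(comps, function(ids) {
      vs <- graph$vertices[graph$vertices$vertex_id %in% ids, ]
      es <- graph$edges[graph$edges$from %in% ids & graph$edges$to %in% ids, ]
      sol <- list(vertices = vs, edges = es)
      sol$score <- solution_score(sol, params$alpha)
      sol$p_value <- permutation_pvalue(
        sol, pools,
        alpha = params$alpha, n_random_scores = params$n_random_scores
      )
      sol
    })
  })

  res <- tibble(
    score = map_dbl(sols, "score"),
    p_value = map_dbl(sols, "p_value"),
    n_vertices = map_int(sols, \(s) nrow(s$vertices)),
    n_edges = map_int(sols, \(s) nrow(s$edges)),
    vertices = map(sols, "vertices"),
    edges = map(sols, "edges")
  ) |>
    mutate(
      significant = .data$p_value <= params$p_threshold,
      vertex_key = map_chr(.data$vertices, \(v) paste(
        v$query_protein, v$target_protein,
        sep = "|", collapse = ";"
      ))
    ) |>
    arrange(dplyr::desc(.data$score), .data$vertex_key) |>
    mutate(solution_id = row_number()) |>
    select(
      "solution_id", "score", "p_value", "significant",
      "n_vertices", "n_edges", "vertices", "edges"
    )
  if (!keep_insignificant) res <- filter(res, .data$significant)
  structure(res,
    class = c("netalign_result", class(tibble())),
    params = params, seed = seed,
    species = c(attr(query_net, "species_tag"), attr(target_net, "species_tag"))
  )
}

#' @export
print.netalign_result <- function(x, ...) {
  sp <- attr(x, "species")
  cat(
    "# Network alignment ", sp[1], " vs ", sp[2], ": ",
    nrow(x), " solution(s)\n",
    sep = ""
  )
  NextMethod()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an alignment result
#'
#' One row per aligned homolog pair (vertex) with its solution's rank,
#' score and p-value.
#'
#' @param x A `netalign_result`.
#' @param ... Unused.
#' @return A tibble with columns `solution_id`, `query_protein`,
#'   `target_protein`, `vertex_probability`, `score`, `p_value`.
#' @exportS3Method generics::tidy
tidy.netalign_result <- function(x, ...) {
  if (nrow(x) == 0) {
    return(tibble(
      solution_id = integer(), query_protein = character(),
      target_protein = character(), vertex_probability = double(),
      score = double(), p_value = double()
    ))
  }
  as_tibble(x) |>
    select("solution_id", "score", "p_value", "vertices") |>
    tidyr::unnest("vertices") |>
    select(
      "solution_id", "query_protein", "target_protein",
      vertex_probability = "probability", "score", "p_value"
    )
}

#' One-line summary of an alignment run
#'
#' @param x A `netalign_result`.
#' @param ... Unused.
#' @return A one-row tibble: solution counts, aligned-pair count, best
#'   score and smallest p-value.
#' @exportS3Method generics::glance
glance.netalign_result <- function(x, ...) {
  tibble(
    n_solutions = nrow(x),
    n_significant = sum(x$significant),
    n_aligned_pairs = if (nrow(x) == 0) 0L else sum(x$n_vertices),
    best_score = if (nrow(x) == 0) NA_real_ else max(x$score),
    min_p_value = if (nrow(x) == 0) NA_real_ else min(x$p_value)
  )
}
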