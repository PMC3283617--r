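#' Probability of an alignment-graph edge
#'
#' Assuming mutual independence of interaction reliabilities and
#' conservation probabilities, every edge probability is the joint
#' probability of the interactions (and, for likely-conserved edges, the
#' conservation event) that realise it:
#' * `conserved`: `r_query * r_target` (one direct interaction per side);
#' * `likely_conserved_*`: reliability of the observed interaction times
#'   the conservation probability of the flanking pairs' distance
#'   difference;
#' * `gap_*`: direct-side reliability times the product over the indirect
#'   path's reliabilities;
#' * `mismatch`: product over both paths' reliabilities.
#'
#' @param edge_type One of the six edge types.
#' @param query_reliabilities,target_reliabilities Reliabilities of the
#'   interactions along the query/target side (length 1 for a direct
#'   interaction, `>= 2` for an indirect path, `NULL` for an unobserved
#'   side).
#' @param cons_prob Conservation probability; required for
#'   likely-conserved edges.
#' @return Probability in `[0, 1]`.
#' @examples
#' edge_probability("conserved", 0.5, 0.8)
#' edge_probability("gap_query", c(0.8, 0.5), 0.9)
#' @export
edge_probability <- function(edge_type, query_reliabilities = NULL,
                             target_reliabilities = NULL, cons_prob = NULL) {
  if (!edge_type %in% EDGE_TYPES) {
    abort(sprintf("unknown edge type '%s'", edge_type))
  }
  nq <- length(query_reliabilities)
  nt <- length(target_reliabilities)
  ok <- switch(edge_type,
    conserved = nq == 1 && nt == 1,
    likely_conserved_query = nq >= 1 && nt == 0,
    likely_conserved_target = nq == 0 && nt >= 1,
    gap_query = nq >= 2 && nt == 1,
    gap_target = nq == 1 && nt >= 2,
    mismatch = nq >= 2 && nt >= 2
  )
  if (!ok) {
    abort(sprintf(
      "edge type '%s' incompatible with %d query / %d target reliabilities",
      edge_type, nq, nt
    ))
  }
  if (grepl("^likely", edge_type) && is.null(cons_prob)) {
    abort("likely-conserved edges require a conservation probability")
  }
  rels <- c(query_reliabilities, target_reliabilities)
  if (any(rels < 0 | rels > 1)) abort("reliabilities must lie in [0, 1]")
  p <- prod(rels)
  if (grepl("^likely", edge_type)) p <- p * cons_prob
  p
}

#' Score an alignment solution
#'
#' `S = alpha * sum_v log(1 + p_v) + (1 - alpha) * sum_e log(1 + p_e)`.
#' Vertex and edge probabilities are transformed identically so `alpha`
#' directly sets the vertex-to-edge balance; adding one keeps all scores
#' positive so solutions can be ranked by decreasing score, without
#' affecting their relative order.
#'
#' @param solution A list with tibbles `vertices` (column `probability`)
#'   and `edges` (column `probability`; may have zero rows).
#' @param alpha Vertex-to-edge balance in `[0, 1]` (default 0.5).
#' @return A non-negative score.
#' @export
solution_score <- function(solution, alpha = 0.5) {
  if (alpha < 0 || alpha > 1) abort("alpha must lie in [0, 1]")
  pv <- solution$vertices$probability
  if (length(pv) == 0) abort("cannot score an empty solution")
  pe <- solution$edges$probability
  alpha * sum(log1p(pv)) + (1 - alpha) * sum(log1p(pe))
}

#' Probability pools for the permutation test
#'
#' The random score backgrounds resample from the actual inputs: all
#' vertex probabilities of the species pair, all interaction
#' reliabilities of each input network, and conservation probabilities of
#' random homolog-pair combinations under the fitted model.  Homology
#' relationships themselves are never randomised.
#'
#' @param query_net,target_net The input [interactome()]s.
#' @param pairs Homolog pairs with `vertex_probability` (and `distance`
#'   if a conservation model is supplied).
#' @param cons_model Optional [fit_conservation_model()] fit.
#' @param n_conservation Size of the conservation-probability pool
#'   sampled from random pair combinations (default 10000).
#' @return A list of class `probability_pools`.
#' @export
probability_pools <- function(query_net, target_net, pairs,
                              cons_model = NULL, n_conservation = 10000L) {
  pairs <- as_tibble(pairs)
  cons_pool <- numeric(0)
  if (!is.null(cons_model)) {
    d <- pairs$distance[!is.na(pairs$distance)]
    if (length(d) >= 2) {
      i <- sample.int(length(d), n_conservation, replace = TRUE)
      j <- sample.int(length(d), n_conservation, replace = TRUE)
      cons_pool <- conservation_probability(abs(d[i] - d[j]), cons_model)
    }
  }
  structure(
    list(
      vertex_pool = pairs$vertex_probability,
      reliability_pool_query = query_net$reliability,
      reliability_pool_target = target_net$reliability,
      conservation_pool = cons_pool
    ),
    class = "probability_pools"
  )
}

# number of reliability draws each edge consumes per side, and whether it
# multiplies in a conservation draw — this preserves the solution topology
# and edge types in the random backgrounds
edge_sampling_plan <- function(edges) {
  tibble(
    n_query = map_int(edges$query_path, \(p) max(length(p) - 1L, 0L)),
    n_target = map_int(edges$target_path, \(p) max(length(p) - 1L, 0L)),
    uses_cons = grepl("^likely", edges$edge_type)
  )
}

#' Monte-Carlo permutation p-value of an alignment solution
#'
#' Builds `n_random_scores` random solution scores that preserve the
#' solution's topology and edge types: each vertex draws a fresh vertex
#' probability from the pool, each edge draws as many reliabilities (and,
#' for likely-conserved edges, a conservation probability) as its type and
#' path lengths dictate, and the same scoring function is applied.  The
#' p-value is `(1 + #random >= observed) / (1 + N)`, counting ties as
#' exceedances, so it can never be exactly zero.
#'
#' @param solution List with tibbles `vertices` and `edges` (edges need
#'   `edge_type`, `probability` and the path list-columns).
#' @param pools [probability_pools()].
#' @param alpha Vertex-to-edge balance used for scoring.
#' @param n_random_scores Background size (default 10000).
#' @return p-value in `[1/(N+1), 1]`.
#' @export
permutation_pvalue <- function(solution, pools, alpha = 0.5,
                               n_random_scores = 10000L) {
  observed <- solution_score(solution, alpha)
  n <- as.integer(n_random_scores)
  nv <- nrow(solution$vertices)
  if (length(pools$vertex_pool) == 0) abort("empty vertex pool")
  vmat <- matrix(
    sample(pools$vertex_pool, n * nv, replace = TRUE),
    nrow = n
  )
  rand <- alpha * rowSums(log1p(vmat))
  plan <- edge_sampling_plan(solution$edges)
  if (nrow(plan) > 0) {
    esum <- numeric(n)
    draw_prod <- function(pool, k) {
      if (k == 0L) return(rep(1, n))
      if (length(pool) == 0) abort("empty reliability pool needed by an edge type")
      m <- matrix(sample(pool, n * k, replace = TRUE), nrow = n)
      apply(m, 1, prod)
    }
    for (e in seq_len(nrow(plan))) {
      pe <- draw_prod(pools$reliability_pool_query, plan$n_query[e]) *
        draw_prod(pools$reliability_pool_target, plan$n_target[e])
      if (plan$uses_cons[e]) {
        if (length(pools$conservation_pool) == 0) {
          abort("empty conservation pool needed by a likely-conserved edge")
        }
        pe <- pe * sample(pools$conservation_pool, n, replace = TRUE)
      }
      esum <- esum + log1p(pe)
    }
    rand <- rand + (1 - alpha) * esum
  }
  (1 + sum(rand >= observed)) / (1 + n)
}
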