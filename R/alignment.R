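#' Alignment parameters
#'
#' Bundles the tunable knobs of the aligner.  Thresholds filter distant
#' homologies (vertex) and unreliable interactions (edge); the path cap
#' bounds gap/mismatch length, kept at 3 because the small-world structure
#' of interactomes would otherwise connect unrelated proteins; `alpha`
#' balances vertex against edge scores.
#'
#' @param vertex_prob_threshold Minimum vertex probability (default 0.5
#'   for interactome-to-interactome, 0.2 for query modes).
#' @param edge_prob_threshold Minimum edge probability (default 0.6 for
#'   interactome-to-interactome — whole-interactome comparison needs
#'   strict filtering or gap/mismatch bridges chain unrelated modules
#'   into one giant solution; 0.05 for query modes).  Task profiles were
#'   fixed by grid calibration on the synthetic benchmark (highest
#'   average F measure over set- and protein-level evaluation).
#' @param predict_likely_conserved Predict likely-conserved interactions
#'   from evolutionary-distance differences (default `FALSE`).
#' @param max_path_length Maximum gap/mismatch path length in edges,
#'   `>= 2` (default 3).
#' @param alpha Vertex-to-edge score balance in `[0, 1]` (default 0.5).
#' @param p_threshold Significance level for reported solutions
#'   (default 0.05).
#' @param n_random_scores Random background size per solution
#'   (default 10000).
#' @param mode Alignment task: interactome-to-interactome (`"i2i"`),
#'   complex-to-interactome (`"c2i"`) or pathway-to-interactome
#'   (`"p2i"`).  Query modes default to permissive thresholds since the
#'   query already encodes strong prior knowledge.
#' @param intra_species Intra-species alignment (divergence instead of
#'   distance); changes no contract, only documentation intent.
#' @return A list of class `align_params`.
#' @export
align_params <- function(vertex_prob_threshold = NULL,
                         edge_prob_threshold = NULL,
                         predict_likely_conserved = FALSE,
                         max_path_length = 3L,
                         alpha = 0.5,
                         p_threshold = 0.05,
                         n_random_scores = 10000L,
                         mode = c("i2i", "c2i", "p2i"),
                         intra_species = FALSE) {
  mode <- match.arg(mode)
  # per-task default profiles: query modes keep weak vertices because the
  # molecule set itself restricts the search space
  vertex_prob_threshold <- vertex_prob_threshold %||%
    if (mode == "i2i") 0.5 else 0.2
  edge_prob_threshold <- edge_prob_threshold %||%
    if (mode == "i2i") 0.6 else 0.05
  if (max_path_length < 2) abort("max_path_length must be >= 2")
  if (alpha < 0 || alpha > 1) abort("alpha must lie in [0, 1]")
  if (n_random_scores < 1) abort("n_random_scores must be >= 1")
  structure(
    list(
      vertex_prob_threshold = vertex_prob_threshold,
      edge_prob_threshold = edge_prob_threshold,
      predict_likely_conserved = isTRUE(predict_likely_conserved),
      max_path_length = as.integer(max_path_length),
      alpha = alpha,
      p_threshold = p_threshold,
      n_random_scores = as.integer(n_random_scores),
      mode = mode,
      intra_species = isTRUE(intra_species)
    ),
    class = "align_params"
  )
}

# fast reliability lookup for canonical pairs: named numeric vector
edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

reliability_index <- function(net) {
  setNames(net$reliability, edge_key(net$protein_a, net$protein_b))
}

adjacency_index <- function(net) {
  # adjacency list with reliabilities, neighbours sorted for deterministic
  # path enumeration; self-loops excluded (they cannot lie on a simple path)
  edges <- as_tibble(net) |> filter(.data$protein_a != .data$protein_b)
  both <- bind_rows(
    select(edges, from = "protein_a", to = "protein_b", "reliability"),
    select(edges, from = "protein_b", to = "protein_a", "reliability")
  ) |> arrange(.data$from, .data$to)
  split(both[c("to", "reliability")], both$from)
}

#' Build the initial alignment graph
#'
#' Vertices are homolog pairs passing the vertex-probability threshold.
#' Two vertices `(a1, b1)` and `(a2, b2)` are joined by a conserved edge
#' when the interaction `a1-a2` exists in the query network and `b1-b2`
#' in the target network; when `predict_likely_conserved` is on, an
#' interaction present in exactly one network yields a likely-conserved
#' edge whose probability multiplies the observed reliability with the
#' conservation probability of the pairs' distance difference.  Edge
#' probabilities below the edge threshold are dropped.
#'
#' @param query_net,target_net [interactome()]s.
#' @param pairs Homolog pairs with `vertex_probability` (and `distance`
#'   when prediction is enabled).
#' @param cons_model A [fit_conservation_model()] fit; required when
#'   `params$predict_likely_conserved`.
#' @param params [align_params()].
#' @return An `alignment_graph`: list with tibbles `vertices`
#'   (`vertex_id`, proteins, `probability`, `distance`) and `edges`
#'   (`from`, `to`, `edge_type`, `probability`, path list-columns).
#' @export
build_initial_graph <- function(query_net, target_net, pairs,
                                cons_model = NULL, params = align_params()) {
  pairs <- as_tibble(pairs)
  if (!"vertex_probability" %in% names(pairs)) {
    abort("pairs need a vertex_probability column; see assign_vertex_probabilities()")
  }
  if (!"distance" %in% names(pairs)) pairs$distance <- NA_real_
  qprot <- interactome_proteins(query_net)
  tprot <- interactome_proteins(target_net)
  if (nrow(pairs) > 0 &&
    !any(pairs$query_protein %in% qprot & pairs$target_protein %in% tprot)) {
    abort("inconsistent identifier namespaces: no homolog pair references both networks")
  }
  vertices <- pairs |>
    filter(
      .data$query_protein %in% qprot, .data$target_protein %in% tprot,
      .data$vertex_probability >= params$vertex_prob_threshold
    ) |>
    arrange(.data$query_protein, .data$target_protein) |>
    mutate(vertex_id = row_number()) |>
    select(
      "vertex_id", "query_protein", "target_protein",
      probability = "vertex_probability", "distance"
    )
  if (params$predict_likely_conserved && is.null(cons_model)) {
    abort("predict_likely_conserved requires a fitted conservation model")
  }

  rel_q <- reliability_index(query_net)
  rel_t <- reliability_index(target_net)
  # vertices indexed by each side's protein
  by_query <- split(vertices$vertex_id, vertices$query_protein)
  by_target <- split(vertices$vertex_id, vertices$target_protein)

  # candidate vertex pairs supported by a query-side interaction
  cand_from_edges <- function(net, by_side) {
    out <- vector("list", nrow(net))
    for (i in seq_len(nrow(net))) {
      v1 <- by_side[[net$protein_a[i]]]
      v2 <- by_side[[net$protein_b[i]]]
      if (is.null(v1) || is.null(v2)) next
      grid <- expand.grid(from = v1, to = v2)
      grid <- grid[grid$from != grid$to, , drop = FALSE]
      if (nrow(grid) == 0) next
      out[[i]] <- tibble(
        from = pmin(grid$from, grid$to), to = pmax(grid$from, grid$to)
      )
    }
    res <- dplyr::distinct(bind_rows(out))
    if (nrow(res) == 0) tibble(from = integer(), to = integer()) else res
  }
  cq <- cand_from_edges(query_net, by_query)
  ct <- cand_from_edges(target_net, by_target)

  annotate <- function(cand) {
    if (nrow(cand) == 0) {
      return(tibble(
        from = integer(), to = integer(),
        r_query = double(), r_target = double(), delta = double()
      ))
    }
    v <- vertices
    cand |>
      mutate(
        qa = v$query_protein[.data$from], qb = v$query_protein[.data$to],
        ta = v$target_protein[.data$from], tb = v$target_protein[.data$to],
        r_query = unname(rel_q[edge_key(.data$qa, .data$qb)]),
        r_target = unname(rel_t[edge_key(.data$ta, .data$tb)]),
        delta = delta_distance_na(v$distance[.data$from], v$distance[.data$to])
      ) |>
      select(-"qa", -"qb", -"ta", -"tb")
  }
  cand <- annotate(dplyr::distinct(bind_rows(cq, ct)))

  conserved <- cand |>
    filter(!is.na(.data$r_query) & !is.na(.data$r_target)) |>
    mutate(
      edge_type = "conserved",
      probability = .data$r_query * .data$r_target
    )
  edges <- conserved
  if (params$predict_likely_conserved) {
    one_sided <- cand |>
      filter(xor(is.na(.data$r_query), is.na(.data$r_target)), !is.na(.data$delta)) |>
      mutate(
        edge_type = ifelse(is.na(.data$r_target),
          "likely_conserved_query", "likely_conserved_target"
        ),
        cons_prob = conservation_probability(.data$delta, cons_model),
        probability = ifelse(is.na(.data$r_target), .data$r_query, .data$r_target) *
          .data$cons_prob
      ) |>
      select(-"cons_prob")
    if (nrow(one_sided) > 0) edges <- bind_rows(edges, one_sided)
  }
  edges <- edges |>
    filter(.data$probability >= params$edge_prob_threshold) |>
    arrange(.data$from, .data$to)
  # vertex_id equals the row number, so it can index the vertex tibble
  if (nrow(edges) > 0) {
    edges$query_path <- map2(
      vertices$query_protein[edges$from], vertices$query_protein[edges$to], c
    )
    edges$target_path <- map2(
      vertices$target_protein[edges$from], vertices$target_protein[edges$to], c
    )
    # one-sided edges only carry a path on the observed side
    edges$query_path[is.na(edges$r_query)] <- list(NULL)
    edges$target_path[is.na(edges$r_target)] <- list(NULL)
  }
  new_alignment_graph(vertices, edges)
}

delta_distance_na <- function(d1, d2) {
  ifelse(is.na(d1) | is.na(d2), NA_real_, abs(d1 - d2))
}

new_alignment_graph <- function(vertices, edges) {
  if (nrow(edges) == 0) {
    edges <- tibble(
      from = integer(), to = integer(),
      r_query = double(), r_target = double(), delta = double(),
      edge_type = character(), probability = double(),
      query_path = list(), target_path = list()
    )
  }
  structure(
    list(vertices = vertices, edges = edges),
    class = "alignment_graph"
  )
}

#' @export
print.alignment_graph <- function(x, ...) {
  cat(
    "# Alignment graph: ", nrow(x$vertices), " vertices, ",
    nrow(x$edges), " edges\n",
    sep = ""
  )
  if (nrow(x$edges) > 0) print(table(x$edges$edge_type))
  invisible(x)
}

#' Connected components of an alignment graph
#'
#' Maximal connected vertex sets of the graph (depth-first search via
#' igraph).  Isolated vertices are discarded: a component must contain at
#' least one edge to describe conserved interaction structure.
#'
#' @param graph An `alignment_graph`.
#' @return List of integer vectors of `vertex_id`s, each sorted; ordered
#'   by their smallest vertex id.
#' @export
alignment_components <- function(graph) {
  if (nrow(graph$edges) == 0) return(list())
  g <- igraph::graph_from_data_frame(
    graph$edges[c("from", "to")],
    directed = FALSE,
    vertices = data.frame(name = graph$vertices$vertex_id)
  )
  memb <- igraph::components(g)$membership
  ids <- as.integer(names(memb))
  comps <- split(ids, memb)
  comps <- purrr::keep(comps, \(x) length(x) >= 2)
  comps <- map(comps, sort)
  unname(comps[order(map_int(comps, 1))])
}

#' Best bounded indirect path between two proteins
#'
#' Searches for the indirect path (2 up to `max_len` edges) between two
#' proteins that maximises the product of edge reliabilities — the
#' shortest weighted path under `-log` reliabilities, restricted to a
#' user-defined length because most interactomes are small worlds and
#' longer paths connect unrelated proteins.  Ties break on the
#' lexicographically smallest node sequence.
#'
#' @param net An [interactome()].
#' @param a,b Protein identifiers in `net` (equal identifiers search for
#'   a shortest cycle through `a`).
#' @param max_len Maximum number of edges, `>= 2` (default 3).
#' @return `NULL` if no such path, else a list with `path` (node
#'   sequence) and `probability` (reliability product).
#' @export
bounded_best_path <- function(net, a, b, max_len = 3L) {
  if (max_len < 2) abort("max_len must be >= 2")
  prots <- interactome_proteins(net)
  if (!a %in% prots || !b %in% prots) {
    abort(sprintf("protein %s not in network", if (a %in% prots) b else a))
  }
  adj <- adjacency_index(net)
  bounded_best_path_adj(adj, a, b, max_len)
}

# core search over a prebuilt adjacency index (reused by extend_graph)
bounded_best_path_adj <- function(adj, a, b, max_len) {
  best <- NULL
  best_p <- -1
  best_key <- ""
  path <- character(max_len + 1L)
  path[1L] <- a
  walk <- function(node, depth, prob) {
    nbrs <- adj[[node]]
    if (is.null(nbrs)) return()
    for (i in seq_len(nrow(nbrs))) {
      nxt <- nbrs$to[i]
      p <- prob * nbrs$reliability[i]
      if (nxt == b && depth >= 2L) {
        cand <- c(path[seq_len(depth)], b)
        key <- paste(cand, collapse = "\r")
        if (p > best_p || (p == best_p && key < best_key)) {
          best_p <<- p
          best <<- cand
          best_key <<- key
        }
      }
      if (depth < max_len && nxt != b && !(nxt %in% path[seq_len(depth)]) &&
        nxt != a) {
        path[depth + 1L] <<- nxt
        walk(nxt, depth + 1L, p)
      }
    }
  }
  walk(a, 1L, 1)
  if (is.null(best)) NULL else list(path = best, probability = best_p)
}

#' Extend an alignment graph with gap and mismatch edges
#'
#' Connects vertices of *different* seeds (never within a seed, where
#' indirect connections are trivially abundant) whose proteins are
#' related indirectly: a gap edge when the interaction is direct in one
#' network and an indirect bounded path exists in the other, a mismatch
#' edge when both networks only offer indirect paths.  Edge probability
#' is the joint reliability product over all interactions involved; the
#' edge threshold applies.  Initial edges are left untouched.
#'
#' @param graph Initial `alignment_graph`.
#' @param seeds Components from [alignment_components()].
#' @param query_net,target_net The input [interactome()]s.
#' @param params [align_params()].
#' @return The extended `alignment_graph`.
#' @export
extend_graph <- function(graph, seeds, query_net, target_net,
                         params = align_params()) {
  if (length(seeds) < 2) return(graph)
  v <- graph$vertices
  seed_of <- rep(NA_integer_, max(v$vertex_id))
  for (s in seq_along(seeds)) seed_of[seeds[[s]]] <- s
  seeded <- v[!is.na(seed_of[v$vertex_id]), ]

  rel_q <- reliability_index(query_net)
  rel_t <- reliability_index(target_net)
  adj_q <- adjacency_index(query_net)
  adj_t <- adjacency_index(target_net)
  # unweighted-hop pruning: skip protein pairs farther than max_len
  hop <- function(net, prots) {
    g <- igraph::graph_from_data_frame(
      as_tibble(net)[c("protein_a", "protein_b")],
      directed = FALSE,
      vertices = data.frame(name = interactome_proteins(net))
    )
    igraph::distances(g, v = prots, to = prots)
  }
  pq <- unique(seeded$query_protein)
  pt <- unique(seeded$target_protein)
  hop_q <- hop(query_net, pq)
  hop_t <- hop(target_net, pt)

  cap <- params$max_path_length
  out <- list()
  k <- 0L
  n <- nrow(seeded)
  for (i in seq_len(n - 1L)) {
    v1 <- seeded$vertex_id[i]
    for (j in seq((i + 1L), n)) {
      v2 <- seeded$vertex_id[j]
      if (seed_of[v1] == seed_of[v2]) next
      qa <- seeded$query_protein[i]; qb <- seeded$query_protein[j]
      ta <- seeded$target_protein[i]; tb <- seeded$target_protein[j]
      if (hop_q[qa, qb] > cap || hop_t[ta, tb] > cap) next
      rq <- rel_q[edge_key(qa, qb)]
      rt <- rel_t[edge_key(ta, tb)]
      q_direct <- !is.na(rq)
      t_direct <- !is.na(rt)
      if (q_direct && t_direct) next # conserved-edge territory, not extension
      qp <- NULL; tp <- NULL
      if (!q_direct) {
        qp <- bounded_best_path_adj(adj_q, qa, qb, cap)
        if (is.null(qp)) next
      }
      if (!t_direct) {
        tp <- bounded_best_path_adj(adj_t, ta, tb, cap)
        if (is.null(tp)) next
      }
      if (q_direct) {
        type <- "gap_target"
        prob <- unname(rq) * tp$probability
        qpath <- c(qa, qb); tpath <- tp$path
      } else if (t_direct) {
        type <- "gap_query"
        prob <- unname(rt) * qp$probability
        qpath <- qp$path; tpath <- c(ta, tb)
      } else {
        type <- "mismatch"
        prob <- qp$probability * tp$probability
        qpath <- qp$path; tpath <- tp$path
      }
      if (prob < params$edge_prob_threshold) next
      k <- k + 1L
      out[[k]] <- tibble(
        from = min(v1, v2), to = max(v1, v2),
        r_query = unname(rq), r_target = unname(rt), delta = NA_real_,
        edge_type = type, probability = prob,
        query_path = list(qpath), target_path = list(tpath)
      )
    }
  }
  edges <- bind_rows(graph$edges, bind_rows(out))
  new_alignment_graph(graph$vertices, edges)
}
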