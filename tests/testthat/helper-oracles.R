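# Independent oracles used to validate the package's own algorithms.
# Each deliberately takes a different route than the implementation.

# weighted isotonic regression by the closed-form max-min formula:
# nondecreasing fit_i = max_{s<=i} min_{t>=i} weighted mean(v[s..t])
oracle_isotonic <- function(values, weights = rep(1, length(values)),
                            direction = "nonincreasing") {
  v <- if (direction == "nonincreasing") -values else values
  n <- length(v)
  wmean <- function(s, t) sum(weights[s:t] * v[s:t]) / sum(weights[s:t])
  fit <- vapply(seq_len(n), function(i) {
    max(vapply(seq_len(i), function(s) {
      min(vapply(i:n, function(t) wmean(s, t), numeric(1)))
    }, numeric(1)))
  }, numeric(1))
  if (direction == "nonincreasing") -fit else fit
}

# Grishin distance by plain bisection on ln(1 + 2d) - 2dq
oracle_grishin <- function(q, tol = 1e-12) {
  vapply(q, function(qi) {
    if (qi == 1) return(0)
    g <- function(d) log(1 + 2 * d) - 2 * d * qi
    lo <- 0; hi <- 1
    while (g(hi) > 0) hi <- hi * 2
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (g(mid) > 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
}

# connected components by boolean transitive closure of the adjacency matrix
oracle_components <- function(n, edges) {
  m <- diag(TRUE, n)
  for (k in seq_len(nrow(edges))) {
    m[edges$from[k], edges$to[k]] <- TRUE
    m[edges$to[k], edges$from[k]] <- TRUE
  }
  repeat {
    m2 <- (m %*% m) > 0
    if (identical(m2, m > 0)) break
    m <- m2
  }
  groups <- unique(apply(m, 1, \(r) paste(which(r), collapse = ",")))
  comps <- lapply(strsplit(groups, ","), as.integer)
  comps <- Filter(\(x) length(x) >= 2, comps)
  comps[order(vapply(comps, min, integer(1)))]
}

# best bounded indirect path via igraph's exhaustive simple-path enumeration
oracle_best_path <- function(net, a, b, max_len) {
  edges <- tibble::as_tibble(net)
  edges <- edges[edges$protein_a != edges$protein_b, ]
  g <- igraph::graph_from_data_frame(
    edges[c("protein_a", "protein_b")],
    directed = FALSE,
    vertices = data.frame(name = interactome_proteins(net))
  )
  rel <- stats::setNames(
    edges$reliability,
    paste(pmin(edges$protein_a, edges$protein_b),
      pmax(edges$protein_a, edges$protein_b),
      sep = "\r"
    )
  )
  paths <- if (a == b) {
    # cycles: simple paths a -> neighbour of a, closed by the final edge
    nb <- igraph::neighbors(g, a)$name
    out <- list()
    for (x in nb) {
      for (p in igraph::all_simple_paths(g, a, x, cutoff = max_len - 1)) {
        out[[length(out) + 1L]] <- c(igraph::as_ids(p), a)
      }
    }
    out
  } else {
    lapply(
      igraph::all_simple_paths(g, a, b, cutoff = max_len),
      igraph::as_ids
    )
  }
  best <- NULL; best_p <- -1; best_key <- ""
  for (p in paths) {
    len <- length(p) - 1L
    if (len < 2 || len > max_len) next
    pr <- prod(rel[paste(pmin(p[-length(p)], p[-1]), pmax(p[-length(p)], p[-1]),
      sep = "\r"
    )])
    key <- paste(p, collapse = "\r")
    if (pr > best_p || (pr == best_p && key < best_key)) {
      best <- p; best_p <- pr; best_key <- key
    }
  }
  if (is.null(best)) NULL else list(path = best, probability = best_p)
}
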