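test_that("initial graph draws conserved edges only where both networks interact", {
  q <- net("a1-a2:1", "a2-a3:1")
  t <- net("b1-b2:1", proteins = c("b1", "b2", "b3"))
  pr <- pairs_tbl(c("a1", "a2", "a3"), c("b1", "b2", "b3"))
  params <- align_params(vertex_prob_threshold = 0, edge_prob_threshold = 0)
  g <- build_initial_graph(q, t, pr, params = params)
  expect_equal(nrow(g$vertices), 3)
  expect_equal(nrow(g$edges), 1) # a2-a3 exists only in query: no edge
  expect_equal(g$edges$edge_type, "conserved")
  expect_equal(g$edges$probability, 1)
})

test_that("edge probability multiplies reliabilities and thresholds filter", {
  q <- net("a1-a2:0.5")
  t <- net("b1-b2:0.8")
  pr <- pairs_tbl(c("a1", "a2"), c("b1", "b2"))
  g <- build_initial_graph(q, t, pr,
    params = align_params(vertex_prob_threshold = 0, edge_prob_threshold = 0)
  )
  expect_equal(g$edges$probability, 0.4)
  # raising the edge threshold can only remove edges
  g2 <- build_initial_graph(q, t, pr,
    params = align_params(vertex_prob_threshold = 0, edge_prob_threshold = 0.5)
  )
  expect_equal(nrow(g2$edges), 0)
})

test_that("sub-threshold vertices disappear together with their edges", {
  q <- net("a1-a2:1")
  t <- net("b1-b2:1")
  pr <- pairs_tbl(c("a1", "a2"), c("b1", "b2"), vp = c(0.2, 1))
  g <- build_initial_graph(q, t, pr,
    params = align_params(vertex_prob_threshold = 0.5, edge_prob_threshold = 0)
  )
  expect_equal(nrow(g$vertices), 1)
  expect_equal(nrow(g$edges), 0)
})

test_that("self-interactions can support alignment edges", {
  # two vertices sharing the query protein need a query self-interaction
  q <- net("a1-a1:1")
  t <- net("b1-b2:1")
  pr <- pairs_tbl(c("a1", "a1"), c("b1", "b2"))
  g <- build_initial_graph(q, t, pr,
    params = align_params(vertex_prob_threshold = 0, edge_prob_threshold = 0)
  )
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$edge_type, "conserved")
})

test_that("likely-conserved edges require prediction, one-sided interactions and distances", {
  q <- net("a1-a2:0.8")
  t <- net(proteins = c("b1", "b2"))
  pr <- pairs_tbl(c("a1", "a2"), c("b1", "b2"), d = c(0.3, 0.32))
  m <- fit_conservation_model(abs(stats::rnorm(200, 0, 0.05)), stats::runif(2000, 0, 2))
  off <- align_params(vertex_prob_threshold = 0, edge_prob_threshold = 0)
  expect_equal(nrow(build_initial_graph(q, t, pr, params = off)$edges), 0)
  on <- align_params(
    vertex_prob_threshold = 0, edge_prob_threshold = 0,
    predict_likely_conserved = TRUE
  )
  g <- build_initial_graph(q, t, pr, m, on)
  expect_equal(g$edges$edge_type, "likely_conserved_query")
  expect_equal(
    g$edges$probability,
    0.8 * conservation_probability(abs(0.3 - 0.32), m)
  )
  # no distance, no prediction
  g2 <- build_initial_graph(q, t, pairs_tbl(c("a1", "a2"), c("b1", "b2")), m, on)
  expect_equal(nrow(g2$edges), 0)
  expect_error(build_initial_graph(q, t, pr, NULL, on), "conservation model")
})

test_that("namespace mismatches are rejected", {
  q <- net("a1-a2:1")
  t <- net("b1-b2:1")
  pr <- pairs_tbl("x1", "y1")
  expect_error(
    build_initial_graph(q, t, pr, params = align_params()),
    "namespace"
  )
})

test_that("components match a transitive-closure oracle on random graphs", {
  # fixed case: path plus isolated vertex
  vs <- tibble::tibble(
    vertex_id = 1:4, query_protein = letters[1:4],
    target_protein = LETTERS[1:4], probability = 1, distance = NA_real_
  )
  es <- tibble::tibble(from = c(1L, 2L), to = c(2L, 3L))
  g <- structure(list(vertices = vs, edges = es), class = "alignment_graph")
  expect_equal(alignment_components(g), list(1:3))
  empty <- structure(
    list(vertices = vs[0, ], edges = es[0, ]),
    class = "alignment_graph"
  )
  expect_equal(alignment_components(empty), list())

  withr::with_seed(11, {
    for (i in 1:80) {
      n <- sample(2:12, 1)
      m <- sample(0:(n * 2), 1)
      es <- tibble::tibble(
        from = sample.int(n, m, replace = TRUE),
        to = sample.int(n, m, replace = TRUE)
      )
      es <- es[es$from != es$to, ]
      vs_n <- tibble::tibble(
        vertex_id = 1:n, query_protein = as.character(1:n),
        target_protein = as.character(1:n), probability = 1,
        distance = NA_real_
      )
      g <- structure(list(vertices = vs_n, edges = es), class = "alignment_graph")
      expect_equal(alignment_components(g), oracle_components(n, es))
    }
  })
})

test_that("bounded best paths match exhaustive enumeration on random graphs", {
  # a longer path can beat a shorter one on joint reliability
  g <- net("a-x:0.9", "x-b:0.9", "a-u:0.99", "u-v:0.99", "v-b:0.99")
  got <- bounded_best_path(g, "a", "b", max_len = 3)
  expect_equal(got$path, c("a", "u", "v", "b"))
  expect_equal(got$probability, 0.99^3)
  # with cap 2 the two-hop path wins instead
  got2 <- bounded_best_path(g, "a", "b", max_len = 2)
  expect_equal(got2$path, c("a", "x", "b"))
  # direct-only connection is not an indirect path
  expect_null(bounded_best_path(net("a-b:1"), "a", "b"))
  expect_error(bounded_best_path(g, "a", "zz"), "not in network")
  expect_error(bounded_best_path(g, "a", "b", max_len = 1), ">= 2")

  withr::with_seed(23, {
    for (i in 1:60) {
      n <- sample(4:12, 1)
      rg <- random_interactome(n, stats::runif(1, 0.15, 0.5), seed = i)
      prots <- interactome_proteins(rg)
      ab <- sample(prots, 2)
      cap <- sample(2:4, 1)
      got <- bounded_best_path(rg, ab[1], ab[2], cap)
      want <- oracle_best_path(rg, ab[1], ab[2], cap)
      if (is.null(want)) {
        expect_null(got)
      } else {
        expect_equal(got$probability, want$probability, tolerance = 1e-12)
        expect_equal(got$path, want$path)
      }
    }
  })
})

test_that("extension adds gap and mismatch edges between, never within, seeds", {
  # two conserved seeds: (a1,b1)-(a2,b2) and (a4,b4)-(a5,b5)
  # a2-a4 direct in query; b2-x-b4 two-hop in target -> gap in the target
  q <- net("a1-a2:1", "a4-a5:1", "a2-a4:0.9")
  t <- net("b1-b2:1", "b4-b5:1", "b2-x:0.8", "x-b4:0.5")
  pr <- pairs_tbl(
    c("a1", "a2", "a4", "a5"),
    c("b1", "b2", "b4", "b5")
  )
  params <- align_params(vertex_prob_threshold = 0, edge_prob_threshold = 0)
  g0 <- build_initial_graph(q, t, pr, params = params)
  seeds <- alignment_components(g0)
  expect_length(seeds, 2)
  g1 <- extend_graph(g0, seeds, q, t, params)
  added <- g1$edges[g1$edges$edge_type != "conserved", ]
  # every inter-seed pair within reach is bridged; the (a2,b2)-(a4,b4)
  # bridge must be the direct-in-query, two-hop-in-target gap
  seed_of <- integer(4); for (sdx in 1:2) seed_of[seeds[[sdx]]] <- sdx
  expect_true(all(seed_of[added$from] != seed_of[added$to]))
  v <- g1$vertices
  gap <- added[v$query_protein[added$from] == "a2" &
    v$query_protein[added$to] == "a4", ]
  expect_equal(gap$edge_type, "gap_target")
  expect_equal(gap$probability, 0.9 * 0.8 * 0.5)
  expect_equal(gap$target_path[[1]], c("b2", "x", "b4"))
  # initial edges survive extension untouched
  expect_true(all(
    paste(g0$edges$from, g0$edges$to) %in% paste(g1$edges$from, g1$edges$to)
  ))

  # indirect on both sides -> mismatch
  q2 <- net("a1-a2:1", "a4-a5:1", "a2-y:1", "y-a4:1")
  g0b <- build_initial_graph(q2, t, pr, params = params)
  g1b <- extend_graph(g0b, alignment_components(g0b), q2, t, params)
  addedb <- g1b$edges[g1b$edges$edge_type != "conserved", ]
  expect_true(all(addedb$edge_type == "mismatch"))
  vb <- g1b$vertices
  mm <- addedb[vb$query_protein[addedb$from] == "a2" &
    vb$query_protein[addedb$to] == "a4", ]
  expect_equal(mm$query_path[[1]], c("a2", "y", "a4"))

  # within-seed pairs are never bridged: one seed spanning all vertices
  q3 <- net("a1-a2:1", "a2-a4:1", "a4-a5:1")
  t3 <- net("b1-b2:1", "b2-b4:1", "b4-b5:1", "b2-x:1", "x-b5:1")
  g0c <- build_initial_graph(q3, t3, pr, params = params)
  seedsc <- alignment_components(g0c)
  expect_length(seedsc, 1)
  g1c <- extend_graph(g0c, seedsc, q3, t3, params)
  expect_equal(nrow(g1c$edges), nrow(g0c$edges))
})

test_that("alignment solutions are disjoint, deterministic and threshold-monotone", {
  syn <- generate_synthetic(small_synth(5))
  lr <- fit_likelihood_ratios(
    pmin(syn$pairs$evalue_qt, syn$pairs$evalue_tq), syn$null_evalues
  )
  pairs <- assign_vertex_probabilities(syn$pairs, lr)
  params <- align_params(n_random_scores = 199)
  r1 <- align_networks(syn$query_net, syn$target_net, pairs, params = params, seed = 9)
  r2 <- align_networks(syn$query_net, syn$target_net, pairs, params = params, seed = 9)
  expect_equal(as.data.frame(tidy(r1)), as.data.frame(tidy(r2))) # determinism
  keys <- unlist(map(
    r1$vertices,
    \(v) paste(v$query_protein, v$target_protein, sep = "|")
  ))
  expect_equal(anyDuplicated(keys), 0L) # maximality: no pair in two solutions
  expect_true(all(diff(r1$score) <= 1e-12)) # ranked by decreasing score

  # empty homolog set: no solutions
  r0 <- align_networks(
    syn$query_net, syn$target_net,
    pairs_tbl(character(0), character(0)),
    params = params, seed = 1
  )
  expect_equal(nrow(r0), 0)
  expect_equal(nrow(tidy(r0)), 0)
  expect_equal(glance(r0)$n_solutions, 0)
})

test_that("zero rewiring and permissive thresholds recover exactly the planted modules", {
  syn <- generate_synthetic(small_synth(13,
    rewiring_fraction = 0, decoy_fraction = 0,
    background_homolog_fraction = 0, background_edge_density = 0
  ))
  pairs <- dplyr::mutate(syn$pairs, vertex_probability = 1)
  params <- align_params(
    vertex_prob_threshold = 0, edge_prob_threshold = 0,
    n_random_scores = 99, p_threshold = 1
  )
  res <- align_networks(syn$query_net, syn$target_net, pairs,
    params = params, seed = 2, keep_insignificant = TRUE
  )
  expect_equal(nrow(res), nrow(syn$ground_truth))
  got <- lapply(res$vertices, \(v) sort(v$query_protein))
  want <- lapply(syn$ground_truth$query_members, sort)
  expect_setequal(got, want)
})
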