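test_that("set distance is Jaccard and clustering is single-linkage at 0.5", {
  expect_equal(set_distance(c("a", "b"), c("a", "b")), 0)
  expect_equal(set_distance(c("a", "b"), c("c", "d")), 1)
  expect_equal(set_distance(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_error(set_distance(character(0), "a"), "non-empty")

  sets <- tibble::tibble(
    set_id = c("s1", "s2", "s3"),
    kind = "complex",
    members = list(
      c("a", "b", "c"), # d(s1,s2) = 1 - 2/4 = 0.5 (not < 0.5)
      c("b", "c", "d"),
      c("x", "y")
    )
  )
  cl <- cluster_nonredundant(sets, threshold = 0.5)
  expect_length(unique(cl$cluster), 3)
  # chained sets merge transitively under single linkage
  chain <- tibble::tibble(
    set_id = c("s1", "s2", "s3"),
    kind = "complex",
    members = list(
      c("a", "b", "c", "d"), # d(1,2) = 1 - 3/5 = 0.4
      c("a", "b", "c", "e"), # d(2,3) = 0.4, d(1,3) = 1 - 2/6 ~ 0.67
      c("a", "b", "e", "f")
    )
  )
  cl2 <- cluster_nonredundant(chain, threshold = 0.5)
  expect_length(unique(cl2$cluster), 1)
  expect_error(cluster_nonredundant(sets, threshold = 0), "\\(0, 1\\)")
})

test_that("the conserved-pair criterion needs >= 2 and 25% matched, reciprocally", {
  pairs8 <- tibble::tibble(
    query_protein = c("q1", "q2"), target_protein = c("t1", "t2")
  )
  q8 <- paste0("q", 1:8)
  t8 <- paste0("t", 1:8)
  expect_true(conserved_pair(q8, t8, pairs8)) # 2 of 8 = 25%
  expect_false(conserved_pair(q8, t8, pairs8[1, ])) # only 1 matched
  # forward passes but reverse has 1/10 matched -> fails "vice versa"
  q2 <- c("q1", "q2")
  t10 <- paste0("t", 1:10)
  pairs_fwd <- tibble::tibble(
    query_protein = c("q1", "q2"), target_protein = c("t1", "t1")
  )
  expect_false(conserved_pair(q2, t10, pairs_fwd))
})

test_that("coverage thresholds differ between complexes and pathways", {
  sol <- c("t1", "t2")
  expect_true(covers(sol, paste0("t", 1:4), kind = "complex")) # 2/4 = 50%
  expect_false(covers(sol, paste0("t", 1:6), kind = "complex")) # 2/6 < 50%
  expect_true(covers(sol, paste0("t", 1:6), kind = "pathway")) # 2/6 >= 1/3
  expect_false(covers("t1", c("t1", "t2"), kind = "complex")) # needs >= 2
})

fake_result <- function(entries, p_values = NULL) {
  # entries: list of character vectors (target-side proteins per solution)
  rows <- purrr::imap(entries, function(tp, i) {
    nv <- length(tp)
    tibble::tibble(
      solution_id = i,
      score = 10 - i,
      p_value = if (is.null(p_values)) 0.01 else p_values[i],
      significant = (if (is.null(p_values)) 0.01 else p_values[i]) <= 0.05,
      n_vertices = nv, n_edges = nv - 1L,
      vertices = list(tibble::tibble(
        vertex_id = seq_len(nv),
        query_protein = paste0("q_", tp), target_protein = tp,
        probability = 1, distance = NA_real_
      )),
      edges = list(tibble::tibble(
        from = seq_len(nv - 1L), to = seq_len(nv - 1L) + 1L,
        edge_type = "conserved", probability = 1,
        query_path = purrr::map(seq_len(nv - 1L), \(k) paste0("q_", tp[k:(k + 1)])),
        target_path = purrr::map(seq_len(nv - 1L), \(k) tp[k:(k + 1)])
      ))
    )
  })
  structure(dplyr::bind_rows(rows),
    class = c("netalign_result", class(tibble::tibble())),
    species = c("query", "target")
  )
}

test_that("set-level precision/recall follow the covered-distinct-complex rules", {
  benchmark <- tibble::tibble(
    query_id = c("qc1", "qc2", "qc3", "qc4"),
    target_id = c("c1", "c2", "c3", "c4"),
    kind = "complex",
    query_members = list("x", "x", "x", "x"),
    target_members = list(
      c("t1", "t2", "t3", "t4"),
      c("u1", "u2"),
      c("v1", "v2", "v3"),
      c("w1", "w2", "w3")
    )
  )
  # sol1 covers c1 (3/4), sol2 covers c2 (2/2), sol3 covers nothing
  res <- fake_result(list(
    c("t1", "t2", "t3"),
    c("u1", "u2"),
    c("z1", "z2")
  ))
  rep <- evaluate_alignment(res, benchmark, mode = "i2i", kind = "complex")
  set_row <- rep[rep$level == "complex", ]
  expect_equal(set_row$tp, 2) # distinct complexes covered
  expect_equal(set_row$fp, 1) # solutions covering nothing
  expect_equal(set_row$fn, 2) # complexes left uncovered
  expect_equal(set_row$precision, 2 / 3)
  expect_equal(set_row$recall, 1 / 2)
  expect_equal(set_row$f_measure, 2 * (2 / 3) * (1 / 2) / (2 / 3 + 1 / 2),
    tolerance = 1e-12
  )
  prot <- rep[rep$level == "protein", ]
  # overlaps: {t1,t2,t3} and {u1,u2}; unique to solutions: {z1,z2};
  # unique to covered complexes: {t4}
  expect_equal(prot$tp, 5)
  expect_equal(prot$fp, 2)
  expect_equal(prot$fn, 1)

  # one solution covering two clustered complexes counts two TPs
  bench2 <- benchmark[1:2, ]
  bench2$target_members <- list(c("t1", "t2"), c("t1", "t3"))
  res2 <- fake_result(list(c("t1", "t2", "t3")))
  rep2 <- evaluate_alignment(res2, bench2, mode = "i2i", kind = "complex")
  expect_equal(rep2$tp[rep2$level == "complex"], 2)
})

test_that("insignificant or absent solutions degrade recall, not crash", {
  benchmark <- tibble::tibble(
    query_id = "qc", target_id = "c1", kind = "complex",
    query_members = list("x"), target_members = list(c("t1", "t2"))
  )
  res <- fake_result(list(c("t1", "t2")), p_values = 0.5) # not significant
  rep <- evaluate_alignment(res, benchmark, mode = "i2i", kind = "complex")
  set_row <- rep[rep$level == "complex", ]
  expect_equal(set_row$recall, 0)
  expect_equal(set_row$precision, 0)
  expect_true(set_row$degenerate)
  expect_error(evaluate_alignment(res, benchmark[0, ], "i2i"), "empty")
})

test_that("query mode scores only the top-ranked significant solution per query", {
  benchmark <- tibble::tibble(
    query_id = c("qa", "qb"), target_id = c("ca", "cb"), kind = "complex",
    query_members = list("x", "x"),
    target_members = list(c("t1", "t2"), c("u1", "u2", "u3", "u4"))
  )
  # first query: top solution covers; second: top solution misses even
  # though a lower-ranked one would cover
  r1 <- fake_result(list(c("t1", "t2"), c("zz")))
  r2 <- fake_result(list(c("n1", "n2"), c("u1", "u2")))
  rep <- evaluate_alignment(list(r1, r2), benchmark, mode = "query", kind = "complex")
  set_row <- rep[rep$level == "complex", ]
  expect_equal(set_row$tp, 1)
  expect_equal(set_row$fp, 1)
  expect_equal(set_row$fn, 1)
})

test_that("pathway evaluation adds an interaction level", {
  benchmark <- tibble::tibble(
    query_id = "qp", target_id = "p1", kind = "pathway",
    query_members = list("x"),
    target_members = list(c("t1", "t2", "t3", "t4", "t5", "t6")),
    target_interactions = list(c("t1\rt2", "t2\rt3", "t3\rt4"))
  )
  res <- fake_result(list(c("t1", "t2", "t3"))) # path t1-t2-t3
  rep <- evaluate_alignment(res, benchmark, mode = "query", kind = "pathway")
  expect_setequal(rep$level, c("pathway", "protein", "interaction"))
  irow <- rep[rep$level == "interaction", ]
  expect_equal(irow$tp, 2) # t1-t2, t2-t3 overlap
  expect_equal(irow$fp, 0)
  expect_equal(irow$fn, 1) # t3-t4 missed
})

test_that("precision/recall/F stay consistent on random counts", {
  withr::with_seed(5, {
    for (i in 1:50) {
      tp <- sample(0:20, 1); fp <- sample(0:20, 1); fn <- sample(0:20, 1)
      r <- netaligner:::prf(tp, fp, fn)
      expect_true(r$precision >= 0 && r$precision <= 1)
      expect_true(r$recall >= 0 && r$recall <= 1)
      mn <- min(r$precision, r$recall)
      expect_lte(r$f_measure, 2 * mn / (1 + mn) + 1e-12)
    }
  })
})

test_that("grid calibration ranks parameter settings by mean F", {
  grid <- tibble::tibble(vertex_prob_threshold = c(0.2, 0.9))
  out <- calibrate_parameters(grid, function(p) {
    tibble::tibble(f_measure = if (p$vertex_prob_threshold < 0.5) c(1, 1) else c(0.2, 0))
  })
  expect_equal(out$vertex_prob_threshold[1], 0.2)
  expect_equal(out$mean_f, c(1, 0.1))
})
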