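test_that("edge probabilities are independence products per edge type", {
  expect_equal(edge_probability("conserved", 1, 1), 1)
  expect_equal(edge_probability("conserved", 0.5, 0.8), 0.4)
  expect_equal(edge_probability("gap_query", c(0.8, 0.5), 0.9), 0.36)
  expect_equal(edge_probability("gap_target", 0.9, c(0.8, 0.5)), 0.36)
  expect_equal(
    edge_probability("likely_conserved_query", 0.8, NULL, cons_prob = 0.9),
    0.72
  )
  expect_equal(
    edge_probability("mismatch", c(0.9, 0.9), c(0.5, 0.5)), 0.2025
  )
  expect_error(edge_probability("likely_conserved_query", 0.8, NULL), "conservation")
  expect_error(edge_probability("conserved", c(1, 1), 1), "incompatible")
  expect_error(edge_probability("nonsense", 1, 1), "unknown")
})

sol_fixture <- function(pv, pe, nq = 1L, nt = 1L, type = "conserved") {
  list(
    vertices = tibble::tibble(probability = pv),
    edges = tibble::tibble(
      edge_type = rep(type, length(pe)),
      probability = pe,
      query_path = rep(list(letters[seq_len(nq + 1L)]), length(pe)),
      target_path = rep(list(LETTERS[seq_len(nt + 1L)]), length(pe))
    )
  )
}

test_that("the score is the alpha-balanced sum of log(1 + p)", {
  s <- sol_fixture(pv = c(1, 1), pe = 1)
  expect_equal(solution_score(s, alpha = 0.5), 1.5 * log(2))
  # alpha = 1: edges have no influence
  s2 <- sol_fixture(pv = c(0.4, 0.7), pe = 0.1)
  expect_equal(solution_score(s2, alpha = 1), log1p(0.4) + log1p(0.7))
  # zero probabilities give zero score
  expect_equal(solution_score(sol_fixture(0, 0)), 0)
  # additive over disjoint union of components, and non-negative
  a <- sol_fixture(c(0.3, 0.9), c(0.5, 0.2))
  b <- sol_fixture(0.8, 0.7)
  ab <- list(
    vertices = dplyr::bind_rows(a$vertices, b$vertices),
    edges = dplyr::bind_rows(a$edges, b$edges)
  )
  expect_equal(
    solution_score(ab, 0.3),
    solution_score(a, 0.3) + solution_score(b, 0.3)
  )
  expect_gte(solution_score(a, 0.3), 0)
  expect_error(solution_score(sol_fixture(numeric(0), numeric(0))), "empty")
})

test_that("permutation p-values hit their documented extremes", {
  pools <- structure(list(
    vertex_pool = 0.1, reliability_pool_query = 0.1,
    reliability_pool_target = 0.1, conservation_pool = numeric(0)
  ), class = "probability_pools")
  s <- sol_fixture(pv = c(0.9, 0.9), pe = 0.81)
  n <- 200L
  # no random score can reach the observed one
  expect_equal(
    withr::with_seed(1, permutation_pvalue(s, pools, n_random_scores = n)),
    1 / (n + 1)
  )
  # every random score ties the observed one (ties count as >=)
  pools_eq <- structure(list(
    vertex_pool = 0.9, reliability_pool_query = 0.9,
    reliability_pool_target = 0.9, conservation_pool = numeric(0)
  ), class = "probability_pools")
  expect_equal(
    withr::with_seed(1, permutation_pvalue(s, pools_eq, n_random_scores = n)),
    1
  )
  expect_error(
    permutation_pvalue(
      sol_fixture(0.5, 0.5, type = "likely_conserved_query"),
      pools, n_random_scores = 10
    ),
    "conservation pool"
  )
})

test_that("p-values are uniform when the observed solution is pool-sampled", {
  # topology: 3 vertices in a path (2 conserved edges); observed values are
  # drawn from the same pools the background resamples
  withr::with_seed(17, {
    pools <- structure(list(
      vertex_pool = stats::runif(500),
      reliability_pool_query = stats::runif(500),
      reliability_pool_target = stats::runif(500),
      conservation_pool = numeric(0)
    ), class = "probability_pools")
    n_rep <- 200L
    pvals <- vapply(seq_len(n_rep), function(i) {
      s <- sol_fixture(
        pv = sample(pools$vertex_pool, 3, replace = TRUE),
        pe = sample(pools$reliability_pool_query, 2, replace = TRUE) *
          sample(pools$reliability_pool_target, 2, replace = TRUE)
      )
      permutation_pvalue(s, pools, n_random_scores = 499L)
    }, numeric(1))
    # p-values live on the grid k/(N+1): ties with the continuous uniform
    # are expected and make the KS test conservative
    ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
    expect_gt(ks$p.value, 0.01)
    expect_true(all(pvals >= 1 / 500 & pvals <= 1))
  })
})

test_that("typical-probability solutions are not significant just for being large", {
  withr::with_seed(29, {
    pools <- structure(list(
      vertex_pool = stats::runif(2000),
      reliability_pool_query = stats::runif(2000),
      reliability_pool_target = stats::runif(2000),
      conservation_pool = numeric(0)
    ), class = "probability_pools")
    pvals <- vapply(1:40, function(i) {
      k <- 12L # large solution: 13 vertices, 12 edges
      s <- sol_fixture(
        pv = sample(pools$vertex_pool, k + 1, replace = TRUE),
        pe = sample(pools$reliability_pool_query, k, replace = TRUE) *
          sample(pools$reliability_pool_target, k, replace = TRUE)
      )
      permutation_pvalue(s, pools, n_random_scores = 299L)
    }, numeric(1))
    expect_gte(mean(pvals), 0.35) # ~0.5 in expectation
  })
})

test_that("pools are built from the actual inputs", {
  q <- net("a1-a2:0.4", "a2-a3:0.6")
  t <- net("b1-b2:0.9")
  pr <- pairs_tbl(c("a1", "a2"), c("b1", "b2"), vp = c(0.3, 0.8), d = c(0.1, 0.2))
  m <- fit_conservation_model(abs(stats::rnorm(100, 0, 0.1)), stats::runif(1000, 0, 2))
  pools <- withr::with_seed(1, probability_pools(q, t, pr, m, n_conservation = 50))
  expect_setequal(pools$vertex_pool, c(0.3, 0.8))
  expect_setequal(pools$reliability_pool_query, c(0.4, 0.6))
  expect_setequal(pools$reliability_pool_target, 0.9)
  expect_length(pools$conservation_pool, 50)
  expect_true(all(pools$conservation_pool <= 0.9))
})
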