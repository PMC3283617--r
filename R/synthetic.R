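#' Configuration for the synthetic-data generator
#'
#' The generator emulates the statistical structure the aligner exploits:
#' planted conserved modules present in both networks (with a fraction of
#' their edges rewired on one side), Erdos-Renyi background interactions,
#' BLAST-like E-values far smaller for homologs than for random pairs,
#' publication counts higher for curated conserved interactions than for
#' background ones, and fraction identities correlated within a module so
#' that conserved interactions show small evolutionary-distance
#' differences while random pairs do not.
#'
#' @param n_proteins_query,n_proteins_target Network sizes (default 300).
#' @param n_planted_modules Number of planted conserved modules
#'   (default 20).
#' @param module_size_range Inclusive size range of planted modules
#'   (default `c(3, 8)`).
#' @param background_edge_density Erdos-Renyi edge probability of the
#'   background (default 0.008, mean degree about 2.4 at the default
#'   sizes).
#' @param rewiring_fraction Fraction of planted conserved edges deleted
#'   and re-attached on one randomly chosen side (default 0.1).
#' @param decoy_fraction Spurious homolog pairs added per true pair
#'   (default 0.2); their weak E-values exercise the vertex threshold.
#' @param background_homolog_fraction True-like homolog pairs between
#'   background proteins per planted pair (default 0.2); strong E-values
#'   but uncorrelated identities.
#' @param planted_deletion_rate Extra fraction of planted edges deleted
#'   (not re-attached) on one side only, producing one-sided interactions
#'   a likely-conserved prediction can rescue (default 0).
#' @param module_extra_edge_prob Probability of each non-tree member pair
#'   of a planted module interacting (default 0.6): conserved complexes
#'   are densely connected, not just spanning trees.
#' @param pub_geom_p_background,pub_geom_p_planted,pub_offset_planted
#'   Publication-count model: background counts are `1 + rgeom(p_bg)`,
#'   planted counts `offset + rgeom(p_pl)` — curated conserved
#'   interactions carry more literature support.
#' @param evalue_model List describing the BLAST-like E-value draws:
#'   homologs are uniformly strong hits, log10-uniform over
#'   `homolog_log10_range`, optionally with an exact-zero BLAST
#'   underflow spike (`underflow_prob`, default 0); decoys are
#'   log10-uniform over `decoy_log10_range`; the all-pairs null is
#'   log10-normal (`null_log10_mean`, `null_log10_sd`); `n_null` null
#'   draws are emitted for likelihood-ratio fitting.
#' @param identity_model List: `module_base_range`, `within_module_sd`,
#'   `random_range`.
#' @param rng_seed Integer seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_proteins_query = 300L, n_proteins_target = 300L,
                             n_planted_modules = 20L,
                             module_size_range = c(3L, 8L),
                             background_edge_density = 0.008,
                             rewiring_fraction = 0.1,
                             decoy_fraction = 0.2,
                             background_homolog_fraction = 0.2,
                             planted_deletion_rate = 0,
                             module_extra_edge_prob = 0.6,
                             pub_geom_p_background = 0.6,
                             pub_geom_p_planted = 0.5,
                             pub_offset_planted = 3L,
                             evalue_model = list(
                               homolog_log10_range = c(-32, -28),
                               underflow_prob = 0,
                               decoy_log10_range = c(-8, -2),
                               null_log10_mean = -2, null_log10_sd = 2,
                               n_null = 5000L
                             ),
                             identity_model = list(
                               module_base_range = c(0.35, 0.85),
                               within_module_sd = 0.02,
                               random_range = c(0.3, 0.9)
                             ),
                             rng_seed = 1L) {
  cfg <- as.list(environment())
  if (any(unlist(cfg[c(
    "background_edge_density", "rewiring_fraction", "decoy_fraction",
    "background_homolog_fraction", "planted_deletion_rate"
  )]) < 0) ||
    cfg$background_edge_density > 1 || cfg$rewiring_fraction > 1) {
    abort("densities and fractions must lie in [0, 1]")
  }
  if (module_size_range[1] < 2) abort("module sizes must be >= 2")
  need <- n_planted_modules * module_size_range[2]
  if (need > min(n_proteins_query, n_proteins_target)) {
    abort("planted modules cannot exceed the network size")
  }
  structure(cfg, class = "synthetic_config")
}

# random connected graph on 1..s: spanning tree plus extra random pairs
random_module_edges <- function(s, extra_prob = 0.3) {
  tree <- tibble(
    a = 2:s,
    b = map_int(2:s, \(i) sample.int(i - 1L, 1L))
  )
  rest <- tidyr::expand_grid(a = seq_len(s), b = seq_len(s)) |>
    filter(.data$a < .data$b) |>
    anti_join(
      mutate(tree, lo = pmin(.data$a, .data$b), hi = pmax(.data$a, .data$b)) |>
        select(a = "lo", b = "hi"),
      by = c("a", "b")
    )
  extra <- rest[runif(nrow(rest)) < extra_prob, ]
  bind_rows(tibble(a = pmin(tree$a, tree$b), b = pmax(tree$a, tree$b)), extra)
}

#' Generate a synthetic alignment problem with known ground truth
#'
#' @param config A [synthetic_config()].
#' @return List with `query_net`, `target_net` ([interactome()]s),
#'   `pairs` (homolog tibble with E-values, `fraction_identity`,
#'   `distance`, `is_decoy`), `null_evalues` (E-value null sample),
#'   `ground_truth` (tibble of planted modules with member and conserved
#'   edge list-columns, plus the true homolog map as attribute) and the
#'   `config`.
#' @export
generate_synthetic <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_rng(config$rng_seed, generate_synthetic_impl(config))
}

generate_synthetic_impl <- function(cfg) {
  qprot <- sprintf("Q%04d", seq_len(cfg$n_proteins_query))
  tprot <- sprintf("T%04d", seq_len(cfg$n_proteins_target))

  sizes <- sample(
    seq(cfg$module_size_range[1], cfg$module_size_range[2]),
    cfg$n_planted_modules,
    replace = TRUE
  )
  qm_pool <- sample(qprot, sum(sizes))
  tm_pool <- sample(tprot, sum(sizes))
  off <- c(0L, cumsum(sizes))
  modules <- map(seq_len(cfg$n_planted_modules), function(m) {
    idx <- (off[m] + 1L):off[m + 1L]
    list(
      q = qm_pool[idx], t = tm_pool[idx],
      edges = random_module_edges(sizes[m], cfg$module_extra_edge_prob)
    )
  })

  planted_q <- bind_rows(imap(modules, \(m, i) tibble(
    protein_a = m$q[m$edges$a], protein_b = m$q[m$edges$b], module = i
  )))
  planted_t <- bind_rows(imap(modules, \(m, i) tibble(
    protein_a = m$t[m$edges$a], protein_b = m$t[m$edges$b], module = i
  )))

  # one-sided deletions (rescuable by likely-conserved prediction): drop the
  # edge from one network only, keep its twin
  n_planted <- nrow(planted_q)
  drop_q <- logical(n_planted)
  drop_t <- logical(n_planted)
  if (cfg$planted_deletion_rate > 0) {
    hit <- which(runif(n_planted) < cfg$planted_deletion_rate)
    side <- runif(length(hit)) < 0.5
    drop_q[hit[side]] <- TRUE
    drop_t[hit[!side]] <- TRUE
  }
  # rewiring: exact count of planted edges altered on one random side
  n_rew <- round(cfg$rewiring_fraction * n_planted)
  if (n_rew > 0) {
    rew <- sample(setdiff(seq_len(n_planted), which(drop_q | drop_t)),
      min(n_rew, n_planted - sum(drop_q | drop_t))
    )
    side <- runif(length(rew)) < 0.5
    forbidden_q <- edge_key(planted_q$protein_a, planted_q$protein_b)
    forbidden_t <- edge_key(planted_t$protein_a, planted_t$protein_b)
    reattach <- function(anchor, prots, forbidden) {
      for (try in 1:100) {
        other <- sample(prots, 1L)
        if (!edge_key(anchor, other) %in% forbidden) break
      }
      other
    }
    for (k in seq_along(rew)) {
      i <- rew[k]
      if (side[k]) {
        drop_q[i] <- TRUE
        new_b <- reattach(planted_q$protein_a[i], qprot, forbidden_q)
        forbidden_q <- c(forbidden_q, edge_key(planted_q$protein_a[i], new_b))
        planted_q <- bind_rows(planted_q, tibble(
          protein_a = planted_q$protein_a[i], protein_b = new_b,
          module = NA_integer_
        ))
      } else {
        drop_t[i] <- TRUE
        new_b <- reattach(planted_t$protein_a[i], tprot, forbidden_t)
        forbidden_t <- c(forbidden_t, edge_key(planted_t$protein_a[i], new_b))
        planted_t <- bind_rows(planted_t, tibble(
          protein_a = planted_t$protein_a[i], protein_b = new_b,
          module = NA_integer_
        ))
      }
    }
  }
  kept_q <- planted_q[c(!drop_q, rep(TRUE, nrow(planted_q) - n_planted)), ]
  kept_t <- planted_t[c(!drop_t, rep(TRUE, nrow(planted_t) - n_planted)), ]

  er_edges <- function(prots, density, exclude) {
    n <- length(prots)
    m <- stats::rbinom(1, n * (n - 1) / 2, density)
    if (m == 0) {
      return(tibble(protein_a = character(), protein_b = character()))
    }
    i <- sample.int(n, m, replace = TRUE)
    j <- sample.int(n, m, replace = TRUE)
    keep <- i != j
    e <- tibble(
      protein_a = pmin(prots[i[keep]], prots[j[keep]]),
      protein_b = pmax(prots[i[keep]], prots[j[keep]])
    ) |> dplyr::distinct()
    anti_join(e, exclude, by = c("protein_a", "protein_b"))
  }
  canon <- function(df) {
    mutate(df,
      lo = pmin(.data$protein_a, .data$protein_b),
      hi = pmax(.data$protein_a, .data$protein_b),
      protein_a = .data$lo, protein_b = .data$hi
    ) |> select("protein_a", "protein_b")
  }
  bg_q <- er_edges(qprot, cfg$background_edge_density, canon(kept_q))
  bg_t <- er_edges(tprot, cfg$background_edge_density, canon(kept_t))

  pubs <- function(n, planted) {
    if (planted) cfg$pub_offset_planted + rgeom(n, cfg$pub_geom_p_planted)
    else 1L + rgeom(n, cfg$pub_geom_p_background)
  }
  make_net <- function(kept, bg, prots, tag) {
    interactome(
      bind_rows(
        mutate(canon(kept), n_publications = pubs(nrow(kept), TRUE)),
        mutate(bg, n_publications = pubs(nrow(bg), FALSE))
      ),
      species_tag = tag, proteins = prots
    )
  }
  query_net <- make_net(kept_q, bg_q, qprot, "query")
  target_net <- make_net(kept_t, bg_t, tprot, "target")

  # homolog pairs: planted 1-1 map + background homologs + decoys
  true_pairs <- bind_rows(imap(modules, \(m, i) tibble(
    query_protein = m$q, target_protein = m$t, module = i
  )))
  n_true <- nrow(true_pairs)
  free_q <- setdiff(qprot, true_pairs$query_protein)
  free_t <- setdiff(tprot, true_pairs$target_protein)
  n_bg <- round(cfg$background_homolog_fraction * n_true)
  bg_pairs <- tibble(
    query_protein = sample(free_q, n_bg),
    target_protein = sample(free_t, n_bg),
    module = NA_integer_
  )
  n_decoy <- round(cfg$decoy_fraction * n_true)
  decoys <- tibble(
    query_protein = sample(qprot, n_decoy, replace = TRUE),
    target_protein = sample(tprot, n_decoy, replace = TRUE),
    module = NA_integer_
  )
  em <- cfg$evalue_model
  # reciprocal E-values of one pair are strongly correlated (same local
  # alignment, different database size): one log10 draw per pair plus
  # small reciprocal noise
  pairs <- bind_rows(
    mutate(true_pairs, is_decoy = FALSE),
    mutate(bg_pairs, is_decoy = FALSE),
    mutate(decoys, is_decoy = TRUE)
  ) |>
    dplyr::distinct(.data$query_protein, .data$target_protein, .keep_all = TRUE) |>
    mutate(
      .l10 = ifelse(.data$is_decoy,
        runif(n(), em$decoy_log10_range[1], em$decoy_log10_range[2]),
        runif(n(), em$homolog_log10_range[1], em$homolog_log10_range[2])
      ),
      .under = !.data$is_decoy & runif(n()) < em$underflow_prob,
      evalue_qt = ifelse(.data$.under, 0, 10^.data$.l10),
      evalue_tq = ifelse(.data$.under, 0, 10^(.data$.l10 + rnorm(n(), 0, 0.3)))
    ) |>
    select(-".l10", -".under")
  im <- cfg$identity_model
  base <- runif(cfg$n_planted_modules, im$module_base_range[1], im$module_base_range[2])
  pairs <- pairs |>
    mutate(
      fraction_identity = ifelse(is.na(.data$module),
        runif(n(), im$random_range[1], im$random_range[2]),
        pmin(pmax(base[ifelse(is.na(.data$module), 1L, .data$module)] +
          rnorm(n(), 0, im$within_module_sd), 0.2), 0.99)
      ),
      distance = grishin_distance(.data$fraction_identity, tolerance = 1e-6)
    )

  null_evalues <- 10^rnorm(em$n_null, em$null_log10_mean, em$null_log10_sd)

  ground_truth <- tibble(
    module = seq_len(cfg$n_planted_modules),
    query_members = map(modules, "q"),
    target_members = map(modules, "t"),
    conserved_edges = imap(modules, \(m, i) tibble(
      query_a = m$q[m$edges$a], query_b = m$q[m$edges$b],
      target_a = m$t[m$edges$a], target_b = m$t[m$edges$b]
    ))
  )
  attr(ground_truth, "homolog_map") <- select(
    true_pairs, "query_protein", "target_protein", "module"
  )
  list(
    query_net = query_net, target_net = target_net,
    pairs = pairs, null_evalues = null_evalues,
    ground_truth = ground_truth, config = cfg
  )
}

#' Randomly rewire a fraction of a network's interactions
#'
#' Deletes exactly `round(fraction * n)` interactions and re-attaches one
#' endpoint of each to a random protein (duplicates of existing
#' interactions are re-drawn).  Models the connectivity changes an
#' aligner must tolerate; deterministic under `seed`.
#'
#' @param net An [interactome()].
#' @param fraction Fraction of interactions to alter, in `[0, 1]`.
#' @param seed Integer seed.
#' @return The rewired [interactome()].
#' @export
rewire_network <- function(net, fraction, seed = 1L) {
  if (fraction < 0 || fraction > 1) abort("fraction must lie in [0, 1]")
  n <- nrow(net)
  k <- round(fraction * n)
  if (k == 0) return(net)
  with_rng(seed, {
    prots <- interactome_proteins(net)
    edges <- as_tibble(net)
    hit <- sample.int(n, k)
    keys <- edge_key(edges$protein_a, edges$protein_b)
    original <- keys
    for (i in hit) {
      anchor <- if (runif(1) < 0.5) edges$protein_a[i] else edges$protein_b[i]
      for (try in 1:100) {
        other <- sample(prots, 1L)
        key <- edge_key(anchor, other)
        # never duplicate a current edge nor resurrect a removed one
        if (!key %in% keys && !key %in% original) break
      }
      edges$protein_a[i] <- pmin(anchor, other)
      edges$protein_b[i] <- pmax(anchor, other)
      keys[i] <- key
    }
    interactome(edges, species_tag = attr(net, "species_tag"), proteins = prots)
  })
}

#' Distance-difference samples for conservation-model fitting
#'
#' The observable analogue of the conservation/null contrast: `delta`
#' values of homolog-pair combinations whose interaction is present in
#' *both* networks (the conservation sample) versus `delta` values of
#' random homolog-pair combinations (the null sample, default `1e6`
#' draws).
#'
#' @param query_net,target_net [interactome()]s.
#' @param pairs Homolog pairs with a `distance` column.
#' @param n_null Null sample size (default `1e6`).
#' @return List with numeric vectors `conserved` and `null`.
#' @export
conservation_samples <- function(query_net, target_net, pairs, n_null = 1e6) {
  pairs <- filter(as_tibble(pairs), !is.na(.data$distance))
  if (nrow(pairs) < 2) abort("need at least two homolog pairs with distances")
  rel_q <- reliability_index(query_net)
  rel_t <- reliability_index(target_net)
  pairs <- mutate(pairs, id = row_number())
  by_query <- split(pairs$id, pairs$query_protein)
  conserved <- c()
  for (i in seq_len(nrow(query_net))) {
    v1 <- by_query[[query_net$protein_a[i]]]
    v2 <- by_query[[query_net$protein_b[i]]]
    if (is.null(v1) || is.null(v2)) next
    grid <- expand.grid(x = v1, y = v2)
    grid <- grid[grid$x != grid$y, , drop = FALSE]
    if (nrow(grid) == 0) next
    tkey <- edge_key(
      pairs$target_protein[grid$x], pairs$target_protein[grid$y]
    )
    hit <- !is.na(rel_t[tkey])
    if (any(hit)) {
      conserved <- c(
        conserved,
        abs(pairs$distance[grid$x[hit]] - pairs$distance[grid$y[hit]])
      )
    }
  }
  i <- sample.int(nrow(pairs), n_null, replace = TRUE)
  j <- sample.int(nrow(pairs), n_null, replace = TRUE)
  list(
    conserved = conserved,
    null = abs(pairs$distance[i] - pairs$distance[j])
  )
}
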