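#' Overlap distance between two member sets
#'
#' Jaccard distance `D = 1 - |a . b| / |a u b|`, used to cluster
#' redundant complexes/pathways before benchmarking so shared components
#' do not inflate performance.
#'
#' @param a,b Non-empty character vectors of members.
#' @return Distance in `[0, 1]`.
#' @export
set_distance <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) abort("sets must be non-empty")
  1 - length(intersect(a, b)) / length(union(a, b))
}

#' Cluster molecule sets into non-redundant groups
#'
#' Single-linkage clustering: sets closer than `threshold` (default 0.5)
#' in [set_distance()] end up in the same cluster.
#'
#' @param sets Tibble from [read_molecule_sets()] (columns `set_id`,
#'   `members`).
#' @param threshold Distance cutoff in `(0, 1)`.
#' @return `sets` with an integer `cluster` column.
#' @export
cluster_nonredundant <- function(sets, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) abort("threshold must be in (0, 1)")
  n <- nrow(sets)
  if (n == 0) return(mutate(sets, cluster = integer()))
  pairs <- which(
    outer(seq_len(n), seq_len(n), Vectorize(function(i, j) {
      i < j && set_distance(sets$members[[i]], sets$members[[j]]) < threshold
    })),
    arr.ind = TRUE
  )
  g <- igraph::graph_from_data_frame(
    data.frame(from = pairs[, 1], to = pairs[, 2]),
    directed = FALSE, vertices = data.frame(name = seq_len(n))
  )
  memb <- igraph::components(g)$membership
  mutate(sets, cluster = as.integer(memb[as.character(seq_len(n))]))
}

#' Is a query/target set pair conserved?
#'
#' True iff at least `min_count` and at least `min_frac` of the query
#' members have at least one homolog inside the target set, and vice
#' versa (the reciprocal criterion; defaults 2 and 25%).
#'
#' @param query_members,target_members Character vectors.
#' @param pairs Homolog pairs (`query_protein`, `target_protein`).
#' @param min_count,min_frac Conservation thresholds.
#' @return Logical scalar.
#' @export
conserved_pair <- function(query_members, target_members, pairs,
                           min_count = 2L, min_frac = 0.25) {
  if (length(query_members) == 0 || length(target_members) == 0) {
    abort("sets must be non-empty")
  }
  p <- filter(
    as_tibble(pairs),
    .data$query_protein %in% query_members,
    .data$target_protein %in% target_members
  )
  nq <- length(unique(p$query_protein))
  nt <- length(unique(p$target_protein))
  nq >= min_count && nq >= min_frac * length(query_members) &&
    nt >= min_count && nt >= min_frac * length(target_members)
}

#' Build non-redundant benchmark pairs
#'
#' Clusters each species' molecule sets ([cluster_nonredundant()]), keeps
#' cluster pairs satisfying [conserved_pair()], and picks as
#' representative the member pair minimising the number of unmatched
#' components (ties: maximising matched components, then lexicographic
#' set ids).
#'
#' @param query_sets,target_sets [read_molecule_sets()] tibbles.
#' @param pairs Homolog pairs.
#' @param min_count,min_frac Conservation thresholds (defaults 2, 0.25).
#' @param distance_threshold Clustering cutoff (default 0.5).
#' @return Tibble of benchmark pairs: `query_id`, `target_id`, `kind`
#'   and member list-columns.
#' @export
build_benchmark_pairs <- function(query_sets, target_sets, pairs,
                                  min_count = 2L, min_frac = 0.25,
                                  distance_threshold = 0.5) {
  qs <- cluster_nonredundant(query_sets, distance_threshold)
  ts <- cluster_nonredundant(target_sets, distance_threshold)
  out <- list()
  for (qc in unique(qs$cluster)) {
    for (tc in unique(ts$cluster)) {
      qsub <- qs[qs$cluster == qc, ]
      tsub <- ts[ts$cluster == tc, ]
      cand <- tidyr::expand_grid(qi = seq_len(nrow(qsub)), ti = seq_len(nrow(tsub)))
      stats <- pmap(cand, function(qi, ti) {
        qm <- qsub$members[[qi]]
        tm <- tsub$members[[ti]]
        p <- filter(
          as_tibble(pairs),
          .data$query_protein %in% qm, .data$target_protein %in% tm
        )
        matched <- length(unique(p$query_protein)) + length(unique(p$target_protein))
        unmatched <- (length(qm) + length(tm)) - matched
        ok <- conserved_pair(qm, tm, pairs, min_count, min_frac)
        tibble(
          qi = qi, ti = ti, ok = ok, matched = matched, unmatched = unmatched,
          qid = qsub$set_id[qi], tid = tsub$set_id[ti]
        )
      }) |> bind_rows()
      stats <- filter(stats, .data$ok)
      if (nrow(stats) == 0) next
      best <- stats |>
        arrange(.data$unmatched, dplyr::desc(.data$matched), .data$qid, .data$tid) |>
        dplyr::slice(1)
      out[[length(out) + 1L]] <- tibble(
        query_id = best$qid, target_id = best$tid,
        kind = qsub$kind[1],
        query_members = list(qsub$members[[best$qi]]),
        target_members = list(tsub$members[[best$ti]])
      )
    }
  }
  bind_rows(out)
}

#' Does a solution cover a molecule set?
#'
#' A solution covers a target complex/pathway when its target-side
#' proteins include at least `min_count` and at least `min_frac` of the
#' set's members (defaults: 2 and 50% for complexes, 2 and 1/3 for
#' pathways).
#'
#' @param solution_target_proteins Character vector: the solution's
#'   target-side proteins (or a one-row `netalign_result` slice).
#' @param members Members of the benchmark set.
#' @param min_count,min_frac Coverage thresholds.
#' @param kind `"complex"` or `"pathway"`; sets `min_frac` when omitted.
#' @return Logical scalar.
#' @export
covers <- function(solution_target_proteins, members, min_count = 2L,
                   min_frac = NULL, kind = c("complex", "pathway")) {
  kind <- match.arg(kind)
  min_frac <- min_frac %||% if (kind == "complex") 0.5 else 1 / 3
  if (is.data.frame(solution_target_proteins)) {
    solution_target_proteins <- solution_target_proteins$vertices[[1]]$target_protein
  }
  hit <- length(intersect(unique(solution_target_proteins), members))
  hit >= min_count && hit >= min_frac * length(members)
}

prf <- function(tp, fp, fn) {
  degenerate <- (tp + fp) == 0
  precision <- if (degenerate) 0 else tp / (tp + fp)
  recall <- if ((tp + fn) == 0) 0 else tp / (tp + fn)
  f <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  tibble(
    tp = tp, fp = fp, fn = fn,
    precision = precision, recall = recall, f_measure = f,
    degenerate = degenerate
  )
}

# direct target-network interactions realised by a solution's edges
solution_target_interactions <- function(edges) {
  direct <- map_lgl(edges$target_path, \(p) length(p) == 2)
  if (!any(direct)) return(character(0))
  unique(map_chr(edges$target_path[direct], \(p) edge_key(p[1], p[2])))
}

#' Evaluate alignment solutions against a benchmark
#'
#' Implements the benchmark bookkeeping at up to three levels.
#' * Set level (`i2i` mode): each significant solution is matched to the
#'   benchmark set minimising its number of unmatched proteins; TP is the
#'   number of distinct benchmark sets covered ([covers()]), FP the
#'   number of solutions covering none, FN the number of sets left
#'   uncovered.
#' * Query mode (`c2i`/`p2i`): only the top-ranked significant solution
#'   per benchmark pair is considered (supply one result per query via
#'   `results`).
#' * Protein level: TP = distinct proteins in solution/covered-set
#'   overlaps, FP = distinct proteins unique to solutions, FN = distinct
#'   proteins unique to covered sets.
#' * Interaction level (pathways with interaction lists): same
#'   bookkeeping on target-side interactions.
#'
#' @param results A `netalign_result`, or (query mode) a list of them,
#'   one per benchmark row.
#' @param benchmark Tibble from [build_benchmark_pairs()] (needs
#'   `target_members`; optionally `target_interactions` list-column of
#'   canonical `a<TAB>b` keys for the interaction level).
#' @param mode `"i2i"` or `"query"`.
#' @param kind `"complex"` or `"pathway"` (sets the coverage fraction).
#' @return Tibble of performance rows, one per level: `level`, `tp`,
#'   `fp`, `fn`, `precision`, `recall`, `f_measure`, `degenerate`.
#' @export
evaluate_alignment <- function(results, benchmark, mode = c("i2i", "query"),
                               kind = c("complex", "pathway")) {
  mode <- match.arg(mode)
  kind <- match.arg(kind)
  if (nrow(benchmark) == 0) abort("empty benchmark")
  set_label <- if (kind == "complex") "complex" else "pathway"

  # collect (solution target proteins, target interactions) per evaluated
  # solution together with the benchmark set it covers (if any)
  entries <- list()
  if (mode == "i2i") {
    stopifnot(inherits(results, "netalign_result"))
    sig <- filter(as_tibble(results), .data$significant)
    for (i in seq_len(nrow(sig))) {
      tprot <- unique(sig$vertices[[i]]$target_protein)
      # a solution may cover several (e.g. clustered) benchmark sets; all
      # count as distinct covered sets.  The best match — minimising the
      # total number of unmatched proteins — is used for the protein-level
      # overlap bookkeeping.
      hits <- which(map_lgl(
        benchmark$target_members, \(m) covers(tprot, m, kind = kind)
      ))
      best <- NA_integer_
      if (length(hits) > 0) {
        unmatched <- map_dbl(
          benchmark$target_members[hits],
          \(m) length(setdiff(tprot, m)) + length(setdiff(m, tprot))
        )
        best <- hits[which.min(unmatched)]
      }
      entries[[length(entries) + 1L]] <- list(
        proteins = tprot, covered = best, covered_all = hits,
        interactions = solution_target_interactions(sig$edges[[i]])
      )
    }
  } else {
    if (inherits(results, "netalign_result")) results <- list(results)
    if (length(results) != nrow(benchmark)) {
      abort("query mode needs one result per benchmark row")
    }
    for (j in seq_len(nrow(benchmark))) {
      res <- results[[j]]
      sig <- filter(as_tibble(res), .data$significant)
      if (nrow(sig) == 0) next
      top <- sig[which.max(sig$score), ] # highest-ranked significant solution
      tprot <- unique(top$vertices[[1]]$target_protein)
      hit <- covers(tprot, benchmark$target_members[[j]], kind = kind)
      entries[[length(entries) + 1L]] <- list(
        proteins = tprot, covered = if (hit) j else NA_integer_,
        covered_all = if (hit) j else integer(0),
        interactions = solution_target_interactions(top$edges[[1]])
      )
    }
  }

  covered <- unique(unlist(map(entries, "covered_all")))
  n_cov_none <- sum(map_lgl(entries, \(e) is.na(e$covered)))
  set_report <- prf(
    tp = length(covered), fp = n_cov_none,
    fn = nrow(benchmark) - length(covered)
  )

  # protein level: overlaps with covered sets only
  overlap <- character(0); sol_only <- character(0); set_only <- character(0)
  for (e in entries) {
    if (is.na(e$covered)) {
      sol_only <- union(sol_only, e$proteins)
    } else {
      m <- benchmark$target_members[[e$covered]]
      overlap <- union(overlap, intersect(e$proteins, m))
      sol_only <- union(sol_only, setdiff(e$proteins, m))
      set_only <- union(set_only, setdiff(m, e$proteins))
    }
  }
  sol_only <- setdiff(sol_only, overlap)
  set_only <- setdiff(set_only, overlap)
  protein_report <- prf(length(overlap), length(sol_only), length(set_only))

  out <- bind_rows(
    mutate(set_report, level = set_label, .before = 1),
    mutate(protein_report, level = "protein", .before = 1)
  )

  if (kind == "pathway" && "target_interactions" %in% names(benchmark)) {
    io <- character(0); is_ <- character(0); ib <- character(0)
    for (e in entries) {
      if (is.na(e$covered)) {
        is_ <- union(is_, e$interactions)
      } else {
        m <- benchmark$target_interactions[[e$covered]]
        io <- union(io, intersect(e$interactions, m))
        is_ <- union(is_, setdiff(e$interactions, m))
        ib <- union(ib, setdiff(m, e$interactions))
      }
    }
    is_ <- setdiff(is_, io)
    ib <- setdiff(ib, io)
    out <- bind_rows(
      out,
      mutate(prf(length(io), length(is_), length(ib)), level = "interaction", .before = 1)
    )
  }
  out
}

#' Grid-search calibration of alignment parameters
#'
#' Runs a user-supplied evaluation function over a parameter grid and
#' returns the grid ordered by decreasing mean F-measure, the rule used
#' to pick per-task default profiles.
#'
#' @param grid Data frame of parameter combinations (one column per
#'   [align_params()] argument to vary).
#' @param eval_fun Function taking one grid row (as a list) and returning
#'   an [evaluate_alignment()] report.
#' @return `grid` with a `mean_f` column, best first.
#' @export
calibrate_parameters <- function(grid, eval_fun) {
  grid <- as_tibble(grid)
  grid$mean_f <- map_dbl(seq_len(nrow(grid)), function(i) {
    rep <- eval_fun(as.list(grid[i, ]))
    mean(rep$f_measure)
  })
  arrange(grid, dplyr::desc(.data$mean_f))
}
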