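#' Read a homolog-pair table from TSV
#'
#' Format: `query_id<TAB>target_id<TAB>evalue_qt<TAB>evalue_tq`, no
#' header.  Used for precomputed ortholog/paralog lists; for raw BLAST
#' tabular output see [infer_reciprocal_orthologs()].
#'
#' @param path Path to the TSV.
#' @return Tibble with columns `query_protein`, `target_protein`,
#'   `evalue_qt`, `evalue_tq`.
#' @export
read_homologs <- function(path) {
  df <- readr::read_tsv(
    path,
    col_names = c("query_protein", "target_protein", "evalue_qt", "evalue_tq"),
    col_types = "ccdd", progress = FALSE
  )
  if (any(is.na(df$evalue_qt)) || any(is.na(df$evalue_tq))) {
    abort(sprintf("missing or non-numeric E-value in %s", path))
  }
  if (any(df$evalue_qt < 0) || any(df$evalue_tq < 0)) {
    abort("E-values must be >= 0")
  }
  df
}

#' Infer orthologs by reciprocal BLAST
#'
#' Keeps the pair (a, b) iff b appears among a's `top_k` best hits with
#' E-value at most `evalue_cutoff` in the query-to-target search AND a
#' appears among b's `top_k` hits under the same cutoff in the reverse
#' search.  One-to-many and many-to-many relations are retained — no
#' best-hit uniqueness is imposed.
#'
#' @param hits_qt,hits_tq Tibbles of BLAST tabular hits with columns
#'   `query`, `subject`, `evalue` and optionally `rank` (computed per
#'   query by increasing E-value when absent).  `hits_qt` searches the
#'   query proteome against the target proteome, `hits_tq` the reverse.
#' @param evalue_cutoff Maximum E-value (default `1e-10`).
#' @param top_k Hits beyond this rank per query are discarded as spurious
#'   (default 10).
#' @return Tibble `query_protein`, `target_protein`, `evalue_qt`,
#'   `evalue_tq`.
#' @export
infer_reciprocal_orthologs <- function(hits_qt, hits_tq,
                                       evalue_cutoff = 1e-10, top_k = 10L) {
  if (is.null(hits_qt) || is.null(hits_tq)) {
    abort("both reciprocal hit lists are required")
  }
  prep <- function(hits) {
    hits <- as_tibble(hits)
    stopifnot(all(c("query", "subject", "evalue") %in% names(hits)))
    if (!"rank" %in% names(hits)) {
      hits <- hits |>
        group_by(.data$query) |>
        arrange(.data$evalue, .data$subject, .by_group = TRUE) |>
        mutate(rank = row_number()) |>
        ungroup()
    }
    hits |>
      filter(.data$rank <= top_k, .data$evalue <= evalue_cutoff) |>
      group_by(.data$query, .data$subject) |>
      summarise(evalue = min(.data$evalue), .groups = "drop")
  }
  fwd <- prep(hits_qt)
  rev <- prep(hits_tq) |>
    rename(target = "query", query = "subject", evalue_tq = "evalue")
  inner_join(
    rename(fwd, target = "subject", evalue_qt = "evalue"),
    rev,
    by = c("query", "target")
  ) |>
    select(
      query_protein = "query", target_protein = "target",
      "evalue_qt", "evalue_tq"
    ) |>
    arrange(.data$query_protein, .data$target_protein)
}

#' Assign calibrated vertex probabilities to homolog pairs
#'
#' Each pair's likelihood ratio is looked up from the fitted E-value
#' table at the smaller of its two reciprocal E-values (the stronger
#' direction), then scaled with [vertex_probability()] so the best pair
#' reaches `target_max`.
#'
#' @param pairs Homolog-pair tibble ([read_homologs()] /
#'   [infer_reciprocal_orthologs()] output).
#' @param table `lr_table` from [fit_likelihood_ratios()].
#' @param target_max Calibration point for the maximal-ratio pair
#'   (default 1).
#' @return `pairs` with columns `likelihood_ratio` and
#'   `vertex_probability` added.
#' @export
assign_vertex_probabilities <- function(pairs, table, target_max = 1) {
  pairs <- as_tibble(pairs)
  ev <- pmin(pairs$evalue_qt, pairs$evalue_tq)
  pairs$likelihood_ratio <- lr_lookup(ev, table)
  pairs$vertex_probability <-
    vertex_probability(pairs$likelihood_ratio, table, target_max)
  pairs
}

#' Identity pairing for intra-species alignment
#'
#' When two condition-specific networks of the same species are aligned
#' and no paralog list is wanted, every shared protein is paired with
#' itself at vertex probability 1.
#'
#' @param query_net,target_net [interactome()]s over the same namespace.
#' @return Homolog-pair tibble with `vertex_probability = 1` and
#'   `distance = 0` for every shared protein.
#' @export
identity_pairs <- function(query_net, target_net) {
  shared <- intersect(
    interactome_proteins(query_net), interactome_proteins(target_net)
  )
  tibble(
    query_protein = shared, target_protein = shared,
    evalue_qt = 0, evalue_tq = 0,
    likelihood_ratio = Inf, vertex_probability = 1,
    fraction_identity = 1, distance = 0
  )
}
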