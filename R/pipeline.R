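#' Run the full alignment pipeline from files
#'
#' Orchestrates the end-to-end tool run: read networks, homologs and
#' identities, fit the E-value likelihood-ratio table (when a null
#' E-value sample is given) or fall back to precomputed vertex
#' probabilities, fit the conservation model from the observed conserved
#' interactions if prediction is requested, align, and write the
#' solutions (TSV + SIF + GraphML) along with a run manifest recording
#' all parameters, the seed and input checksums — identical manifests
#' imply identical outputs.
#'
#' @param config A list (e.g. from [read_run_config()]) with entries:
#'   `query`, `target` (interaction TSVs), `homologs`, `identities`
#'   (optional), `null_evalues` (optional TSV, one E-value per line),
#'   `support` (`"count"`/`"reliability"`), `mode`, `query_set` (optional
#'   molecule-set file for c2i/p2i; its first set becomes the query
#'   network), plus any [align_params()] fields, `seed` and `out_dir`.
#' @return The `netalign_result`, invisibly; artifacts land in
#'   `config$out_dir`.
#' @export
run_align <- function(config) {
  cfg <- config
  for (f in c("query", "target", "homologs")) {
    if (is.null(cfg[[f]])) abort(sprintf("config is missing '%s'", f))
    if (!file.exists(cfg[[f]])) abort(sprintf("input file not found: %s", cfg[[f]]))
  }
  params <- align_params(
    vertex_prob_threshold = cfg$vertex_prob_threshold,
    edge_prob_threshold = cfg$edge_prob_threshold,
    predict_likely_conserved = cfg$predict_likely_conserved %||% FALSE,
    max_path_length = cfg$max_path_length %||% 3L,
    alpha = cfg$alpha %||% 0.5,
    p_threshold = cfg$p_threshold %||% 0.05,
    n_random_scores = cfg$n_random_scores %||% 10000L,
    mode = cfg$mode %||% "i2i",
    intra_species = cfg$intra_species %||% FALSE
  )
  seed <- as.integer(cfg$seed %||% 1L)
  support <- cfg$support %||% "count"
  target_net <- read_interactions(cfg$target, support = support, species_tag = "target")
  query_net <- read_interactions(cfg$query, support = support, species_tag = "query")
  if (!is.null(cfg$query_set)) {
    sets <- read_molecule_sets(
      cfg$query_set,
      kind = if (params$mode == "p2i") "pathway" else "complex"
    )
    query_net <- build_query_network(sets$members[[1]], query_net)
  }
  pairs <- read_homologs(cfg$homologs)
  if (!is.null(cfg$null_evalues)) {
    nulls <- as.numeric(readr::read_lines(cfg$null_evalues))
    lr <- fit_likelihood_ratios(pmin(pairs$evalue_qt, pairs$evalue_tq), nulls)
    pairs <- assign_vertex_probabilities(pairs, lr)
  } else if (!"vertex_probability" %in% names(pairs)) {
    abort("either a null E-value sample or precomputed vertex probabilities are required")
  }
  if (!is.null(cfg$identities)) {
    pairs <- assign_distances(
      pairs,
      read_identities(cfg$identities, value = cfg$identity_value %||% "identity")
    )
  }
  cons_model <- NULL
  if (params$predict_likely_conserved) {
    if (!"distance" %in% names(pairs)) {
      abort("likely-conserved prediction needs an identity/distance table")
    }
    cons_model <- with_rng(seed + 1L, {
      s <- conservation_samples(
        query_net, target_net, pairs,
        n_null = cfg$n_null_deltas %||% 1e6
      )
      fit_conservation_model(s$conserved, s$null)
    })
  }
  result <- align_networks(
    query_net, target_net, pairs, cons_model,
    params = params, seed = seed
  )

  out <- cfg$out_dir %||% "."
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_solutions(result, file.path(out, "solutions.tsv"), "tsv")
  write_solutions(result, file.path(out, "solutions.sif"), "sif")
  write_solutions(result, file.path(out, "solutions.graphml"), "graphml")
  manifest <- c(
    unclass(params),
    list(
      seed = seed, support = support,
      inputs = as.list(tools::md5sum(unlist(cfg[c("query", "target", "homologs")])))
    )
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(result)
}

#' Evaluate written solutions against a benchmark
#'
#' @param result A `netalign_result` (or [run_align()] output).
#' @param benchmark_query,benchmark_target Molecule-set files for the two
#'   species.
#' @param homologs Homolog TSV used for the conserved-pair criterion.
#' @param mode `"i2i"` or `"query"`.
#' @param kind `"complex"` or `"pathway"`.
#' @param out_path Optional TSV path for the report.
#' @return The [evaluate_alignment()] report.
#' @export
run_evaluate <- function(result, benchmark_query, benchmark_target, homologs,
                         mode = "i2i", kind = "complex", out_path = NULL) {
  pairs <- read_homologs(homologs)
  bench <- build_benchmark_pairs(
    read_molecule_sets(benchmark_query, kind = kind),
    read_molecule_sets(benchmark_target, kind = kind),
    pairs
  )
  rep <- evaluate_alignment(result, bench, mode = mode, kind = kind)
  if (!is.null(out_path)) write_report(rep, out_path)
  rep
}

#' Generate synthetic input files
#'
#' Writes the exact TSV formats the readers consume: `query.tsv`,
#' `target.tsv` (publication-count dialect), `homologs.tsv`,
#' `identities.tsv`, `null_evalues.tsv`, plus the planted modules as
#' molecule-set files (`truth_query.tsv`, `truth_target.tsv`).
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory.
#' @return The [generate_synthetic()] list, invisibly.
#' @export
run_synth <- function(config = synthetic_config(), out_dir = ".") {
  syn <- generate_synthetic(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_interactions(syn$query_net, file.path(out_dir, "query.tsv"), "count")
  write_interactions(syn$target_net, file.path(out_dir, "target.tsv"), "count")
  readr::write_lines(
    sprintf(
      "%s\t%s\t%.6e\t%.6e",
      syn$pairs$query_protein, syn$pairs$target_protein,
      syn$pairs$evalue_qt, syn$pairs$evalue_tq
    ),
    file.path(out_dir, "homologs.tsv")
  )
  readr::write_lines(
    sprintf(
      "%s\t%s\t%.6f",
      syn$pairs$query_protein, syn$pairs$target_protein,
      syn$pairs$fraction_identity
    ),
    file.path(out_dir, "identities.tsv")
  )
  readr::write_lines(
    format(syn$null_evalues, digits = 8, scientific = TRUE, trim = TRUE),
    file.path(out_dir, "null_evalues.tsv")
  )
  gt <- syn$ground_truth
  readr::write_lines(
    sprintf("M%02d\t%s", gt$module, map_chr(gt$query_members, paste, collapse = ",")),
    file.path(out_dir, "truth_query.tsv")
  )
  readr::write_lines(
    sprintf("M%02d\t%s", gt$module, map_chr(gt$target_members, paste, collapse = ",")),
    file.path(out_dir, "truth_target.tsv")
  )
  invisible(syn)
}

#' Read a YAML run configuration
#'
#' Flat YAML mapping of [run_align()] fields; command-line flags can
#' override individual entries.
#'
#' @param path YAML file.
#' @param overrides Named list of overriding values.
#' @return Config list.
#' @export
read_run_config <- function(path, overrides = list()) {
  cfg <- yaml::read_yaml(path)
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  cfg
}
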