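#' Grishin evolutionary distance from fraction identity
#'
#' Solves `q = ln(1 + 2d) / (2d)` for the number of amino-acid
#' substitutions per site `d`, the Grishin model that allows substitution
#' rates to vary both across sites and across residue types.  The solver
#' iterates the contractive rearrangement `d <- ln(1 + 2d) / (2q)` from
#' the sites-only starting point `d0 = (1 - q)/q` until successive
#' estimates differ by less than `tolerance`, falling back to bisection on
#' the residual `ln(1 + 2d) - 2dq` if the iteration fails to settle.
#'
#' @param q Fraction of identical residues, in `(0, 1]` (vectorised).
#' @param tolerance Convergence threshold on successive estimates, in
#'   substitutions per site (default `1e-3`).
#' @param max_iter Iteration cap before the bisection fallback engages.
#' @return Distances `d >= 0`; `d = 0` iff `q = 1`.
#' @examples
#' grishin_distance(c(1, 0.9, 0.5), tolerance = 1e-9)
#' @export
grishin_distance <- function(q, tolerance = 1e-3, max_iter = 10000L) {
  if (any(is.na(q)) || any(q <= 0) || any(q > 1)) {
    abort("fraction identity must lie in (0, 1]")
  }
  if (tolerance <= 0) abort("tolerance must be positive")
  vapply(q, grishin_one, numeric(1),
    tolerance = tolerance, max_iter = max_iter
  )
}

grishin_one <- function(q, tolerance, max_iter) {
  if (q == 1) return(0)
  d <- (1 - q) / q
  for (i in seq_len(max_iter)) {
    d_new <- log(1 + 2 * d) / (2 * q)
    if (abs(d_new - d) < tolerance) return(d_new)
    d <- d_new
  }
  # bisection on g(d) = ln(1+2d) - 2dq; g(0+) > 0, g -> -Inf
  lo <- 0
  hi <- max(d, 1)
  g <- function(x) log(1 + 2 * x) - 2 * x * q
  while (g(hi) > 0) hi <- hi * 2
  for (i in seq_len(200L)) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tolerance) break
  }
  (lo + hi) / 2
}

#' Difference of evolutionary distances
#'
#' The statistic behind likely-conserved-interaction prediction:
#' interacting proteins evolve at correlated rates, so the two homolog
#' pairs flanking a conserved interaction tend to have similar distances
#' and hence a small `delta = |d1 - d2|`.
#'
#' @param d1,d2 Non-negative distances (substitutions per site).
#' @return `abs(d1 - d2)`.
#' @export
delta_distance <- function(d1, d2) {
  if (any(d1 < 0) || any(d2 < 0)) abort("distances must be >= 0")
  abs(d1 - d2)
}

# fixed-width binning of distance differences
delta_bin <- function(delta, bin_width = 0.1) {
  floor(delta / bin_width)
}

#' Fit an interaction-conservation model
#'
#' Likelihood-ratio calibration over distance differences: `delta`
#' values observed for homolog pairs flanking a conserved interaction
#' (the conservation model) are compared against `delta` values of random
#' homolog-pair combinations (the null model) in fixed-width bins
#' (default 0.1 substitutions/site), with add-one count smoothing and a
#' monotone non-increasing PAVA fit — a larger distance difference never
#' yields a larger conservation probability.  The maximal-ratio bin is
#' calibrated to probability `target_max` (default 0.9).
#'
#' @param conserved_deltas Distance differences from conserved
#'   interactions.
#' @param null_deltas Distance differences from random homolog pairs
#'   (default size `1e6` when generated by
#'   [conservation_samples()]).
#' @param target_max Conservation probability of the maximal-ratio bin.
#' @param bin_width Bin width in substitutions per site.
#' @return A `conservation_model`: an `lr_table` over delta bins plus the
#'   calibration target.
#' @export
fit_conservation_model <- function(conserved_deltas, null_deltas,
                                   target_max = 0.9, bin_width = 0.1) {
  if (length(conserved_deltas) == 0 || length(null_deltas) == 0) {
    abort("both the conservation and the null sample must be non-empty")
  }
  if (any(c(conserved_deltas, null_deltas) < 0)) abort("deltas must be >= 0")
  cb <- delta_bin(conserved_deltas, bin_width)
  nb <- delta_bin(null_deltas, bin_width)
  bins <- seq(0, max(cb, nb))
  tab <- new_lr_table(cb, nb, bins, statistic = "delta")
  tab$bin_width <- bin_width
  tab$target_max <- target_max
  class(tab) <- c("conservation_model", "lr_table")
  tab
}

#' Interaction conservation probability
#'
#' `p = target_max * LR(bin(delta)) / max_ratio`, bounded by the model's
#' `target_max` and monotone non-increasing in `delta`.
#'
#' @param delta Non-negative distance differences.
#' @param model A [fit_conservation_model()] result.
#' @return Probabilities in `[0, target_max]`.
#' @export
conservation_probability <- function(delta, model) {
  if (!inherits(model, "conservation_model")) {
    abort("`model` must be a fitted conservation_model")
  }
  if (any(delta < 0)) abort("delta must be >= 0")
  lr <- lr_lookup(delta, model)
  pmin(model$target_max * lr / model$max_ratio, model$target_max)
}

#' Read a fraction-identity (or distance) table
#'
#' Format: `query_id<TAB>target_id<TAB>value`, no header.  With
#' `value = "identity"` the third column is a fraction identity in
#' `(0, 1]` converted through [grishin_distance()]; with
#' `value = "distance"` it is used as a precomputed distance.  When a pair
#' occurs several times (multiple alignments), the smallest distance
#' (best alignment) is kept.
#'
#' @param path TSV path.
#' @param value `"identity"` or `"distance"`.
#' @param tolerance Passed to [grishin_distance()].
#' @return Tibble `query_protein`, `target_protein`, `distance`.
#' @export
read_identities <- function(path, value = c("identity", "distance"),
                            tolerance = 1e-6) {
  value <- match.arg(value)
  df <- readr::read_tsv(
    path,
    col_names = c("query_protein", "target_protein", "x"),
    col_types = "ccd", progress = FALSE
  )
  if (any(is.na(df$x))) abort(sprintf("non-numeric value in %s", path))
  d <- if (value == "identity") grishin_distance(df$x, tolerance) else df$x
  if (any(d < 0)) abort("distances must be >= 0")
  df |>
    mutate(distance = d) |>
    group_by(.data$query_protein, .data$target_protein) |>
    summarise(distance = min(.data$distance), .groups = "drop")
}

#' Attach evolutionary distances to homolog pairs
#'
#' @param pairs Homolog-pair tibble.
#' @param identities [read_identities()]-style tibble, or a tibble with
#'   `fraction_identity` instead of `distance`.
#' @param tolerance Passed to [grishin_distance()] if identities need
#'   converting.
#' @return `pairs` with a `distance` column; pairs without a record get
#'   `NA` (they can never support a likely-conserved edge).
#' @export
assign_distances <- function(pairs, identities, tolerance = 1e-6) {
  identities <- as_tibble(identities)
  if (!"distance" %in% names(identities)) {
    identities$distance <- grishin_distance(
      identities$fraction_identity, tolerance
    )
  }
  left_join(
    as_tibble(pairs),
    select(identities, "query_protein", "target_protein", "distance"),
    by = c("query_protein", "target_protein")
  )
}
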