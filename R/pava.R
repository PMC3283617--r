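#' Monotone (isotonic) regression by pool-adjacent-violators
#'
#' Weighted least-squares projection of a vector onto the cone of
#' monotone vectors, used to smooth empirical likelihood-ratio curves.
#' Adjacent blocks that violate the requested direction are pooled into
#' their weighted mean until the fit is monotone.
#'
#' @param values Numeric vector to smooth.
#' @param weights Positive weights, same length (default unit weights).
#' @param direction `"nonincreasing"` (default, the likelihood-ratio use
#'   case) or `"nondecreasing"`.
#' @return Numeric vector of the same length, monotone in the requested
#'   direction, minimising `sum(weights * (fit - values)^2)`.
#' @examples
#' pava_monotone(c(3, 1, 2)) # c(3, 1.5, 1.5)
#' @export
pava_monotone <- function(values, weights = NULL,
                          direction = c("nonincreasing", "nondecreasing")) {
  direction <- match.arg(direction)
  n <- length(values)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) abort("values and weights differ in length")
  if (any(weights <= 0)) abort("weights must be positive")
  if (n == 0) return(numeric(0))
  v <- if (direction == "nonincreasing") -values else values
  # block-merging PAVA for nondecreasing fit of v
  mean_ <- numeric(n); wt <- numeric(n); size <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    top <- top + 1L
    mean_[top] <- v[i]; wt[top] <- weights[i]; size[top] <- 1L
    while (top > 1L && mean_[top - 1L] > mean_[top]) {
      w <- wt[top - 1L] + wt[top]
      mean_[top - 1L] <- (wt[top - 1L] * mean_[top - 1L] + wt[top] * mean_[top]) / w
      wt[top - 1L] <- w
      size[top - 1L] <- size[top - 1L] + size[top]
      top <- top - 1L
    }
  }
  fit <- rep(mean_[seq_len(top)], times = size[seq_len(top)])
  if (direction == "nonincreasing") -fit else fit
}

#' Bin an E-value (or any positive score) by order of magnitude
#'
#' Returns `floor(log10(x))`; an exact zero (BLAST E-value underflow) maps
#' to `-Inf`, a dedicated bin ordered below all finite bins so monotone
#' smoothing across bins remains well defined.
#'
#' @param evalue Numeric vector of non-negative values.
#' @return Numeric vector of bin indices (`-Inf` for zeros).
#' @examples
#' bin_by_magnitude(c(3e-5, 1e-10, 9.9e-10, 0))
#' @export
bin_by_magnitude <- function(evalue) {
  if (any(is.na(evalue)) || any(evalue < 0)) abort("E-values must be >= 0")
  out <- rep(-Inf, length(evalue))
  pos <- evalue > 0
  out[pos] <- floor(log10(evalue[pos]))
  out
}

# shared constructor for a binned, PAVA-smoothed likelihood-ratio table.
# `bin` maps raw statistics to bin indices; bins are ordered increasing and
# ratios are non-increasing along that order after smoothing.
new_lr_table <- function(model_bins, null_bins, all_bins, statistic) {
  counts <- tibble(bin = all_bins) |>
    mutate(
      n_model = map_dbl(.data$bin, \(b) sum(model_bins == b)),
      n_null = map_dbl(.data$bin, \(b) sum(null_bins == b)),
      # add-one smoothing keeps finite ratios in bins the null never hit
      f_model = (.data$n_model + 1) / (sum(.data$n_model) + dplyr::n()),
      f_null = (.data$n_null + 1) / (sum(.data$n_null) + dplyr::n()),
      raw_ratio = .data$f_model / .data$f_null
    )
  counts$ratio <- pava_monotone(counts$raw_ratio, direction = "nonincreasing")
  structure(
    list(table = counts, max_ratio = max(counts$ratio), statistic = statistic),
    class = "lr_table"
  )
}

#' Fit a likelihood-ratio table from E-value samples
#'
#' Empirical-Bayes calibration of sequence similarity: E-values observed
#' under a homology model (accepted ortholog pairs) and under a null model
#' (all protein pairs between the two species) are binned by order of
#' magnitude ([bin_by_magnitude()]); the per-bin frequency ratio
#' model/null, with add-one count smoothing, is then projected onto the
#' monotone non-increasing cone with [pava_monotone()] — smaller E-values
#' never get smaller ratios.
#'
#' @param model_values E-values sampled under the homology model.
#' @param null_values E-values sampled under the null model.
#' @return An object of class `lr_table` with elements `table` (tibble of
#'   `bin`, counts and smoothed `ratio`), `max_ratio` and `statistic`.
#' @seealso [vertex_probability()], [lr_lookup()]
#' @export
fit_likelihood_ratios <- function(model_values, null_values) {
  if (length(model_values) == 0 || length(null_values) == 0) {
    abort("both the model and the null sample must be non-empty")
  }
  mb <- bin_by_magnitude(model_values)
  nb <- bin_by_magnitude(null_values)
  finite <- c(mb[is.finite(mb)], nb[is.finite(nb)])
  bins <- if (length(finite) > 0) seq(min(finite), max(finite)) else numeric(0)
  if (any(!is.finite(c(mb, nb)))) bins <- c(-Inf, bins)
  new_lr_table(mb, nb, bins, statistic = "evalue")
}

#' @export
print.lr_table <- function(x, ...) {
  cat("# Likelihood-ratio table (", x$statistic, "), ",
    nrow(x$table), " bins, max ratio ", format(x$max_ratio, digits = 4),
    "\n",
    sep = ""
  )
  print(x$table, ...)
  invisible(x)
}

#' Look up smoothed likelihood ratios for new statistics
#'
#' Values falling below the fitted bin range take the first (largest)
#' ratio, values above take the last; this keeps lookups monotone.
#'
#' @param x Numeric vector of statistics on the table's original scale
#'   (raw E-values for tables from [fit_likelihood_ratios()], distance
#'   differences for [fit_conservation_model()] tables).
#' @param table An `lr_table`.
#' @return Numeric vector of smoothed likelihood ratios.
#' @export
lr_lookup <- function(x, table) {
  stopifnot(inherits(table, "lr_table"))
  bins <- if (table$statistic == "evalue") bin_by_magnitude(x) else
    delta_bin(x, table$bin_width)
  tb <- table$table$bin
  idx <- findInterval(bins, tb)
  idx[idx < 1L] <- 1L
  idx[idx > length(tb)] <- length(tb)
  table$table$ratio[idx]
}

#' Vertex probability from a likelihood ratio
#'
#' Calibrated so the homolog pair with the highest smoothed likelihood
#' ratio receives probability `target_max` (default 1):
#' `p = target_max * LR / max_ratio`, clamped to `[0, 1]`.  The scaling is
#' invariant to multiplying all ratios by a constant.
#'
#' @param likelihood_ratio Non-negative likelihood ratio(s).
#' @param table The fitted `lr_table` (supplies `max_ratio`).
#' @param target_max Probability assigned at the maximal ratio.
#' @return Probabilities in `[0, target_max]`.
#' @export
vertex_probability <- function(likelihood_ratio, table, target_max = 1) {
  if (any(likelihood_ratio < 0)) abort("likelihood ratios must be >= 0")
  if (target_max <= 0 || target_max > 1) abort("target_max must be in (0, 1]")
  mr <- if (inherits(table, "lr_table")) table$max_ratio else as.numeric(table)
  if (!is.finite(mr) || mr <= 0) abort("max_ratio must be positive")
  pmin(pmax(target_max * likelihood_ratio / mr, 0), 1)
}
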