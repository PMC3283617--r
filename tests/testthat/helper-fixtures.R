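# compact builders for hand-written fixtures

# net("A-B:0.5", "B-C:1") -> interactome with those reliabilities
net <- function(..., species_tag = "net", proteins = NULL) {
  spec <- c(...)
  if (length(spec) == 0) {
    return(interactome(
      tibble::tibble(protein_a = character(), protein_b = character()),
      species_tag = species_tag, proteins = proteins
    ))
  }
  parts <- strsplit(spec, "[-:]")
  interactome(
    tibble::tibble(
      protein_a = vapply(parts, `[`, "", 1),
      protein_b = vapply(parts, `[`, "", 2),
      reliability = vapply(
        parts, \(p) if (length(p) > 2) as.numeric(p[3]) else 1, 0
      )
    ),
    species_tag = species_tag, proteins = proteins
  )
}

# homolog pairs with ready-made vertex probabilities (and distances)
pairs_tbl <- function(q, t, vp = 1, d = NA_real_) {
  tibble::tibble(
    query_protein = q, target_protein = t,
    vertex_probability = rep_len(vp, length(q)),
    distance = rep_len(d, length(q))
  )
}

random_interactome <- function(n, p, seed, tag = "rand") {
  withr::with_seed(seed, {
    prots <- sprintf("P%02d", seq_len(n))
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keep <- stats::runif(nrow(idx)) < p
    interactome(
      tibble::tibble(
        protein_a = prots[idx[keep, 1]],
        protein_b = prots[idx[keep, 2]],
        reliability = round(stats::runif(sum(keep), 0.1, 1), 3)
      ),
      species_tag = tag, proteins = prots
    )
  })
}

small_synth <- function(seed = 1L, ...) {
  synthetic_config(
    n_proteins_query = 120L, n_proteins_target = 120L,
    n_planted_modules = 6L, module_size_range = c(3L, 6L),
    rng_seed = seed, ...
  )
}
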