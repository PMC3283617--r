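#' Construct an interactome
#'
#' An interactome is a weighted undirected protein-protein interaction
#' network: a tibble of interactions (one row per unordered protein pair)
#' carrying a per-interaction reliability in `[0, 1]`, plus the set of
#' proteins it spans.  Pairs are canonicalised (`protein_a <=
#' protein_b` lexicographically) and deduplicated; self-interactions are
#' legal.  Reliabilities derive from publication counts via
#' [reliability_from_publications()] unless given directly.
#'
#' @param interactions A data frame with columns `protein_a`, `protein_b`
#'   and either `n_publications` (non-negative integer counts) or
#'   `reliability` (probabilities in `[0, 1]`), or both.
#' @param species_tag Short label for the species/network (e.g. `"yeast"`).
#' @param proteins Optional character vector of proteins; proteins
#'   referenced by interactions are always included, so this only adds
#'   isolated proteins.
#'
#' @return An `interactome`: a tibble with columns `protein_a`,
#'   `protein_b`, `n_publications`, `reliability` and attributes
#'   `species_tag` and `proteins`.
#' @examples
#' interactome(
#'   tibble::tibble(
#'     protein_a = c("B", "A"), protein_b = c("A", "C"),
#'     n_publications = c(2L, 1L)
#'   ),
#'   species_tag = "toy"
#' )
#' @export
interactome <- function(interactions, species_tag = "network", proteins = NULL) {
  stopifnot(is.data.frame(interactions))
  if (nrow(interactions) == 0) {
    edges <- tibble(
      protein_a = character(), protein_b = character(),
      n_publications = integer(), reliability = double()
    )
  } else {
    if (!all(c("protein_a", "protein_b") %in% names(interactions))) {
      abort("`interactions` needs columns protein_a and protein_b")
    }
    edges <- as_tibble(interactions)
    if (!"n_publications" %in% names(edges)) edges$n_publications <- NA_integer_
    if (!"reliability" %in% names(edges)) {
      if (all(is.na(edges$n_publications))) {
        abort("need either n_publications or reliability")
      }
      edges$reliability <- reliability_from_publications(edges$n_publications)
    }
    if (any(edges$reliability < 0 | edges$reliability > 1, na.rm = TRUE)) {
      abort("reliability must lie in [0, 1]")
    }
    # canonical unordered pair, then merge duplicates by maximum support
    edges <- edges |>
      mutate(
        .a = pmin(.data$protein_a, .data$protein_b),
        .b = pmax(.data$protein_a, .data$protein_b)
      ) |>
      group_by(.data$.a, .data$.b) |>
      summarise(
        n_publications = if (all(is.na(.data$n_publications))) NA_integer_
          else as.integer(max(.data$n_publications, na.rm = TRUE)),
        reliability = max(.data$reliability),
        .groups = "drop"
      ) |>
      rename(protein_a = ".a", protein_b = ".b") |>
      arrange(.data$protein_a, .data$protein_b)
  }
  prots <- sort(unique(c(edges$protein_a, edges$protein_b, proteins)))
  structure(edges,
    class = c("interactome", class(tibble())),
    species_tag = species_tag, proteins = prots
  )
}

#' @export
print.interactome <- function(x, ...) {
  cat(
    "# Interactome <", attr(x, "species_tag"), ">: ",
    length(attr(x, "proteins")), " proteins, ", nrow(x), " interactions\n",
    sep = ""
  )
  NextMethod()
}

#' List the proteins of an interactome
#'
#' @param net An [interactome()].
#' @return Character vector of protein identifiers (including isolated
#'   proteins added at construction).
#' @export
interactome_proteins <- function(net) {
  stopifnot(inherits(net, "interactome"))
  attr(net, "proteins")
}

#' Interaction reliability from supporting publication counts
#'
#' Maps the number of publications supporting an interaction to a
#' reliability `1 - 2^(-n)`: each independent publication halves the
#' residual doubt, so `r` is monotone in `n`, bounded in `[0, 1)` and zero
#' for unsupported interactions.  Precomputed reliabilities in input files
#' override this mapping.
#'
#' @param n Vector of non-negative publication counts.
#' @return Reliabilities in `[0, 1)`.
#' @examples
#' reliability_from_publications(c(0, 1, 3))
#' @export
reliability_from_publications <- function(n) {
  if (any(is.na(n)) || any(n < 0)) abort("publication counts must be >= 0")
  if (any(n != floor(n))) abort("publication counts must be integers")
  1 - 2^(-as.numeric(n))
}

#' Read an interaction list from TSV
#'
#' Expects `proteinA<TAB>proteinB[<TAB>support]` without a header.  The
#' third column is interpreted according to `support`: publication counts
#' (converted with [reliability_from_publications()]), precomputed
#' reliabilities, or absent (every interaction gets `default_count`
#' publications).  Duplicate pairs (in any orientation) are merged keeping
#' the maximum support, so reading is idempotent and line-order
#' independent.
#'
#' @param path Path to the TSV file.
#' @param support One of `"count"`, `"reliability"`, `"none"`.
#' @param species_tag Label passed to [interactome()].
#' @param default_count Publication count assumed when `support = "none"`.
#' @return An [interactome()].
#' @export
read_interactions <- function(path, support = c("count", "reliability", "none"),
                              species_tag = "network", default_count = 1L) {
  support <- match.arg(support)
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(interactome(tibble(
      protein_a = character(), protein_b = character()
    ), species_tag = species_tag))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  need <- if (support == "none") 2L else 3L
  bad <- which(lengths(fields) < need)
  if (length(bad) > 0) {
    abort(sprintf(
      "malformed interaction line %d in %s: expected >= %d tab-separated fields",
      bad[1], path, need
    ))
  }
  a <- map_chr(fields, 1)
  b <- map_chr(fields, 2)
  df <- tibble(protein_a = a, protein_b = b)
  if (support == "count") {
    raw <- map_chr(fields, 3)
    cnt <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(cnt) | cnt < 0 | cnt != floor(cnt))
    if (length(bad) > 0) {
      abort(sprintf(
        "malformed interaction line %d in %s: '%s' is not a non-negative integer count",
        bad[1], path, raw[bad[1]]
      ))
    }
    df$n_publications <- as.integer(cnt)
  } else if (support == "reliability") {
    raw <- map_chr(fields, 3)
    rel <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(rel) | rel < 0 | rel > 1)
    if (length(bad) > 0) {
      abort(sprintf(
        "malformed interaction line %d in %s: reliability '%s' outside [0, 1]",
        bad[1], path, raw[bad[1]]
      ))
    }
    df$reliability <- rel
  } else {
    df$n_publications <- as.integer(default_count)
  }
  interactome(df, species_tag = species_tag)
}

#' Write an interactome to TSV
#'
#' Inverse of [read_interactions()]: writes `proteinA<TAB>proteinB<TAB>
#' support` with the reliability (or the publication count when
#' `support = "count"`) as third column, no header, canonical order.
#'
#' @param net An [interactome()].
#' @param path Output path.
#' @param support `"reliability"` (default) or `"count"`.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(net, path, support = c("reliability", "count")) {
  support <- match.arg(support)
  stopifnot(inherits(net, "interactome"))
  third <- if (support == "count") net$n_publications else
    format(net$reliability, digits = 12, trim = TRUE, scientific = FALSE)
  readr::write_lines(
    paste(net$protein_a, net$protein_b, third, sep = "\t"), path
  )
  invisible(path)
}

#' Read complex / pathway membership files
#'
#' Format: `set_id<TAB>member1,member2,...`, one molecule set (complex or
#' pathway) per line; an optional companion edge list (same format as
#' [read_interactions()], `support = "none"` allowed) can give pathway
#' interactions whose endpoints must lie within the member sets.
#'
#' @param path Membership TSV.
#' @param kind `"complex"` or `"pathway"`.
#' @return A tibble with columns `set_id`, `kind` and list-column
#'   `members`.
#' @export
read_molecule_sets <- function(path, kind = c("complex", "pathway")) {
  kind <- match.arg(kind)
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2)
  if (length(bad) > 0) {
    abort(sprintf("malformed molecule-set line %d in %s", bad[1], path))
  }
  members <- map(fields, \(f) sort(unique(strsplit(f[2], ",", fixed = TRUE)[[1]])))
  if (any(lengths(members) == 0)) abort("molecule set with no members")
  tibble(
    set_id = map_chr(fields, 1),
    kind = kind,
    members = members
  )
}

#' Build a query network from a complex or pathway
#'
#' Induces the subnetwork of `net` on the members of a molecule set.  Every
#' member left without any induced interaction receives a self-interaction
#' of reliability 0, so the composition of the complex is preserved in the
#' query network even for singletons.
#'
#' @param members Character vector of member proteins (or a one-row slice
#'   of [read_molecule_sets()] output).
#' @param net The source [interactome()].
#' @param species_tag Label for the resulting network.
#' @return An [interactome()] on exactly the member proteins.
#' @export
build_query_network <- function(members, net, species_tag = "query") {
  if (is.data.frame(members)) members <- members$members[[1]]
  members <- unique(as.character(members))
  if (length(members) == 0) abort("empty member set")
  stopifnot(inherits(net, "interactome"))
  induced <- dplyr::filter(
    as_tibble(net),
    .data$protein_a %in% members & .data$protein_b %in% members
  )
  covered <- unique(c(induced$protein_a, induced$protein_b))
  singles <- setdiff(members, covered)
  if (length(singles) > 0) {
    induced <- bind_rows(induced, tibble(
      protein_a = singles, protein_b = singles,
      n_publications = 0L, reliability = 0
    ))
  }
  interactome(induced, species_tag = species_tag, proteins = members)
}
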