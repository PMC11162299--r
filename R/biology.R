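#' Mean pairwise score over a protein set
#'
#' Averages a caller-supplied pair scorer over all unordered member pairs;
#' with a Gene Ontology semantic-similarity scorer this yields the
#' per-category (BP/CC/MF) coherence score of a complex. The scorer itself
#' (e.g. an ontology-based similarity) is supplied by the caller, typically
#' via [pair_scorer_from_table()].
#'
#' @param members character vector with at least 2 identifiers.
#' @param pair_scorer function of two identifiers returning a numeric
#'   score.
#' @return the mean pair score.
#' @export
mean_pairwise_score <- function(members, pair_scorer) {
  members <- unique(as.character(members))
  if (length(members) < 2) stop("mean_pairwise_score needs >= 2 members")
  pairs <- utils::combn(members, 2)
  mean(vapply(seq_len(ncol(pairs)),
              function(k) pair_scorer(pairs[1, k], pairs[2, k]), numeric(1)))
}

#' Build a pair scorer from a three-column score table
#'
#' @param table a data frame with two identifier columns and a score
#'   column (in that order); pairs are looked up unordered.
#' @param default value returned for absent pairs.
#' @return a function of two identifiers for [mean_pairwise_score()].
#' @export
pair_scorer_from_table <- function(table, default = NA_real_) {
  a <- as.character(table[[1]]); b <- as.character(table[[2]])
  key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
  val <- as.numeric(table[[3]])
  lookup <- setNames(val, key)
  function(x, y) {
    v <- lookup[paste(min(x, y), max(x, y), sep = "\r")]
    if (is.na(v)) default else unname(v)
  }
}

#' Within-complex expression concordance by Manhattan distance
#'
#' For each complex, the Manhattan distance
#' `D[i, j] = sum_s |M[i, s] - M[j, s]|` is computed over all member pairs,
#' and the mean, median and minimum are reported. Complexes with members
#' absent from the abundance matrix are skipped with a warning.
#'
#' @param M abundance matrix (proteins x samples) with protein-id
#'   rownames, as from [read_abundance()].
#' @param complexes a [complex_set()].
#' @return a tibble: complex_id, n_members, mean_dist, median_dist,
#'   min_dist.
#' @export
manhattan_concordance <- function(M, complexes) {
  rows <- list()
  skipped <- 0
  for (i in seq_len(nrow(complexes))) {
    mem <- complexes$members[[i]]
    if (!all(mem %in% rownames(M)) || length(mem) < 2) {
      skipped <- skipped + 1
      next
    }
    D <- as.numeric(stats::dist(M[mem, , drop = FALSE], method = "manhattan"))
    rows[[length(rows) + 1]] <- tibble::tibble(
      complex_id = complexes$complex_id[i], n_members = length(mem),
      mean_dist = mean(D), median_dist = median(D), min_dist = min(D))
  }
  if (skipped > 0)
    warning("skipped ", skipped, " complex(es) with missing abundance rows")
  dplyr::bind_rows(rows)
}

#' Hypergeometric enrichment p-value for an annotated complex
#'
#' The probability of observing `hits` or more members annotated with a
#' term, when `annotated` of the `network_size` network proteins carry it:
#' the upper tail `1 - sum_{i < hits} C(F,i) C(V-F, C-i) / C(V, C)`.
#'
#' @param complex_size number of proteins in the complex (`|C|`).
#' @param hits members of the complex carrying the term (`t`).
#' @param annotated network proteins carrying the term (`|F|`).
#' @param network_size proteins in the network (`|V|`).
#' @return p-value in \[0, 1\]; `hits = 0` gives 1.
#' @export
hypergeom_enrichment_p <- function(complex_size, hits, annotated, network_size) {
  stopifnot(complex_size >= 0, hits >= 0, annotated >= 0, network_size >= 0)
  if (hits > min(complex_size, annotated) || annotated > network_size ||
      complex_size > network_size)
    stop("combinatorially impossible arguments")
  if (hits == 0) return(1)
  phyper(hits - 1, annotated, network_size - annotated, complex_size,
         lower.tail = FALSE)
}

#' Random pseudo-complexes matching a size template
#'
#' Draws one uniformly random protein set per template complex, with the
#' same size — the null model against which the biological coherence of
#' predicted complexes is compared.
#'
#' @param template a [complex_set()] supplying the size distribution.
#' @param universe character vector of candidate protein identifiers.
#' @param seed RNG seed.
#' @return a [complex_set()] of pseudo complexes.
#' @export
random_pseudo_complexes <- function(template, universe, seed = 1) {
  sizes <- complex_sizes(template)
  if (max(sizes) > length(universe)) stop("universe smaller than template size")
  set.seed(seed)
  complex_set(lapply(sizes, function(k) sample(universe, k)),
              ids = sprintf("R%04d", seq_along(sizes)))
}
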