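#' Configuration for complex detection
#'
#' @param alpha classifier-score threshold for adopting a neighbor during
#'   seed expansion.
#' @param beta overlap threshold above which two candidates are considered
#'   for merging.
#' @param min_output_size smallest complex emitted (default 3, i.e. more
#'   than 2 members).
#' @param overlap overlap statistic used when merging: neighborhood
#'   affinity (`"na"`, default) or Jaccard.
#' @param expansion `"monotone"` (default) keeps the running best score
#'   across growth rounds, so a neighbor is adopted only when it improves
#'   on every previous score — growth stops once scores saturate.
#'   `"threshold"` resets the bar each round and grows while any neighbor
#'   clears `alpha`.
#' @return a list of class `detection_config`.
#' @export
detection_config <- function(alpha = 0.9, beta = 0.5, min_output_size = 3,
                             overlap = c("na", "jaccard"),
                             expansion = c("monotone", "threshold")) {
  stopifnot(alpha >= 0, alpha <= 1, beta >= 0, beta <= 1)
  structure(list(alpha = alpha, beta = beta,
                 min_output_size = min_output_size,
                 overlap = match.arg(overlap),
                 expansion = match.arg(expansion)),
            class = "detection_config")
}

overlap_score <- function(a, b, method = "na") {
  if (method == "na") na_score(a, b)
  else length(intersect(a, b)) / length(union(a, b))
}

#' Grow a candidate complex from a seed interaction
#'
#' Starting from one PPI edge, every neighbor of the current set is scored
#' as a candidate addition; the highest-scoring neighbor (ties broken by
#' lexicographically smallest id) is adopted when its score exceeds
#' `alpha` and the running best score so far, the neighbor pool of the
#' grown set is recomputed, and the process repeats until no admissible
#' neighbor remains. With `expansion = "threshold"` the running-best
#' condition is dropped and any neighbor above `alpha` is admissible.
#'
#' @param edge character vector of two protein identifiers forming a
#'   network edge.
#' @param network a [ppi_network()].
#' @param classifier a scoring object (see [score_member_sets()]).
#' @param embeddings node embedding matrix.
#' @param alpha adoption threshold.
#' @param expansion `"monotone"` or `"threshold"`; see
#'   [detection_config()].
#' @param neighbors optional precomputed adjacency list (internal reuse).
#' @return list with `members` (sorted ids) and `score` (classifier score
#'   of the final set).
#' @export
expand_seed <- function(edge, network, classifier, embeddings, alpha,
                        expansion = "monotone", neighbors = NULL) {
  if (is.null(neighbors)) neighbors <- neighbor_map(network)
  members <- sort(unique(as.character(edge)))
  fast <- inherits(classifier, "complex_classifier")
  base_sum <- if (fast) colSums(embeddings[members, , drop = FALSE])
  best_so_far <- 0
  repeat {
    pool <- setdiff(sort(unique(unlist(neighbors[members]))), members)
    if (length(pool) == 0) break
    if (fast) {
      # candidate embedding = running member sum plus one neighbor, averaged
      cand_emb <- sweep(embeddings[pool, , drop = FALSE], 2, base_sum, `+`) /
        (length(members) + 1)
      sc <- score_embedding_matrix(classifier, cand_emb)
    } else {
      sc <- score_member_sets(classifier, embeddings,
                              lapply(pool, function(v) c(members, v)))
    }
    best <- which(sc == max(sc))[1]   # pool sorted => lexicographic tie-break
    if (sc[best] > alpha &&
        (expansion == "threshold" || sc[best] > best_so_far)) {
      best_so_far <- sc[best]
      members <- sort(c(members, pool[best]))
      if (fast) base_sum <- base_sum + embeddings[pool[best], ]
    } else break
  }
  list(members = members,
       score = score_member_sets(classifier, embeddings, list(members)))
}

#' Merge and filter candidate complexes
#'
#' Candidates are sorted by score (descending; ties by size then member
#' ids). Scanning down from each retained candidate, any lower-scoring
#' candidate whose overlap with it exceeds `beta` is either merged into it
#' (when the union scores higher than the retained candidate) or removed.
#' Only sets with at least `min_output_size` members are emitted.
#'
#' @param candidates a [complex_set()] with scores.
#' @param classifier,embeddings scoring objects for union rescoring.
#' @param beta overlap threshold.
#' @param min_output_size smallest emitted complex.
#' @param overlap `"na"` or `"jaccard"`.
#' @return a [complex_set()] of merged complexes.
#' @export
merge_candidates <- function(candidates, classifier, embeddings, beta,
                             min_output_size = 3, overlap = "na") {
  n <- nrow(candidates)
  if (n == 0) return(candidates)
  mems <- candidates$members
  sc <- candidates$score
  key <- vapply(mems, paste, character(1), collapse = "\r")
  ord <- order(-sc, -lengths(mems), key)
  mems <- mems[ord]
  sc <- sc[ord]
  removed <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (removed[i]) next
    j <- i
    while (j < n) {
      j <- j + 1
      if (removed[j]) next
      ov <- overlap_score(mems[[i]], mems[[j]], overlap)
      if (ov > beta) {
        u <- sort(union(mems[[i]], mems[[j]]))
        su <- score_member_sets(classifier, embeddings, list(u))
        if (su > sc[i]) {
          mems[[i]] <- u
          sc[i] <- su
        }
        removed[j] <- TRUE
      }
    }
  }
  keep <- !removed & lengths(mems) >= min_output_size
  complex_set(mems[keep], sc[keep])
}

#' Mine protein complexes from a PPI network
#'
#' Runs [expand_seed()] from every network edge, deduplicates identical
#' candidate sets, then applies [merge_candidates()].
#'
#' @param network a [ppi_network()].
#' @param classifier a scoring object.
#' @param embeddings node embedding matrix covering the network nodes.
#' @param config a [detection_config()].
#' @param progress print progress every 500 seeds?
#' @return a [complex_set()] of predicted complexes, sorted by score.
#' @export
detect_complexes <- function(network, classifier, embeddings,
                             config = detection_config(), progress = FALSE) {
  edges <- network$edges
  if (nrow(edges) == 0)
    return(complex_set(list(), ids = character(0)))
  nbrs <- neighbor_map(network)
  cands <- vector("list", nrow(edges))
  scores <- numeric(nrow(edges))
  for (i in seq_len(nrow(edges))) {
    res <- expand_seed(c(edges$from[i], edges$to[i]), network, classifier,
                       embeddings, config$alpha,
                       expansion = config$expansion, neighbors = nbrs)
    cands[[i]] <- res$members
    scores[i] <- res$score
    if (progress && i %% 500 == 0)
      message("expanded ", i, "/", nrow(edges), " seeds")
  }
  key <- vapply(cands, paste, character(1), collapse = "\r")
  first <- !duplicated(key)
  dedup <- complex_set(cands[first], scores[first])
  merge_candidates(dedup, classifier, embeddings, config$beta,
                   config$min_output_size, config$overlap)
}
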