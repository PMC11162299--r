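# shared fixture builders: everything is generated in code, no data files

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# small deterministic network: triangle a-b-c plus pendant edge d-e
toy_network <- function() {
  suppressMessages(ppi_network(data.frame(
    from = c("a", "a", "b", "d"),
    to   = c("b", "c", "c", "e"))))
}

# an Erdos-Renyi network over n nodes (seeded)
random_network <- function(n, p, seed) {
  set.seed(seed)
  pairs <- t(utils::combn(sprintf("n%02d", seq_len(n)), 2))
  on <- stats::runif(nrow(pairs)) < p
  suppressMessages(ppi_network(
    data.frame(from = pairs[on, 1], to = pairs[on, 2]),
    nodes = sprintf("n%02d", seq_len(n))))
}

random_aa_sequence <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len, replace = TRUE),
        collapse = "")
}

# brute-force maximal-clique enumeration over all vertex subsets
brute_maximal_cliques <- function(network, min_size) {
  nodes <- network$nodes
  adj <- matrix(FALSE, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(network$edges))) {
    adj[network$edges$from[r], network$edges$to[r]] <- TRUE
    adj[network$edges$to[r], network$edges$from[r]] <- TRUE
  }
  is_clique <- function(s) all(adj[s, s] | diag(TRUE, length(s)))
  out <- list()
  for (k in seq_along(nodes)) {
    if (k < min_size) next
    for (ci in utils::combn(seq_along(nodes), k, simplify = FALSE)) {
      s <- nodes[ci]
      if (!is_clique(s)) next
      extendable <- any(vapply(setdiff(nodes, s),
                               function(v) all(adj[v, s]), logical(1)))
      if (!extendable) out[[length(out) + 1]] <- sort(s)
    }
  }
  key <- vapply(out, paste, character(1), collapse = "\r")
  out[order(key)]
}

# canonical key for comparing lists of sets
set_keys <- function(sets) {
  sort(vapply(lapply(sets, sort), paste, character(1), collapse = "\r"))
}
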