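#' Construct a protein-protein interaction network
#'
#' An undirected, simple (no self-loops, no multi-edges) graph over protein
#' identifiers. Edges are stored canonically with `from < to` so that two
#' networks built from the same interactions compare identical regardless of
#' input order.
#'
#' @param edges a two-column data frame, matrix, or tibble of protein-id
#'   pairs (one interaction per row).
#' @param nodes optional character vector of node identifiers; defaults to
#'   the sorted set of identifiers appearing in `edges`. Identifiers in
#'   `edges` but not in `nodes` are an error.
#' @return an object of class `ppi_network` with elements `nodes`
#'   (character) and `edges` (tibble with columns `from`, `to`).
#' @export
ppi_network <- function(edges, nodes = NULL) {
  if (is.matrix(edges)) edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2 && nrow(edges) > 0)
    stop("`edges` must have two columns of protein identifiers")
  a <- as.character(edges[[1]])
  b <- as.character(edges[[2]])
  keep <- a != b
  n_self <- sum(!keep)
  if (n_self > 0) message("dropped ", n_self, " self-loop(s)")
  a2 <- pmin(a[keep], b[keep])
  b2 <- pmax(a[keep], b[keep])
  key <- paste(a2, b2, sep = "\r")
  dup <- duplicated(key)
  e <- tibble::tibble(from = a2[!dup], to = b2[!dup])
  e <- e[order(e$from, e$to), ]
  found <- sort(unique(c(e$from, e$to)))
  if (is.null(nodes)) {
    nodes <- found
  } else {
    nodes <- as.character(nodes)
    if (anyDuplicated(nodes)) stop("duplicate node identifiers")
    missing <- setdiff(found, nodes)
    if (length(missing) > 0)
      stop("edge endpoints not in `nodes`: ", paste(head(missing, 5), collapse = ", "))
  }
  structure(list(nodes = nodes, edges = e), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("<ppi_network> ", length(x$nodes), " nodes, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Number of nodes and edges of a network
#'
#' @param network a [ppi_network()].
#' @return a named integer vector with elements `nodes` and `edges`.
#' @export
network_size <- function(network) {
  stopifnot(inherits(network, "ppi_network"))
  c(nodes = length(network$nodes), edges = nrow(network$edges))
}

# igraph view of a ppi_network, preserving node order
as_igraph <- function(network) {
  igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                vertices = network$nodes)
}

# adjacency list: named list of character neighbor vectors
neighbor_map <- function(network) {
  nb <- vector("list", length(network$nodes))
  names(nb) <- network$nodes
  for (nm in names(nb)) nb[[nm]] <- character(0)
  if (nrow(network$edges) > 0) {
    sp1 <- split(network$edges$to, network$edges$from)
    sp2 <- split(network$edges$from, network$edges$to)
    for (nm in names(sp1)) nb[[nm]] <- c(nb[[nm]], sp1[[nm]])
    for (nm in names(sp2)) nb[[nm]] <- c(nb[[nm]], sp2[[nm]])
  }
  lapply(nb, function(v) sort(unique(v)))
}
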