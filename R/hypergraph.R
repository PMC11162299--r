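#' Enumerate maximal cliques as hyperedges
#'
#' Every maximal clique of the PPI network with at least `min_size` members
#' becomes a hyperedge: a fully connected protein subset treated as one
#' higher-order relation. Output order is deterministic (each clique sorted
#' by id, cliques sorted lexicographically).
#'
#' @param network a [ppi_network()].
#' @param min_size smallest clique size to keep (default 3).
#' @return a list of character vectors of protein identifiers.
#' @export
enumerate_clique_hyperedges <- function(network, min_size = 3) {
  stopifnot(inherits(network, "ppi_network"))
  if (length(network$nodes) == 0) return(list())
  g <- as_igraph(network)
  cl <- igraph::max_cliques(g, min = min_size)
  cl <- lapply(cl, function(v) sort(igraph::V(g)$name[v]))
  key <- vapply(cl, paste, character(1), collapse = "\r")
  cl[order(key)]
}

#' Build an attributed hypergraph from a PPI network
#'
#' Hyperedges are maximal cliques of size >= `min_size`; any node covered by
#' no clique receives a singleton hyperedge so every vertex degree is
#' positive. The binary incidence matrix `H` has `H[i,k] = 1` iff node `i`
#' belongs to hyperedge `k`; hyperedge weights `W` start at 1.
#'
#' @param network a [ppi_network()].
#' @param X node feature matrix with one row per network node (rownames must
#'   match `network$nodes`); e.g. from [encode_catalog()].
#' @param min_size smallest clique size used as a hyperedge.
#' @return an object of class `protein_hypergraph`: list with `nodes`,
#'   `hyperedges` (list of integer node-index vectors), `H` (sparse
#'   incidence matrix), `W` (hyperedge weights), `X`.
#' @export
build_hypergraph <- function(network, X, min_size = 3) {
  stopifnot(inherits(network, "ppi_network"))
  nodes <- network$nodes
  n <- length(nodes)
  if (n == 0) stop("empty network")
  if (is.null(rownames(X)) || !all(nodes %in% rownames(X)))
    stop("rownames(X) must cover the network nodes")
  X <- X[nodes, , drop = FALSE]
  cliques <- enumerate_clique_hyperedges(network, min_size)
  he <- lapply(cliques, function(v) match(v, nodes))
  covered <- rep(FALSE, n)
  for (e in he) covered[e] <- TRUE
  orphans <- which(!covered)
  he <- c(he, as.list(orphans))
  m <- length(he)
  i <- unlist(he)
  j <- rep(seq_len(m), lengths(he))
  H <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, m))
  structure(list(nodes = nodes, hyperedges = he, H = H,
                 W = rep(1, m), X = X),
            class = "protein_hypergraph")
}

#' @export
print.protein_hypergraph <- function(x, ...) {
  cat("<protein_hypergraph> ", length(x$nodes), " nodes, ",
      length(x$hyperedges), " hyperedges, ", ncol(x$X),
      "-dim node features\n", sep = "")
  invisible(x)
}

#' Normalized hypergraph propagation operator
#'
#' Returns the symmetric operator
#' `A = D_v^{-1/2} H W D_e^{-1} H^T D_v^{-1/2}`, where `D_v` holds the
#' (weight-summed) vertex degrees and `D_e` the hyperedge cardinalities.
#' This is the smoothing kernel of each hypergraph-convolution layer. With
#' unit weights, `D_v^{1/2} 1` is an eigenvector with eigenvalue 1 and the
#' spectral radius is 1.
#'
#' @param hg a `protein_hypergraph` from [build_hypergraph()].
#' @return a dense symmetric `|V| x |V|` matrix.
#' @export
propagation_operator <- function(hg) {
  H <- hg$H
  W <- hg$W
  dv <- as.numeric(H %*% W)
  de <- Matrix::colSums(H)
  if (any(dv <= 0))
    stop("zero vertex degree: add coverage hyperedges (see build_hypergraph)")
  if (any(de <= 0)) stop("empty hyperedge")
  Dvi <- 1 / sqrt(dv)
  HW <- H %*% Matrix::Diagonal(x = W / de)
  A <- as.matrix(HW %*% Matrix::t(H))
  A <- Dvi * sweep(A, 2, Dvi, `*`)
  (A + t(A)) / 2
}
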