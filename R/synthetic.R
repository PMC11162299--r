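#' Generate a synthetic planted-complex benchmark
#'
#' Builds a self-contained benchmark emulating the structure of a curated
#' complex catalog over a PPI network: complex sizes follow a truncated
#' discrete power law (minimum 3); planted members are densely
#' interconnected (a clique at the default within-complex edge probability
#' of 1) on top of an Erdos-Renyi background; member sequences draw
#' residues from a mixture of a complex-specific 7-class profile and the
#' uniform background, so conjoint-triad features carry planted signal;
#' and member abundances share a latent per-sample profile plus noise.
#' Every output is reproducible from `seed`.
#'
#' @param n_nodes number of proteins.
#' @param n_complexes number of planted complexes.
#' @param size_exponent power-law exponent of the size distribution.
#' @param max_size largest planted complex.
#' @param background_edge_prob edge probability between random node pairs.
#' @param within_complex_edge_prob edge probability inside a planted
#'   complex (must exceed the background); planted complexes are always
#'   left internally connected.
#' @param overlap_prob probability that a planted member is reused from an
#'   earlier complex (0 keeps complexes disjoint, which keeps oracle tests
#'   exact).
#' @param sequence_length_range min/max sequence length.
#' @param signal_strength mixture weight on the complex-specific residue
#'   class profile (0 = no sequence signal).
#' @param n_samples abundance samples (columns).
#' @param abundance_noise_sd lognormal noise around the shared profile.
#' @param seed RNG seed.
#' @return an object of class `synthetic_benchmark`: list with `network`
#'   ([ppi_network()]), `catalog` (tibble as from [read_fasta()]),
#'   `planted` ([complex_set()]), `abundance` (matrix), `config`.
#' @export
generate_benchmark <- function(n_nodes = 300, n_complexes = 20,
                               size_exponent = 2, max_size = 10,
                               background_edge_prob = 0.01,
                               within_complex_edge_prob = 1,
                               overlap_prob = 0,
                               sequence_length_range = c(60, 180),
                               signal_strength = 0.8, n_samples = 6,
                               abundance_noise_sd = 0.25, seed = 1) {
  stopifnot(within_complex_edge_prob > background_edge_prob,
            signal_strength >= 0, signal_strength <= 1)
  set.seed(seed)
  nodes <- sprintf("P%04d", seq_len(n_nodes))

  # planted sizes: truncated discrete power law on [3, max_size]
  supp <- 3:max_size
  pr <- supp^(-size_exponent)
  sizes <- if (n_complexes > 0) sample(supp, n_complexes, replace = TRUE,
                                       prob = pr / sum(pr)) else integer(0)
  unused <- nodes
  planted <- vector("list", n_complexes)
  for (ci in seq_len(n_complexes)) {
    k <- sizes[ci]
    mem <- character(0)
    used <- setdiff(nodes, unused)
    for (s in seq_len(k)) {
      from_used <- length(used) > 0 && runif(1) < overlap_prob
      pool <- setdiff(if (from_used) used else unused, mem)
      if (length(pool) == 0) pool <- setdiff(nodes, mem)
      if (length(pool) == 0) stop("planted membership exceeds n_nodes")
      mem <- c(mem, sample(pool, 1))
    }
    unused <- setdiff(unused, mem)
    planted[[ci]] <- sort(mem)
  }

  # edges: within-complex at high density (kept connected), background ER
  edge_from <- character(0); edge_to <- character(0)
  for (mem in planted) {
    pr2 <- utils::combn(mem, 2)
    on <- runif(ncol(pr2)) < within_complex_edge_prob
    if (within_complex_edge_prob < 1) {
      # keep the planted subgraph internally connected
      g <- igraph::make_empty_graph(directed = FALSE) |>
        igraph::add_vertices(length(mem), name = mem)
      if (any(on))
        g <- igraph::add_edges(g, match(as.vector(pr2[, on, drop = FALSE]),
                                        igraph::V(g)$name))
      comp <- igraph::components(g)
      while (comp$no > 1) {
        c1 <- igraph::V(g)$name[comp$membership == 1]
        c2 <- igraph::V(g)$name[comp$membership == 2]
        extra <- c(sample(c1, 1), sample(c2, 1))
        g <- igraph::add_edges(g, match(extra, igraph::V(g)$name))
        comp <- igraph::components(g)
      }
      el <- igraph::as_edgelist(g)
      edge_from <- c(edge_from, el[, 1]); edge_to <- c(edge_to, el[, 2])
    } else {
      edge_from <- c(edge_from, pr2[1, ]); edge_to <- c(edge_to, pr2[2, ])
    }
  }
  if (n_nodes > 1) {
    all_pairs <- utils::combn(nodes, 2)
    on <- runif(ncol(all_pairs)) < background_edge_prob
    edge_from <- c(edge_from, all_pairs[1, on])
    edge_to <- c(edge_to, all_pairs[2, on])
  }
  network <- suppressMessages(
    ppi_network(data.frame(from = edge_from, to = edge_to), nodes = nodes))

  # sequences: per-complex peaked 7-class profile, mixed with uniform
  alphabet <- ct_alphabet()
  class_letters <- split(names(alphabet), alphabet)
  profile_of <- rep(NA_integer_, n_nodes)
  names(profile_of) <- nodes
  for (ci in seq_len(n_complexes))
    profile_of[planted[[ci]]][is.na(profile_of[planted[[ci]]])] <- ci
  profiles <- lapply(seq_len(max(n_complexes, 1)), function(i) {
    w <- rgamma(7, shape = 0.5)
    w / sum(w)
  })
  lmin <- sequence_length_range[1]; lmax <- sequence_length_range[2]
  seqs <- vapply(nodes, function(nd) {
    L <- sample(lmin:lmax, 1)
    ci <- profile_of[[nd]]
    if (is.na(ci)) {
      paste(sample(names(alphabet), L, replace = TRUE), collapse = "")
    } else {
      p <- signal_strength * profiles[[ci]] + (1 - signal_strength) / 7
      cls <- sample(0:6, L, replace = TRUE, prob = p)
      paste(vapply(cls, function(k) {
        ls <- class_letters[[as.character(k)]]
        ls[sample.int(length(ls), 1)]
      }, character(1)), collapse = "")
    }
  }, character(1))
  catalog <- tibble::tibble(protein_id = nodes, sequence = unname(seqs))

  # abundance: complex members share a latent per-sample profile
  ab <- matrix(0, n_nodes, n_samples,
               dimnames = list(nodes, paste0("S", seq_len(n_samples))))
  latents <- lapply(seq_len(max(n_complexes, 1)), function(i) rnorm(n_samples))
  for (nd in nodes) {
    ci <- profile_of[[nd]]
    base <- if (is.na(ci)) rnorm(n_samples) else latents[[ci]]
    ab[nd, ] <- exp(base + rnorm(n_samples, sd = abundance_noise_sd))
  }

  structure(list(network = network, catalog = catalog,
                 planted = complex_set(planted,
                                       ids = sprintf("K%03d", seq_len(n_complexes))),
                 abundance = ab,
                 config = list(n_nodes = n_nodes, n_complexes = n_complexes,
                               size_exponent = size_exponent, max_size = max_size,
                               background_edge_prob = background_edge_prob,
                               within_complex_edge_prob = within_complex_edge_prob,
                               overlap_prob = overlap_prob,
                               sequence_length_range = sequence_length_range,
                               signal_strength = signal_strength,
                               n_samples = n_samples,
                               abundance_noise_sd = abundance_noise_sd,
                               seed = seed)),
            class = "synthetic_benchmark")
}

#' @export
print.synthetic_benchmark <- function(x, ...) {
  cat("<synthetic_benchmark> ", length(x$network$nodes), " nodes, ",
      nrow(x$network$edges), " edges, ", nrow(x$planted),
      " planted complexes (seed ", x$config$seed, ")\n", sep = "")
  invisible(x)
}

#' Inject false-positive / false-negative interaction noise
#'
#' Adds `round(fp_rate * |E|)` uniformly sampled non-edges and removes
#' `round(fn_rate * |E|)` uniformly sampled true edges, emulating spurious
#' and missed interactions in experimental PPI data.
#'
#' @param network a [ppi_network()].
#' @param fp_rate,fn_rate rates in \[0, 1\] relative to the current edge
#'   count.
#' @param seed RNG seed.
#' @return a perturbed [ppi_network()] over the same node set.
#' @export
perturb_network <- function(network, fp_rate, fn_rate, seed = 1) {
  stopifnot(fp_rate >= 0, fp_rate <= 1, fn_rate >= 0, fn_rate <= 1)
  set.seed(seed)
  e <- network$edges
  n_e <- nrow(e)
  n_add <- round(fp_rate * n_e)
  n_del <- round(fn_rate * n_e)
  nodes <- network$nodes
  max_edges <- length(nodes) * (length(nodes) - 1) / 2
  if (n_add > max_edges - n_e)
    stop("cannot add ", n_add, " false positives: graph too dense")
  existing <- paste(e$from, e$to, sep = "\r")
  new_from <- character(0); new_to <- character(0)
  seen <- character(0)
  while (length(new_from) < n_add) {
    pair <- sort(sample(nodes, 2))
    key <- paste(pair[1], pair[2], sep = "\r")
    if (key %in% existing || key %in% seen) next
    seen <- c(seen, key)
    new_from <- c(new_from, pair[1]); new_to <- c(new_to, pair[2])
  }
  keep <- rep(TRUE, n_e)
  if (n_del > 0) keep[sample.int(n_e, n_del)] <- FALSE
  message("perturb_network: added ", n_add, " edges, removed ", n_del)
  suppressMessages(ppi_network(
    data.frame(from = c(e$from[keep], new_from),
               to = c(e$to[keep], new_to)), nodes = nodes))
}
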