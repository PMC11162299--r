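#' Read protein sequences from a FASTA file
#'
#' The protein identifier is the header token before the first whitespace;
#' sequences are upper-cased. Duplicate identifiers or an empty file are
#' errors.
#'
#' @param path path to a FASTA file of amino-acid sequences.
#' @return a tibble with columns `protein_id` and `sequence`, in file order.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0)
    stop("duplicate protein id(s) in FASTA: ", paste(unique(dup), collapse = ", "))
  tibble::tibble(protein_id = ids,
                 sequence = unname(toupper(as.character(seqs))))
}

#' Write a protein catalog to FASTA
#'
#' @param catalog a tibble with columns `protein_id` and `sequence`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(catalog, path) {
  x <- Biostrings::BStringSet(setNames(catalog$sequence, catalog$protein_id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a PPI network from a two-column edge list
#'
#' Lines are tab- or whitespace-separated identifier pairs; lines starting
#' with `#` and blank lines are skipped. Self-loops are dropped (with a
#' message) and duplicate edges collapsed, so the result is independent of
#' input line order.
#'
#' @param path path to the edge-list file.
#' @return a [ppi_network()].
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(toks) != 2)
  if (length(bad) > 0)
    stop("line ", idx[bad[1]], ": expected 2 identifiers, found ",
         length(toks[[bad[1]]]))
  if (length(toks) == 0)
    return(structure(list(nodes = character(0),
                          edges = tibble::tibble(from = character(0), to = character(0))),
                     class = "ppi_network"))
  m <- do.call(rbind, toks)
  ppi_network(data.frame(from = m[, 1], to = m[, 2]))
}

#' Write a PPI network as a two-column edge list
#'
#' @param network a [ppi_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  writeLines(paste(network$edges$from, network$edges$to, sep = "\t"), path)
  invisible(path)
}

#' Read complexes from a membership flat file
#'
#' One complex per line, members whitespace/tab separated; an optional
#' trailing `score=<value>` token carries a prediction score. Lines starting
#' with `#` are skipped. Duplicate member tokens within a line are
#' collapsed, and complexes smaller than `min_size` are dropped with a
#' message. Gold-standard sets for training conventionally use
#' `min_size = 3`.
#'
#' @param path path to the complex file.
#' @param min_size minimum number of members for a complex to be retained.
#' @return a [complex_set()].
#' @export
read_complex_sets <- function(path, min_size = 1) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0) return(complex_set(list(), ids = character(0)))
  toks <- strsplit(trimws(lines), "\\s+")
  score <- vapply(toks, function(tk) {
    sc <- grep("^score=", tk, value = TRUE)
    if (length(sc)) as.numeric(sub("^score=", "", sc[1])) else NA_real_
  }, numeric(1))
  members <- lapply(toks, function(tk) unique(tk[!grepl("^score=", tk)]))
  keep <- lengths(members) >= min_size
  if (any(!keep))
    message("dropped ", sum(!keep), " complex(es) smaller than ", min_size)
  complex_set(members[keep], score[keep])
}

#' Write complexes to a membership flat file
#'
#' One complex per line, tab-separated members, with a trailing
#' `score=<value>` token for scored complexes.
#'
#' @param complexes a [complex_set()].
#' @param path output file path.
#' @param digits printed precision for scores.
#' @return `path`, invisibly.
#' @export
write_complexes <- function(complexes, path, digits = 6) {
  lines <- vapply(seq_len(nrow(complexes)), function(i) {
    ln <- paste(complexes$members[[i]], collapse = "\t")
    s <- complexes$score[i]
    if (!is.na(s)) ln <- paste0(ln, "\tscore=", formatC(s, digits = digits, format = "g"))
    ln
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a protein abundance matrix
#'
#' Tab-separated, with a header row of sample names and a first column of
#' protein identifiers. Rows containing missing values are removed with a
#' warning, so downstream distance computations see complete data.
#'
#' @param path path to the abundance TSV.
#' @return a numeric matrix (proteins x samples) with protein-id rownames.
#' @export
read_abundance <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate protein ids in abundance table")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  bad <- apply(m, 1, function(r) any(!is.finite(r)))
  if (any(bad)) {
    warning("removed ", sum(bad), " abundance row(s) with missing values")
    m <- m[!bad, , drop = FALSE]
  }
  m
}

#' Write a protein abundance matrix
#'
#' @param m numeric matrix with protein-id rownames.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(m, path) {
  df <- data.frame(protein_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
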