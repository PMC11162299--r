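#' The conjoint-triad amino-acid alphabet
#'
#' The conjoint-triad (CT) scheme groups the 20 standard amino acids into 7
#' classes by dipole moment and side-chain volume: \{A,G,V\}, \{I,L,F,P\},
#' \{Y,M,T,S\}, \{H,N,Q,W\}, \{R,K\}, \{D,E\}, \{C\}. Triads of classes in a
#' sliding window of 3 give 7^3 = 343 features per sequence.
#'
#' @return a named integer vector mapping each of the 20 standard one-letter
#'   residue codes to a class index in 0..6.
#' @export
ct_alphabet <- function() {
  classes <- list(c("A", "G", "V"),
                  c("I", "L", "F", "P"),
                  c("Y", "M", "T", "S"),
                  c("H", "N", "Q", "W"),
                  c("R", "K"),
                  c("D", "E"),
                  c("C"))
  out <- integer(0)
  for (k in seq_along(classes))
    out <- c(out, setNames(rep(k - 1L, length(classes[[k]])), classes[[k]]))
  out[order(names(out))]
}

#' Read a conjoint-triad alphabet from a key-value file
#'
#' Each non-comment line holds a residue letter and a class index (0-based),
#' whitespace separated, so an alternative class partition can be swapped in.
#'
#' @param path path to the alphabet file.
#' @return a named integer vector as from [ct_alphabet()].
#' @export
read_ct_alphabet <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  toks <- strsplit(trimws(lines), "\\s+")
  if (any(lengths(toks) != 2)) stop("alphabet lines must be `letter class`")
  m <- do.call(rbind, toks)
  ab <- setNames(as.integer(m[, 2]), toupper(m[, 1]))
  validate_alphabet(ab)
  ab[order(names(ab))]
}

validate_alphabet <- function(alphabet) {
  std <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (!all(std %in% names(alphabet)))
    stop("alphabet must map all 20 standard residues")
  if (length(unique(alphabet)) != 7 || !all(alphabet %in% 0:6))
    stop("alphabet must use exactly the 7 class indices 0..6")
  invisible(alphabet)
}

#' Conjoint-triad encoding of one amino-acid sequence
#'
#' A window of 3 consecutive residues slides along the sequence; each window
#' whose residues are all standard letters contributes one count to the triad
#' `(c1, c2, c3)` of its residue classes, at flat index `c1*49 + c2*7 + c3`.
#' Counts are divided by the number of valid windows, so each feature is the
#' frequency of its triad type and the vector sums to 1. Windows touching a
#' non-standard letter (B, J, O, U, X, Z) are skipped. Sequences shorter
#' than 3, or with no valid window, yield an all-zero vector with a warning.
#'
#' @param sequence an amino-acid string.
#' @param alphabet a class map from [ct_alphabet()].
#' @return a numeric vector of length 343.
#' @export
ct_encode <- function(sequence, alphabet = ct_alphabet()) {
  validate_alphabet(alphabet)
  v <- numeric(343)
  chars <- strsplit(toupper(sequence), "")[[1]]
  L <- length(chars)
  if (L < 3) {
    warning("sequence shorter than 3; returning zero vector")
    return(v)
  }
  cls <- unname(alphabet[chars])  # NA for non-standard letters
  c1 <- cls[1:(L - 2)]
  c2 <- cls[2:(L - 1)]
  c3 <- cls[3:L]
  idx <- c1 * 49L + c2 * 7L + c3 + 1L
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0) {
    warning("no valid triad window; returning zero vector")
    return(v)
  }
  tabulate(idx, 343) / length(idx)
}

#' Conjoint-triad feature matrix for a protein catalog
#'
#' @param catalog a tibble with columns `protein_id` and `sequence`
#'   (as from [read_fasta()]).
#' @param alphabet a class map from [ct_alphabet()].
#' @return an `n x 343` numeric matrix with protein-id rownames; row `i`
#'   is [ct_encode()] of sequence `i`, so each row sums to 1 (or 0 for
#'   sequences with no valid triad).
#' @export
encode_catalog <- function(catalog, alphabet = ct_alphabet()) {
  if (nrow(catalog) == 0) stop("empty catalog")
  X <- t(vapply(catalog$sequence, ct_encode, numeric(343),
                alphabet = alphabet, USE.NAMES = FALSE))
  rownames(X) <- catalog$protein_id
  X
}
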