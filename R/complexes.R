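#' Construct a set of protein complexes
#'
#' A complex set is a tibble with one row per complex: a `complex_id`, a
#' list-column `members` of unique protein identifiers, and an optional
#' `score` in \[0, 1\] (NA when unscored). This is the common currency for
#' gold-standard complexes, sampled non-complexes, and predictions.
#'
#' @param members a list of character vectors of protein identifiers.
#' @param score optional numeric vector of per-complex scores.
#' @param ids optional character vector of complex identifiers.
#' @return a tibble of class `complex_set`.
#' @export
complex_set <- function(members, score = NULL, ids = NULL) {
  members <- lapply(members, function(m) sort(unique(as.character(m))))
  if (any(lengths(members) == 0)) stop("complexes must be non-empty")
  n <- length(members)
  if (is.null(score)) score <- rep(NA_real_, n)
  if (length(score) != n) stop("`score` length must match `members`")
  if (any(!is.na(score) & (score < 0 | score > 1)))
    stop("scores must lie in [0, 1]")
  if (is.null(ids)) ids <- sprintf("C%04d", seq_len(n))
  out <- tibble::tibble(complex_id = as.character(ids),
                        members = members, score = as.numeric(score))
  class(out) <- c("complex_set", class(out))
  out
}

#' @export
print.complex_set <- function(x, ...) {
  cat("<complex_set> ", nrow(x), " complexes, sizes ",
      if (nrow(x)) paste(range(lengths(x$members)), collapse = "-") else "-",
      "\n", sep = "")
  NextMethod()
}

#' Sizes of the complexes in a set
#'
#' @param x a [complex_set()].
#' @return integer vector of member counts.
#' @export
complex_sizes <- function(x) lengths(x$members)
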