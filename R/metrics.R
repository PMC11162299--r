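#' Neighborhood affinity between two protein sets
#'
#' `NA(p, b) = |p & b|^2 / (|p| * |b|)`: 1 iff the sets are equal, 0 iff
#' disjoint, symmetric in its arguments.
#'
#' @param p,b non-empty character vectors of protein identifiers.
#' @return a real in \[0, 1\].
#' @export
na_score <- function(p, b) {
  p <- unique(p); b <- unique(b)
  if (length(p) == 0 || length(b) == 0) stop("empty set in na_score")
  length(intersect(p, b))^2 / (length(p) * length(b))
}

#' Complex-matching precision, recall and F1
#'
#' A predicted complex matches when some known complex has neighborhood
#' affinity at least `threshold` with it (and symmetrically for known
#' complexes). Precision is the matched fraction of predictions, recall the
#' matched fraction of known complexes, F1 their harmonic mean.
#'
#' @param predicted,known non-empty [complex_set()] objects.
#' @param threshold the neighborhood-affinity match threshold
#'   (default 0.25).
#' @return a one-row tibble: precision, recall, f1, n_matched_predicted,
#'   n_matched_known.
#' @export
match_metrics <- function(predicted, known, threshold = 0.25) {
  if (nrow(predicted) == 0 || nrow(known) == 0)
    stop("match_metrics needs non-empty predicted and known sets")
  NAm <- na_matrix(predicted$members, known$members)
  n_cp <- sum(apply(NAm, 1, max) >= threshold)
  n_cb <- sum(apply(NAm, 2, max) >= threshold)
  precision <- n_cp / nrow(predicted)
  recall <- n_cb / nrow(known)
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  tibble::tibble(precision = precision, recall = recall, f1 = f1,
                 n_matched_predicted = n_cp, n_matched_known = n_cb)
}

na_matrix <- function(pred_members, known_members) {
  outer(seq_along(pred_members), seq_along(known_members),
        Vectorize(function(i, j) na_score(pred_members[[i]], known_members[[j]])))
}

#' Complex-wise sensitivity, positive predictive value and accuracy
#'
#' With `T[i, j]` the member overlap between known complex `i` and
#' predicted complex `j`: `Sn = sum_i max_j T[i,j] / sum_i |b_i|`,
#' `PPV = sum_j max_i T[i,j] / sum_j sum_i T[i,j]`, and
#' `Acc = sqrt(Sn * PPV)`. A predicted complex intersecting no known
#' complex contributes zero to both PPV sums; setting
#' `ppv_denominator = "sizes"` instead divides by the summed predicted
#' sizes.
#'
#' @param predicted,known non-empty [complex_set()] objects.
#' @param ppv_denominator `"intersections"` (default) or `"sizes"`.
#' @return a one-row tibble: sn, ppv, acc.
#' @export
accuracy_metrics <- function(predicted, known,
                             ppv_denominator = c("intersections", "sizes")) {
  ppv_denominator <- match.arg(ppv_denominator)
  if (nrow(predicted) == 0 || nrow(known) == 0)
    stop("accuracy_metrics needs non-empty predicted and known sets")
  Tm <- outer(seq_len(nrow(known)), seq_len(nrow(predicted)),
              Vectorize(function(i, j)
                length(intersect(known$members[[i]], predicted$members[[j]]))))
  sn <- sum(apply(Tm, 1, max)) / sum(lengths(known$members))
  denom <- if (ppv_denominator == "intersections") sum(Tm)
           else sum(lengths(predicted$members))
  if (denom == 0) {
    warning("no overlap between predicted and known complexes; Acc = 0")
    return(tibble::tibble(sn = sn, ppv = 0, acc = 0))
  }
  ppv <- sum(apply(Tm, 2, max)) / denom
  tibble::tibble(sn = sn, ppv = ppv, acc = sqrt(sn * ppv))
}

#' Full complex-matching evaluation report
#'
#' Combines [match_metrics()] and [accuracy_metrics()] into one row.
#'
#' @inheritParams match_metrics
#' @return a one-row tibble: precision, recall, f1, sn, ppv, acc,
#'   n_matched_predicted, n_matched_known, na_threshold.
#' @export
evaluate_complexes <- function(predicted, known, threshold = 0.25) {
  mm <- match_metrics(predicted, known, threshold)
  am <- accuracy_metrics(predicted, known)
  dplyr::bind_cols(mm[, c("precision", "recall", "f1")], am,
                   mm[, c("n_matched_predicted", "n_matched_known")],
                   tibble::tibble(na_threshold = threshold))
}
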