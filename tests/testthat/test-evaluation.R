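# brute-force oracles over all pairs of complexes
brute_match <- function(P, B, thr) {
  nam <- function(p, b) length(intersect(p, b))^2 / (length(p) * length(b))
  ncp <- sum(vapply(P, function(p)
    any(vapply(B, function(b) nam(p, b) >= thr, logical(1))), logical(1)))
  ncb <- sum(vapply(B, function(b)
    any(vapply(P, function(p) nam(p, b) >= thr, logical(1))), logical(1)))
  prec <- ncp / length(P); rec <- ncb / length(B)
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(precision = prec, recall = rec, f1 = f1, ncp = ncp, ncb = ncb)
}

brute_acc <- function(P, B) {
  Tm <- matrix(0, length(B), length(P))
  for (i in seq_along(B)) for (j in seq_along(P))
    Tm[i, j] <- length(intersect(B[[i]], P[[j]]))
  sn <- sum(apply(Tm, 1, max)) / sum(lengths(B))
  ppv <- if (sum(Tm) > 0) sum(apply(Tm, 2, max)) / sum(Tm) else 0
  list(sn = sn, ppv = ppv, acc = sqrt(sn * ppv))
}

random_instance <- function(seed) {
  set.seed(seed)
  universe <- letters[1:20]
  P <- lapply(seq_len(sample(1:8, 1)),
              function(i) sample(universe, sample(2:6, 1)))
  B <- lapply(seq_len(sample(1:8, 1)),
              function(i) sample(universe, sample(2:6, 1)))
  list(P = P, B = B)
}

test_that("neighborhood affinity has its defining values and symmetry", {
  expect_equal(na_score(c("a", "b"), c("a", "b")), 1)
  expect_equal(na_score(c("a", "b"), c("x", "y")), 0)
  expect_equal(na_score(c("a", "b", "c"), c("b", "c", "d")), 4 / 9)
  set.seed(30)
  for (i in 1:50) {
    p <- sample(letters, sample(1:6, 1))
    b <- sample(letters, sample(1:6, 1))
    v <- na_score(p, b)
    expect_equal(v, na_score(b, p))
    expect_gte(v, 0); expect_lte(v, 1)
    if (v == 1) expect_setequal(p, b)
  }
  expect_error(na_score(character(0), "a"), "empty")
})

test_that("match metrics equal the double-loop oracle on random instances", {
  expect_equal(match_metrics(complex_set(list(c("a", "b", "c"))),
                             complex_set(list(c("a", "b", "c"))))$f1, 1)
  no_match <- match_metrics(complex_set(list(c("a", "b", "c"))),
                            complex_set(list(c("x", "y", "z"))))
  expect_equal(no_match$precision, 0)
  expect_equal(no_match$f1, 0)
  for (s in 1:250) {
    inst <- random_instance(s)
    got <- match_metrics(complex_set(inst$P), complex_set(inst$B), 0.25)
    want <- brute_match(inst$P, inst$B, 0.25)
    expect_equal(got$precision, want$precision)
    expect_equal(got$recall, want$recall)
    expect_equal(got$f1, want$f1)
    expect_equal(got$n_matched_predicted, want$ncp)
    expect_equal(got$n_matched_known, want$ncb)
  }
})

test_that("Sn/PPV/Acc equal the T-matrix oracle and worked examples", {
  # single known {a,b,c,d}, single predicted {a,b}
  am <- accuracy_metrics(complex_set(list(c("a", "b"))),
                         complex_set(list(c("a", "b", "c", "d"))))
  expect_equal(am$sn, 0.5)
  expect_equal(am$ppv, 1)
  expect_equal(am$acc, sqrt(0.5))
  # exact recovery of disjoint complexes
  B <- complex_set(list(c("a", "b", "c"), c("x", "y", "z")))
  expect_equal(accuracy_metrics(B, B)$acc, 1)
  for (s in 1:250) {
    inst <- random_instance(1000 + s)
    # zero-overlap instances legitimately warn; that path has its own test
    got <- suppressWarnings(accuracy_metrics(complex_set(inst$P),
                                             complex_set(inst$B)))
    want <- brute_acc(inst$P, inst$B)
    expect_equal(got$sn, want$sn)
    expect_equal(got$ppv, want$ppv)
    expect_equal(got$acc, want$acc)
  }
  expect_warning(
    z <- accuracy_metrics(complex_set(list(c("a", "b"))),
                          complex_set(list(c("x", "y")))), "no overlap")
  expect_equal(z$acc, 0)
})

test_that("mean pairwise scores average over unordered pairs", {
  expect_equal(mean_pairwise_score(c("a", "b", "c"), function(x, y) 0.7), 0.7)
  tab <- data.frame(i = c("a", "b", "a"), j = c("b", "c", "c"),
                    s = c(0.3, 0.6, 0.9))
  sc <- pair_scorer_from_table(tab)
  expect_equal(mean_pairwise_score(c("a", "b", "c"), sc), 0.6)
  # 5 members: brute-force loop over the 10 pairs
  set.seed(31)
  ids <- letters[1:5]
  prs <- t(utils::combn(ids, 2))
  vals <- runif(10)
  tab5 <- data.frame(i = prs[, 1], j = prs[, 2], s = vals)
  expect_equal(mean_pairwise_score(ids, pair_scorer_from_table(tab5)),
               mean(vals))
  expect_error(mean_pairwise_score("a", sc), "2")
})

test_that("Manhattan concordance matches a pair-loop oracle", {
  m <- rbind(p1 = c(1, 2), p2 = c(3, 5), p3 = c(1, 2))
  colnames(m) <- c("s1", "s2")
  cs <- complex_set(list(c("p1", "p2"), c("p1", "p3")))
  out <- manhattan_concordance(m, cs)
  expect_equal(out$mean_dist, c(5, 0))
  set.seed(32)
  M <- matrix(abs(rnorm(40)), 8, 5,
              dimnames = list(paste0("q", 1:8), paste0("s", 1:5)))
  mem <- paste0("q", c(1, 3, 5, 7))
  res <- manhattan_concordance(M, complex_set(list(mem)))
  ds <- c()
  for (i in 1:3) for (j in (i + 1):4)
    ds <- c(ds, sum(abs(M[mem[i], ] - M[mem[j], ])))
  expect_equal(res$mean_dist, mean(ds))
  expect_equal(res$median_dist, median(ds))
  expect_equal(res$min_dist, min(ds))
  # complexes with missing members are skipped
  expect_warning(sk <- manhattan_concordance(M, complex_set(list(c("q1", "zz")))),
                 "skipped")
  expect_equal(nrow(sk), 0)
})

test_that("hypergeometric enrichment equals exhaustive summation", {
  expect_equal(hypergeom_enrichment_p(5, 0, 10, 100), 1)
  expect_equal(hypergeom_enrichment_p(4, 4, 4, 4), 1)
  brute_p <- function(C, t, F, V) {
    tot <- 0
    for (i in 0:(t - 1))
      tot <- tot + choose(F, i) * choose(V - F, C - i) / choose(V, C)
    1 - tot
  }
  expect_equal(hypergeom_enrichment_p(5, 3, 10, 100), brute_p(5, 3, 10, 100),
               tolerance = 1e-9)
  for (V in c(10, 25, 40, 60)) {
    for (s in 1:20) {
      set.seed(V * 100 + s)
      F_ <- sample(1:V, 1)
      C_ <- sample(1:V, 1)
      t_ <- sample(0:min(F_, C_), 1)
      expect_lt(abs(hypergeom_enrichment_p(C_, t_, F_, V) -
                      (if (t_ == 0) 1 else brute_p(C_, t_, F_, V))), 1e-9)
    }
  }
  # monotone non-increasing in the hit count
  ps <- vapply(0:5, function(t) hypergeom_enrichment_p(5, t, 12, 50), numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
  expect_error(hypergeom_enrichment_p(5, 6, 10, 100), "impossible")
})

test_that("pseudo complexes match template sizes and are seed-stable", {
  tmpl <- complex_set(list(letters[1:3], letters[1:4], letters[1:5]))
  uni <- paste0("u", 1:50)
  ps <- random_pseudo_complexes(tmpl, uni, seed = 5)
  expect_equal(lengths(ps$members), c(3, 4, 5))
  expect_identical(random_pseudo_complexes(tmpl, uni, seed = 5), ps)
  # inclusion frequencies are uniform within binomial error
  tmpl1 <- complex_set(list(letters[1:5]))
  uni10 <- paste0("u", 1:10)
  counts <- setNames(numeric(10), uni10)
  for (s in 1:1000) {
    d <- random_pseudo_complexes(tmpl1, uni10, seed = s)$members[[1]]
    counts[d] <- counts[d] + 1
  }
  p_hat <- counts / 1000
  se <- sqrt(0.5 * 0.5 / 1000)
  expect_true(all(abs(p_hat - 0.5) < 5 * se))
})
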