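test_that("delay embedding yields T - (m-1)t windows in order", {
  e <- delay_embed(c(1, 2, 3, 4), m = 3, t = 1)
  expect_equal(nrow(e), 2)
  expect_equal(e[1, ], c(1, 2, 3))
  expect_equal(e[2, ], c(2, 3, 4))

  expect_equal(nrow(delay_embed(rnorm(100), m = 7, t = 1)), 94)
  expect_equal(nrow(delay_embed(rnorm(10), m = 4, t = 3)), 1)
  expect_error(delay_embed(rnorm(5), m = 7, t = 1), "too short")
})

test_that("codewords are stable argsort rank patterns", {
  expect_equal(codeword_of_window(c(2, 3, 1)), c(2L, 0L, 1L))
  expect_equal(codeword_of_window(c(5, 5, 5)), c(0L, 1L, 2L))
  expect_equal(codeword_of_window(c(2, 3, 2)), c(0L, 2L, 1L))
})

test_that("codebooks count codeword frequencies", {
  cb <- build_codebook(c(1, 2, 3, 2, 1), m = 3)
  f <- codebook_frequencies(cb)
  expect_equal(sort(names(f)), sort(c("0,1,2", "0,2,1", "2,1,0")))
  expect_equal(unname(f), rep(1 / 3, 3))
  expect_equal(cb$total, 3)

  inc <- build_codebook(seq_len(20), m = 4)
  expect_equal(names(inc$counts), "0,1,2,3")
  expect_equal(unname(codebook_frequencies(inc)), 1)

  const <- build_codebook(rep(2, 10), m = 3)
  expect_equal(names(const$counts), "0,1,2")
})

test_that("codebooks match a naive enumerate-and-count oracle", {
  set.seed(101)
  for (rep in 1:30) {
    n <- sample(10:50, 1)
    m <- sample(2:4, 1)
    t <- sample(1:2, 1)
    if (n < (m - 1) * t + 1) next
    # heavy ties with 50% probability to exercise the stable rule
    x <- if (runif(1) < 0.5) sample(1:4, n, replace = TRUE) else rnorm(n)
    cb <- build_codebook(x, m, t)
    oracle <- naive_codebook_counts(x, m, t)
    expect_identical(unname(cb$counts), unname(oracle))
    expect_identical(names(cb$counts), names(oracle))
  }
})

test_that("normalized permutation entropy spans [0, 1]", {
  expect_equal(permutation_entropy(build_codebook(1:50, m = 3)), 0)
  uni <- new_codebook(
    stats::setNames(rep(1, 6),
                    c("0,1,2", "0,2,1", "1,0,2", "1,2,0", "2,0,1", "2,1,0")),
    total = 6, m = 3, t = 1)
  expect_equal(permutation_entropy(uni), 1)
  expect_equal(permutation_entropy(build_codebook(c(1, 2, 3, 2, 1), m = 3)),
               log(3) / log(6))
})

test_that("the entropy heuristic is deterministic and duplication-invariant", {
  set.seed(7)
  series <- lapply(1:6, function(i) {
    rep(c(8, 8, 8, 8, 40), 40) + rnorm(200, 0, 0.1)
  })
  pick <- entropy_heuristic(series, ms = 3:5)
  pick_dup <- entropy_heuristic(c(series, series), ms = 3:5)
  expect_equal(pick$m, pick_dup$m)
  expect_equal(pick$t, pick_dup$t)

  single <- entropy_heuristic(series, ms = 4, ts = 2)
  expect_equal(single$m, 4L)
  expect_equal(single$t, 2L)

  # white noise: entropy near 1 for every candidate
  noise <- lapply(1:3, function(i) rnorm(2000))
  h <- entropy_heuristic(noise, ms = 2:4)
  expect_true(all(h$trace$mean_entropy > 0.95))

  expect_error(suppressMessages(entropy_heuristic(list(rnorm(3)), ms = 7)),
               "feasible")
})

test_that("the symmetric alpha divergence satisfies its axioms", {
  set.seed(11)
  cb1 <- build_codebook(rnorm(100), m = 3)
  expect_equal(alpha_divergence(cb1, cb1), 0)

  a <- point_codebook("0,1,2", 3)
  b <- point_codebook("2,1,0", 3)
  expect_equal(alpha_divergence(a, b), 4)

  cb2 <- build_codebook(rnorm(100), m = 3)
  expect_equal(alpha_divergence(cb1, cb2), alpha_divergence(cb2, cb1))
  # closed form at alpha = 0.5: 2 * sum((sqrt p - sqrt q)^2)
  p <- codebook_frequencies(cb1); q <- codebook_frequencies(cb2)
  supp <- union(names(p), names(q))
  pv <- stats::setNames(numeric(length(supp)), supp); qv <- pv
  pv[names(p)] <- p; qv[names(q)] <- q
  expect_equal(alpha_divergence(cb1, cb2),
               2 * sum((sqrt(pv) - sqrt(qv))^2))

  expect_error(alpha_divergence(a, point_codebook("0,1", 2)), "different m")
})

test_that("employee distance is the root-sum-of-squares of divergences", {
  a <- list(shift_length = point_codebook("0,1,2", 3),
            rest_after = point_codebook("0,1,2", 3),
            start_hour = point_codebook("0,1,2", 3))
  expect_equal(employee_distance(a, a), 0)

  # construct divergences (3, 4, 0): a point mass against (1/16, 15/16)
  # gives 4 - 4 sqrt(1/16) = 3; disjoint point masses give 4
  mix <- new_codebook(c("0,1,2" = 1, "0,2,1" = 15), total = 16, m = 3,
                      t = 1)
  b <- list(shift_length = mix,
            rest_after = point_codebook("2,1,0", 3),
            start_hour = point_codebook("0,1,2", 3))
  expect_equal(employee_distance(a, b), 5)

  # oracle: recompute from the raw series and the formula
  set.seed(12)
  s1 <- lapply(1:3, function(i) rnorm(80))
  s2 <- lapply(1:3, function(i) rnorm(80))
  dims <- c("shift_length", "rest_after", "start_hour")
  ca <- stats::setNames(lapply(s1, build_codebook, m = 3), dims)
  cb <- stats::setNames(lapply(s2, build_codebook, m = 3), dims)
  manual <- sqrt(sum(vapply(dims, function(d) {
    alpha_divergence(ca[[d]], cb[[d]])^2
  }, numeric(1))))
  expect_equal(employee_distance(ca, cb), manual)
  expect_error(employee_distance(ca[1:2], cb), "missing dimension")
})

test_that("distance is invariant to strictly increasing transforms", {
  set.seed(13)
  mk <- function(f1 = identity, f2 = identity, f3 = identity, x) {
    stats::setNames(list(build_codebook(f1(x[[1]]), m = 4),
                         build_codebook(f2(x[[2]]), m = 4),
                         build_codebook(f3(x[[3]]), m = 4)),
                    c("shift_length", "rest_after", "start_hour"))
  }
  x <- lapply(1:3, function(i) sample(1:6, 60, replace = TRUE))
  y <- lapply(1:3, function(i) sample(1:6, 60, replace = TRUE))
  d0 <- employee_distance(mk(x = x), mk(x = y))
  d1 <- employee_distance(mk(exp, function(v) 2 * v + 1, function(v) v^3,
                             x = x),
                          mk(exp, function(v) 2 * v + 1, function(v) v^3,
                             x = y))
  expect_equal(d0, d1, tolerance = 1e-15)
})

test_that("pairwise distances form a symmetric zero-diagonal matrix", {
  set.seed(14)
  dims <- c("shift_length", "rest_after", "start_hour")
  mk <- function() stats::setNames(lapply(1:3, function(i) {
    build_codebook(rnorm(60), m = 3)
  }), dims)
  cbs <- list(a = mk(), b = mk(), c = mk())
  D <- pairwise_distances(cbs)
  expect_equal(D, t(D))
  expect_equal(diag(D), c(a = 0, b = 0, c = 0))
  expect_equal(D["a", "b"], employee_distance(cbs$a, cbs$b))

  # identical employees at zero distance
  cbs2 <- list(a = cbs$a, b = cbs$a)
  expect_equal(pairwise_distances(cbs2)["a", "b"], 0)

  # permuting employees permutes the matrix consistently
  Dp <- pairwise_distances(cbs[c("c", "a", "b")])
  expect_equal(Dp[c("a", "b", "c"), c("a", "b", "c")], D)
})

test_that("complete-linkage agglomeration behaves canonically", {
  D2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"),
                                                 c("a", "b")))
  tr <- agglomerate_complete(D2)
  expect_equal(tr$height, 3)

  # ultrametric input: cophenetic distances reproduce the input
  Du <- matrix(c(0, 1, 2, 1, 0, 2, 2, 2, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  tru <- agglomerate_complete(Du)
  expect_equal(as.matrix(stats::cophenetic(tru))[letters[1:3],
                                                 letters[1:3]], Du)

  # two separated groups: the k=2 cut minimizes the maximal
  # within-cluster distance over all 2-partitions (brute force, n = 6)
  set.seed(15)
  pts <- c(rnorm(3, 0, 0.1), rnorm(3, 10, 0.1))
  D6 <- as.matrix(stats::dist(pts))
  dimnames(D6) <- list(letters[1:6], letters[1:6])
  cut2 <- stats::cutree(agglomerate_complete(D6), 2)
  maxwithin <- function(lab) {
    max(vapply(split(seq_along(lab), lab), function(i) {
      if (length(i) < 2) 0 else max(D6[i, i])
    }, numeric(1)))
  }
  best <- Inf
  for (mask in 1:(2^5 - 1)) { # all 2-partitions up to relabelling
    lab <- c(1L, as.integer(intToBits(mask))[1:5] + 1L)
    best <- min(best, maxwithin(lab))
  }
  expect_equal(maxwithin(cut2), best)
  expect_equal(unname(cut2), rep(1:2, each = 3))
})

test_that("the multinomial information criterion ranks partitions sensibly", {
  set.seed(16)
  dims <- c("shift_length", "rest_after", "start_hour")
  mk <- function(pattern) stats::setNames(lapply(1:3, function(i) {
    build_codebook(pattern + rnorm(200, 0, 0.01), m = 3)
  }), dims)
  up <- rep(c(1, 2, 3, 4), 50)     # rising patterns
  zig <- rep(c(1, 3, 2, 4), 50)    # zigzag patterns
  cbs <- list(a1 = mk(up), a2 = mk(up), b1 = mk(zig), b2 = mk(zig))

  true_lab <- c(a1 = 1, a2 = 1, b1 = 2, b2 = 2)
  bic1 <- clustering_bic(cbs, c(a1 = 1, a2 = 1, b1 = 1, b2 = 1))
  bic2 <- clustering_bic(cbs, true_lab)
  bic4 <- clustering_bic(cbs, c(a1 = 1, a2 = 2, b1 = 3, b2 = 4))
  expect_lt(bic2, bic1)
  expect_lt(bic2, bic4)

  # the saturated partition attains the maximal log-likelihood
  expect_gte(attr(bic4, "loglik"), attr(bic2, "loglik"))
  expect_gte(attr(bic2, "loglik"), attr(bic1, "loglik"))

  # merging employees with identical codebooks leaves LL unchanged
  cbs_id <- list(a1 = cbs$a1, a2 = cbs$a1)
  l_sep <- attr(clustering_bic(cbs_id, c(a1 = 1, a2 = 2)), "loglik")
  l_mrg <- attr(clustering_bic(cbs_id, c(a1 = 1, a2 = 1)), "loglik")
  expect_equal(l_sep, l_mrg)

  expect_error(clustering_bic(cbs, c(1, 1, 1)), "length")
})

test_that("k selection scans tree cuts and AIC never picks fewer clusters", {
  set.seed(17)
  coh <- recovery_cohort(17, n_per = 6, days = 300)
  prep <- prep_series(coh)
  cbs <- lapply(prep$series, employee_codebooks, m = 4, t = 1)
  D <- pairwise_distances(cbs)
  tree <- agglomerate_complete(D)

  sol <- select_k(tree, cbs, ks = 1:6)
  expect_equal(sol$k, 3)
  expect_equal(adjusted_rand(sol$labels, coh$labels[names(sol$labels)]), 1)
  expect_equal(nrow(sol$trace), 6)

  forced <- select_k(tree, cbs, ks = 5)
  expect_equal(forced$k, 5)

  aic <- select_k(tree, cbs, ks = 1:6, criterion = "AIC")
  expect_gte(aic$k, sol$k)
})
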