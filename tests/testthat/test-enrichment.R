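test_that("hypergeometric tail matches hand-computed values", {
  # certain event
  expect_identical(hypergeomTail(0, 10, 5, 3), 1.0)
  # C(2,2)C(2,0)/C(4,2) = 1/6
  expect_equal(hypergeomTail(2, 4, 2, 2), 1 / 6, tolerance = 1e-12)
  # 1 - C(5,0)C(5,1)/C(10,1) = 0.5
  expect_equal(hypergeomTail(1, 10, 5, 1), 0.5, tolerance = 1e-12)
  expect_error(hypergeomTail(3, 4, 2, 2), "domain")
})

test_that("statistic handles hand-worked and degenerate lists", {
  # all zeros: no annotated genes at all
  expect_identical(xlmhgStatistic(rep(0L, 6), 1L, 6L),
                   list(sMhg = 1.0, nStar = 0L, kStar = 0L))
  # hand evaluation of all 4 cutoffs of [1,1,0,0]
  st <- xlmhgStatistic(c(1, 1, 0, 0), X = 1L, L = 4L)
  expect_equal(st$sMhg, 1 / 6, tolerance = 1e-12)
  expect_identical(st$nStar, 2L)
  expect_identical(st$kStar, 2L)
  # X = 3 leaves no testable cutoff
  expect_identical(xlmhgStatistic(c(1, 1, 0, 0), X = 3L, L = 4L)$sMhg, 1.0)
  # top block: s = 1/C(N,K) at n = K
  v <- simulateRankedList(100, 10, "top_block")
  st <- xlmhgStatistic(v, X = 1L, L = 100L)
  expect_equal(st$sMhg, 1 / choose(100, 10), tolerance = 1e-12)
  expect_identical(st$nStar, 10L)
  # bottom block under L = N/8: nothing above L
  vb <- simulateRankedList(100, 10, "bottom_block")
  expect_identical(xlmhgStatistic(vb, X = 1L, L = 12L)$sMhg, 1.0)
})

test_that("DP p-value reproduces hand-enumerated cases", {
  expect_identical(xlmhgPvalue(8, 0, 1, 8, 0.5), 1.0)
  # exactly one of the C(4,2)=6 placements achieves s <= 1/6
  expect_equal(xlmhgPvalue(4, 2, 1, 4, 1 / 6), 1 / 6, tolerance = 1e-12)
})

test_that("enumeration oracle tabulates the exact null distribution", {
  d <- xlmhgNullDistribution(4, 2, 1, 4)
  expect_equal(d$s, c(1 / 6, 1 / 2, 5 / 6, 1), tolerance = 1e-12)
  expect_equal(as.numeric(d$count), c(1, 3, 1, 1))
  expect_equal(sum(d$count), choose(4, 2))
  # N = K: a single arrangement
  dk <- xlmhgNullDistribution(5, 5, 1, 5)
  expect_equal(sum(dk$count), 1)
  expect_error(xlmhgNullDistribution(30, 15, 1, 30, maxArrangements = 100),
               "too large")
})

test_that("per-term constraints follow the max(xMin, ceil(xFrac K)) rule", {
  expect_identical(termConstraints(30, 0.25, 5L, 100L)$X, 8L)
  expect_identical(termConstraints(10, 0.25, 5L, 100L)$X, 5L)
  expect_identical(termConstraints(5, 0.25, 5L, 100L)$X, 5L)
  expect_identical(termConstraints(30, 0.25, 5L, 100L)$L, 100L)
})

test_that("fold enrichment is the density ratio", {
  expect_identical(foldEnrichment(5, 5, 10, 100), 10.0)
  expect_identical(foldEnrichment(10, 100, 10, 100), 1.0)
  expect_identical(foldEnrichment(0, 5, 10, 100), 0.0)
  expect_error(foldEnrichment(1, 0, 10, 100), ">= 1")
})

test_that("DP equals the enumeration oracle on exhaustive small instances", {
  for (N in c(5L, 8L)) {
    for (K in 0:N) {
      for (X in c(1L, 2L)) {
        for (L in unique(c(ceiling(N / 2), N))) {
          dist <- xlmhgNullDistribution(N, K, X, L)
          cdf <- cumsum(dist$count) / choose(N, K)
          for (i in seq_along(dist$s)) {
            expect_equal(xlmhgPvalue(N, K, X, L, dist$s[i]), cdf[i],
                         tolerance = 1e-12,
                         label = sprintf("N=%d K=%d X=%d L=%d s=%g",
                                         N, K, X, L, dist$s[i]))
          }
        }
      }
    }
  }
})

test_that("statistic and p-value obey bound and monotonicity properties", {
  set.seed(123)
  for (i in 1:25) {
    N <- sample(10:60, 1)
    K <- sample(1:min(10, N), 1)
    v <- simulateRankedList(N, K, "random", seed = i)
    X <- sample(1:3, 1)
    L <- sample(seq(2L, N), 1)
    st <- xlmhgStatistic(v, X, L)
    p <- xlmhgPvalue(N, K, X, L, st$sMhg)
    # bounds: s <= p <= min(1, s * #testable cutoffs)
    kcum <- cumsum(v)
    nTestable <- sum(seq_len(N) <= L & kcum >= X)
    expect_lte(st$sMhg, p + 1e-12)
    expect_lte(p, min(1, st$sMhg * max(nTestable, 1)) + 1e-12)
    # monotonicity: shrinking L or raising X never decreases s
    expect_gte(xlmhgStatistic(v, X, max(2L, L %/% 2L))$sMhg + 1e-15,
               st$sMhg)
    expect_gte(xlmhgStatistic(v, X + 1L, L)$sMhg + 1e-15, st$sMhg)
    # label invariance: p depends on the arrangement only through s
    v2 <- simulateRankedList(N, K, "random", seed = i + 1000)
    st2 <- xlmhgStatistic(v2, X, L)
    if (isTRUE(all.equal(st2$sMhg, st$sMhg, tolerance = 1e-12))) {
      expect_equal(xlmhgPvalue(N, K, X, L, st2$sMhg), p,
                   tolerance = 1e-12)
    }
    # k* counts the ones above the attaining cutoff
    if (st$nStar > 0) {
      expect_identical(st$kStar, sum(v[seq_len(st$nStar)]))
      expect_gte(st$kStar, X)
    }
  }
})

test_that("X = 1, L = N recovers the unconstrained minimum-HG test", {
  # independent reference: direct minimization over every cutoff, and the
  # p-value by enumeration
  for (seed in 1:5) {
    N <- 12L; K <- 4L
    v <- simulateRankedList(N, K, "random", seed = seed)
    kcum <- cumsum(v)
    sRef <- min(vapply(seq_len(N), function(n)
      hypergeomTail(kcum[n], N, K, n), numeric(1)))
    st <- xlmhgStatistic(v, X = 1L, L = N)
    expect_equal(st$sMhg, sRef, tolerance = 1e-12)
    expect_equal(xlmhgPvalue(N, K, 1L, N, st$sMhg),
                 xlmhgPvalueOracle(N, K, 1L, N, st$sMhg),
                 tolerance = 1e-12)
  }
})

test_that("p-values are approximately uniform on random lists", {
  ps <- vapply(1:300, function(s) {
    v <- simulateRankedList(100, 10, "random", seed = s)
    xlmhgTest(v, X = 1L, L = 100L)$pMhg
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
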