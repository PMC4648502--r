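# Relative tolerance used both when minimizing the statistic and when the
# dynamic program classifies lattice cells as "at or below s"; the two sides
# must use identical arithmetic or ties at s split inconsistently.
.MHG_REL_TOL <- 1e-12

#' Hypergeometric tail probability
#'
#' \eqn{P(X \ge k)} for \eqn{X \sim} Hypergeometric(N, K, n): the probability
#' of at least \code{k} annotated genes among the first \code{n} of a
#' uniformly shuffled list of \code{N} genes of which \code{K} are annotated.
#' Equivalent to a one-sided Fisher exact test; evaluated with
#' \code{stats::phyper}, which works on log-stable internals.
#'
#' @param k observed count of annotated genes above the cutoff.
#' @param N total genes in the list.
#' @param K total annotated genes.
#' @param n cutoff rank.
#' @return probability in (0, 1].
#' @export
hypergeomTail <- function(k, N, K, n) {
  if (any(k < 0) || any(k > pmin(K, n)) || any(n > N) || K > N)
    stop("hypergeomTail: domain violation (k=", k[1], ", N=", N,
         ", K=", K, ", n=", n[1], ")")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Per-term cutoff constraints
#'
#' The minimum-overlap constraint X is adapted to the term's annotated-gene
#' count: a cutoff is only tested once at least
#' \code{max(xMin, ceiling(xFrac * K))} annotated genes lie above it, e.g.
#' \code{ceiling(0.25 * 30) = 8} for a 30-gene term at the defaults.  The
#' rank limit L is taken as configured (by default \code{floor(N/8)},
#' reflecting that the test is applied to both ends of each ranking).
#'
#' @param K annotated genes present in the ranked list.
#' @param xFrac fraction of K required above a testable cutoff.
#' @param xMin absolute minimum count required above a testable cutoff.
#' @param lRank largest rank tested.
#' @return list with integer elements \code{X} and \code{L}.
#' @export
termConstraints <- function(K, xFrac = 0.25, xMin = 5L, lRank) {
  stopifnot(xFrac >= 0, xFrac <= 1, xMin >= 1L)
  list(X = as.integer(max(xMin, ceiling(xFrac * K))), L = as.integer(lRank))
}

#' Fold enrichment at a cutoff
#'
#' \code{(k/n) / (K/N)}: the density of annotated genes above the cutoff
#' relative to their density in the whole list.  Used as the effect size
#' when ordering enriched terms for the within-component filter.
#'
#' @inheritParams hypergeomTail
#' @return nonnegative ratio.
#' @export
foldEnrichment <- function(k, n, K, N) {
  if (n < 1 || K < 1) stop("foldEnrichment: n and K must be >= 1")
  (k / n) / (K / N)
}

#' XL-mHG enrichment statistic
#'
#' Scans the ranked binary list and returns the minimum hypergeometric tail
#' probability over the testable cutoffs: ranks \code{n <= L} at which at
#' least \code{X} annotated genes have been seen.  Only ranks holding an
#' annotated gene can attain the minimum (the tail grows as unannotated
#' genes accumulate), so the scan touches K candidate cutoffs.  Ties are
#' broken by the smallest attaining rank, making the reported driving set
#' minimal.  With no testable cutoff the statistic is 1 and
#' \code{nStar = kStar = 0}.
#'
#' @param v integer/logical vector of 0/1; 1 marks an annotated gene.
#' @param X minimum annotated genes above a testable cutoff.
#' @param L largest testable rank.
#' @return list with \code{sMhg}, \code{nStar}, \code{kStar}.
#' @export
xlmhgStatistic <- function(v, X = 1L, L = length(v)) {
  v <- as.integer(v)
  stopifnot(all(v %in% c(0L, 1L)), X >= 1L, L >= 1L, L <= length(v))
  N <- length(v)
  K <- sum(v)
  if (K == 0L)
    return(list(sMhg = 1.0, nStar = 0L, kStar = 0L))
  kcum <- cumsum(v)
  cand <- which(v == 1L)
  cand <- cand[cand <= L & kcum[cand] >= X]
  if (!length(cand))
    return(list(sMhg = 1.0, nStar = 0L, kStar = 0L))
  tails <- hypergeomTail(kcum[cand], N, K, cand)
  best <- which(tails <= min(tails) * (1 + .MHG_REL_TOL))[1L]
  list(sMhg = tails[best], nStar = cand[best], kStar = kcum[cand[best]])
}

#' Exact XL-mHG p-value by dynamic programming
#'
#' The probability, under a uniform random arrangement of K annotated genes
#' among N ranks, that the constrained minimum statistic is at most
#' \code{sMhg}.  Arrangements are lattice paths from (0, 0) to (N, K); the
#' "significant region" is the set of cells (n, k) with \code{n <= L},
#' \code{k >= X} and tail probability at most \code{sMhg}.  Because the tail
#' grows along rank-only steps and shrinks along annotated steps, a path can
#' first enter the region only via an annotated step, so the p-value is the
#' sum over region-boundary cells of (probability of reaching the cell's
#' diagonal predecessor while avoiding the region) x (probability of the
#' completing step).  The recursion runs over normalized path counts
#' \code{a(n, k) = A(n, k) / C(n, k)}, which stay in [0, 1] so no overflow
#' occurs, and only ranks up to L are visited: O(LK) time.
#'
#' The value depends on the list only through (N, K), never on which
#' arrangement attained the statistic.
#'
#' @param N list length.
#' @param K annotated genes in the list.
#' @param X,L cutoff constraints (as used for the statistic).
#' @param sMhg the observed statistic.
#' @return exact p-value in (0, 1].
#' @export
xlmhgPvalue <- function(N, K, X, L, sMhg) {
  stopifnot(N >= 1L, K >= 0L, K <= N, X >= 1L, L >= 1L, L <= N)
  if (K == 0L || sMhg >= 1)
    return(1.0)
  thresh <- sMhg * (1 + .MHG_REL_TOL)
  a <- c(1.0, rep(0.0, K))      # a[k+1] = a(n-1, k); start at n = 0
  p <- 0.0
  for (n in seq_len(L)) {
    kmax <- min(n, K)
    aprev <- a
    anew <- numeric(K + 1L)
    anew[1:(kmax + 1L)] <- aprev[1:(kmax + 1L)] * (n - 0:kmax) / n
    if (kmax >= 1L)
      anew[2:(kmax + 1L)] <- anew[2:(kmax + 1L)] +
        aprev[1:kmax] * (1:kmax) / n
    # region cells at this rank
    if (kmax >= X) {
      kr <- X:kmax
      tails <- stats::phyper(kr - 1, K, N - K, n, lower.tail = FALSE)
      inR <- tails <= thresh
      if (any(inR)) {
        krIn <- kr[inR]
        p <- p + sum(aprev[krIn] * (krIn / n) *
                       stats::dhyper(krIn, K, N - K, n))
        anew[krIn + 1L] <- 0.0
      }
    }
    a <- anew
  }
  min(p, 1.0)
}

#' Full null distribution of the XL-mHG statistic by enumeration
#'
#' Test oracle: enumerates every arrangement of K annotated genes among N
#' ranks (combinations, not permutations), evaluates the statistic on each,
#' and tabulates the exact distribution.  Exponential in problem size, hence
#' restricted to \code{choose(N, K) <= maxArrangements}.
#'
#' @inheritParams xlmhgPvalue
#' @param maxArrangements refuse instances larger than this.
#' @return data.frame with columns \code{s} (sorted support) and
#'   \code{count}; counts sum to \code{choose(N, K)}.
#' @export
xlmhgNullDistribution <- function(N, K, X, L, maxArrangements = 200000) {
  stopifnot(K >= 0L, K <= N)
  if (choose(N, K) > maxArrangements)
    stop("instance too large to enumerate: choose(", N, ",", K, ") > ",
         maxArrangements)
  if (K == 0L)
    return(data.frame(s = 1.0, count = 1))
  combs <- utils::combn(N, K)
  svals <- apply(combs, 2L, function(pos) {
    v <- integer(N); v[pos] <- 1L
    xlmhgStatistic(v, X = X, L = L)$sMhg
  })
  svals <- sort(svals)
  # support values equal up to the statistic's tie tolerance are one value:
  # mathematically identical tails can differ by a few ulp when reached
  # through different (n, k) cells
  newGroup <- c(TRUE, diff(svals) > svals[-length(svals)] * .MHG_REL_TOL)
  grp <- cumsum(newGroup)
  data.frame(s = svals[newGroup], count = as.vector(table(grp)))
}

#' @describeIn xlmhgNullDistribution p-value by direct enumeration:
#'   \eqn{P(S \le s)} from the tabulated distribution.
#' @export
xlmhgPvalueOracle <- function(N, K, X, L, sMhg, maxArrangements = 200000) {
  if (sMhg >= 1) return(1.0)
  dist <- xlmhgNullDistribution(N, K, X, L, maxArrangements)
  sum(dist$count[dist$s <= sMhg * (1 + .MHG_REL_TOL)]) / choose(N, K)
}

#' One-call XL-mHG test
#'
#' @inheritParams xlmhgStatistic
#' @return list with \code{sMhg}, \code{pMhg}, \code{nStar}, \code{kStar}.
#' @export
xlmhgTest <- function(v, X = 1L, L = length(v)) {
  st <- xlmhgStatistic(v, X = X, L = L)
  st$pMhg <- xlmhgPvalue(length(v), sum(as.integer(v)), X, L, st$sMhg)
  st[c("sMhg", "pMhg", "nStar", "kStar")]
}
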