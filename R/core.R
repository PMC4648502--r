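#' Create a run configuration
#'
#' See \linkS4class{SigPCAConfig} for the meaning and provenance of the
#' defaults.
#'
#' @param xFrac,xMin per-term cutoff constraint: X = max(xMin,
#'   ceiling(xFrac * K)).
#' @param lRank largest tested rank; NA means floor(N/8) at run time.
#' @param alphaB per-test significance threshold.
#' @param rCorr signature inclusion correlation; -1 disables filtering.
#' @param zThreshold,nPerm permutation-test settings for choosing D.
#' @param dOverride fix the number of tested components instead of
#'   estimating it.
#' @param topNVariance keep only this many most-variable genes; NA keeps all.
#' @param seed integer seed for all randomness of the run.
#' @return a \linkS4class{SigPCAConfig}.
#' @export
sigPCAConfig <- function(xFrac = 0.25, xMin = 5L, lRank = NA_integer_,
                         alphaB = 1e-6, rCorr = 0.5, zThreshold = 2.0,
                         nPerm = 15L, dOverride = NA_integer_,
                         topNVariance = NA_integer_, seed = 0L) {
  new("SigPCAConfig", xFrac = xFrac, xMin = as.integer(xMin),
      lRank = as.integer(lRank), alphaB = alphaB, rCorr = rCorr,
      zThreshold = zThreshold, nPerm = as.integer(nPerm),
      dOverride = as.integer(dOverride),
      topNVariance = as.integer(topNVariance), seed = as.integer(seed))
}

#' Bonferroni-corrected threshold
#'
#' @param alpha family-wise significance level.
#' @param nTests number of tests.
#' @return per-test threshold \code{alpha / nTests}.
#' @export
bonferroniThreshold <- function(alpha, nTests) {
  stopifnot(alpha > 0, alpha < 1, nTests >= 1)
  alpha / nTests
}

#' Rank genes by component loading
#'
#' Each component yields two rankings: descending loadings (direction +1)
#' and ascending loadings (direction -1).  Genes at the top of either
#' ranking contribute most strongly to the component, in opposite
#' directions.  Ties are broken alphabetically by gene name.
#'
#' @param pca a \code{PcaModel} from [fitPca()].
#' @param pc component index in 1..D.
#' @param direction +1 (descending) or -1 (ascending).
#' @return character vector of gene names, best-ranked first.
#' @export
rankByLoadings <- function(pca, pc, direction = 1L) {
  stopifnot(inherits(pca, "PcaModel"), direction %in% c(-1L, 1L))
  if (pc < 1L || pc > pca$D)
    stop("pc must be in 1..", pca$D)
  l <- pca$loadings[, pc]
  genes <- rownames(pca$loadings)
  genes[order(-direction * l, genes)]
}

# one XL-mHG test of a term's gene set against a ranked gene list;
# returns NULL when K < xMin or the result cannot reach alphaB
.testTerm <- function(termId, set, ranked, xFrac, xMin, lRank, alphaB,
                      pc = NA_integer_) {
  v <- as.integer(ranked %in% set)
  K <- sum(v)
  if (K < xMin) return(NULL)
  N <- length(ranked)
  cst <- termConstraints(K, xFrac = xFrac, xMin = xMin,
                         lRank = min(lRank, N))
  st <- xlmhgStatistic(v, X = cst$X, L = cst$L)
  if (st$sMhg > alphaB) return(NULL)   # p >= s, cannot pass
  p <- xlmhgPvalue(N, K, cst$X, cst$L, st$sMhg)
  if (p > alphaB) return(NULL)
  driving <- ranked[seq_len(st$nStar)]
  driving <- driving[driving %in% set]
  list(termId = termId, pc = as.integer(pc), sMhg = st$sMhg, pMhg = p,
       nStar = st$nStar, kStar = st$kStar, K = K, N = N,
       X = cst$X, L = cst$L,
       escore = foldEnrichment(st$kStar, st$nStar, K, N),
       drivingGenes = driving)
}

.resultsToFrame <- function(resList) {
  if (!length(resList))
    return(data.frame(termId = character(), pc = integer(),
                      sMhg = numeric(), pMhg = numeric(), nStar = integer(),
                      kStar = integer(), K = integer(), N = integer(),
                      X = integer(), L = integer(), escore = numeric(),
                      drivingGenes = I(list())))
  df <- data.frame(
    termId = vapply(resList, `[[`, character(1), "termId"),
    pc = vapply(resList, `[[`, integer(1), "pc"),
    sMhg = vapply(resList, `[[`, numeric(1), "sMhg"),
    pMhg = vapply(resList, `[[`, numeric(1), "pMhg"),
    nStar = vapply(resList, function(r) as.integer(r$nStar), integer(1)),
    kStar = vapply(resList, function(r) as.integer(r$kStar), integer(1)),
    K = vapply(resList, function(r) as.integer(r$K), integer(1)),
    N = vapply(resList, function(r) as.integer(r$N), integer(1)),
    X = vapply(resList, function(r) as.integer(r$X), integer(1)),
    L = vapply(resList, function(r) as.integer(r$L), integer(1)),
    escore = vapply(resList, `[[`, numeric(1), "escore"),
    stringsAsFactors = FALSE)
  df$drivingGenes <- I(lapply(resList, `[[`, "drivingGenes"))
  rownames(df) <- NULL
  df
}

#' Enrichment of every gene set in one ranking
#'
#' Tests each set of the collection against the ranked gene list with the
#' XL-mHG test.  Set genes absent from the ranked list are dropped before
#' testing, so K is the number of annotated genes actually in the analysis;
#' terms with K below \code{xMin} are not tested.  Only results with exact
#' p-value at most \code{alphaB} are returned, each carrying its effect
#' size (fold enrichment at the attaining cutoff) and driving genes
#' (annotated genes at or above the attaining cutoff).
#'
#' @param ranked character vector of gene names, best-ranked first.
#' @param collection a \linkS4class{GeneSetCollection}.
#' @param config a \linkS4class{SigPCAConfig}.
#' @param pc signed component index recorded in the results.
#' @return data.frame of significant results with a \code{drivingGenes}
#'   list column.
#' @export
enrichRanking <- function(ranked, collection, config, pc = NA_integer_) {
  N <- length(ranked)
  lRank <- if (is.na(config@lRank)) max(1L, N %/% 8L) else config@lRank
  res <- lapply(termIds(collection), function(tid)
    .testTerm(tid, collection@sets[[tid]], ranked,
              config@xFrac, config@xMin, lRank, config@alphaB, pc = pc))
  .resultsToFrame(Filter(Negate(is.null), res))
}

#' Within-ranking redundancy filter
#'
#' Gene sets enriched in the same ranking often overlap because of the
#' nested ontology structure.  Terms are processed in decreasing order of
#' effect size (ties: smaller p-value, then term id); the strongest term is
#' always kept and its driving genes marked as "seen".  Each subsequent term
#' is re-tested on the ranking with all seen genes deleted (the list
#' contracts and K is recomputed), reusing the term's original X and the
#' configured L capped at the shrunken length; it is kept only if the
#' re-test is still significant at \code{alphaB}, in which case its driving
#' genes join the seen set.
#'
#' @param results data.frame from [enrichRanking()] (one PC and direction).
#' @param ranked the ranking the results were computed on.
#' @param config a \linkS4class{SigPCAConfig}.
#' @param collection the \linkS4class{GeneSetCollection} tested.
#' @return the kept subset of \code{results}, in filter order.
#' @export
localFilter <- function(results, ranked, config, collection) {
  if (nrow(results) <= 1L) return(results)
  N <- length(ranked)
  lRank <- if (is.na(config@lRank)) max(1L, N %/% 8L) else config@lRank
  ord <- order(-results$escore, results$pMhg, results$termId)
  results <- results[ord, , drop = FALSE]
  keep <- logical(nrow(results))
  keep[1L] <- TRUE
  seen <- results$drivingGenes[[1L]]
  for (i in 2L:nrow(results)) {
    shrunk <- ranked[!(ranked %in% seen)]
    set <- collection@sets[[results$termId[i]]]
    v <- as.integer(shrunk %in% set)
    K2 <- sum(v)
    ok <- FALSE
    if (K2 >= results$X[i]) {
      L2 <- min(lRank, length(shrunk))
      st <- xlmhgStatistic(v, X = results$X[i], L = L2)
      if (st$sMhg <= config@alphaB) {
        p <- xlmhgPvalue(length(shrunk), K2, results$X[i], L2, st$sMhg)
        ok <- p <= config@alphaB
      }
    }
    if (ok) {
      keep[i] <- TRUE
      seen <- union(seen, results$drivingGenes[[i]])
    }
  }
  out <- results[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-component redundancy filter
#'
#' Strong biological effects can surface on several components.  Results are
#' processed in component order (|pc| ascending; within a component the
#' positive-direction results precede the negative ones): a term is dropped
#' if it, or any transitively related term (ancestor or descendant in the
#' ontology), has already produced a kept result.  Earlier components are
#' thereby prioritized, as they capture more variance.
#'
#' @param results data.frame of local-filtered results from all rankings.
#' @param ontology an \linkS4class{Ontology} or NULL (no relatedness; only
#'   exact term repeats are dropped).
#' @return the kept subset, ordered by (|pc|, direction, -escore).
#' @export
globalFilter <- function(results, ontology = NULL) {
  if (nrow(results) <= 1L) return(results)
  ord <- order(abs(results$pc), -sign(results$pc), -results$escore,
               results$termId)
  results <- results[ord, , drop = FALSE]
  used <- character()
  keep <- logical(nrow(results))
  for (i in seq_len(nrow(results))) {
    tid <- results$termId[i]
    rel <- tid
    if (!is.null(ontology) && tid %in% ontology@terms$id)
      rel <- c(tid, relatedTerms(ontology, tid))
    if (!any(rel %in% used)) {
      keep[i] <- TRUE
      used <- c(used, tid)
    }
  }
  out <- results[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a signature from one enrichment result
#'
#' Seed-and-extend construction on standardized expression: (1) average the
#' standardized profiles of the driving genes; (2) the seed is the mean
#' profile of the X driving genes most strongly Pearson-correlated with that
#' average (all of them if there are at most X); (3) every remaining driving
#' gene joins if its correlation with the seed is at least \code{rCorr}
#' (\code{rCorr = -1} keeps all driving genes).  The signature expression is
#' the unweighted mean of the standardized profiles of the final members,
#' and therefore has mean ~0 across samples.
#'
#' @param result one row of an enrichment result data.frame.
#' @param Estd standardized genes x samples matrix ([standardizeRows()]).
#' @param config a \linkS4class{SigPCAConfig}.
#' @param collection the \linkS4class{GeneSetCollection} (for term labels).
#' @return a \linkS4class{Signature}.
#' @export
buildSignature <- function(result, Estd, config, collection) {
  driving <- result$drivingGenes[[1L]]
  missing <- setdiff(driving, rownames(Estd))
  if (length(missing))
    stop("driving genes absent from expression data: ",
         paste(missing[1:min(3L, length(missing))], collapse = ", "))
  P <- Estd[driving, , drop = FALSE]
  avg <- colMeans(P)
  X <- result$X
  if (length(driving) > X) {
    r <- as.vector(stats::cor(t(P), avg))
    seedGenes <- driving[order(-r, driving)][seq_len(X)]
  } else {
    seedGenes <- driving
  }
  seed <- colMeans(Estd[seedGenes, , drop = FALSE])
  rest <- setdiff(driving, seedGenes)
  joiners <- character()
  if (length(rest)) {
    rSeed <- as.vector(stats::cor(t(Estd[rest, , drop = FALSE]), seed))
    joiners <- rest[rSeed >= config@rCorr]
  }
  members <- c(seedGenes, joiners)
  rMem <- as.vector(stats::cor(t(Estd[members, , drop = FALSE]), seed))
  members <- members[order(-rMem, members)]
  meta <- collection@termMeta[match(result$termId, collection@termMeta$id), ]
  new("Signature",
      termId = result$termId,
      termName = if (!is.na(meta$name[1L])) meta$name[1L] else result$termId,
      namespace = if (!is.na(meta$namespace[1L])) meta$namespace[1L]
                  else "custom",
      pc = as.integer(result$pc),
      genes = members,
      expression = colMeans(Estd[members, , drop = FALSE]),
      enrichment = list(sMhg = result$sMhg, pMhg = result$pMhg,
                        nStar = result$nStar, kStar = result$kStar,
                        escore = result$escore, X = result$X, L = result$L,
                        drivingGenes = driving),
      kTotal = as.integer(result$K))
}

#' Human-readable signature label
#'
#' Domain prefix (BP/MF/CC, or GS for custom sets), the term name, then
#' \code{(pc, number of member genes, total annotated genes K)}; a negative
#' pc marks enrichment among the lowest loadings.
#'
#' @param sig a \linkS4class{Signature}.
#' @return character label.
#' @export
signatureLabel <- function(sig) {
  prefix <- switch(sig@namespace,
                   biological_process = "BP",
                   molecular_function = "MF",
                   cellular_component = "CC",
                   "GS")
  sprintf("%s: %s (%d, %d, %d)", prefix, sig@termName, sig@pc,
          length(sig@genes), sig@kTotal)
}

#' Order signatures for presentation
#'
#' \code{method = "cluster"} (the default used for the persisted signature
#' matrix) returns the leaf order of average-linkage hierarchical clustering
#' on Pearson correlation distance (1 - r) between signature expression
#' profiles; \code{method = "pc"} orders by (|pc|, direction, decreasing
#' effect size).
#'
#' @param sigs list of \linkS4class{Signature}s.
#' @param method "cluster" or "pc".
#' @return integer permutation of \code{seq_along(sigs)}.
#' @export
orderSignatures <- function(sigs, method = c("cluster", "pc")) {
  method <- match.arg(method)
  if (length(sigs) < 1L) stop("need at least one signature")
  if (length(sigs) == 1L) return(1L)
  if (method == "pc") {
    pc <- vapply(sigs, function(s) s@pc, integer(1))
    es <- vapply(sigs, function(s) s@enrichment$escore, numeric(1))
    return(order(abs(pc), -sign(pc), -es))
  }
  M <- do.call(rbind, lapply(sigs, function(s) s@expression))
  cc <- suppressWarnings(stats::cor(t(M)))
  cc[!is.finite(cc)] <- 0
  d <- stats::as.dist(1 - cc)
  stats::hclust(d, method = "average")$order
}

#' Run the full signature-discovery pipeline
#'
#' Pipeline: optional variance filter; permutation test for the number of
#' components D (or \code{dOverride}); PCA; for each component and each
#' ranking direction, XL-mHG enrichment of every gene set followed by the
#' within-ranking filter; the cross-component filter; signature construction
#' on standardized expression; assembly of the signature matrix in
#' clustered order.  Fully deterministic given \code{config@seed}.  Because
#' the significance threshold is not adjusted for D, re-running with a
#' larger D leaves the signatures from earlier components unchanged.
#'
#' @param E genes x samples numeric matrix with dimnames (log-scale values).
#' @param collection a \linkS4class{GeneSetCollection}.
#' @param ontology an \linkS4class{Ontology} for relatedness queries, or
#'   NULL when running with arbitrary gene sets.
#' @param config a \linkS4class{SigPCAConfig}.
#' @return a \linkS4class{SigPCAResult} (empty, with a warning, if D = 0 or
#'   nothing is enriched).
#' @export
runSigPCA <- function(E, collection, ontology = NULL,
                      config = sigPCAConfig()) {
  t0 <- proc.time()[["elapsed"]]
  .checkExpression(E)
  removedVar <- 0
  if (!is.na(config@topNVariance) && config@topNVariance < nrow(E)) {
    vf <- varianceFilter(E, config@topNVariance)
    E <- vf$matrix
    removedVar <- vf$removedVarianceFraction
  }
  D <- if (!is.na(config@dOverride)) config@dOverride
       else estimateNumPcs(E, nPerm = config@nPerm,
                           zThreshold = config@zThreshold,
                           seed = config@seed)
  D <- min(D, nrow(E), ncol(E) - 1L)
  emptyResult <- function() {
    M <- matrix(numeric(0), nrow = 0L, ncol = ncol(E),
                dimnames = list(NULL, colnames(E)))
    new("SigPCAResult", config = config, D = as.integer(D),
        signatures = list(), matrix = M,
        provenance = .provenance(E, collection, config, removedVar, t0))
  }
  if (D == 0L) {
    warning("no component passed the permutation test (D = 0); ",
            "empty result")
    return(emptyResult())
  }
  pca <- fitPca(E, D)
  allRes <- list()
  for (pc in seq_len(D)) {
    for (dir in c(1L, -1L)) {
      ranked <- rankByLoadings(pca, pc, dir)
      res <- enrichRanking(ranked, collection, config, pc = dir * pc)
      if (nrow(res))
        allRes[[length(allRes) + 1L]] <-
          localFilter(res, ranked, config, collection)
    }
  }
  results <- if (length(allRes)) do.call(rbind, allRes) else
    .resultsToFrame(list())
  results <- globalFilter(results, ontology)
  if (!nrow(results)) {
    warning("no gene set enriched at alphaB = ", config@alphaB,
            "; empty result")
    return(emptyResult())
  }
  Estd <- standardizeRows(E)
  sigs <- lapply(seq_len(nrow(results)), function(i)
    buildSignature(results[i, , drop = FALSE], Estd, config, collection))
  ord <- orderSignatures(sigs, "cluster")
  sigs <- sigs[ord]
  M <- do.call(rbind, lapply(sigs, function(s) s@expression))
  rownames(M) <- vapply(sigs, signatureLabel, character(1))
  new("SigPCAResult", config = config, D = as.integer(D),
      signatures = sigs, matrix = M,
      provenance = .provenance(E, collection, config, removedVar, t0))
}

.provenance <- function(E, collection, config, removedVar, t0) {
  list(nGenes = nrow(E), nSamples = ncol(E), nSets = nSets(collection),
       removedVarianceFraction = removedVar, seed = config@seed,
       elapsedSeconds = round(proc.time()[["elapsed"]] - t0, 3),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       version = tryCatch(as.character(utils::packageVersion("sigPCA")),
                          error = function(e) "unversioned"))
}
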