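test_that("loading rankings respect direction and break ties by name", {
  loadings <- matrix(c(0.9, -0.9, 0.1), ncol = 1,
                     dimnames = list(c("a", "b", "c"), NULL))
  pca <- structure(list(loadings = loadings, scores = NULL,
                        varFrac = 1, D = 1L), class = "PcaModel")
  expect_identical(rankByLoadings(pca, 1, 1L), c("a", "c", "b"))
  expect_identical(rankByLoadings(pca, 1, -1L), c("b", "c", "a"))
  expect_error(rankByLoadings(pca, 2, 1L), "pc must be")

  tied <- matrix(c(0.5, 0.5, 0.5), ncol = 1,
                 dimnames = list(c("z", "a", "m"), NULL))
  pcaT <- structure(list(loadings = tied, scores = NULL,
                         varFrac = 1, D = 1L), class = "PcaModel")
  expect_identical(rankByLoadings(pcaT, 1, 1L), c("a", "m", "z"))
})

test_that("ranking enrichment finds planted blocks and screens decoys", {
  cfg <- sigPCAConfig(lRank = 25L)
  ranked <- plantedRanking(200)   # 10 planted genes on top
  coll <- geneSetCollection(list(
    planted = sprintf("p%02d", 1:10),
    absent = sprintf("x%02d", 1:10),          # no gene in the matrix
    small = c("p01", "p02")))                 # K < xMin, not tested
  res <- enrichRanking(ranked, coll, cfg, pc = 1L)
  expect_identical(res$termId, "planted")
  # hypergeometric tail at n = 10 is 1/C(200,10), far below alphaB
  expect_lt(res$pMhg, 1e-6)
  expect_identical(res$kStar, 10L)
  expect_setequal(res$drivingGenes[[1]], sprintf("p%02d", 1:10))

  # a random ranking yields nothing against decoy sets
  set.seed(8)
  genes <- sprintf("g%03d", 1:200)
  decoys <- lapply(1:100, function(i) sample(genes, 15))
  names(decoys) <- sprintf("d%03d", 1:100)
  resNull <- enrichRanking(sample(genes), geneSetCollection(decoys), cfg)
  expect_identical(nrow(resNull), 0L)
})

test_that("the within-ranking filter drops redundant terms only", {
  cfg <- sigPCAConfig(lRank = 25L)
  ranked <- c(sprintf("p%02d", 1:10), sprintf("q%02d", 1:10),
              sprintf("bg%03d", 1:180))
  pset <- sprintf("p%02d", 1:10)
  qset <- sprintf("q%02d", 1:10)
  coll <- geneSetCollection(list(
    termP = pset, dupP = pset, termQ = qset))
  res <- enrichRanking(ranked, coll, cfg, pc = 1L)
  expect_setequal(res$termId, c("termP", "dupP", "termQ"))
  kept <- localFilter(res, ranked, cfg, coll)
  # the duplicated term dies once the first term's genes are removed;
  # the disjoint planted term survives
  expect_identical(sort(kept$termId[kept$termId != "termQ"]),
                   sort(kept$termId)[1])
  expect_true("termQ" %in% kept$termId)
  expect_identical(nrow(kept), 2L)
  # output is a subset preserving the highest-escore element
  top <- res$termId[order(-res$escore, res$pMhg, res$termId)][1]
  expect_true(top %in% kept$termId)

  # single result is always kept
  single <- res[res$termId == "termQ", ]
  expect_identical(localFilter(single, ranked, cfg, coll)$termId, "termQ")
})

test_that("the cross-component filter suppresses related repeats", {
  ont <- chainOntology()
  mk <- function(term, pc, escore = 5) {
    data.frame(termId = term, pc = pc, sMhg = 1e-9, pMhg = 1e-8,
               nStar = 10L, kStar = 6L, K = 10L, N = 100L, X = 3L,
               L = 12L, escore = escore,
               drivingGenes = I(list(letters[1:6])),
               stringsAsFactors = FALSE)
  }
  # same term on two components: the later one is dropped
  out <- globalFilter(rbind(mk("T:C", 1L), mk("T:C", 2L)), ont)
  expect_identical(out$pc, 1L)
  # child on PC1, parent on PC3: parent dropped
  out2 <- globalFilter(rbind(mk("T:C", 1L), mk("T:A", 3L)), ont)
  expect_identical(out2$termId, "T:C")
  # unrelated terms on different components: both kept
  out3 <- globalFilter(rbind(mk("T:C", 1L), mk("DY:1", 2L)), ont)
  expect_identical(nrow(out3), 2L)
  # positive direction processed before negative within a component
  out4 <- globalFilter(rbind(mk("T:C", -1L), mk("T:A", 1L)), ont)
  expect_identical(out4$termId, "T:A")
})

test_that("signature construction follows seed-and-extend with R filtering", {
  samples <- sprintf("s%02d", 1:12)
  base <- c(rep(2, 6), rep(-2, 6)) + seq(-0.1, 0.1, length.out = 12)
  mkE <- function(rows) {
    E <- do.call(rbind, rows)
    dimnames(E) <- list(names(rows), samples)
    E
  }
  set.seed(4)
  rows <- lapply(1:6, function(i) base + rnorm(12, 0, 0.1))
  names(rows) <- sprintf("d%d", 1:6)
  rows$anti <- -base + rnorm(12, 0, 0.1)
  rows$bg <- rnorm(12)
  Estd <- standardizeRows(mkE(rows))

  resRow <- data.frame(termId = "T:S", pc = 1L, sMhg = 1e-9, pMhg = 1e-8,
                       nStar = 8L, kStar = 7L, K = 7L, N = 8L, X = 3L,
                       L = 8L, escore = 1.1, stringsAsFactors = FALSE)
  resRow$drivingGenes <- I(list(c(sprintf("d%d", 1:6), "anti")))
  coll <- geneSetCollection(list("T:S" = c(sprintf("d%d", 1:6), "anti")))

  sig <- buildSignature(resRow, Estd, sigPCAConfig(rCorr = 0.5), coll)
  expect_false("anti" %in% sig@genes)
  expect_setequal(sig@genes, sprintf("d%d", 1:6))
  # unfiltered variant keeps every driving gene
  sigAll <- buildSignature(resRow, Estd, sigPCAConfig(rCorr = -1), coll)
  expect_setequal(sigAll@genes, c(sprintf("d%d", 1:6), "anti"))
  # filtering raises the median within-signature correlation
  medCor <- function(s) {
    cm <- cor(t(Estd[s@genes, , drop = FALSE]))
    median(cm[lower.tri(cm)])
  }
  expect_gt(medCor(sig), medCor(sigAll))
  # profile is the unweighted mean of member standardized rows: mean ~ 0
  expect_lt(abs(mean(sig@expression)), 1e-9)
  expect_equal(unname(sig@expression),
               unname(colMeans(Estd[sig@genes, ])), tolerance = 1e-12)
})

test_that("signature ordering clusters correlated profiles together", {
  samples <- sprintf("s%02d", 1:8)
  a <- sin(1:8); b <- sin(1:8) + 0.01 * cos(1:8); c <- -sin(1:8)
  sigs <- list(fakeSignature("T:1", samples = samples, expr = a),
               fakeSignature("T:2", samples = samples, expr = c),
               fakeSignature("T:3", samples = samples, expr = b))
  expect_identical(orderSignatures(sigs[1]), 1L)
  ord <- orderSignatures(sigs)
  # the correlated pair (1 and 3) must be adjacent leaves
  pos <- match(c(1L, 3L), ord)
  expect_identical(abs(diff(pos)), 1L)
  # pc ordering: by |pc|, direction, then effect size
  sigs2 <- list(fakeSignature("T:1", pc = -1L, samples = samples),
                fakeSignature("T:2", pc = 2L, samples = samples),
                fakeSignature("T:3", pc = 1L, samples = samples))
  expect_identical(orderSignatures(sigs2, "pc"), c(3L, 1L, 2L))
})

test_that("Bonferroni threshold is alpha over the test count", {
  expect_equal(bonferroniThreshold(0.05, 20000), 2.5e-6)
  expect_identical(bonferroniThreshold(0.05, 1), 0.05)
  expect_identical(bonferroniThreshold(1e-6, 1), 1e-6)
})

test_that("the pipeline recovers planted modules deterministically", {
  sim <- simulateDataset(seed = 21, nDecoySets = 200)
  cfg <- sigPCAConfig(seed = 21)
  res <- runSigPCA(sim$expression, sim$collection, sim$ontology, cfg)
  rec <- vapply(signatures(res), function(s) s@termId, character(1))
  expect_setequal(rec, sim$truth$plantedTerms)

  # active samples sit high in the signature profile (standardized units)
  for (s in signatures(res)) {
    act <- sim$truth$activeSamples[[s@termId]]
    rest <- setdiff(names(s@expression), act)
    expect_gt(mean(s@expression[act]), 1.0)
    expect_lt(mean(s@expression[rest]), 0)
  }

  # byte-identical rerun with the same seed
  res2 <- runSigPCA(sim$expression, sim$collection, sim$ontology, cfg)
  expect_identical(signatureMatrix(res2), signatureMatrix(res))
  expect_identical(
    lapply(signatures(res2), function(s) s@genes),
    lapply(signatures(res), function(s) s@genes))

  # signature genes all carry the term's annotation, within k* bounds
  for (s in signatures(res)) {
    expect_true(all(s@genes %in% geneSets(sim$collection)[[s@termId]]))
    expect_lte(length(s@genes), length(s@enrichment$drivingGenes))
    expect_identical(length(s@enrichment$drivingGenes),
                     as.integer(s@enrichment$kStar))
  }
})

test_that("an all-noise matrix yields an empty result with a warning", {
  E <- toyExpression(120, 20, seed = 77)
  coll <- geneSetCollection(list(set1 = sprintf("g%02d", 1:10)))
  cfg <- sigPCAConfig(seed = 77)
  expect_warning(res <- runSigPCA(E, coll, NULL, cfg),
                 "D = 0|empty result")
  expect_length(signatures(res), 0)
  expect_identical(nrow(signatureMatrix(res)), 0L)
})

test_that("testing extra components leaves earlier signatures unchanged", {
  sim <- simulateDataset(seed = 31)
  cfg <- sigPCAConfig(seed = 31)
  res <- runSigPCA(sim$expression, sim$collection, sim$ontology, cfg)
  D <- numComponentsTested(res)
  cfg2 <- sigPCAConfig(seed = 31, dOverride = D + 2L)
  res2 <- runSigPCA(sim$expression, sim$collection, sim$ontology, cfg2)
  key <- function(r, maxPc = Inf) {
    sigs <- Filter(function(s) abs(s@pc) <= maxPc, signatures(r))
    sigs <- sigs[order(vapply(sigs, function(s) s@termId, character(1)))]
    lapply(sigs, function(s) list(s@termId, s@pc, s@genes))
  }
  expect_identical(key(res2, maxPc = D), key(res))
})
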