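test_that("OBO parsing captures terms, edges, alt ids and drops obsoletes", {
  path <- writeObo(list(
    oboTerm("T:P", name = "parent"),
    oboTerm("T:C", name = "child", isA = "T:P", altIds = "T:OLD"),
    oboTerm("T:OBS", name = "gone", obsolete = TRUE)))
  ont <- suppressMessages(parseOBO(path))
  expect_setequal(termIds(ont), c("T:P", "T:C"))
  expect_identical(ont@isA[["T:C"]], "T:P")
  expect_identical(unname(ont@altIds["T:OLD"]), "T:C")
  expect_false("T:OBS" %in% termIds(ont))

  single <- parseOBO(writeObo(list(oboTerm("T:X"))))
  expect_identical(termIds(single), "T:X")
  expect_length(single@isA[["T:X"]], 0)
})

test_that("malformed stanzas and cyclic relations are rejected", {
  bad <- tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: T:1", "name broken line"), bad)
  expect_error(parseOBO(bad), "malformed.*line 3")

  cyc <- writeObo(list(oboTerm("T:A", isA = "T:B"),
                       oboTerm("T:B", isA = "T:A")))
  expect_error(parseOBO(cyc), "cycle")
})

test_that("GAF parsing applies evidence, NOT and duplicate rules", {
  path <- writeGaf(c(
    gafLine("HBB", "T:1", evidence = "IDA"),
    gafLine("HBB", "T:1", evidence = "IDA"),          # duplicate
    gafLine("CA1", "T:1", evidence = "IEA"),          # not curated
    gafLine("CA2", "T:2", evidence = "IMP", qualifier = "NOT"),
    gafLine("RHAG", "T:2", evidence = "TAS")))
  ann <- suppressMessages(parseGAF(path))
  expect_identical(nrow(ann), 2L)
  expect_setequal(ann$gene, c("HBB", "RHAG"))

  ragged <- tempfile()
  writeLines(c("!header", "just\tthree\tcols"), ragged)
  expect_error(parseGAF(ragged), "line 2 has 3 columns")
})

test_that("propagation is transitive and part_of counts only for CC", {
  ann <- data.frame(gene = "g1", termId = "T:C",
                    stringsAsFactors = FALSE)
  sets <- propagateAnnotations(chainOntology(relation = "is_a"), ann)
  expect_setequal(names(sets), c("T:A", "T:B", "T:C"))
  expect_true(all(vapply(sets, function(s) "g1" %in% s, logical(1))))

  # part_of chain: propagates in cellular_component ...
  cc <- propagateAnnotations(
    chainOntology("cellular_component", relation = "part_of"), ann)
  expect_true("g1" %in% cc[["T:A"]])
  # ... but not in biological_process
  bp <- propagateAnnotations(
    chainOntology("biological_process", relation = "part_of"), ann)
  expect_false("T:A" %in% names(bp))
  expect_identical(bp[["T:C"]], "g1")
})

test_that("propagation is monotone and warns on unknown terms", {
  ont <- chainOntology()
  set.seed(42)
  ann <- data.frame(
    gene = sprintf("g%d", sample(20, 30, replace = TRUE)),
    termId = sample(c("T:A", "T:B", "T:C"), 30, replace = TRUE),
    stringsAsFactors = FALSE)
  sets <- propagateAnnotations(ont, ann)
  # every ancestor's set contains each descendant's set
  expect_true(all(sets[["T:C"]] %in% sets[["T:B"]]))
  expect_true(all(sets[["T:B"]] %in% sets[["T:A"]]))

  expect_warning(
    propagateAnnotations(ont, data.frame(gene = "g1", termId = "T:NOPE")),
    "unknown")
})

test_that("size filter bounds are inclusive", {
  mk <- function(n) sprintf("g%03d", seq_len(n))
  coll <- geneSetCollection(list(tiny = mk(4), lo = mk(5),
                                 hi = mk(200), big = mk(201)))
  out <- filterSetsBySize(coll, 5, 200)
  expect_setequal(termIds(out), c("lo", "hi"))
})

test_that("identical-parent collapse removes only direct identical parents", {
  ont <- chainOntology()
  g15 <- sprintf("g%02d", 1:15)
  # parent B identical to child C -> B removed, C kept
  coll <- geneSetCollection(list("T:C" = g15, "T:B" = g15,
                                 "T:A" = c(g15, "extra")))
  out <- collapseRedundantParents(coll, ont)
  expect_setequal(termIds(out), c("T:C", "T:A"))

  # sets differing by one gene are both kept
  coll2 <- geneSetCollection(list("T:C" = g15, "T:B" = c(g15, "extra")))
  expect_setequal(termIds(collapseRedundantParents(coll2, ont)),
                  c("T:C", "T:B"))

  # grandparent A identical to C, but intermediate B differs:
  # A survives (only direct parent/child pairs are compared)
  coll3 <- geneSetCollection(list("T:C" = g15, "T:B" = c(g15, "extra"),
                                  "T:A" = g15))
  expect_setequal(termIds(collapseRedundantParents(coll3, ont)),
                  c("T:C", "T:B", "T:A"))

  # surviving sets are never modified
  expect_identical(geneSets(out)[["T:A"]],
                   sort(c(g15, "extra")))
})

test_that("relatedTerms returns transitive relatives, symmetrically", {
  ont <- chainOntology()
  expect_setequal(relatedTerms(ont, "T:B"), c("T:A", "T:C"))
  expect_error(relatedTerms(ont, "T:NOPE"), "unknown term")

  # diamond: D -> B -> A, D -> C -> A; each ancestor once
  ids <- c("T:A", "T:B", "T:C", "T:D")
  isA <- list("T:A" = character(), "T:B" = "T:A", "T:C" = "T:A",
              "T:D" = c("T:B", "T:C"))
  dia <- new("Ontology",
             terms = data.frame(id = ids, name = ids,
                                namespace = "biological_process"),
             isA = isA[ids],
             partOf = stats::setNames(rep(list(character()), 4), ids),
             altIds = character())
  rel <- relatedTerms(dia, "T:D")
  expect_identical(anyDuplicated(rel), 0L)
  expect_setequal(rel, c("T:A", "T:B", "T:C"))

  # isolated term
  iso <- parseOBO(writeObo(list(oboTerm("T:X"))))
  expect_length(relatedTerms(iso, "T:X"), 0)

  # symmetry over all pairs
  for (a in ids) for (b in ids) {
    expect_identical(b %in% relatedTerms(dia, a),
                     a %in% relatedTerms(dia, b))
  }
})

test_that("gene-set files round-trip, including custom sets", {
  path <- tempfile()
  coll <- geneSetCollection(
    list("T:1" = c("b", "a"), "MY:SET" = c("z", "q", "a")),
    termNames = c("term one", "my custom set"),
    namespaces = c("biological_process", "custom"))
  writeGeneSets(coll, path)
  back <- readGeneSets(path)
  expect_identical(geneSets(back), geneSets(coll))
  expect_identical(back@termMeta, coll@termMeta)

  # empty collection round-trips (header only)
  empty <- geneSetCollection(stats::setNames(list(), character()))
  writeGeneSets(empty, path)
  expect_identical(nSets(readGeneSets(path)), 0L)
  expect_identical(readLines(path), "id\tname\tnamespace\tgenes")

  # hand-written file with an arbitrary set loads
  writeLines(c("id\tname\tnamespace\tgenes",
               "CUSTOM:1\thand made\tcustom\tTP53,MYC,EGFR"), path)
  hand <- readGeneSets(path)
  expect_identical(geneSets(hand)[["CUSTOM:1"]],
                   sort(c("TP53", "MYC", "EGFR")))

  # duplicate ids rejected
  writeLines(c("id\tname\tnamespace\tgenes",
               "X\tx\tcustom\ta", "X\tx\tcustom\tb"), path)
  expect_error(readGeneSets(path), "duplicate")
})

test_that("randomized collections round-trip through the gene-set format", {
  set.seed(7)
  for (i in 1:5) {
    n <- sample(1:8, 1)
    sets <- lapply(seq_len(n), function(j)
      sprintf("gene%03d", sample(500, sample(5:30, 1))))
    names(sets) <- sprintf("R:%04d", sample(9999, n))
    coll <- geneSetCollection(sets)
    path <- tempfile()
    writeGeneSets(coll, path)
    back <- readGeneSets(path)
    expect_identical(geneSets(back), geneSets(coll))
  }
})
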