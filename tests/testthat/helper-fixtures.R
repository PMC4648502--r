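# In-code fixtures shared across test files.

# write an OBO file from stanza fragments; returns the path
writeObo <- function(stanzas, path = tempfile(fileext = ".obo")) {
  writeLines(c("format-version: 1.2", "", unlist(stanzas)), path)
  path
}

oboTerm <- function(id, name = id, namespace = "biological_process",
                    isA = character(), partOf = character(),
                    altIds = character(), obsolete = FALSE) {
  c("[Term]",
    paste0("id: ", id),
    paste0("name: ", name),
    paste0("namespace: ", namespace),
    paste0("is_a: ", isA, " ! parent"),
    paste0("relationship: part_of ", partOf, " ! parent"),
    paste0("alt_id: ", altIds),
    if (obsolete) "is_obsolete: true",
    "")
}

# a 17-column GAF 2.x line
gafLine <- function(gene, term, evidence = "IDA", qualifier = "") {
  fields <- rep("", 17)
  fields[2] <- paste0("DB:", gene)
  fields[3] <- gene
  fields[4] <- qualifier
  fields[5] <- term
  fields[7] <- evidence
  paste(fields, collapse = "\t")
}

writeGaf <- function(lines, path = tempfile(fileext = ".gaf")) {
  writeLines(c("!gaf-version: 2.1", lines), path)
  path
}

# toy chain ontology A <- B <- C (C is_a B is_a A), in-memory
chainOntology <- function(namespace = "biological_process",
                          relation = c("is_a", "part_of")) {
  relation <- match.arg(relation)
  ids <- c("T:A", "T:B", "T:C")
  empty <- stats::setNames(rep(list(character()), 3), ids)
  edges <- empty
  edges[["T:B"]] <- "T:A"
  edges[["T:C"]] <- "T:B"
  new("Ontology",
      terms = data.frame(id = ids, name = ids, namespace = namespace,
                         stringsAsFactors = FALSE),
      isA = if (relation == "is_a") edges else empty,
      partOf = if (relation == "part_of") edges else empty,
      altIds = character())
}

# small deterministic expression matrix with named dims
toyExpression <- function(nGenes = 20, nSamples = 10, seed = 1) {
  set.seed(seed)
  matrix(rnorm(nGenes * nSamples), nGenes, nSamples,
         dimnames = list(sprintf("g%02d", seq_len(nGenes)),
                         sprintf("s%02d", seq_len(nSamples))))
}

# a ranked list with a planted block of annotated genes at the top
plantedRanking <- function(N = 200, topGenes = sprintf("p%02d", 1:10)) {
  c(topGenes, sprintf("bg%03d", seq_len(N - length(topGenes))))
}

# a minimal hand-built Signature (for detection-rate and IO tests)
fakeSignature <- function(termId, pc = 1L, samples = sprintf("s%02d", 1:6),
                          genes = c("gA", "gB"), namespace = "custom",
                          expr = NULL) {
  if (is.null(expr)) {
    expr <- seq_along(samples) - mean(seq_along(samples))
  }
  new("Signature", termId = termId, termName = paste("term", termId),
      namespace = namespace, pc = as.integer(pc), genes = genes,
      expression = stats::setNames(as.numeric(expr), samples),
      enrichment = list(sMhg = 1e-8, pMhg = 1e-7, nStar = 10L, kStar = 5L,
                        escore = 4.0, X = 3L, L = 25L,
                        drivingGenes = genes),
      kTotal = length(genes))
}

fakeResult <- function(sigs, D = 2L, config = sigPCAConfig()) {
  M <- do.call(rbind, lapply(sigs, function(s) s@expression))
  rownames(M) <- vapply(sigs, signatureLabel, character(1))
  new("SigPCAResult", config = config, D = as.integer(D),
      signatures = sigs, matrix = M, provenance = list())
}
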