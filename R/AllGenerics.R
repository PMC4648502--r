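#' @rdname GeneSetCollection-class
#' @param x object
#' @export
setGeneric("termIds", function(x) standardGeneric("termIds"))

#' @rdname GeneSetCollection-class
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname GeneSetCollection-class
#' @export
setGeneric("nSets", function(x) standardGeneric("nSets"))

#' @rdname SigPCAResult-class
#' @param object,x a result
#' @export
setGeneric("signatures", function(x) standardGeneric("signatures"))

#' @rdname SigPCAResult-class
#' @export
setGeneric("signatureMatrix", function(x) standardGeneric("signatureMatrix"))

#' @rdname SigPCAResult-class
#' @export
setGeneric("numComponentsTested", function(x)
  standardGeneric("numComponentsTested"))

#' @describeIn GeneSetCollection-class term ids of an ontology or collection
setMethod("termIds", "Ontology", function(x) x@terms$id)

#' @describeIn GeneSetCollection-class term ids of the sets
setMethod("termIds", "GeneSetCollection", function(x) names(x@sets))

#' @describeIn GeneSetCollection-class the term id -> gene-set mapping
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @describeIn GeneSetCollection-class m, the number of tested sets
setMethod("nSets", "GeneSetCollection", function(x) length(x@sets))

#' @describeIn SigPCAResult-class the list of signatures, in persisted order
setMethod("signatures", "SigPCAResult", function(x) x@signatures)

#' @describeIn SigPCAResult-class the signatures x samples expression matrix
setMethod("signatureMatrix", "SigPCAResult", function(x) x@matrix)

#' @describeIn SigPCAResult-class D, the number of components tested
setMethod("numComponentsTested", "SigPCAResult", function(x) x@D)

setMethod("show", "Ontology", function(object) {
  cat("Ontology with", nrow(object@terms), "terms (",
      sum(lengths(object@isA)), "is_a edges,",
      sum(lengths(object@partOf)), "part_of edges )\n")
})

setMethod("show", "GeneSetCollection", function(object) {
  sz <- lengths(object@sets)
  cat("GeneSetCollection with", length(object@sets), "sets")
  if (length(sz))
    cat("; set sizes", min(sz), "-", max(sz))
  cat("\n")
})

setMethod("show", "SigPCAConfig", function(object) {
  cat("SigPCAConfig: xFrac =", object@xFrac, ", xMin =", object@xMin,
      ", L =", ifelse(is.na(object@lRank), "floor(N/8)", object@lRank),
      ", alphaB =", object@alphaB, ", rCorr =", object@rCorr,
      ", zThreshold =", object@zThreshold, ", nPerm =", object@nPerm,
      ", seed =", object@seed, "\n")
})

setMethod("show", "Signature", function(object) {
  cat(sprintf("Signature %s [pc %d, %d genes, K = %d, p = %.3g]\n",
              signatureLabel(object), object@pc, length(object@genes),
              object@kTotal, object@enrichment$pMhg))
})

setMethod("show", "SigPCAResult", function(object) {
  cat("SigPCAResult:", length(object@signatures), "signatures from",
      object@D, "tested components across", ncol(object@matrix),
      "samples\n")
})

setMethod("show", "BootstrapReport", function(object) {
  cat("BootstrapReport:", length(object@exactRates), "signatures, B =",
      object@B, "replicates, sizes:", paste(object@sizes, collapse = ", "),
      "\n")
})
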