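#' @import methods
NULL

setClassUnion("integerOrNULL", c("integer", "NULL"))

#' Ontology of terms connected by is_a / part_of relations
#'
#' A directed acyclic graph of terms, each with an accession, a human-readable
#' name and a namespace (\code{biological_process}, \code{molecular_function}
#' or \code{cellular_component}).  For terms in the cellular-component
#' namespace, \code{part_of} edges are treated the same as \code{is_a} edges
#' when annotations are propagated and when relatedness is queried.
#'
#' @slot terms data.frame with columns \code{id}, \code{name},
#'   \code{namespace}; one row per non-obsolete term.
#' @slot isA named list; for each term id, the character vector of its
#'   \code{is_a} parent ids.
#' @slot partOf named list; \code{part_of} parent ids per term.
#' @slot altIds named character vector mapping secondary (alt) ids to their
#'   primary term id.
#'
#' @seealso [parseOBO()], [relatedTerms()], [propagateAnnotations()]
#' @export
setClass("Ontology",
  representation(
    terms  = "data.frame",
    isA    = "list",
    partOf = "list",
    altIds = "character"
  )
)

setValidity("Ontology", function(object) {
  msg <- character()
  tm <- object@terms
  if (!all(c("id", "name", "namespace") %in% colnames(tm)))
    msg <- c(msg, "terms must have columns id, name, namespace")
  else {
    if (anyDuplicated(tm$id))
      msg <- c(msg, "duplicate term ids")
    bad <- setdiff(tm$namespace,
                   c("biological_process", "molecular_function",
                     "cellular_component"))
    if (length(bad))
      msg <- c(msg, paste("unknown namespace:", paste(bad, collapse = ", ")))
    ids <- tm$id
    refs <- unique(c(unlist(object@isA, use.names = FALSE),
                     unlist(object@partOf, use.names = FALSE)))
    if (length(setdiff(refs, ids)))
      msg <- c(msg, "relation edges reference unknown terms")
    else if (length(ids) && .hasCycle(ids, object@isA, object@partOf))
      msg <- c(msg, "relation graph contains a cycle")
  }
  if (length(msg)) msg else TRUE
})

# Kahn's algorithm on the union of is_a and part_of edges.
.hasCycle <- function(ids, isA, partOf) {
  parents <- lapply(ids, function(i) unique(c(isA[[i]], partOf[[i]])))
  names(parents) <- ids
  indeg <- lengths(parents)
  children <- new.env(parent = emptyenv())
  for (i in ids) {
    for (p in parents[[i]])
      assign(p, c(get0(p, envir = children, ifnotfound = character()), i),
             envir = children)
  }
  queue <- ids[indeg == 0L]
  seen <- 0L
  indeg <- stats::setNames(indeg, ids)
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    seen <- seen + 1L
    for (ch in get0(v, envir = children, ifnotfound = character())) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  seen < length(ids)
}

#' Collection of gene sets derived from ontology annotations
#'
#' The tested gene sets: a mapping from term id to a set of gene symbols,
#' together with the term name and namespace.  The number of sets, \code{m},
#' is the number of hypotheses tested per ranking and drives the Bonferroni
#' correction.
#'
#' @slot sets named list of character vectors (term id -> gene symbols).
#' @slot termMeta data.frame with columns \code{id}, \code{name},
#'   \code{namespace}, aligned with \code{sets}.
#'
#' @seealso [propagateAnnotations()], [readGeneSets()], [writeGeneSets()]
#' @export
setClass("GeneSetCollection",
  representation(sets = "list", termMeta = "data.frame")
)

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  if (!identical(names(object@sets), object@termMeta$id))
    msg <- c(msg, "names(sets) must equal termMeta$id (same order)")
  if (anyDuplicated(names(object@sets)))
    msg <- c(msg, "duplicate term ids")
  if (length(object@sets) &&
      !all(vapply(object@sets, is.character, logical(1))))
    msg <- c(msg, "every gene set must be a character vector")
  if (length(msg)) msg else TRUE
})

#' Configuration for a signature-discovery run
#'
#' Holds every tunable of the pipeline.  Defaults follow the published
#' method: cutoff constraints X determined per term as
#' \code{max(xMin, ceiling(xFrac * K))} with \code{xFrac = 0.25},
#' \code{xMin = 5}; cutoff rank limit \code{L = floor(N/8)} (the test is run
#' in both ranking directions, hence the two-sided choice); per-test
#' significance threshold \code{alphaB = 1e-6} (a Bonferroni-style fixed
#' threshold, not re-adjusted for the number of components tested);
#' signature-inclusion correlation \code{rCorr = 0.5}; permutation test with
#' \code{nPerm = 15} replicates and z-score threshold 2.0.
#'
#' @slot xFrac numeric fraction in [0, 1].
#' @slot xMin integer >= 1.
#' @slot lRank integer, or NA to use \code{floor(N/8)} at run time.
#' @slot alphaB per-test p-value threshold in (0, 1).
#' @slot rCorr signature inclusion correlation in [-1, 1]; -1 disables the
#'   correlation filter.
#' @slot zThreshold z-score threshold of the permutation test.
#' @slot nPerm number of permutation replicates.
#' @slot dOverride integer, or NA to estimate D by the permutation test.
#' @slot topNVariance integer, or NA to skip the variance filter.
#' @slot seed integer seed controlling all randomness of a run.
#'
#' @seealso [sigPCAConfig()], [runSigPCA()]
#' @export
setClass("SigPCAConfig",
  representation(
    xFrac = "numeric", xMin = "integer", lRank = "integer",
    alphaB = "numeric", rCorr = "numeric", zThreshold = "numeric",
    nPerm = "integer", dOverride = "integer", topNVariance = "integer",
    seed = "integer"
  )
)

setValidity("SigPCAConfig", function(object) {
  msg <- character()
  if (object@xFrac < 0 || object@xFrac > 1)
    msg <- c(msg, "xFrac must be in [0, 1]")
  if (object@xMin < 1L) msg <- c(msg, "xMin must be >= 1")
  if (object@alphaB <= 0 || object@alphaB >= 1)
    msg <- c(msg, "alphaB must be in (0, 1)")
  if (object@rCorr < -1 || object@rCorr > 1)
    msg <- c(msg, "rCorr must be in [-1, 1]")
  if (object@nPerm < 2L) msg <- c(msg, "nPerm must be >= 2")
  if (length(msg)) msg else TRUE
})

#' An expression signature
#'
#' A labeled set of mutually correlated genes generated from one enriched
#' gene set on one principal component, with its per-sample expression
#' profile: the unweighted mean of the standardized expression of the member
#' genes.
#'
#' @slot termId id of the generating gene set.
#' @slot termName human-readable label.
#' @slot namespace ontology namespace of the term (or "custom").
#' @slot pc signed component index; negative means the enrichment was found
#'   among the lowest loadings of component \code{abs(pc)}.
#' @slot genes member genes, ordered by decreasing correlation with the
#'   signature seed.
#' @slot expression named numeric vector, one value per sample.
#' @slot enrichment list with the generating test's \code{sMhg}, \code{pMhg},
#'   \code{nStar}, \code{kStar}, \code{escore}, \code{X}, \code{L} and the
#'   driving genes.
#' @slot kTotal total genes in the analysis annotated with the term.
#'
#' @seealso [buildSignature()], [signatureLabel()]
#' @export
setClass("Signature",
  representation(
    termId = "character", termName = "character", namespace = "character",
    pc = "integer", genes = "character", expression = "numeric",
    enrichment = "list", kTotal = "integer"
  )
)

setValidity("Signature", function(object) {
  msg <- character()
  if (length(object@genes) < 1L) msg <- c(msg, "a signature needs >= 1 gene")
  if (is.null(names(object@expression)))
    msg <- c(msg, "expression must be named by sample")
  if (length(msg)) msg else TRUE
})

#' Result of a signature-discovery run
#'
#' @slot config the \linkS4class{SigPCAConfig} used.
#' @slot D number of principal components tested.
#' @slot signatures list of \linkS4class{Signature}, in persisted (clustered)
#'   order.
#' @slot matrix signatures x samples expression matrix, rows in the same
#'   order as \code{signatures}.
#' @slot provenance list: input dimensions, gene-set count, timings, seed.
#'
#' @seealso [runSigPCA()], [signatureMatrix()], [writeResult()]
#' @export
setClass("SigPCAResult",
  representation(
    config = "SigPCAConfig", D = "integer", signatures = "list",
    matrix = "matrix", provenance = "list"
  )
)

setValidity("SigPCAResult", function(object) {
  msg <- character()
  if (nrow(object@matrix) != length(object@signatures))
    msg <- c(msg, "matrix rows must match the number of signatures")
  if (length(msg)) msg else TRUE
})

#' Bootstrap robustness report
#'
#' Per-signature detection rates across bootstrap replicates: exact (same
#' term) and related (same term or any transitive ancestor/descendant), plus
#' detection as a function of the PC prefix used and of the resample size.
#'
#' @slot exactRates named numeric in [0, 1], one entry per original signature.
#' @slot relatedRates named numeric in [0, 1].
#' @slot pcPrefix signatures x prefix-size detection-rate matrix (full-size
#'   replicates only).
#' @slot sampleSize signatures x resample-size detection-rate matrix
#'   (related matching).
#' @slot B replicates per size.
#' @slot sizes resample sizes (numbers of samples).
#' @slot runsMeta data.frame: one row per replicate with size, D and
#'   signature count.
#' @export
setClass("BootstrapReport",
  representation(
    exactRates = "numeric", relatedRates = "numeric",
    pcPrefix = "matrix", sampleSize = "matrix",
    B = "integer", sizes = "integer", runsMeta = "data.frame"
  )
)

setValidity("BootstrapReport", function(object) {
  msg <- character()
  if (any(object@relatedRates < object@exactRates - 1e-12))
    msg <- c(msg, "relatedRates must dominate exactRates")
  rates <- c(object@exactRates, object@relatedRates)
  if (length(rates) && (any(rates < 0) || any(rates > 1)))
    msg <- c(msg, "rates must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
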