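#' Simulate an expression matrix with planted annotated modules
#'
#' Generates the study conditions the pipeline is designed for: blocks of
#' mutually correlated genes overexpressed in subsets of samples, embedded
#' in i.i.d. Gaussian noise, with matching gene-set annotations, decoy sets
#' of random genes, and a miniature DAG ontology linking each planted term
#' to a parent term (so relatedness queries are exercised).  Each module's
#' genes receive an additive shift of \code{effect} noise-sd units in that
#' module's active samples; active sample blocks are assigned contiguously
#' and disjointly in module order (wrapping around if the fractions exceed
#' 1).  All randomness derives from \code{seed}.
#'
#' @param nGenes,nSamples matrix dimensions (defaults 800 x 60).
#' @param modules data.frame (or list coercible to one) with columns
#'   \code{size}, \code{sampleFraction}, \code{effect}; one row per planted
#'   module.  Default: three disjoint 40-gene modules, each active in 30%
#'   of samples with effect 3.
#' @param nDecoySets number of random decoy gene sets (default 500), with
#'   sizes drawn uniformly from 5..50.
#' @param noiseSd standard deviation of the background noise (default 1).
#' @param contamination fraction of extra random (non-module) genes added
#'   to each planted term's annotation (default 0).
#' @param seed integer seed.
#' @return list with \code{expression} (genes x samples matrix),
#'   \code{collection} (planted + decoy sets), \code{ontology} (toy DAG with
#'   one parent per planted term) and \code{truth} (planted term ids, module
#'   genes, active samples, effects, noiseSd, seed).
#' @export
simulateDataset <- function(nGenes = 800L, nSamples = 60L,
                            modules = data.frame(size = rep(40L, 3),
                                                 sampleFraction = rep(0.3, 3),
                                                 effect = rep(3, 3)),
                            nDecoySets = 500L, noiseSd = 1,
                            contamination = 0, seed = 0L) {
  modules <- as.data.frame(modules)
  stopifnot(all(c("size", "sampleFraction", "effect") %in% colnames(modules)),
            all(modules$effect >= 0), all(modules$size >= 1),
            nSamples >= 2L)
  if (sum(modules$size) > nGenes)
    stop("module sizes exceed nGenes")
  nMod <- nrow(modules)
  genes <- sprintf("G%05d", seq_len(nGenes))
  samples <- sprintf("S%03d", seq_len(nSamples))

  .withSeed(seed, {
    E <- matrix(stats::rnorm(nGenes * nSamples, 0, noiseSd),
                nrow = nGenes, dimnames = list(genes, samples))
    modGenes <- list(); active <- list()
    pool <- sample(genes)          # random disjoint gene blocks
    offset <- 0L
    sampleCursor <- 0L
    plantedIds <- sprintf("PT:%07d", seq_len(nMod))
    for (i in seq_len(nMod)) {
      g <- pool[offset + seq_len(modules$size[i])]
      offset <- offset + modules$size[i]
      nAct <- max(1L, round(modules$sampleFraction[i] * nSamples))
      idx <- ((sampleCursor + seq_len(nAct) - 1L) %% nSamples) + 1L
      sampleCursor <- sampleCursor + nAct
      E[g, idx] <- E[g, idx] + modules$effect[i]
      modGenes[[plantedIds[i]]] <- sort(g)
      active[[plantedIds[i]]] <- samples[idx]
    }
    plantedSets <- modGenes
    if (contamination > 0) {
      for (id in plantedIds) {
        nExtra <- ceiling(contamination * length(plantedSets[[id]]))
        extra <- sample(setdiff(genes, plantedSets[[id]]), nExtra)
        plantedSets[[id]] <- sort(c(plantedSets[[id]], extra))
      }
    }
    decoyIds <- if (nDecoySets > 0) sprintf("DY:%07d", seq_len(nDecoySets))
                else character()
    decoySets <- lapply(seq_len(nDecoySets), function(i)
      sort(sample(genes, sample(5:50, 1L))))
    names(decoySets) <- decoyIds

    sets <- c(plantedSets, decoySets)
    collection <- geneSetCollection(
      sets,
      termNames = c(sprintf("planted module %d", seq_len(nMod)),
                    sprintf("decoy set %d", seq_len(nDecoySets))),
      namespaces = rep("biological_process", length(sets)))

    parentIds <- sprintf("PT:%07d", 1000000L + seq_len(nMod))
    allIds <- c(plantedIds, decoyIds, parentIds)
    isA <- c(stats::setNames(as.list(parentIds), plantedIds),
             stats::setNames(rep(list(character()),
                                 length(decoyIds) + nMod),
                             c(decoyIds, parentIds)))
    ontology <- new("Ontology",
      terms = data.frame(
        id = allIds,
        name = c(sprintf("planted module %d", seq_len(nMod)),
                 sprintf("decoy set %d", seq_len(nDecoySets)),
                 sprintf("parent of planted module %d", seq_len(nMod))),
        namespace = "biological_process", stringsAsFactors = FALSE),
      isA = isA[allIds],
      partOf = stats::setNames(rep(list(character()), length(allIds)),
                               allIds),
      altIds = character())

    list(expression = E, collection = collection, ontology = ontology,
         truth = list(plantedTerms = plantedIds, moduleGenes = modGenes,
                      activeSamples = active,
                      effectSize = stats::setNames(modules$effect,
                                                   plantedIds),
                      noiseSd = noiseSd, seed = seed))
  })
}

#' Simulate a ranked binary list
#'
#' Unit-test feeder for the enrichment machinery: K annotated genes among N
#' ranks, placed as a top block, a bottom block, or uniformly at random.
#'
#' @param N list length.
#' @param K number of annotated entries.
#' @param arrangement "top_block", "bottom_block" or "random".
#' @param seed integer seed (used for "random").
#' @return integer vector of 0/1 of length N.
#' @export
simulateRankedList <- function(N, K,
                               arrangement = c("top_block", "random",
                                               "bottom_block"),
                               seed = 0L) {
  arrangement <- match.arg(arrangement)
  stopifnot(K >= 0L, K <= N)
  v <- integer(N)
  pos <- switch(arrangement,
    top_block = seq_len(K),
    bottom_block = if (K > 0) (N - K + 1L):N else integer(),
    random = .withSeed(seed, sample(N, K)))
  v[pos] <- 1L
  v
}
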