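#' Resample samples with replacement
#'
#' Draws \code{size} columns i.i.d. uniformly with replacement; gene rows
#' are untouched.  Repeated sample names are disambiguated with a numeric
#' suffix so the result is a valid expression matrix.
#'
#' @param E genes x samples numeric matrix with dimnames.
#' @param size number of columns to draw (>= 2, since a 1-sample matrix
#'   cannot be standardized).
#' @param seed integer seed; deterministic given it.
#' @return genes x size matrix.
#' @export
resampleSamples <- function(E, size, seed = 0L) {
  .checkExpression(E)
  if (size < 2L) stop("resample size must be >= 2")
  idx <- .withSeed(seed, sample(ncol(E), size, replace = TRUE))
  out <- E[, idx, drop = FALSE]
  colnames(out) <- make.unique(colnames(E)[idx])
  out
}

#' Bootstrap replicate runs of the pipeline
#'
#' For each requested resample size, draws \code{B} bootstrap datasets and
#' applies the full pipeline to each with the same configuration as the
#' original analysis.  Sizes are given as fractions of the sample count and
#' rounded half-up (minimum 2).  Replicate seeds are derived as
#' \code{config@seed + replicate index} (counting across sizes), so any
#' single replicate can be reproduced in isolation.  A replicate whose run
#' fails is recorded and excluded from detection rates.
#'
#' @param E genes x samples numeric matrix with dimnames.
#' @param collection a \linkS4class{GeneSetCollection}.
#' @param ontology an \linkS4class{Ontology} or NULL.
#' @param config a \linkS4class{SigPCAConfig}.
#' @param B replicates per size (default 50).
#' @param sizeFractions numeric vector of resample sizes as fractions of
#'   \code{ncol(E)} (default 1: full size).
#' @return list of class \code{"BootstrapRuns"}: \code{runs} (list per
#'   size of lists of \linkS4class{SigPCAResult} or NULL for failures),
#'   \code{sizes}, \code{B} and \code{meta} (data.frame: size, replicate,
#'   seed, D, nSignatures, failed).
#' @export
bootstrapSigPCA <- function(E, collection, ontology = NULL,
                            config = sigPCAConfig(), B = 50L,
                            sizeFractions = 1.0) {
  .checkExpression(E)
  sizes <- vapply(sizeFractions, function(f)
    max(2L, as.integer(floor(f * ncol(E) + 0.5))), integer(1))
  runs <- vector("list", length(sizes))
  names(runs) <- as.character(sizes)
  meta <- list()
  rep_i <- 0L
  for (si in seq_along(sizes)) {
    runs[[si]] <- vector("list", B)
    for (b in seq_len(B)) {
      rep_i <- rep_i + 1L
      seed_b <- config@seed + rep_i
      Eb <- resampleSamples(E, sizes[si], seed = seed_b)
      cfg_b <- config
      cfg_b@seed <- as.integer(seed_b)
      res <- tryCatch(
        suppressWarnings(runSigPCA(Eb, collection, ontology, cfg_b)),
        error = function(e) {
          message("bootstrap replicate ", rep_i, " (size ", sizes[si],
                  ") failed: ", conditionMessage(e))
          NULL
        })
      runs[[si]][[b]] <- res
      meta[[rep_i]] <- data.frame(
        size = sizes[si], replicate = b, seed = seed_b,
        D = if (is.null(res)) NA_integer_ else res@D,
        nSignatures = if (is.null(res)) NA_integer_
                      else length(signatures(res)),
        failed = is.null(res))
    }
  }
  structure(list(runs = runs, sizes = sizes, B = as.integer(B),
                 meta = do.call(rbind, meta)),
            class = "BootstrapRuns")
}

.runTermIds <- function(run) {
  vapply(signatures(run), function(s) s@termId, character(1))
}

.matchesRun <- function(termId, ontology, run, mode, maxPc = Inf) {
  ids <- .runTermIds(run)
  if (is.finite(maxPc)) {
    pcs <- abs(vapply(signatures(run), function(s) s@pc, integer(1)))
    ids <- ids[pcs <= maxPc]
  }
  if (!length(ids)) return(FALSE)
  if (termId %in% ids) return(TRUE)
  if (mode == "related" && !is.null(ontology) &&
      termId %in% ontology@terms$id)
    return(any(relatedTerms(ontology, termId) %in% ids))
  FALSE
}

#' Per-signature bootstrap detection rates
#'
#' A signature counts as detected in a replicate if the replicate produced a
#' signature based on the exact same term (\code{mode = "exact"}) or on the
#' same term or any transitive ancestor/descendant (\code{mode =
#' "related"}).  The component index is ignored when matching: a signature
#' rediscovered on a different component still counts.
#'
#' @param original the \linkS4class{SigPCAResult} of the original analysis.
#' @param runs list of \linkS4class{SigPCAResult}s (failed replicates as
#'   NULL are skipped).
#' @param ontology an \linkS4class{Ontology} or NULL.
#' @param mode "exact" or "related".
#' @return named numeric vector of rates in [0, 1] (names: signature
#'   labels).
#' @export
detectionRates <- function(original, runs, ontology = NULL,
                           mode = c("exact", "related")) {
  mode <- match.arg(mode)
  runs <- Filter(Negate(is.null), runs)
  if (!length(runs)) stop("no successful bootstrap runs")
  sigs <- signatures(original)
  rates <- vapply(sigs, function(s)
    mean(vapply(runs, function(r)
      .matchesRun(s@termId, ontology, r, mode), logical(1))), numeric(1))
  stats::setNames(rates, vapply(sigs, signatureLabel, character(1)))
}

#' Detection rate as a function of the component prefix
#'
#' Cell (s, n) is the detection rate of original signature s when only
#' replicate signatures generated from the first n components are counted.
#' Rows are non-decreasing in n and the last column equals the overall rate.
#'
#' @inheritParams detectionRates
#' @param maxPc largest prefix size; defaults to the largest D over runs.
#' @return signatures x prefix-size matrix of rates.
#' @export
pcPrefixDetection <- function(original, runs, ontology = NULL,
                              mode = c("exact", "related"),
                              maxPc = NULL) {
  mode <- match.arg(mode)
  runs <- Filter(Negate(is.null), runs)
  if (!length(runs)) stop("no successful bootstrap runs")
  if (is.null(maxPc))
    maxPc <- max(1L, vapply(runs, function(r) r@D, integer(1)))
  sigs <- signatures(original)
  M <- matrix(0, nrow = length(sigs), ncol = maxPc,
              dimnames = list(vapply(sigs, signatureLabel, character(1)),
                              seq_len(maxPc)))
  for (i in seq_along(sigs)) {
    for (n in seq_len(maxPc)) {
      M[i, n] <- mean(vapply(runs, function(r)
        .matchesRun(sigs[[i]]@termId, ontology, r, mode, maxPc = n),
        logical(1)))
    }
  }
  M
}

#' Assemble a bootstrap robustness report
#'
#' Exact and related detection rates and the component-prefix matrix are
#' computed from the replicates at the largest resample size; the
#' sample-size matrix (related matching) spans all sizes.
#'
#' @param original the original \linkS4class{SigPCAResult}.
#' @param boot a \code{"BootstrapRuns"} object from [bootstrapSigPCA()].
#' @param ontology an \linkS4class{Ontology} or NULL.
#' @return a \linkS4class{BootstrapReport}.
#' @export
detectionReport <- function(original, boot, ontology = NULL) {
  stopifnot(inherits(boot, "BootstrapRuns"))
  fullIdx <- which.max(boot$sizes)
  fullRuns <- boot$runs[[fullIdx]]
  exact <- detectionRates(original, fullRuns, ontology, "exact")
  related <- detectionRates(original, fullRuns, ontology, "related")
  prefix <- pcPrefixDetection(original, fullRuns, ontology, "exact")
  sigs <- signatures(original)
  bySize <- matrix(
    0, nrow = length(sigs), ncol = length(boot$sizes),
    dimnames = list(vapply(sigs, signatureLabel, character(1)),
                    as.character(boot$sizes)))
  for (si in seq_along(boot$sizes)) {
    ok <- Filter(Negate(is.null), boot$runs[[si]])
    if (length(ok) && length(sigs))
      bySize[, si] <- detectionRates(original, ok, ontology, "related")
  }
  new("BootstrapReport", exactRates = exact, relatedRates = related,
      pcPrefix = prefix, sampleSize = bySize, B = boot$B,
      sizes = as.integer(boot$sizes), runsMeta = boot$meta)
}
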