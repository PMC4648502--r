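# run code with a private RNG stream; the caller's .Random.seed survives
.withSeed <- function(seed, code) {
  hasSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hasSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hasSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.checkExpression <- function(E) {
  if (!is.matrix(E) || !is.numeric(E))
    stop("expression data must be a numeric matrix")
  if (is.null(rownames(E)) || is.null(colnames(E)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(E)))
    stop("duplicate gene names: ",
         paste(unique(rownames(E)[duplicated(rownames(E))])[1:3],
               collapse = ", "))
  if (nrow(E) < 2L || ncol(E) < 2L)
    stop("expression matrix needs >= 2 genes and >= 2 samples")
  if (!all(is.finite(E)))
    stop("expression matrix contains non-finite values")
  invisible(E)
}

#' Standardize expression per gene
#'
#' Centers and scales every gene (row) to mean 0 and sample standard
#' deviation 1 (denominator n - 1) across samples.  Standardized values are
#' what signature expression profiles average, so that genes contribute on a
#' common scale regardless of their dynamic range.
#'
#' @param E genes x samples numeric matrix with dimnames.
#' @return matrix of the same shape.
#' @export
standardizeRows <- function(E) {
  .checkExpression(E)
  mu <- rowMeans(E)
  sdev <- apply(E, 1L, stats::sd)
  zero <- sdev == 0
  if (any(zero))
    stop("zero-variance gene(s): ",
         paste(rownames(E)[zero][1:min(3L, sum(zero))], collapse = ", "),
         "; apply a variance filter first")
  (E - mu) / sdev
}

#' Keep the most variable genes
#'
#' Retains the \code{topN} genes with largest per-gene variance and reports
#' the fraction of total variance removed.  Restricting the analysis to
#' variable genes avoids biasing enrichment toward gene sets overrepresented
#' among unexpressed genes.  Ties at the boundary are broken by gene name
#' (lexicographically smaller names kept), so the filter is stable.
#'
#' @param E genes x samples numeric matrix with dimnames.
#' @param topN number of genes to keep.
#' @return list with \code{matrix} (the filtered matrix, original row order
#'   preserved) and \code{removedVarianceFraction}.
#' @export
varianceFilter <- function(E, topN) {
  .checkExpression(E)
  stopifnot(topN >= 1L, topN <= nrow(E))
  v <- apply(E, 1L, stats::var)
  ord <- order(-v, rownames(E))
  keep <- sort(ord[seq_len(topN)])
  list(matrix = E[keep, , drop = FALSE],
       removedVarianceFraction = 1 - sum(v[keep]) / sum(v))
}

# fraction of variance per component: squared singular values of the
# column-centered samples x genes matrix, normalized
.varianceFractions <- function(E) {
  X <- scale(t(E), center = TRUE, scale = FALSE)
  d <- svd(X, nu = 0L, nv = 0L)$d
  d^2 / sum(d^2)
}

#' Principal component analysis of an expression matrix
#'
#' Genes are the variables and samples the observations: each gene is
#' centered across samples (not rescaled) and the decomposition is computed
#' by \code{stats::prcomp}.  Component signs are canonicalized so that the
#' loading of largest magnitude is positive, making results reproducible
#' across runs and platforms.
#'
#' @param E genes x samples numeric matrix with dimnames.
#' @param nComponents number of components to retain; at most
#'   \code{min(nrow(E), ncol(E) - 1)}.
#' @return list of class \code{"PcaModel"}: \code{loadings} (genes x D,
#'   unit-norm columns), \code{scores} (samples x D), \code{varFrac}
#'   (fraction of total variance per retained component, non-increasing)
#'   and \code{D}.
#' @export
fitPca <- function(E, nComponents) {
  .checkExpression(E)
  maxD <- min(nrow(E), ncol(E) - 1L)
  if (nComponents < 1L || nComponents > maxD)
    stop("nComponents must be in 1..", maxD)
  pc <- stats::prcomp(t(E), center = TRUE, scale. = FALSE)
  varFrac <- pc$sdev^2 / sum(pc$sdev^2)
  D <- as.integer(nComponents)
  loadings <- pc$rotation[, seq_len(D), drop = FALSE]
  scores <- pc$x[, seq_len(D), drop = FALSE]
  for (j in seq_len(D)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(loadings = loadings, scores = scores,
                 varFrac = varFrac[seq_len(D)], D = D),
            class = "PcaModel")
}

#' Number of components to test, by permutation
#'
#' Breaks the correlation structure of the data by permuting every gene's
#' values independently across samples, fits a PCA to each permuted matrix
#' and records the fraction of variance explained by its first component.
#' Repeating this \code{nPerm} times yields a null mean and sample standard
#' deviation, from which a z-score is computed for every real component's
#' variance fraction.  D is the length of the initial run of components
#' with \code{z >= zThreshold}: components are retained as a prefix because
#' they are consumed in order of variance explained.  Using the first
#' permuted component as the reference for all real components is
#' conservative for later components.
#'
#' @param E genes x samples numeric matrix with dimnames.
#' @param nPerm number of permutation replicates (default 15).
#' @param zThreshold z-score a component must reach (default 2.0).
#' @param seed integer seed; the function is deterministic given it.
#' @return integer D >= 0.
#' @export
estimateNumPcs <- function(E, nPerm = 15L, zThreshold = 2.0, seed = 0L) {
  .checkExpression(E)
  stopifnot(nPerm >= 2L)
  nullFrac <- .withSeed(seed, {
    vapply(seq_len(nPerm), function(b) {
      Eperm <- t(apply(E, 1L, sample))
      .varianceFractions(Eperm)[1L]
    }, numeric(1))
  })
  mu <- mean(nullFrac)
  sigma <- stats::sd(nullFrac)
  if (sigma == 0)
    stop("degenerate permutation distribution (sd = 0)")
  real <- .varianceFractions(E)
  real <- real[seq_len(min(length(real), nrow(E), ncol(E) - 1L))]
  z <- (real - mu) / sigma
  pass <- z >= zThreshold
  D <- if (!length(pass) || !pass[1L]) 0L else {
    runs <- rle(pass)
    as.integer(runs$lengths[1L])
  }
  if (any(pass[-seq_len(D)]))
    warning("non-prefix component(s) also exceed the z threshold; ",
            "only the initial run of ", D, " is retained")
  D
}
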