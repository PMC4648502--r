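#' Read a tab-delimited expression matrix
#'
#' First column gene names, header row sample names (the first header field
#' is a placeholder such as "gene").  Ragged rows, non-numeric cells and
#' duplicate sample names are errors with the offending location.  Duplicate
#' gene names are an error by default; \code{duplicatePolicy =
#' "keep-max-mean"} instead keeps, per duplicated name, the row with highest
#' mean expression (the usual rule when several probesets map to one gene).
#' Missing values are an error by default; \code{naAction =
#' "impute-gene-median"} replaces them with the gene's median.
#'
#' @param path input file.
#' @param duplicatePolicy "error" or "keep-max-mean".
#' @param naAction "error" or "impute-gene-median".
#' @return genes x samples numeric matrix.
#' @export
readExpressionMatrix <- function(path,
                                 duplicatePolicy = c("error",
                                                     "keep-max-mean"),
                                 naAction = c("error",
                                              "impute-gene-median")) {
  duplicatePolicy <- match.arg(duplicatePolicy)
  naAction <- match.arg(naAction)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stop("expression file needs a header and at least one gene row: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != nf[1L]))
    stop("ragged expression file: line ", which(nf != nf[1L])[1L],
         " has ", nf[nf != nf[1L]][1L], " fields, expected ", nf[1L])
  samples <- fields[[1L]][-1L]
  if (anyDuplicated(samples))
    stop("duplicate sample names: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  geneNames <- vapply(fields[-1L], `[[`, character(1), 1L)
  vals <- lapply(fields[-1L], function(f) suppressWarnings(as.numeric(f[-1L])))
  E <- do.call(rbind, vals)
  rawNA <- do.call(rbind, lapply(fields[-1L], function(f)
    toupper(f[-1L]) %in% c("NA", "NAN", "")))
  bad <- is.na(E) & !rawNA
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop("non-numeric value at gene '", geneNames[w[1L]], "', sample '",
         samples[w[2L]], "'")
  }
  if (any(is.na(E))) {
    if (naAction == "error") {
      w <- which(is.na(E), arr.ind = TRUE)[1L, ]
      stop("missing value at gene '", geneNames[w[1L]], "', sample '",
           samples[w[2L]], "'")
    }
    for (i in which(rowSums(is.na(E)) > 0L)) {
      E[i, is.na(E[i, ])] <- stats::median(E[i, ], na.rm = TRUE)
    }
  }
  if (anyDuplicated(geneNames)) {
    if (duplicatePolicy == "error")
      stop("duplicate gene name(s): ",
           paste(unique(geneNames[duplicated(geneNames)])[1:3],
                 collapse = ", "))
    means <- rowMeans(E)
    keep <- !logical(length(geneNames))
    for (g in unique(geneNames[duplicated(geneNames)])) {
      idx <- which(geneNames == g)
      keep[setdiff(idx, idx[which.max(means[idx])])] <- FALSE
    }
    E <- E[keep, , drop = FALSE]
    geneNames <- geneNames[keep]
  }
  dimnames(E) <- list(geneNames, samples)
  E
}

#' Write a tab-delimited expression matrix
#'
#' @param E genes x samples numeric matrix with dimnames.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeExpressionMatrix <- function(E, path) {
  .checkExpression(E)
  header <- paste(c("gene", colnames(E)), collapse = "\t")
  body <- vapply(seq_len(nrow(E)), function(i)
    paste(c(rownames(E)[i], formatC(E[i, ], format = "g", digits = 10)),
          collapse = "\t"), character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write the signature matrix as TSV
#'
#' Rows in the persisted (clustered) order, labeled as
#' \code{"NS: name (pc, n, K)"} (see [signatureLabel()]); values to six
#' significant digits.
#'
#' @param result a \linkS4class{SigPCAResult} with at least one signature.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeSignatureMatrix <- function(result, path) {
  M <- signatureMatrix(result)
  if (nrow(M) < 1L) stop("result has no signatures")
  header <- paste(c("signature", colnames(M)), collapse = "\t")
  body <- vapply(seq_len(nrow(M)), function(i)
    paste(c(rownames(M)[i], formatC(M[i, ], format = "g", digits = 6)),
          collapse = "\t"), character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a labeled numeric matrix written by this package
#'
#' @param path a TSV with one label column and a header row.
#' @return numeric matrix with dimnames.
#' @export
readMatrixTsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  M <- as.matrix(df[, -1L, drop = FALSE])
  rownames(M) <- df[[1L]]
  M
}

#' Serialize / load a result directory
#'
#' Writes three plain-text artifacts: \code{signatures.tsv} (one row per
#' signature: label, term id, pc, gene counts, test statistics, member
#' genes), \code{signature_matrix.tsv} and \code{config.json} (resolved
#' configuration plus provenance).  \code{readResult} reconstructs the
#' \linkS4class{SigPCAResult} from such a directory (expression profiles at
#' the file format's 6-significant-digit precision).
#'
#' @param result a \linkS4class{SigPCAResult}.
#' @param dir output directory (created if needed).
#' @return \code{dir} (or the result, for \code{readResult}), invisibly.
#' @export
writeResult <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sigs <- signatures(result)
  tab <- data.frame(
    label = vapply(sigs, signatureLabel, character(1)),
    termId = vapply(sigs, function(s) s@termId, character(1)),
    termName = vapply(sigs, function(s) s@termName, character(1)),
    namespace = vapply(sigs, function(s) s@namespace, character(1)),
    pc = vapply(sigs, function(s) s@pc, integer(1)),
    nGenes = vapply(sigs, function(s) length(s@genes), integer(1)),
    K = vapply(sigs, function(s) s@kTotal, integer(1)),
    pMhg = vapply(sigs, function(s) s@enrichment$pMhg, numeric(1)),
    sMhg = vapply(sigs, function(s) s@enrichment$sMhg, numeric(1)),
    escore = vapply(sigs, function(s) s@enrichment$escore, numeric(1)),
    nStar = vapply(sigs, function(s) as.integer(s@enrichment$nStar),
                   integer(1)),
    kStar = vapply(sigs, function(s) as.integer(s@enrichment$kStar),
                   integer(1)),
    X = vapply(sigs, function(s) as.integer(s@enrichment$X), integer(1)),
    L = vapply(sigs, function(s) as.integer(s@enrichment$L), integer(1)),
    genes = vapply(sigs, function(s) paste(s@genes, collapse = ","),
                   character(1)),
    drivingGenes = vapply(sigs, function(s)
      paste(s@enrichment$drivingGenes, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(tab, file.path(dir, "signatures.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (length(sigs))
    writeSignatureMatrix(result, file.path(dir, "signature_matrix.tsv"))
  cfg <- result@config
  jsonlite::write_json(
    list(config = list(xFrac = cfg@xFrac, xMin = cfg@xMin,
                       lRank = cfg@lRank, alphaB = cfg@alphaB,
                       rCorr = cfg@rCorr, zThreshold = cfg@zThreshold,
                       nPerm = cfg@nPerm, dOverride = cfg@dOverride,
                       topNVariance = cfg@topNVariance, seed = cfg@seed),
         D = result@D, provenance = result@provenance),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA,
    null = "null", na = "null")
  invisible(dir)
}

#' @rdname writeResult
#' @export
readResult <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
  asIntNA <- function(x) if (is.null(x) || is.na(x)) NA_integer_
                         else as.integer(x)
  cfg <- sigPCAConfig(xFrac = meta$config$xFrac,
                      xMin = meta$config$xMin,
                      lRank = asIntNA(meta$config$lRank),
                      alphaB = meta$config$alphaB,
                      rCorr = meta$config$rCorr,
                      zThreshold = meta$config$zThreshold,
                      nPerm = meta$config$nPerm,
                      dOverride = asIntNA(meta$config$dOverride),
                      topNVariance = asIntNA(meta$config$topNVariance),
                      seed = meta$config$seed)
  tab <- utils::read.delim(file.path(dir, "signatures.tsv"),
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = c(termId = "character"))
  sigs <- list()
  if (nrow(tab)) {
    M <- readMatrixTsv(file.path(dir, "signature_matrix.tsv"))
    sigs <- lapply(seq_len(nrow(tab)), function(i) {
      new("Signature",
          termId = tab$termId[i], termName = tab$termName[i],
          namespace = tab$namespace[i], pc = as.integer(tab$pc[i]),
          genes = strsplit(tab$genes[i], ",", fixed = TRUE)[[1L]],
          expression = stats::setNames(M[i, ], colnames(M)),
          enrichment = list(sMhg = tab$sMhg[i], pMhg = tab$pMhg[i],
                            nStar = as.integer(tab$nStar[i]),
                            kStar = as.integer(tab$kStar[i]),
                            escore = tab$escore[i],
                            X = as.integer(tab$X[i]),
                            L = as.integer(tab$L[i]),
                            drivingGenes = strsplit(tab$drivingGenes[i],
                                                    ",", fixed = TRUE)[[1L]]),
          kTotal = as.integer(tab$K[i]))
    })
  }
  M <- if (length(sigs))
    do.call(rbind, lapply(sigs, function(s) s@expression))
  else matrix(numeric(0), nrow = 0L, ncol = 0L)
  if (length(sigs))
    rownames(M) <- tab$label
  new("SigPCAResult", config = cfg, D = as.integer(meta$D),
      signatures = sigs, matrix = M,
      provenance = as.list(meta$provenance))
}

#' Association between signatures and known sample groups
#'
#' For each signature, computes the per-group median expression, then
#' compares the two groups with highest and second-highest median by a
#' two-sided rank-sum (Mann-Whitney U) test: exact enumeration when the two
#' groups together hold at most 12 samples and there are no ties, otherwise
#' the normal approximation with continuity and tie correction.  P-values
#' are assessed against a Bonferroni-corrected threshold over the number of
#' signatures at familywise level \code{alpha}.
#'
#' @param result a \linkS4class{SigPCAResult}.
#' @param groups character/factor vector of group labels, named by sample
#'   or in \code{colnames(signatureMatrix(result))} order.  Groups with
#'   fewer than 2 samples are excluded with a warning.
#' @param alpha familywise significance level (default 0.05).
#' @return data.frame with one row per signature: label, best and
#'   second-best group, their medians, the raw p-value and whether it passes
#'   the corrected threshold.
#' @export
signatureGroupAssociation <- function(result, groups, alpha = 0.05) {
  M <- signatureMatrix(result)
  if (nrow(M) < 1L) stop("result has no signatures")
  groups <- as.character(groups)
  if (!is.null(names(groups))) {
    if (!all(colnames(M) %in% names(groups)))
      stop("groups must cover every sample")
    groups <- groups[colnames(M)]
  } else if (length(groups) != ncol(M)) {
    stop("need one group label per sample")
  }
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warning("excluding group(s) with < 2 samples: ",
            paste(small, collapse = ", "))
    keep <- !(groups %in% small)
    M <- M[, keep, drop = FALSE]
    groups <- groups[keep]
  }
  if (length(unique(groups)) < 2L)
    stop("need at least two groups with >= 2 samples")
  thresh <- bonferroniThreshold(alpha, nrow(M))
  rows <- lapply(seq_len(nrow(M)), function(i) {
    med <- tapply(M[i, ], groups, stats::median)
    ord <- order(-med, names(med))
    g1 <- names(med)[ord[1L]]; g2 <- names(med)[ord[2L]]
    x <- M[i, groups == g1]; y <- M[i, groups == g2]
    hasTies <- anyDuplicated(c(x, y)) > 0L
    useExact <- (length(x) + length(y) <= 12L) && !hasTies
    p <- suppressWarnings(stats::wilcox.test(
      x, y, alternative = "two.sided", exact = useExact,
      correct = TRUE)$p.value)
    data.frame(label = rownames(M)[i], bestGroup = g1, secondGroup = g2,
               medianBest = unname(med[ord[1L]]),
               medianSecond = unname(med[ord[2L]]),
               p = p, significant = p <= thresh,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Heat map of the signature matrix
#'
#' Signatures (rows) in their persisted clustered order; a diverging color
#' scale centered at 0 standardized units.  Samples are ordered by
#' average-linkage hierarchical clustering with Euclidean distance
#' (\code{sampleOrder = "cluster"}), grouped by the supplied labels
#' (\code{"given-labels"}), or left as-is (\code{"none"}).
#'
#' @param result a \linkS4class{SigPCAResult} with >= 1 signature.
#' @param path output image file (.png or .pdf).
#' @param sampleOrder "cluster", "given-labels" or "none".
#' @param groups optional per-sample labels (required for "given-labels");
#'   drawn as an annotation track.
#' @return \code{path}, invisibly.
#' @export
plotSignatureMatrix <- function(result, path,
                                sampleOrder = c("cluster", "given-labels",
                                                "none"),
                                groups = NULL) {
  sampleOrder <- match.arg(sampleOrder)
  M <- signatureMatrix(result)
  if (nrow(M) < 1L) stop("result has no signatures")
  annCol <- NA
  if (!is.null(groups)) {
    groups <- as.character(groups)
    if (!is.null(names(groups))) groups <- groups[colnames(M)]
    annCol <- data.frame(group = groups, row.names = colnames(M))
  }
  if (sampleOrder == "given-labels") {
    if (is.null(groups)) stop("sampleOrder = 'given-labels' needs groups")
    M <- M[, order(groups, colnames(M)), drop = FALSE]
  }
  lim <- max(abs(M))
  breaks <- seq(-lim, lim, length.out = 101L)
  pal <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7",
                                       "#B2182B"))(100L)
  pheatmap::pheatmap(
    M, cluster_rows = FALSE,
    cluster_cols = (sampleOrder == "cluster"),
    clustering_distance_cols = "euclidean",
    clustering_method = "average",
    annotation_col = if (is.data.frame(annCol)) annCol else NA,
    color = pal, breaks = breaks, border_color = NA,
    filename = path, silent = TRUE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records input and output paths with md5 hashes, the fully resolved
#' configuration and free-form counters, as JSON.
#'
#' @param path output JSON file.
#' @param inputs,outputs character vectors of file paths.
#' @param config a \linkS4class{SigPCAConfig} or a plain list.
#' @param extra named list of additional entries (record counts, timings).
#' @return \code{path}, invisibly.
#' @export
writeManifest <- function(path, inputs = character(), outputs = character(),
                          config = list(), extra = list()) {
  hash <- function(files) {
    files <- files[file.exists(files)]
    as.list(tools::md5sum(files))
  }
  if (is(config, "SigPCAConfig"))
    config <- list(xFrac = config@xFrac, xMin = config@xMin,
                   lRank = config@lRank, alphaB = config@alphaB,
                   rCorr = config@rCorr, zThreshold = config@zThreshold,
                   nPerm = config@nPerm, dOverride = config@dOverride,
                   topNVariance = config@topNVariance, seed = config@seed)
  jsonlite::write_json(
    list(inputs = hash(inputs), outputs = hash(outputs), config = config,
         tool = list(
           name = "sigPCA",
           version = tryCatch(
             as.character(utils::packageVersion("sigPCA")),
             error = function(e) "unversioned")),
         extra = extra),
    path, auto_unbox = TRUE, digits = NA, na = "null", null = "null")
  invisible(path)
}
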