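#' Parse an OBO 1.2/1.4 ontology file
#'
#' Reads \code{[Term]} stanzas, capturing id, name, namespace, \code{is_a}
#' parents, \code{part_of} relationships and \code{alt_id} aliases.  Obsolete
#' terms are dropped (a count is reported via \code{message()}); relation
#' edges pointing at dropped or unknown terms are removed likewise.  The
#' resulting relation graph is validated to be acyclic.
#'
#' @param path path to an OBO file.
#' @return an \linkS4class{Ontology}.
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c("[Term]", "id: T:1", "name: root",
#'              "namespace: biological_process"), obo)
#' parseOBO(obo)
#' @export
parseOBO <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\s+$", "", lines)
  stanzaStart <- grep("^\\[", lines)
  if (!length(stanzaStart))
    stop("no stanzas found in OBO file: ", path)

  ids <- character(); nms <- character(); nss <- character()
  isA <- list(); partOf <- list(); altIds <- character()
  nObsolete <- 0L

  starts <- stanzaStart
  ends <- c(stanzaStart[-1L] - 1L, length(lines))
  for (s in seq_along(starts)) {
    header <- lines[starts[s]]
    if (header != "[Term]") next
    body <- lines[seq(starts[s] + 1L, ends[s])]
    body <- body[nzchar(body) & !startsWith(body, "!")]
    bad <- which(!grepl("^[A-Za-z_]+:", body))
    if (length(bad))
      stop("malformed OBO stanza at line ",
           starts[s] + bad[1L], ": '", body[bad[1L]], "'")
    keys <- sub(":.*$", "", body)
    vals <- sub("^[A-Za-z_]+:\\s*", "", body)
    vals <- sub("\\s*!.*$", "", vals)   # trailing comments

    if (any(keys == "is_obsolete" & vals == "true")) {
      nObsolete <- nObsolete + 1L
      next
    }
    id <- vals[keys == "id"][1L]
    if (is.na(id))
      stop("OBO [Term] stanza without id at line ", starts[s])
    ids <- c(ids, id)
    nms <- c(nms, if (any(keys == "name")) vals[keys == "name"][1L] else id)
    nss <- c(nss, if (any(keys == "namespace"))
      vals[keys == "namespace"][1L] else "biological_process")
    isA[[id]] <- unique(vals[keys == "is_a"])
    rel <- vals[keys == "relationship"]
    po <- rel[startsWith(rel, "part_of ")]
    partOf[[id]] <- unique(sub("^part_of\\s+", "", po))
    for (a in vals[keys == "alt_id"]) altIds[[a]] <- id
  }

  if (anyDuplicated(ids))
    stop("duplicate term ids in OBO file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  # drop edges to obsolete/unknown terms
  known <- ids
  nDroppedEdges <- 0L
  for (id in ids) {
    keep <- isA[[id]] %in% known
    nDroppedEdges <- nDroppedEdges + sum(!keep)
    isA[[id]] <- isA[[id]][keep]
    keep <- partOf[[id]] %in% known
    nDroppedEdges <- nDroppedEdges + sum(!keep)
    partOf[[id]] <- partOf[[id]][keep]
  }
  if (nObsolete > 0L)
    message("parseOBO: dropped ", nObsolete, " obsolete terms")
  if (nDroppedEdges > 0L)
    message("parseOBO: dropped ", nDroppedEdges,
            " edges to obsolete/unknown terms")
  new("Ontology",
      terms = data.frame(id = ids, name = nms, namespace = nss,
                         stringsAsFactors = FALSE),
      isA = isA[ids], partOf = partOf[ids], altIds = altIds)
}

#' Parse a GAF 2.x gene association file
#'
#' Comment lines start with \code{'!'}.  Rows whose qualifier contains
#' \code{NOT} are excluded (negative annotations would corrupt enrichment),
#' as are rows whose evidence code is not in \code{allowedEvidence}; the
#' default keeps the manually curated codes only, so that e.g. electronically
#' inferred (IEA) annotations are discarded.  Identical (gene, term,
#' evidence) rows are collapsed.  Kept/dropped counts, both per row and per
#' unique (gene, term) pair, are reported via \code{message()}.
#'
#' @param path path to a GAF 2.x file (17 tab-separated columns).
#' @param allowedEvidence character vector of evidence codes to keep.
#' @return data.frame with columns \code{gene} (the symbol column),
#'   \code{termId} and \code{evidence}.
#' @export
parseGAF <- function(path,
                     allowedEvidence = c("IDA", "IGI", "IMP", "ISO",
                                         "ISS", "IC", "NAS", "TAS")) {
  lines <- readLines(path, warn = FALSE)
  dataIdx <- which(!startsWith(lines, "!") & nzchar(lines))
  if (!length(dataIdx))
    return(data.frame(gene = character(), termId = character(),
                      evidence = character(), stringsAsFactors = FALSE))
  # keep trailing empty columns (column 17 is routinely empty)
  fields <- strsplit(paste0(lines[dataIdx], "\x01"), "\t", fixed = TRUE)
  fields <- lapply(fields, function(f) {
    f[length(f)] <- sub("\x01$", "", f[length(f)])
    f
  })
  nf <- lengths(fields)
  if (any(nf != 17L))
    stop("GAF line ", dataIdx[which(nf != 17L)[1L]], " has ",
         nf[nf != 17L][1L], " columns, expected 17")
  gene <- vapply(fields, `[[`, character(1), 3L)
  qualifier <- vapply(fields, `[[`, character(1), 4L)
  termId <- vapply(fields, `[[`, character(1), 5L)
  evidence <- vapply(fields, `[[`, character(1), 7L)

  isNot <- grepl("(^|\\|)NOT($|\\|)", qualifier)
  okEv <- evidence %in% allowedEvidence
  keep <- !isNot & okEv
  ann <- data.frame(gene = gene[keep], termId = termId[keep],
                    evidence = evidence[keep], stringsAsFactors = FALSE)
  nBefore <- nrow(ann)
  ann <- unique(ann)
  message("parseGAF: kept ", nrow(ann), " of ", length(dataIdx),
          " rows (", sum(isNot), " NOT-qualified, ",
          sum(!okEv & !isNot), " disallowed evidence, ",
          nBefore - nrow(ann), " duplicates); unique (gene,term) pairs kept: ",
          nrow(unique(ann[c("gene", "termId")])), " of ",
          nrow(unique(data.frame(gene, termId)[!isNot, ])))
  rownames(ann) <- NULL
  ann
}

# effective parents: is_a everywhere; part_of treated as is_a for
# cellular_component terms only
.effectiveParents <- function(ontology, id) {
  p <- ontology@isA[[id]]
  ns <- ontology@terms$namespace[match(id, ontology@terms$id)]
  if (identical(ns, "cellular_component"))
    p <- unique(c(p, ontology@partOf[[id]]))
  p
}

.effectiveParentsMap <- function(ontology) {
  ids <- ontology@terms$id
  cc <- ontology@terms$namespace == "cellular_component"
  out <- ontology@isA
  for (i in which(cc))
    out[[ids[i]]] <- unique(c(out[[ids[i]]], ontology@partOf[[ids[i]]]))
  out
}

.childrenMap <- function(parentsMap) {
  children <- list()
  for (id in names(parentsMap)) {
    for (p in parentsMap[[id]])
      children[[p]] <- c(children[[p]], id)
  }
  children
}

.closure <- function(start, edgeMap) {
  out <- character(); frontier <- start
  while (length(frontier)) {
    nxt <- unique(unlist(lapply(frontier, function(i) edgeMap[[i]]),
                         use.names = FALSE))
    nxt <- setdiff(nxt, out)
    out <- c(out, nxt)
    frontier <- nxt
  }
  out
}

#' Transitive relatives of a term
#'
#' All transitive ancestors and descendants of a term (excluding the term
#' itself), following \code{is_a} edges and, for cellular-component terms,
#' \code{part_of} edges as well.  Used by the cross-component filter and by
#' the relaxed ("related term") bootstrap detection criterion.
#'
#' @param ontology an \linkS4class{Ontology}.
#' @param termId a term id present in the ontology.
#' @return character vector of related term ids.
#' @export
relatedTerms <- function(ontology, termId) {
  if (!termId %in% ontology@terms$id)
    stop("unknown term: ", termId)
  parents <- .effectiveParentsMap(ontology)
  children <- .childrenMap(parents)
  setdiff(unique(c(.closure(termId, parents), .closure(termId, children))),
          termId)
}

#' Propagate annotations up the ontology graph
#'
#' A gene annotated with a term is considered annotated with every ancestor
#' of that term: \code{is_a} edges are followed for all namespaces, and
#' \code{part_of} edges are additionally followed for cellular-component
#' terms.  Annotations to unknown terms are skipped with a warning (alt ids
#' are first resolved to their primary term).
#'
#' @param ontology an \linkS4class{Ontology}.
#' @param annotations data.frame with columns \code{gene} and \code{termId},
#'   as returned by [parseGAF()].
#' @return named list mapping term id to a sorted character vector of genes,
#'   for every term with at least one (direct or inherited) annotation.
#' @export
propagateAnnotations <- function(ontology, annotations) {
  ids <- ontology@terms$id
  tid <- annotations$termId
  alt <- ontology@altIds[tid]
  tid <- ifelse(!is.na(alt), alt, tid)
  unknown <- !(tid %in% ids)
  if (any(unknown)) {
    warning("skipping ", sum(unknown),
            " annotations to unknown terms (e.g. ",
            tid[unknown][1L], ")")
    annotations <- annotations[!unknown, , drop = FALSE]
    tid <- tid[!unknown]
  }
  parents <- .effectiveParentsMap(ontology)

  # memoized ancestor closures for the annotated terms
  anc <- new.env(parent = emptyenv())
  ancestorsOf <- function(id) {
    got <- get0(id, envir = anc)
    if (!is.null(got)) return(got)
    res <- unique(unlist(lapply(parents[[id]],
                                function(p) c(p, ancestorsOf(p))),
                         use.names = FALSE))
    if (is.null(res)) res <- character()
    assign(id, res, envir = anc)
    res
  }

  sets <- new.env(parent = emptyenv())
  for (t in unique(tid)) {
    genes <- unique(annotations$gene[tid == t])
    for (target in c(t, ancestorsOf(t)))
      assign(target,
             c(get0(target, envir = sets, ifnotfound = character()), genes),
             envir = sets)
  }
  out <- lapply(as.list(sets), function(g) sort(unique(g)))
  if (!length(out))
    return(stats::setNames(list(), character()))
  out[order(names(out))]
}

#' Assemble a gene-set collection
#'
#' @param sets named list of character vectors (term id -> genes).
#' @param termNames character vector of labels, parallel to \code{sets};
#'   defaults to the ids.
#' @param namespaces character vector of namespaces, parallel to
#'   \code{sets}; defaults to \code{"custom"}.
#' @return a \linkS4class{GeneSetCollection}.
#' @export
geneSetCollection <- function(sets,
                              termNames = names(sets),
                              namespaces = rep("custom", length(sets))) {
  sets <- lapply(sets, function(g) sort(unique(as.character(g))))
  new("GeneSetCollection", sets = sets,
      termMeta = data.frame(id = as.character(names(sets)),
                            name = as.character(termNames),
                            namespace = as.character(namespaces),
                            stringsAsFactors = FALSE))
}

#' Build a collection from an ontology and propagated annotations
#'
#' @param ontology an \linkS4class{Ontology}.
#' @param propagated named list as returned by [propagateAnnotations()].
#' @return a \linkS4class{GeneSetCollection} carrying the ontology's term
#'   names and namespaces.
#' @export
collectionFromOntology <- function(ontology, propagated) {
  idx <- match(names(propagated), ontology@terms$id)
  geneSetCollection(propagated,
                    termNames = ontology@terms$name[idx],
                    namespaces = ontology@terms$namespace[idx])
}

#' Retain gene sets within a size window
#'
#' Sets that are too broad (more than \code{maxGenes} genes) tend to be
#' uninformative; sets that are too specific (fewer than \code{minGenes})
#' cannot support the test's minimum-overlap constraint.  Both bounds are
#' inclusive.
#'
#' @param collection a \linkS4class{GeneSetCollection}.
#' @param minGenes,maxGenes inclusive size window (defaults 5 and 200).
#' @return the filtered \linkS4class{GeneSetCollection}.
#' @export
filterSetsBySize <- function(collection, minGenes = 5L, maxGenes = 200L) {
  stopifnot(minGenes >= 1L, maxGenes >= minGenes)
  sz <- lengths(collection@sets)
  keep <- sz >= minGenes & sz <= maxGenes
  new("GeneSetCollection", sets = collection@sets[keep],
      termMeta = collection@termMeta[keep, , drop = FALSE])
}

#' Remove parent terms identical to a direct child
#'
#' After propagation a parent term inherits all of a child's genes; when the
#' two annotated sets are exactly equal the parent adds no information and is
#' removed (the more specific child is kept).  Only direct parent/child pairs
#' (by \code{is_a}, plus \code{part_of} for cellular-component terms) are
#' compared; removal decisions are computed on the input collection and then
#' applied, so a surviving set is never modified, only dropped.
#'
#' @param collection a propagated \linkS4class{GeneSetCollection}.
#' @param ontology the \linkS4class{Ontology} providing the relations.
#' @return the collapsed \linkS4class{GeneSetCollection}.
#' @export
collapseRedundantParents <- function(collection, ontology) {
  parents <- .effectiveParentsMap(ontology)
  present <- names(collection@sets)
  drop <- character()
  for (child in present) {
    for (p in intersect(parents[[child]], present)) {
      if (setequal(collection@sets[[p]], collection@sets[[child]]))
        drop <- c(drop, p)
    }
  }
  keep <- !(present %in% drop)
  new("GeneSetCollection", sets = collection@sets[keep],
      termMeta = collection@termMeta[keep, , drop = FALSE])
}

#' Write / read the plain-text gene-set interchange format
#'
#' One set per line: \code{id <TAB> name <TAB> namespace <TAB>
#' comma-separated genes}, preceded by a header line.  The file can be edited
#' by hand or written from scratch to run the pipeline with arbitrary
#' (non-ontology) gene sets.
#'
#' @param collection a \linkS4class{GeneSetCollection}.
#' @param path output (or input) file path.
#' @return \code{readGeneSets} returns a \linkS4class{GeneSetCollection};
#'   \code{writeGeneSets} returns \code{path} invisibly.
#' @export
writeGeneSets <- function(collection, path) {
  header <- "id\tname\tnamespace\tgenes"
  body <- vapply(seq_along(collection@sets), function(i) {
    paste(collection@termMeta$id[i], collection@termMeta$name[i],
          collection@termMeta$namespace[i],
          paste(collection@sets[[i]], collapse = ","), sep = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname writeGeneSets
#' @export
readGeneSets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || lines[1L] != "id\tname\tnamespace\tgenes")
    stop("not a gene-set file (missing header): ", path)
  lines <- lines[-1L]
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(geneSetCollection(stats::setNames(list(), character())))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 4L))
    stop("gene-set file line ", which(nf != 4L)[1L] + 1L,
         " has ", nf[nf != 4L][1L], " fields, expected 4")
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate set ids in gene-set file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sets <- lapply(fields, function(f)
    sort(unique(strsplit(f[[4L]], ",", fixed = TRUE)[[1L]])))
  names(sets) <- ids
  geneSetCollection(sets,
                    termNames = vapply(fields, `[[`, character(1), 2L),
                    namespaces = vapply(fields, `[[`, character(1), 3L))
}
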