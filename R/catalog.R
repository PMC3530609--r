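#' Term-to-gene annotation catalog
#'
#' A GO/KEGG-style catalog mapping term ids to gene sets, with a term name
#' and a namespace (GO_BP, GO_CC, GO_MF or KEGG) per term. Used both for
#' zebrafish-side and human-side annotation; [combineAnnotations()] merges
#' the two across a homolog map.
#'
#' @slot terms data.frame with columns term_id, term_name, namespace
#' @slot genes named list (by term_id) of character vectors of gene ids
#' @export
setClass("AnnotationCatalog",
         representation(terms = "data.frame", genes = "list"))

setValidity("AnnotationCatalog", function(object) {
  msg <- character()
  if (!all(c("term_id", "term_name", "namespace") %in% names(object@terms)))
    msg <- c(msg, "terms needs columns term_id, term_name, namespace")
  else {
    if (anyDuplicated(object@terms$term_id))
      msg <- c(msg, "term ids must be unique")
    if (!setequal(names(object@genes), object@terms$term_id))
      msg <- c(msg, "gene list names must match term ids")
    if (any(lengths(object@genes) == 0))
      msg <- c(msg, "every term needs at least one gene")
    if (!all(object@terms$namespace %in% c("GO_BP", "GO_CC", "GO_MF", "KEGG")))
      msg <- c(msg, "namespace must be GO_BP, GO_CC, GO_MF or KEGG")
  }
  if (length(msg)) msg else TRUE
})

#' Build an annotation catalog
#'
#' @param term_id,term_name,namespace parallel character vectors
#' @param genes list of character vectors, one per term (duplicates removed)
#' @return an \linkS4class{AnnotationCatalog}
#' @examples
#' cat <- annotationCatalog("GO:1", "vision", "GO_BP", list(c("g1", "g2")))
#' catalogGenes(cat)[["GO:1"]]
#' @export
annotationCatalog <- function(term_id, term_name, namespace, genes) {
  genes <- lapply(genes, function(g) sort(unique(as.character(g))))
  names(genes) <- term_id
  new("AnnotationCatalog",
      terms = data.frame(term_id = term_id, term_name = term_name,
                         namespace = namespace, stringsAsFactors = FALSE),
      genes = genes)
}

#' @describeIn annotationCatalog term metadata data.frame
#' @param object an \code{AnnotationCatalog}
#' @export
catalogTerms <- function(object) object@terms

#' @describeIn annotationCatalog named list of gene sets
#' @export
catalogGenes <- function(object) object@genes

setMethod("show", "AnnotationCatalog", function(object) {
  ns <- table(object@terms$namespace)
  cat("AnnotationCatalog:", nrow(object@terms), "terms (",
      paste(sprintf("%s:%d", names(ns), ns), collapse = ", "), ");",
      length(unique(unlist(object@genes))), "distinct genes\n")
})

setMethod("length", "AnnotationCatalog", function(x) nrow(x@terms))

#' Translate catalog member ids
#'
#' Maps every member id through a named translation vector (e.g. transcript
#' id to gene-cluster id); ids absent from the map are kept unchanged,
#' duplicates arising from the translation are collapsed, and terms left
#' empty are dropped.
#'
#' @param catalog an \linkS4class{AnnotationCatalog}
#' @param map named character vector: old id -> new id
#' @return translated \linkS4class{AnnotationCatalog}
#' @export
mapCatalogGenes <- function(catalog, map) {
  stopifnot(is(catalog, "AnnotationCatalog"))
  genes <- lapply(catalog@genes, function(g) {
    hit <- g %in% names(map)
    sort(unique(c(unname(map[g[hit]]), g[!hit])))
  })
  keep <- lengths(genes) > 0
  t <- catalog@terms[keep, , drop = FALSE]
  annotationCatalog(t$term_id, t$term_name, t$namespace, genes[keep])
}

#' Read and write GMT catalogs
#'
#' The GMT description field carries \code{namespace|term_name} so the
#' namespace survives a round trip; a bare description is read back as a
#' term name with namespace defaulting to GO_BP.
#'
#' @param path GMT file path
#' @return \code{readGMT}: an \linkS4class{AnnotationCatalog};
#'   \code{writeGMT}: the path, invisibly
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad))
    stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  desc <- vapply(parts, `[[`, "", 2)
  hasNs <- grepl("|", desc, fixed = TRUE)
  ns <- ifelse(hasNs, sub("\\|.*$", "", desc), "GO_BP")
  nm <- ifelse(hasNs, sub("^[^|]*\\|", "", desc), desc)
  annotationCatalog(term_id = vapply(parts, `[[`, "", 1),
                    term_name = nm, namespace = ns,
                    genes = lapply(parts, function(p) p[-(1:2)]))
}

#' @rdname readGMT
#' @param catalog an \linkS4class{AnnotationCatalog}
#' @export
writeGMT <- function(catalog, path) {
  stopifnot(is(catalog, "AnnotationCatalog"))
  t <- catalog@terms
  lines <- vapply(seq_len(nrow(t)), function(i)
    paste(c(t$term_id[i], paste0(t$namespace[i], "|", t$term_name[i]),
            catalog@genes[[t$term_id[i]]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
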