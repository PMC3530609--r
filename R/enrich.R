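#' Fisher-exact gene-set enrichment
#'
#' One-sided hypergeometric upper-tail test per term: with universe size N,
#' K universe genes annotated to the term, n differentially expressed genes
#' and k of them in the term, \eqn{p = \sum_{x \ge k} C(K,x) C(N-K,n-x) /
#' C(N,n)}. Terms with no universe gene are skipped. Q-values are
#' Benjamini-Hochberg adjusted within each namespace (GO_BP, GO_CC, GO_MF,
#' KEGG separately) and results are sorted by q then p; the significance
#' flag uses q < \code{qCut}.
#'
#' @param deGenes character vector of DE gene ids (must lie in the universe)
#' @param universe character vector of tested gene ids
#' @param catalog an \linkS4class{AnnotationCatalog}
#' @param qCut significance threshold on q (default 0.05)
#' @return data.frame: term_id, term_name, namespace, k, K, n, N, p, q,
#'   significant
#' @examples
#' cat <- annotationCatalog("T1", "toy", "KEGG", list(letters[1:5]))
#' fisherEnrichment(letters[1:5], letters[1:20], cat)$p  # 1 / choose(20, 5)
#' @export
fisherEnrichment <- function(deGenes, universe, catalog, qCut = 0.05) {
  stopifnot(is(catalog, "AnnotationCatalog"))
  universe <- unique(universe)
  deGenes <- unique(deGenes)
  if (!all(deGenes %in% universe))
    stop("deGenes must be a subset of the universe")
  N <- length(universe); n <- length(deGenes)
  terms <- catalogTerms(catalog); genes <- catalogGenes(catalog)
  rows <- lapply(terms$term_id, function(id) {
    termU <- intersect(genes[[id]], universe)
    K <- length(termU)
    if (K == 0) return(NULL)
    k <- length(intersect(termU, deGenes))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    i <- match(id, terms$term_id)
    data.frame(term_id = id, term_name = terms$term_name[i],
               namespace = terms$namespace[i], k = k, K = K, n = n, N = N,
               p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(data.frame(term_id = character(), term_name = character(),
                      namespace = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      q = numeric(), significant = logical()))
  res$q <- NA_real_
  for (ns in unique(res$namespace))
    res$q[res$namespace == ns] <- bhAdjust(res$p[res$namespace == ns])
  res <- res[order(res$q, res$p, res$term_id), ]
  res$significant <- res$q < qCut
  rownames(res) <- NULL
  res
}

#' Count DE genes per top-level functional category
#'
#' Maps each differentially expressed gene (up- and down-regulated handled
#' separately) through the term catalog into user-defined top-level
#' categories; a gene counts once per category no matter how many of the
#' category's terms annotate it, and genes with no categorized term are
#' reported under "other".
#'
#' @param deUp,deDown character vectors of up-/down-regulated gene ids
#' @param catalog an \linkS4class{AnnotationCatalog}
#' @param categoryMap named character vector: term_id -> category label
#' @return data.frame: category, direction, count
#' @export
goCategorySummary <- function(deUp, deDown, catalog, categoryMap) {
  stopifnot(is(catalog, "AnnotationCatalog"))
  genes <- catalogGenes(catalog)
  geneCats <- function(g) {
    termsOfG <- names(genes)[vapply(genes, function(x) g %in% x, TRUE)]
    cats <- unique(unname(categoryMap[intersect(termsOfG, names(categoryMap))]))
    if (length(cats)) cats else "other"
  }
  count <- function(de, direction) {
    cats <- unlist(lapply(de, geneCats))
    tab <- table(factor(cats, levels = c(sort(unique(unname(categoryMap))),
                                         "other")))
    data.frame(category = names(tab), direction = direction,
               count = as.integer(tab), stringsAsFactors = FALSE)
  }
  rbind(count(deUp, "up"), count(deDown, "down"))
}

#' Resolve cytoband notation to genomic intervals
#'
#' Resolves locus strings such as \code{"6q14-q16.2"}, \code{"Xp22"},
#' \code{"17q"} or \code{"Xq28-qter"} against a UCSC-format cytoband table.
#' A band label matches every band it prefixes (\code{q14} covers
#' \code{q14.1}, \code{q14.2}, ...), an arm alone covers the whole arm,
#' \code{qter}/\code{pter} denote the arm's terminal band, and a range
#' spans from the start of the first matched band to the end of the last.
#'
#' @param locus character vector of cytoband locus strings (chromosome
#'   prefix included, e.g. "6q14-q16.2")
#' @param cytobands data.frame with columns chrom (e.g. "chr6"), start,
#'   end, band (e.g. "q14.1")
#' @return data.frame: locus, chrom, start, end; unresolvable loci carry NA
#'   coordinates with a warning
#' @export
resolveCytobands <- function(locus, cytobands) {
  bandSpan <- function(chrom, label) {
    cb <- cytobands[cytobands$chrom == chrom, , drop = FALSE]
    if (label %in% c("pter", "qter")) {
      arm <- substr(label, 1, 1)
      cb <- cb[startsWith(cb$band, arm), , drop = FALSE]
      if (!nrow(cb)) return(NULL)
      picked <- if (arm == "p") cb[which.min(cb$start), ]
                else cb[which.max(cb$end), ]
      return(c(picked$start, picked$end))
    }
    hit <- cb[startsWith(cb$band, label), , drop = FALSE]
    if (!nrow(hit)) return(NULL)
    c(min(hit$start), max(hit$end))
  }
  out <- data.frame(locus = locus, chrom = NA_character_,
                    start = NA_integer_, end = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(locus)) {
    mt <- regmatches(locus[i], regexec("^([0-9XY]+)([pq].*)$", locus[i]))[[1]]
    if (length(mt) != 3) { warning("unparsable locus: ", locus[i]); next }
    chrom <- paste0("chr", mt[2])
    parts <- strsplit(mt[3], "-", fixed = TRUE)[[1]]
    # a bare trailing arm+number inherits the arm letter when omitted
    if (length(parts) == 2 && !grepl("^[pq]", parts[2]))
      parts[2] <- paste0(substr(parts[1], 1, 1), parts[2])
    spans <- lapply(parts, bandSpan, chrom = chrom)
    if (any(vapply(spans, is.null, TRUE))) {
      warning("unresolvable cytoband in locus: ", locus[i])
      next
    }
    out$chrom[i] <- chrom
    out$start[i] <- min(vapply(spans, `[[`, 0, 1))
    out$end[i] <- max(vapply(spans, `[[`, 0, 2))
  }
  out
}

#' Map DE genes into human disease loci
#'
#' For every disease locus, lists the differentially expressed zebrafish
#' genes whose best human homolog has a genomic interval overlapping the
#' locus by at least 1 bp (any-overlap rule; a homolog straddling the locus
#' boundary counts). Loci with missing coordinates are skipped with a
#' warning. Output is ordered by disease then gene, and is invariant to the
#' input order of loci and genes.
#'
#' @param deGenes character vector of DE zebrafish gene ids
#' @param homologMap data.frame (query_id, subject_id) or named vector
#'   mapping zebrafish genes to human ids
#' @param humanGeneCoords data.frame: chrom, start, end, gene (0-based
#'   half-open or BED-like; only relative overlap matters)
#' @param loci data.frame: disease, omim_id, chrom, start, end
#' @return data.frame: disease, omim_id, gene_id, human_id
#' @export
diseaseLocusCandidates <- function(deGenes, homologMap, humanGeneCoords,
                                   loci) {
  if (is.data.frame(homologMap))
    homologMap <- setNames(homologMap$subject_id, homologMap$query_id)
  deGenes <- sort(unique(deGenes))
  mapped <- homologMap[intersect(deGenes, names(homologMap))]
  coords <- humanGeneCoords[humanGeneCoords$gene %in% mapped, , drop = FALSE]
  bad <- is.na(loci$start) | is.na(loci$end) | is.na(loci$chrom)
  if (any(bad)) {
    warning(sum(bad), " locus/loci without coordinates skipped: ",
            paste(loci$disease[bad], collapse = "; "))
    loci <- loci[!bad, , drop = FALSE]
  }
  if (!nrow(coords) || !nrow(loci))
    return(data.frame(disease = character(), omim_id = integer(),
                      gene_id = character(), human_id = character()))
  gGr <- GenomicRanges::GRanges(
    coords$chrom, IRanges::IRanges(start = coords$start + 1L,
                                   end = coords$end))
  lGr <- GenomicRanges::GRanges(
    loci$chrom, IRanges::IRanges(start = loci$start + 1L, end = loci$end))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(lGr, gGr, minoverlap = 1L))
  if (!length(hits))
    return(data.frame(disease = character(), omim_id = integer(),
                      gene_id = character(), human_id = character()))
  hsToZf <- split(names(mapped), unname(mapped))
  res <- do.call(rbind, lapply(seq_along(hits), function(i) {
    li <- S4Vectors::queryHits(hits)[i]
    gi <- S4Vectors::subjectHits(hits)[i]
    zf <- hsToZf[[coords$gene[gi]]]
    data.frame(disease = loci$disease[li], omim_id = loci$omim_id[li],
               gene_id = zf, human_id = coords$gene[gi],
               stringsAsFactors = FALSE)
  }))
  res <- unique(res[order(res$disease, res$gene_id), ])
  rownames(res) <- NULL
  res
}
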