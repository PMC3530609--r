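#' Simulate functional annotation, homology and disease-locus resources
#'
#' Emulates the cross-species annotation resources the enrichment and
#' disease-mapping stages consume: a zebrafish-side term catalog containing
#' one spiked enriched term whose members are drawn preferentially from the
#' differentially expressed genes, a human-side catalog keyed by human
#' protein ids, a homolog hit table engineered to straddle both sides of the
#' 30%-identity / 30%-alignment-length filter boundary (boundary hits sit
#' exactly at 30.0% identity and 0.3 x query length), human gene coordinates,
#' and disease loci that do or do not contain the human homolog of a
#' differentially expressed gene.
#'
#' When a \code{transcriptsOf} map is supplied (gene id to its transcript
#' ids) the emitted resources are keyed the way real ones are: homolog
#' queries by a representative transcript accession and zebrafish term
#' members by transcript ids; the pipeline translates transcripts back to
#' its own gene clusters. Without it, keys are the gene ids themselves.
#'
#' @param config a \linkS4class{SimConfig}
#' @param genes character vector of zebrafish gene ids (the universe)
#' @param deGenes character vector of truth-DE gene ids (subset of genes)
#' @param transcriptsOf optional named list: gene id -> transcript ids
#' @return list with \code{zfCatalog}, \code{humanCatalog} (annotation
#'   catalogs, see [annotationCatalog()]), \code{homologHits} (data.frame:
#'   query_id, subject_id, pct_identity, align_length, query_length,
#'   bitscore, evalue), \code{humanGeneCoords} (BED-like data.frame),
#'   \code{loci} (disease, omim_id, chrom, start, end) and \code{truth}
#'   (list: spikedTerm, homologBest, homologBoundary, lociContainsDE)
#' @export
simulateFunctionalAnnotation <- function(config, genes, deGenes,
                                         transcriptsOf = NULL) {
  stopifnot(is(config, "SimConfig"))
  if (config@spikedPathwaySize > length(genes))
    stop("spikedPathwaySize exceeds the number of genes")
  if (!all(deGenes %in% genes)) stop("deGenes must be a subset of genes")
  queryOf <- if (is.null(transcriptsOf)) setNames(genes, genes)
             else vapply(setNames(genes, genes),
                         function(g) sort(transcriptsOf[[g]])[1], "")
  membersOf <- function(gs) {
    if (is.null(transcriptsOf)) gs
    else sort(unlist(transcriptsOf[gs], use.names = FALSE))
  }
  withSeed(familySeed(config@seed, "functional"), {
    nG <- length(genes)
    ## homolog hits: most genes one passing best hit plus a weaker decoy;
    ## a handful engineered at or just below the 30/30 boundary
    hs <- setNames(sprintf("HSP%05d", seq_len(nG)), genes)
    rows <- list(); best <- list(); boundary <- character()
    nEdge <- min(6L, nG)
    edgeKind <- rep(c("boundary", "fail_identity", "fail_length"),
                    length.out = nEdge)
    for (i in seq_len(nG)) {
      g <- genes[i]
      qlen <- sample(30:120, 1) * 10L  # multiple of 10: 0.3*qlen is integer
      if (i <= nEdge) {
        kind <- edgeKind[i]
        if (kind == "boundary") {
          pid <- 30; alen <- as.integer(0.3 * qlen); pass <- TRUE
          boundary <- c(boundary, g)
        } else if (kind == "fail_identity") {
          pid <- 29.9; alen <- qlen; pass <- FALSE
        } else {
          pid <- 80; alen <- as.integer(0.29 * qlen); pass <- FALSE
        }
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = queryOf[[g]], subject_id = hs[[g]], pct_identity = pid,
          align_length = alen, query_length = qlen,
          bitscore = round(runif(1, 100, 400), 1),
          evalue = 10^-sample(5:40, 1), stringsAsFactors = FALSE)
        if (pass) best[[g]] <- hs[[g]]
      } else {
        bs <- round(runif(1, 150, 500), 1)
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = queryOf[[g]], subject_id = hs[[g]],
          pct_identity = round(runif(1, 40, 95), 1),
          align_length = as.integer(qlen * runif(1, 0.5, 1)),
          query_length = qlen, bitscore = bs,
          evalue = 10^-sample(10:60, 1), stringsAsFactors = FALSE)
        # weaker passing decoy hit: must lose on bitscore
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = queryOf[[g]], subject_id = sprintf("HSP%05d", nG + i),
          pct_identity = round(runif(1, 31, 60), 1),
          align_length = as.integer(qlen * runif(1, 0.4, 0.8)),
          query_length = qlen, bitscore = round(bs - runif(1, 20, 100), 1),
          evalue = 10^-sample(3:9, 1), stringsAsFactors = FALSE)
        best[[g]] <- hs[[g]]
      }
    }
    homologHits <- do.call(rbind, rows)
    homologBest <- unlist(best)

    ## zebrafish catalog with one spiked enriched term
    nsCycle <- c("GO_BP", "GO_CC", "GO_MF", "KEGG")
    termIds <- sprintf("SIM:%04d", seq_len(config@nTerms))
    termNs <- rep(nsCycle, length.out = config@nTerms)
    szRange <- seq(min(5L, nG), min(40L, nG))
    members <- lapply(seq_len(config@nTerms), function(i)
      membersOf(sort(sample(genes, sample(szRange, 1)))))
    nDEmem <- round(config@spikedPathwaySize * config@spikedPathwayDEFraction)
    nDEmem <- min(nDEmem, length(deGenes))
    spiked <- sort(c(sample(deGenes, nDEmem),
                     sample(setdiff(genes, deGenes),
                            config@spikedPathwaySize - nDEmem)))
    termIds <- c(termIds, "KEGG:SPIKE")
    termNs <- c(termNs, "KEGG")
    members <- c(members, list(membersOf(spiked)))
    zfCatalog <- annotationCatalog(
      term_id = termIds,
      term_name = c(sprintf("simulated term %d", seq_len(config@nTerms)),
                    "spiked signalling pathway"),
      namespace = termNs,
      genes = members)

    ## human catalog: human-protein-keyed terms, transferable via homologs
    nHTerm <- max(5L, config@nTerms %/% 5L)
    hIds <- sprintf("HSIM:%04d", seq_len(nHTerm))
    hszRange <- seq(min(5L, nG), min(30L, nG))
    hMembers <- lapply(seq_len(nHTerm), function(i)
      sort(sample(unname(hs), sample(hszRange, 1))))
    humanCatalog <- annotationCatalog(
      term_id = hIds,
      term_name = sprintf("human-side term %d", seq_len(nHTerm)),
      namespace = rep(nsCycle, length.out = nHTerm),
      genes = hMembers)

    ## human gene coordinates: sequential intervals with >= 2 kb gaps
    chroms <- paste0("hchr", 1:10)
    coordChrom <- sample(chroms, nG, replace = TRUE)
    coords <- data.frame(chrom = coordChrom, start = 0L, end = 0L,
                         gene = unname(hs), stringsAsFactors = FALSE)
    for (ch in chroms) {
      idx <- which(coordChrom == ch)
      if (!length(idx)) next
      w <- sample(5000:50000, length(idx), replace = TRUE)
      gap <- sample(2000:8000, length(idx), replace = TRUE)
      st <- cumsum(gap) + c(0L, cumsum(w))[seq_along(idx)] + 100000L
      coords$start[idx] <- as.integer(st)
      coords$end[idx] <- as.integer(st + w)
    }

    ## disease loci: half contain the homolog of a DE gene, half avoid all
    ## DE homologs (tight window around one non-DE homolog)
    dePass <- intersect(deGenes, names(homologBest))
    nonDePass <- setdiff(names(homologBest), deGenes)
    nHit <- ceiling(config@locusCount / 2)
    nMiss <- config@locusCount - nHit
    hitG <- sample(dePass, min(nHit, length(dePass)))
    missG <- sample(nonDePass, min(nMiss, length(nonDePass)))
    mkLocus <- function(g, i, margin) {
      ci <- coords[coords$gene == homologBest[[g]], ][1, ]
      data.frame(disease = sprintf("synthetic retinal disease locus %d", i),
                 omim_id = 600000L + i, chrom = ci$chrom,
                 start = max(0L, ci$start - margin),
                 end = ci$end + margin, stringsAsFactors = FALSE)
    }
    loci <- do.call(rbind, c(
      lapply(seq_along(hitG), function(i) mkLocus(hitG[i], i, 50000L)),
      lapply(seq_along(missG),
             function(i) mkLocus(missG[i], length(hitG) + i, 1000L))))
    containsDE <- c(rep(TRUE, length(hitG)), rep(FALSE, length(missG)))
    ## a wide "hit" margin can swallow a neighbouring DE homolog into a
    ## "miss" locus; verify against coordinates and correct the flag
    deIv <- coords[coords$gene %in% homologBest[dePass], ]
    for (j in seq_len(nrow(loci))) {
      ov <- deIv$chrom == loci$chrom[j] &
        deIv$start < loci$end[j] & deIv$end > loci$start[j]
      containsDE[j] <- any(ov)
    }
    list(zfCatalog = zfCatalog, humanCatalog = humanCatalog,
         homologHits = homologHits, humanGeneCoords = coords, loci = loci,
         truth = list(spikedTerm = "KEGG:SPIKE",
                      spikedMembers = spiked,
                      homologBest = homologBest,
                      homologBoundary = boundary,
                      lociContainsDE = data.frame(
                        disease = loci$disease, contains_de = containsDE,
                        stringsAsFactors = FALSE)))
  })
}
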