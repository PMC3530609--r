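#' Read CDS-exon transcript models from GFF3
#'
#' Imports CDS features from one or more GFF3 files (one per source
#' database) into the 0-based half-open exon table used throughout the
#' package. The transcript id is taken from the Parent attribute (falling
#' back to ID), the source database from the GFF source column.
#'
#' @param paths character vector of GFF3 files
#' @return data.frame with columns transcript_id, source_db, chrom, strand,
#'   start, end (0-based half-open), sorted by transcript then start
#' @export
readTranscriptsGFF3 <- function(paths) {
  out <- lapply(paths, function(p) {
    gr <- rtracklayer::import(p, format = "gff3")
    gr <- gr[S4Vectors::mcols(gr)$type %in% "CDS"]
    md <- S4Vectors::mcols(gr)
    tid <- if ("Parent" %in% names(md)) as.character(unlist(md$Parent))
           else as.character(md$ID)
    src <- if ("source" %in% names(md)) as.character(md$source)
           else rep(tools::file_path_sans_ext(basename(p)), length(gr))
    data.frame(transcript_id = tid, source_db = src,
               chrom = as.character(GenomicRanges::seqnames(gr)),
               strand = as.character(GenomicRanges::strand(gr)),
               start = GenomicRanges::start(gr) - 1L,
               end = GenomicRanges::end(gr),
               stringsAsFactors = FALSE)
  })
  ex <- do.call(rbind, out)
  ex[order(ex$transcript_id, ex$start), ]
}

validateExonTable <- function(exons) {
  need <- c("transcript_id", "chrom", "strand", "start", "end")
  if (!all(need %in% names(exons)))
    stop("exon table needs columns: ", paste(need, collapse = ", "))
  if (any(exons$start >= exons$end))
    stop("every exon needs start < end")
  byTx <- split(exons, exons$transcript_id)
  for (tx in byTx) {
    if (length(unique(tx$chrom)) > 1 || length(unique(tx$strand)) > 1)
      stop("duplicate transcript_id with conflicting placement: ",
           tx$transcript_id[1])
    o <- order(tx$start)
    if (any(tx$end[o][-nrow(tx)] > tx$start[o][-1]))
      stop("overlapping exons within transcript ", tx$transcript_id[1])
  }
  invisible(TRUE)
}

#' Cluster transcripts into genes by coding-exon overlap
#'
#' Two transcripts belong to the same gene iff they are connected, directly
#' or transitively, by at least 1 bp of CDS-exon overlap on the same
#' chromosome and (by default) the same strand. Gene ids are assigned
#' deterministically: clusters are ordered by chromosome, hull start, then
#' the lexicographically smallest member transcript id.
#'
#' @param exons exon table as from [readTranscriptsGFF3()] (0-based
#'   half-open); one row per CDS exon
#' @param ignoreStrand if TRUE, antisense overlap also connects transcripts
#' @return list with \code{clusters} (data.frame: gene_id, chrom, strand,
#'   start, end, n_transcripts, transcripts) and \code{map} (data.frame:
#'   transcript_id, gene_id)
#' @examples
#' ex <- data.frame(transcript_id = c("T1", "T2", "T3"), chrom = "chr1",
#'                  strand = "+", start = c(100, 150, 240),
#'                  end = c(200, 250, 300))
#' clusterTranscripts(ex)$clusters$n_transcripts  # one chain of three
#' @export
clusterTranscripts <- function(exons, ignoreStrand = FALSE) {
  if (nrow(exons) == 0)
    return(list(clusters = data.frame(gene_id = character(),
                                      chrom = character(), strand = character(),
                                      start = integer(), end = integer(),
                                      n_transcripts = integer(),
                                      transcripts = character()),
                map = data.frame(transcript_id = character(),
                                 gene_id = character())))
  validateExonTable(exons)
  txIds <- sort(unique(exons$transcript_id))
  gr <- GenomicRanges::GRanges(
    seqnames = exons$chrom,
    ranges = IRanges::IRanges(start = exons$start + 1L, end = exons$end),
    strand = exons$strand)
  hits <- GenomicRanges::findOverlaps(gr, ignore.strand = ignoreStrand,
                                      drop.self = TRUE, drop.redundant = TRUE)
  ti <- match(exons$transcript_id, txIds)
  edges <- cbind(ti[S4Vectors::queryHits(hits)],
                 ti[S4Vectors::subjectHits(hits)])
  g <- igraph::make_empty_graph(n = length(txIds), directed = FALSE)
  if (nrow(edges))
    g <- igraph::add_edges(g, t(unique(edges)))
  comp <- igraph::components(g)$membership

  txChrom <- tapply(exons$chrom, exons$transcript_id, `[[`, 1)[txIds]
  txStrand <- tapply(exons$strand, exons$transcript_id, `[[`, 1)[txIds]
  txMin <- tapply(exons$start, exons$transcript_id, min)[txIds]
  txMax <- tapply(exons$end, exons$transcript_id, max)[txIds]
  cl <- lapply(split(seq_along(txIds), comp), function(idx) {
    strands <- unique(txStrand[idx])
    data.frame(chrom = txChrom[idx][1],
               strand = if (length(strands) == 1) strands else "*",
               start = min(txMin[idx]), end = max(txMax[idx]),
               n_transcripts = length(idx),
               transcripts = paste(sort(txIds[idx]), collapse = ","),
               first_tx = sort(txIds[idx])[1],
               stringsAsFactors = FALSE)
  })
  cl <- do.call(rbind, cl)
  ord <- order(cl$chrom, cl$start, cl$first_tx)
  cl <- cl[ord, , drop = FALSE]
  cl$gene_id <- sprintf("G%06d", seq_len(nrow(cl)))
  clusters <- cl[, c("gene_id", "chrom", "strand", "start", "end",
                     "n_transcripts", "transcripts")]
  rownames(clusters) <- NULL
  map <- do.call(rbind, lapply(seq_len(nrow(clusters)), function(i)
    data.frame(transcript_id = strsplit(clusters$transcripts[i], ",")[[1]],
               gene_id = clusters$gene_id[i], stringsAsFactors = FALSE)))
  map <- map[order(map$transcript_id), ]
  rownames(map) <- NULL
  list(clusters = clusters, map = map)
}

#' Filter probe alignments to the clean, uniquely-assignable set
#'
#' A probe is retained iff it aligns with zero mismatches, hits the genome
#' exactly once, lies entirely within a CDS exon, and every transcript whose
#' exon contains it belongs to a single gene cluster. All other probes are
#' removed and logged with a reason code (mismatch, multi_hit, outside_cds,
#' multi_gene).
#'
#' @param alignments BLAST-tabular-like data.frame (qseqid, chrom, pident,
#'   length, mismatch, sstart, send, strand, hit_count; sstart/send 1-based
#'   inclusive, one row per genomic hit)
#' @param exons exon table (0-based half-open)
#' @param clustering result of [clusterTranscripts()] on the same exons
#' @return list with \code{assignments} (probe_id, gene_id, transcripts) and
#'   \code{log} (probe_id, retained, reason)
#' @export
filterProbeAlignments <- function(alignments, exons, clustering) {
  known <- unique(exons$chrom)
  if (!all(alignments$chrom %in% known))
    stop("alignment references unknown chromosome(s): ",
         paste(head(setdiff(alignments$chrom, known)), collapse = ", "))
  exGr <- GenomicRanges::GRanges(
    seqnames = exons$chrom,
    ranges = IRanges::IRanges(start = exons$start + 1L, end = exons$end))
  txOfExon <- exons$transcript_id
  geneOf <- setNames(clustering$map$gene_id, clustering$map$transcript_id)

  probes <- sort(unique(alignments$qseqid))
  pIdx <- match(alignments$qseqid, probes)
  anyMism <- tapply(alignments$mismatch > 0, pIdx, any)
  nRows <- tabulate(pIdx, length(probes))
  maxHits <- tapply(alignments$hit_count, pIdx, max)
  reason <- rep(NA_character_, length(probes))
  reason[nRows > 1 | maxHits > 1] <- "multi_hit"
  reason[anyMism] <- "mismatch"

  cand <- which(is.na(reason))
  gene <- rep(NA_character_, length(probes))
  txset <- rep(NA_character_, length(probes))
  if (length(cand)) {
    rows <- match(cand, pIdx)  # the single alignment row of each candidate
    hit <- GenomicRanges::GRanges(
      alignments$chrom[rows],
      IRanges::IRanges(start = alignments$sstart[rows],
                       end = alignments$send[rows]))
    within <- suppressWarnings(
      GenomicRanges::findOverlaps(hit, exGr, type = "within"))
    byProbe <- split(txOfExon[S4Vectors::subjectHits(within)],
                     S4Vectors::queryHits(within))
    covered <- which(as.character(seq_along(cand)) %in% names(byProbe))
    reason[cand[setdiff(seq_along(cand), covered)]] <- "outside_cds"
    for (j in covered) {
      txs <- sort(unique(byProbe[[as.character(j)]]))
      genes <- unique(geneOf[txs])
      if (length(genes) != 1 || anyNA(genes)) {
        reason[cand[j]] <- "multi_gene"
      } else {
        gene[cand[j]] <- genes
        txset[cand[j]] <- paste(txs, collapse = ",")
        reason[cand[j]] <- "clean"
      }
    }
  }
  keep <- reason == "clean"
  list(assignments = data.frame(probe_id = probes[keep],
                                gene_id = gene[keep],
                                transcripts = txset[keep],
                                stringsAsFactors = FALSE),
       log = data.frame(probe_id = probes, retained = keep, reason = reason,
                        stringsAsFactors = FALSE))
}

#' Build transcript-level probe sets
#'
#' Within each gene cluster, retained probes are grouped by the exact set of
#' transcripts whose exons contain them; every group with at least
#' \code{minProbes} probes becomes one probe set, so a gene with
#' transcript-specific exons can own several probe sets (transcript-level
#' resolution). Undersized groups are dropped and reported.
#'
#' @param assignments retained probe assignments from
#'   [filterProbeAlignments()]
#' @param minProbes minimum probes per probe set (default 3)
#' @return list with \code{probeSets} (probeset_id, gene_id,
#'   covered_transcripts, n_probes), \code{probeMap} (probe_id, probeset_id)
#'   and \code{dropped} (gene_id, covered_transcripts, n_probes)
#' @export
buildProbeSets <- function(assignments, minProbes = 3L) {
  if (minProbes < 1) stop("minProbes must be >= 1")
  key <- paste(assignments$gene_id, assignments$transcripts, sep = "\r")
  groups <- split(assignments, key)
  groups <- groups[order(names(groups))]
  ps <- list(); dropped <- list(); pm <- list()
  counter <- list()
  for (grp in groups) {
    gid <- grp$gene_id[1]
    if (nrow(grp) >= minProbes) {
      counter[[gid]] <- (counter[[gid]] %||% 0L) + 1L
      pid <- sprintf("%s_PS%d", gid, counter[[gid]])
      ps[[pid]] <- data.frame(probeset_id = pid, gene_id = gid,
                              covered_transcripts = grp$transcripts[1],
                              n_probes = nrow(grp), stringsAsFactors = FALSE)
      pm[[pid]] <- data.frame(probe_id = sort(grp$probe_id),
                              probeset_id = pid, stringsAsFactors = FALSE)
    } else {
      dropped[[length(dropped) + 1L]] <- data.frame(
        gene_id = gid, covered_transcripts = grp$transcripts[1],
        n_probes = nrow(grp), stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(gene_id = character(), covered_transcripts = character(),
                      n_probes = integer())
  list(probeSets = if (length(ps)) do.call(rbind, c(ps, make.row.names = FALSE))
                   else cbind(data.frame(probeset_id = character()), empty),
       probeMap = if (length(pm)) do.call(rbind, c(pm, make.row.names = FALSE))
                  else data.frame(probe_id = character(),
                                  probeset_id = character()),
       dropped = if (length(dropped))
         do.call(rbind, c(dropped, make.row.names = FALSE)) else empty)
}

#' Select the best human homolog per query under the 30/30 rule
#'
#' Keeps hits with at least 30% identity over at least 30% of the query
#' length (both boundaries inclusive; the length test is computed in integer
#' arithmetic, \code{10 * align_length >= 3 * query_length}, so exact
#' boundary hits are never lost to floating-point rounding), then returns
#' the highest-bitscore survivor per query (ties broken by lowest e-value,
#' then lexicographic subject id).
#'
#' @param hits data.frame with columns query_id, subject_id, pct_identity,
#'   align_length, query_length, bitscore, evalue
#' @param minIdentity,minLengthFrac filter thresholds (defaults 30 and 0.3)
#' @return data.frame of one best hit per surviving query, sorted by query
#' @export
filterHomologHits <- function(hits, minIdentity = 30, minLengthFrac = 0.3) {
  if (any(hits$query_length <= 0)) stop("query_length must be > 0")
  keep <- hits$pct_identity >= minIdentity &
    10 * hits$align_length >= round(minLengthFrac * 10) * hits$query_length
  hits <- hits[keep, , drop = FALSE]
  if (nrow(hits) == 0) return(hits)
  ord <- order(hits$query_id, -hits$bitscore, hits$evalue, hits$subject_id)
  hits <- hits[ord, , drop = FALSE]
  best <- hits[!duplicated(hits$query_id), , drop = FALSE]
  rownames(best) <- NULL
  best
}

#' Combine zebrafish and human annotation across a homolog map
#'
#' The output term-to-gene sets are the union of the zebrafish annotation
#' and the transferred human annotation: gene g gains term t whenever g's
#' best human homolog is annotated to t. Terms defined on both sides keep
#' the human metadata (name/namespace). Human terms to which no zebrafish
#' gene maps are dropped.
#'
#' @param zfCatalog \linkS4class{AnnotationCatalog} over zebrafish gene ids
#' @param humanCatalog \linkS4class{AnnotationCatalog} over human ids
#' @param homologMap data.frame (query_id, subject_id) as from
#'   [filterHomologHits()], or a named character vector
#' @param universe optional character vector of known zebrafish genes; map
#'   entries outside it are skipped with a warning
#' @return combined \linkS4class{AnnotationCatalog}
#' @export
combineAnnotations <- function(zfCatalog, humanCatalog, homologMap,
                               universe = NULL) {
  stopifnot(is(zfCatalog, "AnnotationCatalog"),
            is(humanCatalog, "AnnotationCatalog"))
  if (is.data.frame(homologMap))
    homologMap <- setNames(homologMap$subject_id, homologMap$query_id)
  if (!is.null(universe)) {
    bad <- setdiff(names(homologMap), universe)
    if (length(bad)) {
      warning("homolog map references ", length(bad),
              " unknown gene(s); skipped")
      homologMap <- homologMap[!names(homologMap) %in% bad]
    }
  }
  bySubject <- split(names(homologMap), unname(homologMap))
  zfTerms <- catalogTerms(zfCatalog); zfGenes <- catalogGenes(zfCatalog)
  huTerms <- catalogTerms(humanCatalog); huGenes <- catalogGenes(humanCatalog)
  transferred <- lapply(huGenes, function(subj)
    sort(unique(unlist(bySubject[subj], use.names = FALSE))))
  ids <- union(zfTerms$term_id, huTerms$term_id)
  genes <- lapply(ids, function(id)
    sort(unique(c(zfGenes[[id]], transferred[[id]]))))
  names(genes) <- ids
  meta <- rbind(huTerms, zfTerms[!zfTerms$term_id %in% huTerms$term_id, ])
  meta <- meta[match(ids, meta$term_id), ]
  nonEmpty <- lengths(genes) > 0
  annotationCatalog(meta$term_id[nonEmpty], meta$term_name[nonEmpty],
                    meta$namespace[nonEmpty], genes[nonEmpty])
}
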