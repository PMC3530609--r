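#' Simulate multi-database transcript annotation
#'
#' Builds a synthetic genome annotation with the redundancy structure of a
#' multi-source transcript collection: each true gene owns 1-3 transcript
#' models attributed to different source databases; transcripts of one gene
#' always share the gene's first coding exon (so coding-exon overlap connects
#' them), while exon complements and internal boundaries vary between models.
#' Genes never overlap each other. Genes with at least two transcripts carry
#' a private terminal exon on their first transcript, giving downstream
#' probe-set construction a transcript-level target.
#'
#' Coordinates are 0-based half-open internally; GFF3 export converts to
#' 1-based inclusive.
#'
#' @param config a \linkS4class{SimConfig}
#' @return list with elements \code{exons} (data.frame: transcript_id,
#'   source_db, chrom, strand, start, end, exon_rank), \code{geneMap}
#'   (data.frame: transcript_id, gene_id) giving the ground-truth clustering,
#'   and \code{genes} (data.frame: gene_id, chrom, strand, multi_ps,
#'   private_tx) used by the probe generator
#' @export
simulateAnnotation <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  withSeed(familySeed(config@seed, "annotation"), {
    nG <- config@nGenes
    dbs <- c("ensembl", "genbank", "refseq")
    cursor <- setNames(rep(1000L, config@nChromosomes),
                       paste0("chr", seq_len(config@nChromosomes)))
    exons <- vector("list", nG)
    geneMap <- vector("list", nG)
    genes <- vector("list", nG)
    for (g in seq_len(nG)) {
      gid <- sprintf("TG%04d", g)
      chrom <- sample(names(cursor), 1)
      strand <- sample(c("+", "-"), 1)
      nTx <- sample(seq(config@transcriptsPerGene[1],
                        config@transcriptsPerGene[2]), 1)
      nExon <- sample(2:4, 1)
      elen <- sample(120:300, nExon, replace = TRUE)
      ilen <- sample(200:500, nExon, replace = TRUE)  # gap before each exon
      estart <- cursor[[chrom]] + cumsum(ilen) + c(0L, cumsum(elen))[seq_len(nExon)]
      eend <- estart + elen
      multiPS <- nTx >= 2
      if (multiPS) {  # private exon of transcript 1, beyond the shared ones
        pstart <- eend[nExon] + 300L
        pend <- pstart + 150L
      } else {
        pstart <- pend <- NA_integer_
      }
      cursor[[chrom]] <- (if (multiPS) pend else eend[nExon]) +
        sample(5000:10000, 1)
      txl <- vector("list", nTx)
      for (j in seq_len(nTx)) {
        tid <- sprintf("%s.T%d", gid, j)
        keep <- c(TRUE, runif(nExon - 1) < 0.8)  # exon 1 always present
        s <- estart[keep]; e <- eend[keep]
        if (sum(keep) > 1) {  # jitter internal models inward, exon 1 fixed
          idx <- which(keep)[-1]
          pos <- seq_along(s)[-1]
          s[pos] <- s[pos] + sample(0:20, length(pos), replace = TRUE)
          e[pos] <- e[pos] - sample(0:20, length(pos), replace = TRUE)
        }
        if (multiPS && j == 1) {
          s <- c(s, pstart); e <- c(e, pend)
        }
        txl[[j]] <- data.frame(
          transcript_id = tid,
          source_db = sample(dbs, 1),
          chrom = chrom, strand = strand,
          start = as.integer(s), end = as.integer(e),
          exon_rank = seq_along(s),
          stringsAsFactors = FALSE)
      }
      exons[[g]] <- do.call(rbind, txl)
      geneMap[[g]] <- data.frame(
        transcript_id = vapply(txl, function(d) d$transcript_id[1], ""),
        gene_id = gid, stringsAsFactors = FALSE)
      genes[[g]] <- data.frame(
        gene_id = gid, chrom = chrom, strand = strand,
        multi_ps = multiPS,
        private_tx = if (multiPS) sprintf("%s.T1", gid) else NA_character_,
        stringsAsFactors = FALSE)
    }
    list(exons = do.call(rbind, exons),
         geneMap = do.call(rbind, geneMap),
         genes = do.call(rbind, genes))
  })
}

#' Write simulated annotation as one GFF3 file per source database
#'
#' @param annotation result of [simulateAnnotation()]
#' @param dir output directory (created if missing)
#' @return named character vector of written GFF3 paths (one per source db)
#' @export
writeAnnotationGFF3 <- function(annotation, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ex <- annotation$exons
  paths <- character()
  for (db in sort(unique(ex$source_db))) {
    sub <- ex[ex$source_db == db, , drop = FALSE]
    gr <- GenomicRanges::GRanges(
      seqnames = sub$chrom,
      ranges = IRanges::IRanges(start = sub$start + 1L, end = sub$end),
      strand = sub$strand)
    S4Vectors::mcols(gr)$type <- "CDS"
    S4Vectors::mcols(gr)$source <- db
    S4Vectors::mcols(gr)$phase <- 0L
    S4Vectors::mcols(gr)$Parent <- sub$transcript_id
    path <- file.path(dir, sprintf("annotation_%s.gff3", db))
    rtracklayer::export(gr, path, format = "gff3")
    paths[[db]] <- path
  }
  paths
}

#' Simulate probe-to-genome alignments
#'
#' Places 25-mer probes inside the coding exons of the simulated annotation.
#' Every gene receives one clean probe group in its shared first exon
#' (covering all of the gene's transcripts); genes with a private exon
#' receive a second group inside it (covering one transcript only). On top
#' of the clean probes, a fraction of genes gain one "problematic" probe:
#' multi-hit (two genomic hits), mismatched, intergenic, or spanning an
#' exon boundary; the intended filter outcome of every probe is recorded in
#' the ground truth.
#'
#' @param config a \linkS4class{SimConfig}
#' @param annotation result of [simulateAnnotation()]
#' @param fracProblematic fraction of genes receiving one problematic probe
#' @return list with \code{alignments} (BLAST-tabular-like data.frame:
#'   qseqid, chrom, pident, length, mismatch, sstart, send, strand,
#'   hit_count; sstart/send 1-based inclusive) and \code{truth} (data.frame:
#'   probe_id, gene_id, probeset_true, keep, reason)
#' @export
simulateProbeAlignments <- function(config, annotation, fracProblematic = 0.3) {
  stopifnot(is(config, "SimConfig"))
  ex <- annotation$exons
  if (nrow(ex) == 0) stop("annotation has no exons to place probes in")
  plen <- 25L
  withSeed(familySeed(config@seed, "probes"), {
    rows <- list(); truth <- list(); k <- 0L
    addProbe <- function(pid, chrom, start, strand, mism, hits, gid, psTrue,
                         keep, reason, startsExtra = integer()) {
      k <<- k + 1L
      starts <- c(start, startsExtra)
      rows[[k]] <<- data.frame(
        qseqid = pid, chrom = chrom,
        pident = 100 * (plen - mism) / plen, length = plen,
        mismatch = mism, sstart = as.integer(starts + 1L),
        send = as.integer(starts + plen), strand = strand,
        hit_count = hits, stringsAsFactors = FALSE)
      truth[[k]] <<- data.frame(probe_id = pid, gene_id = gid,
                                probeset_true = psTrue, keep = keep,
                                reason = reason, stringsAsFactors = FALSE)
    }
    for (g in seq_len(nrow(annotation$genes))) {
      ginfo <- annotation$genes[g, ]
      gid <- ginfo$gene_id
      gex <- ex[startsWith(ex$transcript_id, paste0(gid, ".")), ]
      # shared exon 1: identical across the gene's transcripts
      e1s <- min(gex$start[gex$exon_rank == 1])
      e1e <- min(gex$end[gex$exon_rank == 1])
      for (p in seq_len(config@nProbesPerProbeset)) {
        st <- sample(e1s:(e1e - plen), 1)
        addProbe(sprintf("%s_a%02d", gid, p), ginfo$chrom, st, ginfo$strand,
                 0L, 1L, gid, paste0(gid, ":all"), TRUE, "clean")
      }
      if (isTRUE(ginfo$multi_ps)) {
        ptx <- gex[gex$transcript_id == ginfo$private_tx, ]
        pe <- ptx[which.max(ptx$start), ]  # the private terminal exon
        for (p in seq_len(config@nProbesPerProbeset)) {
          st <- sample(pe$start:(pe$end - plen), 1)
          addProbe(sprintf("%s_b%02d", gid, p), ginfo$chrom, st, ginfo$strand,
                   0L, 1L, gid, paste0(gid, ":", ginfo$private_tx), TRUE, "clean")
        }
      }
      if (runif(1) < fracProblematic) {
        kind <- sample(c("multi", "mismatch", "intergenic", "spanning"), 1)
        pid <- sprintf("%s_x01", gid)
        if (kind == "multi") {
          other <- e1s + 2000000L  # far-away second genomic hit
          addProbe(pid, ginfo$chrom, e1s, ginfo$strand, 0L, 2L, gid, NA,
                   FALSE, "multi_hit", startsExtra = other)
        } else if (kind == "mismatch") {
          addProbe(pid, ginfo$chrom, e1s + 5L, ginfo$strand, 1L, 1L, gid, NA,
                   FALSE, "mismatch")
        } else if (kind == "intergenic") {
          addProbe(pid, ginfo$chrom, e1e + 50L, ginfo$strand, 0L, 1L, gid, NA,
                   FALSE, "outside_cds")
        } else {
          addProbe(pid, ginfo$chrom, e1e - 10L, ginfo$strand, 0L, 1L, gid, NA,
                   FALSE, "exon_boundary")
        }
      }
    }
    list(alignments = do.call(rbind, rows), truth = do.call(rbind, truth))
  })
}
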