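#' Write the full synthetic study to disk
#'
#' Runs every generator under the one seeded configuration and writes the
#' complete input set of the pipeline plus the ground-truth tables used by
#' recovery tests: per-source-database GFF3 annotation, the probe alignment
#' table, linear-scale intensities with sample metadata, zebrafish and
#' human GMT catalogs, homolog hits, human gene coordinates, disease loci,
#' per-larva activity traces, and one truth TSV per generated family.
#'
#' @param config a \linkS4class{SimConfig}
#' @param dir output directory (created)
#' @return named list of written file paths, invisibly; the \code{truth}
#'   attribute carries the in-memory ground truth
#' @export
simulateStudy <- function(config, dir) {
  stopifnot(is(config, "SimConfig"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  anno <- simulateAnnotation(config)
  gffPaths <- writeAnnotationGFF3(anno, dir)
  pa <- simulateProbeAlignments(config, anno)

  # expression on the intended probe sets, using the clean probes
  clean <- pa$truth[pa$truth$keep, ]
  psTab <- unique(data.frame(probeset_id = clean$probeset_true,
                             gene_id = clean$gene_id,
                             stringsAsFactors = FALSE))
  psTab <- psTab[order(psTab$probeset_id), ]
  probeTab <- data.frame(probe_id = clean$probe_id,
                         probeset_id = clean$probeset_true,
                         stringsAsFactors = FALSE)
  expr <- simulateExpression(config, probeSets = psTab, probes = probeTab)
  # problematic probes still sit on the array: background-only intensities
  badProbes <- pa$truth$probe_id[!pa$truth$keep]
  if (length(badProbes)) {
    bg <- withSeed(familySeed(config@seed, "expression") + 7L,
      2^(matrix(runif(length(badProbes) * nrow(expr$samples), 4, 12),
                length(badProbes))))
    rownames(bg) <- badProbes
    colnames(bg) <- colnames(expr$intensity)
    expr$intensity <- rbind(expr$intensity, bg)
  }
  deGenes <- unique(expr$truthProbesets$gene_id[expr$truthProbesets$de])
  fun <- simulateFunctionalAnnotation(
    config, genes = sort(unique(psTab$gene_id)), deGenes = deGenes,
    transcriptsOf = split(anno$geneMap$transcript_id, anno$geneMap$gene_id))
  beh <- simulateBehaviorTraces(config)

  p <- function(f) file.path(dir, f)
  writeTsv(anno$geneMap, p("truth_transcript_gene.tsv"))
  writeTsv(pa$alignments, p("probe_alignments.tsv"))
  writeTsv(pa$truth, p("truth_probes.tsv"))
  int <- data.frame(probe_id = rownames(expr$intensity),
                    expr$intensity, check.names = FALSE,
                    stringsAsFactors = FALSE)
  writeTsv(int, p("intensities.tsv"))
  writeTsv(expr$samples, p("samples.tsv"))
  writeTsv(expr$truthProbesets, p("truth_probesets.tsv"))
  writeTsv(expr$truthGenes, p("truth_genes.tsv"))
  writeGMT(fun$zfCatalog, p("annotation_zebrafish.gmt"))
  writeGMT(fun$humanCatalog, p("annotation_human.gmt"))
  writeTsv(fun$homologHits, p("homolog_hits.tsv"))
  writeTsv(fun$humanGeneCoords, p("human_gene_coords.bed"))
  writeTsv(fun$loci, p("disease_loci.tsv"))
  writeTsv(fun$truth$lociContainsDE, p("truth_loci.tsv"))
  writeTsv(data.frame(term_id = fun$truth$spikedTerm,
                      gene_id = fun$truth$spikedMembers,
                      stringsAsFactors = FALSE),
           p("truth_spiked_term.tsv"))
  writeTsv(data.frame(query_id = names(fun$truth$homologBest),
                      subject_id = unname(fun$truth$homologBest),
                      boundary = names(fun$truth$homologBest) %in%
                        fun$truth$homologBoundary,
                      stringsAsFactors = FALSE),
           p("truth_homologs.tsv"))
  write.csv(beh$traces, p("traces.csv"), row.names = FALSE, quote = FALSE)
  writeTsv(beh$truth, p("truth_bursts.tsv"))
  paths <- list(
    annotation = unname(gffPaths),
    alignments = p("probe_alignments.tsv"),
    intensities = p("intensities.tsv"),
    samples = p("samples.tsv"),
    zf_gmt = p("annotation_zebrafish.gmt"),
    human_gmt = p("annotation_human.gmt"),
    homologs = p("homolog_hits.tsv"),
    human_coords = p("human_gene_coords.bed"),
    loci = p("disease_loci.tsv"),
    traces = p("traces.csv"))
  attr(paths, "truth") <- list(annotation = anno, probes = pa$truth,
                               expression = expr[c("truthProbesets",
                                                   "truthGenes")],
                               functional = fun$truth, behavior = beh$truth)
  invisible(paths)
}

defaultThresholds <- function() {
  list(signal_floor = 6, q_cut = 0.05, fc_up = 1.5, fc_down = 0.67,
       si_gate = 1, min_identity = 30, min_length_frac = 0.3,
       min_probes = 3, ignore_strand = FALSE,
       settle = 1800, peak_window = 30, base_window = 30)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes re-annotation, differential expression, enrichment, disease
#' mapping and (when traces are supplied) the behaviour stage in order,
#' writes every artifact plus a run report and a manifest of input and
#' output checksums into the output directory. A rerun with identical
#' configuration and inputs reproduces byte-identical outputs.
#'
#' The configuration is a YAML file or an equivalent named list with either
#' a \code{simulate} block (arguments for [simConfig()]; inputs are then
#' generated into \code{<outdir>/inputs}) or an \code{inputs} block naming
#' the files listed by [simulateStudy()], plus \code{outdir},
#' optional \code{contrast} ("5v3", "4v3" or "5v4") and optional
#' \code{thresholds} overriding the defaults (signal_floor 6, q_cut 0.05,
#' fc_up 1.5, fc_down 0.67, si_gate 1, min_identity 30, min_length_frac
#' 0.3, min_probes 3).
#'
#' @param config path to a YAML config or a named list
#' @return named list of result tables, invisibly; files under
#'   \code{outdir}
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  outdir <- config$outdir %||% stop("config needs an outdir")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  th <- utils::modifyList(defaultThresholds(), config$thresholds %||% list())
  contrast <- strsplit(config$contrast %||% "5v3", "v")[[1]]

  if (!is.null(config$simulate)) {
    simArgs <- config$simulate
    cfg <- do.call(simConfig, simArgs)
    inputs <- stage("simulate", simulateStudy(cfg, file.path(outdir, "inputs")))
  } else {
    inputs <- config$inputs %||% stop("config needs simulate: or inputs:")
    missing <- setdiff(c("annotation", "alignments", "intensities", "samples",
                         "zf_gmt", "human_gmt", "homologs", "human_coords",
                         "loci"),
                       names(inputs))
    if (length(missing))
      stop("stage 'reannotate' failed: missing inputs: ",
           paste(missing, collapse = ", "))
  }
  for (f in unlist(inputs[!vapply(inputs, is.null, TRUE)]))
    if (!file.exists(f))
      stop("stage 'reannotate' failed: input file not found: ", f)

  ## reannotate
  exons <- stage("reannotate",
                 readTranscriptsGFF3(unlist(inputs$annotation)))
  clustering <- stage("reannotate",
                      clusterTranscripts(exons,
                                         ignoreStrand = th$ignore_strand))
  alignments <- stage("remap", readTsv(inputs$alignments))
  filt <- stage("remap", filterProbeAlignments(alignments, exons, clustering))
  psBuild <- stage("remap", buildProbeSets(filt$assignments,
                                           minProbes = th$min_probes))
  # homolog queries and zebrafish term members may be transcript accessions;
  # translate both into gene-cluster space before combining annotation
  txToGene <- setNames(clustering$map$gene_id, clustering$map$transcript_id)
  homologs <- stage("reannotate", {
    best <- filterHomologHits(readTsv(inputs$homologs),
                              minIdentity = th$min_identity,
                              minLengthFrac = th$min_length_frac)
    known <- best$query_id %in% names(txToGene)
    best$query_id[known] <- unname(txToGene[best$query_id[known]])
    ord <- order(best$query_id, -best$bitscore, best$evalue, best$subject_id)
    best <- best[ord, , drop = FALSE]
    best <- best[!duplicated(best$query_id), , drop = FALSE]
    rownames(best) <- NULL
    best
  })
  catalog <- stage("reannotate", {
    combineAnnotations(mapCatalogGenes(readGMT(inputs$zf_gmt), txToGene),
                       readGMT(inputs$human_gmt), homologs)
  })

  ## diffexpr
  geneMap <- psBuild$probeSets[, c("probeset_id", "gene_id")]
  de <- stage("diffexpr", {
    se <- readSignalMatrix(inputs$intensities, inputs$samples)
    se <- quantileNormalize(se)
    pse <- summarizeProbeSets(se, psBuild$probeMap, geneMap)
    fse <- lowSignalFilter(pse, threshold = th$signal_floor)
    res <- runModeratedDE(fse, contrast, th$q_cut, th$fc_up, th$fc_down)
    agg <- splicingIndexAggregate(fse, res, geneMap, contrast,
                                  siGate = th$si_gate, qCut = th$q_cut,
                                  fcUp = th$fc_up, fcDown = th$fc_down)
    dend <- hierarchicalClusterSamples(fse)
    list(filtered = fse, results = res, agg = agg, dend = dend,
         removed = S4Vectors::metadata(fse)$removed)
  })

  ## enrichment + disease mapping on gene-level calls
  enr <- stage("enrich", {
    gr <- de$agg$geneResults
    upGenes <- gr$gene_id[gr$status == "up"]
    downGenes <- gr$gene_id[gr$status == "down"]
    sp <- de$agg$splicedProbeSets
    if (nrow(sp)) {
      upGenes <- union(upGenes, sp$gene_id[sp$status == "up"])
      downGenes <- union(downGenes, sp$gene_id[sp$status == "down"])
    }
    universe <- sort(unique(geneMap$gene_id[
      geneMap$probeset_id %in% rownames(de$filtered)]))
    upGenes <- intersect(upGenes, universe)
    downGenes <- intersect(downGenes, universe)
    list(up = fisherEnrichment(upGenes, universe, catalog, th$q_cut),
         down = fisherEnrichment(downGenes, universe, catalog, th$q_cut),
         upGenes = upGenes, downGenes = downGenes, universe = universe)
  })
  disease <- stage("disease-map", {
    loci <- readTsv(inputs$loci)
    coords <- readTsv(inputs$human_coords)
    diseaseLocusCandidates(union(enr$upGenes, enr$downGenes), homologs,
                           coords, loci)
  })

  ## behaviour (optional)
  vmr <- NULL
  if (!is.null(inputs$traces)) {
    vmr <- stage("vmr", {
      traces <- if (grepl("\\.csv$", inputs$traces))
        read.csv(inputs$traces, stringsAsFactors = FALSE)
      else readTsv(inputs$traces)
      vmrSummaries(traces, settle = th$settle,
                   peakWindow = th$peak_window, baseWindow = th$base_window)
    })
  }

  ## artifacts
  p <- function(f) file.path(outdir, f)
  writeTsv(clustering$clusters, p("gene_clusters.tsv"))
  writeTsv(filt$log[order(filt$log$probe_id), ], p("probe_filter_log.tsv"))
  writeTsv(psBuild$probeSets, p("probe_sets.tsv"))
  writeTsv(homologs, p("homologs_best.tsv"))
  writeGMT(catalog, p("combined_catalog.gmt"))
  deTab <- de$results
  deTab$gene_id <- geneMap$gene_id[match(deTab$probeset_id,
                                         geneMap$probeset_id)]
  deTab <- deTab[order(deTab$probeset_id), ]
  writeTsv(deTab, p("de_probesets.tsv"))
  writeTsv(de$agg$summary[order(de$agg$summary$gene_id), ],
           p("gene_summary.tsv"))
  if (!is.null(de$agg$geneResults))
    writeTsv(de$agg$geneResults[order(de$agg$geneResults$gene_id), ],
             p("gene_results.tsv"))
  writeTsv(de$agg$splicedProbeSets, p("spliced_probesets.tsv"))
  writeDendrogramNewick(de$dend$hclust, p("dendrogram.nwk"))
  writeTsv(enr$up, p("enrichment_up.tsv"))
  writeTsv(enr$down, p("enrichment_down.tsv"))
  writeTsv(disease, p("disease_candidates.tsv"))
  if (!is.null(vmr)) writeTsv(vmr, p("vmr_summaries.tsv"))

  gr <- de$agg$geneResults
  report <- c(
    "retinomature run report",
    sprintf("contrast: %s vs %s dpf", contrast[1], contrast[2]),
    sprintf("transcripts: %d -> gene clusters: %d",
            length(unique(exons$transcript_id)), nrow(clustering$clusters)),
    sprintf("probes: %d -> retained: %d -> probe sets: %d",
            length(unique(alignments$qseqid)), nrow(filt$assignments),
            nrow(psBuild$probeSets)),
    sprintf("probe sets surviving signal filter: %d (removed %d)",
            nrow(de$filtered), length(de$removed)),
    sprintf("probe sets up: %d  down: %d",
            sum(deTab$status == "up"), sum(deTab$status == "down")),
    sprintf("genes aggregated: %d  splice-flagged: %d",
            sum(!de$agg$summary$splice_flag),
            sum(de$agg$summary$splice_flag)),
    sprintf("gene-level up: %d  down: %d",
            if (is.null(gr)) 0L else sum(gr$status == "up"),
            if (is.null(gr)) 0L else sum(gr$status == "down")),
    sprintf("enriched terms (q<%g): up %d  down %d", th$q_cut,
            sum(enr$up$significant), sum(enr$down$significant)),
    sprintf("disease loci with candidates: %d (candidate pairs: %d)",
            length(unique(disease$disease)), nrow(disease)),
    if (!is.null(vmr)) sprintf("larvae summarized: %d", nrow(vmr)))
  writeLines(report, p("report.txt"))

  outFiles <- sort(list.files(outdir, recursive = TRUE))
  outFiles <- setdiff(outFiles, "manifest.tsv")
  manifest <- data.frame(
    file = outFiles,
    md5 = unname(tools::md5sum(file.path(outdir, outFiles))),
    stringsAsFactors = FALSE)
  paramStr <- paste(sprintf("%s=%s", names(th),
                            vapply(th, format, "")), collapse = ";")
  manifest <- rbind(manifest,
                    data.frame(file = "(parameters)", md5 = paramStr))
  writeTsv(manifest, p("manifest.tsv"))

  invisible(list(clusters = clustering$clusters, probeSets = psBuild$probeSets,
                 de = deTab, geneSummary = de$agg$summary,
                 geneResults = de$agg$geneResults,
                 enrichmentUp = enr$up, enrichmentDown = enr$down,
                 disease = disease, vmr = vmr, report = report,
                 manifest = manifest))
}
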