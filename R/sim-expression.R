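#' Simulate a probe-level intensity dataset
#'
#' Generates log2-normal probe intensities with the structure the analysis
#' assumes: probe-set baselines drawn Uniform(4, 12) (or Uniform(2, 3.5) for
#' the low-signal fraction, which then stays below the maximal-log2 < 6
#' filter), a per-probe additive offset drawn once, a spiked stage effect
#' (full \code{log2fcDE} at 5 dpf, half at 4 dpf, with randomised sign per
#' gene) on the differentially expressed fraction, discordant +1.25/-1.25
#' spikes on the probe sets of splice-flagged multi-probe-set genes, and
#' Normal(0, \code{noiseSD}) log2 noise. Intensities are exported on the
#' linear scale; the pipeline takes logs.
#'
#' If no probe-set table is supplied a self-contained design is built:
#' \code{nProbesets} probe sets of which 20% are paired into two-probe-set
#' genes (the substrate for the Splicing-Index gate), the remainder being
#' single-probe-set genes.
#'
#' @param config a \linkS4class{SimConfig}
#' @param probeSets optional data.frame (probeset_id, gene_id); default built
#'   from \code{nProbesets}
#' @param probes optional data.frame (probe_id, probeset_id); default
#'   \code{nProbesPerProbeset} probes per probe set
#' @return list with \code{intensity} (linear-scale matrix, probes x
#'   samples), \code{samples} (sample_id, stage, replicate), \code{probes},
#'   \code{truthProbesets} (probeset_id, gene_id, true_log2fc, de,
#'   low_signal) and \code{truthGenes} (gene_id, splice_flag, n_probesets)
#' @export
simulateExpression <- function(config, probeSets = NULL, probes = NULL) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  withSeed(familySeed(config@seed, "expression"), {
    if (is.null(probeSets)) {
      nPS <- config@nProbesets
      nPair <- floor(nPS * 0.2 / 2)  # 20% of probe sets live in 2-PS genes
      gene <- character(nPS)
      if (nPair > 0) {
        gene[seq_len(2 * nPair)] <- rep(sprintf("SG%05d", seq_len(nPair)),
                                        each = 2)
      }
      if (2 * nPair < nPS)
        gene[(2 * nPair + 1):nPS] <-
          sprintf("SG%05d", nPair + seq_len(nPS - 2 * nPair))
      probeSets <- data.frame(probeset_id = sprintf("PS%05d", seq_len(nPS)),
                              gene_id = gene, stringsAsFactors = FALSE)
    }
    nPS <- nrow(probeSets)
    if (is.null(probes)) {
      probes <- data.frame(
        probe_id = sprintf("%s_p%02d",
                           rep(probeSets$probeset_id,
                               each = config@nProbesPerProbeset),
                           seq_len(config@nProbesPerProbeset)),
        probeset_id = rep(probeSets$probeset_id,
                          each = config@nProbesPerProbeset),
        stringsAsFactors = FALSE)
    }
    grp <- config@groups
    if (any(grp$n < 2)) stop("each stage needs >= 2 replicates")
    samples <- data.frame(
      sample_id = unlist(lapply(seq_len(nrow(grp)), function(i)
        sprintf("dpf%s_r%d", grp$stage[i], seq_len(grp$n[i])))),
      stage = rep(grp$stage, grp$n),
      replicate = unlist(lapply(grp$n, seq_len)),
      stringsAsFactors = FALSE)

    psPerGene <- table(probeSets$gene_id)
    multiGenes <- names(psPerGene)[psPerGene >= 2]
    nSplice <- round(config@fracSplice * length(multiGenes))
    spliceGenes <- if (nSplice > 0)
      sort(sample(multiGenes, nSplice)) else character()
    isSplicePS <- probeSets$gene_id %in% spliceGenes

    # low-signal probe sets: never the splice-spiked ones
    eligLow <- which(!isSplicePS)
    nLow <- round(config@fracLowSignal * nPS)
    lowIdx <- if (nLow > 0 && length(eligLow))
      sort(sample(eligLow, min(nLow, length(eligLow)))) else integer()
    low <- seq_len(nPS) %in% lowIdx

    # DE spiked at gene level so concordant multi-PS genes stay concordant
    eligGenes <- setdiff(unique(probeSets$gene_id[!low & !isSplicePS]),
                         unique(probeSets$gene_id[low]))
    nDEps <- round(config@fracDE * nPS)
    deGenes <- character(); cum <- 0L
    for (g in sample(eligGenes)) {
      if (cum >= nDEps) break
      deGenes <- c(deGenes, g)
      cum <- cum + psPerGene[[g]]
    }
    sign <- setNames(sample(c(-1, 1), length(deGenes), replace = TRUE), deGenes)

    trueFc <- numeric(nPS)
    trueFc[probeSets$gene_id %in% deGenes] <-
      config@log2fcDE * sign[probeSets$gene_id[probeSets$gene_id %in% deGenes]]
    for (g in spliceGenes) {  # discordant: SI magnitude 1.25 by construction
      idx <- which(probeSets$gene_id == g)
      trueFc[idx] <- rep(c(1.25, -1.25), length.out = length(idx))
    }

    baseline <- ifelse(low, runif(nPS, 2, 3.5), runif(nPS, 4, 12))
    offset <- runif(nrow(probes), -0.5, 0.5)  # one offset per probe
    psIdx <- match(probes$probeset_id, probeSets$probeset_id)
    if (anyNA(psIdx)) stop("probes reference unknown probe sets")
    stageEff <- function(stage) switch(stage, "5" = 1, "4" = 0.5, 0)
    eff <- vapply(samples$stage, stageEff, numeric(1))
    log2mat <- outer(baseline[psIdx] + offset, rep(0, nrow(samples)), `+`) +
      outer(trueFc[psIdx], eff) +
      if (config@noiseSD > 0)
        matrix(rnorm(nrow(probes) * nrow(samples), sd = config@noiseSD),
               nrow(probes)) else 0
    intensity <- 2^log2mat
    dimnames(intensity) <- list(probes$probe_id, samples$sample_id)

    truthGenes <- data.frame(
      gene_id = names(psPerGene),
      n_probesets = as.integer(psPerGene),
      splice_flag = names(psPerGene) %in% spliceGenes,
      stringsAsFactors = FALSE)
    truthGenes <- truthGenes[order(truthGenes$gene_id), ]
    list(intensity = intensity,
         samples = samples,
         probes = probes,
         truthProbesets = data.frame(
           probeset_id = probeSets$probeset_id,
           gene_id = probeSets$gene_id,
           true_log2fc = trueFc,
           de = trueFc != 0 & !isSplicePS,
           low_signal = low,
           stringsAsFactors = FALSE),
         truthGenes = truthGenes)
  })
}
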