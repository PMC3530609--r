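#' Simulation configuration
#'
#' Holds every parameter of the synthetic-data generator: the genomic layout
#' (chromosomes, genes, transcripts per gene), the array design (probes per
#' probe set, number of probe sets), the experimental design (developmental
#' stages and replicates; default 3/4/5 dpf with three biological replicates
#' each), the intensity model (baseline range, log2 noise, spiked fold
#' changes, discordant splice spikes, low-signal fraction), the functional
#' annotation spikes (term count, spiked pathway size and its DE fraction,
#' disease locus count), and the visual motor response protocol (30 min
#' settling followed by four cycles of 20 min light OFF / 20 min light ON,
#' i.e. four ON and four OFF transitions).
#'
#' @slot seed master RNG seed; per-output-family streams are derived from it
#' @slot nChromosomes,nGenes,transcriptsPerGene genomic layout;
#'   \code{transcriptsPerGene} is an inclusive integer range \code{c(min, max)}
#' @slot nProbesPerProbeset probes per probe set (Affymetrix-style, default 11)
#' @slot nProbesets probe sets for the design-free expression generator
#' @slot groups data.frame with columns \code{stage} and \code{n} (replicates)
#' @slot fracDE,log2fcDE fraction of probe sets with a true 5 vs 3 dpf effect
#'   and its log2 magnitude (sign randomised)
#' @slot noiseSD standard deviation of log2 intensity noise; 0 gives the
#'   deterministic zero-noise limit
#' @slot fracSplice fraction of multi-probe-set genes spiked with discordant
#'   probe-set fold changes (+/-1.25, i.e. Splicing Index magnitude 1.25)
#' @slot fracLowSignal fraction of probe sets drawn at low baseline so their
#'   maximal log2 intensity stays below the signal floor of 6
#' @slot nTerms,spikedPathwaySize,spikedPathwayDEFraction,locusCount
#'   functional-annotation generator parameters
#' @slot nLarvae,settleMinutes,phaseMinutes,nCycles,burstAmplitude,
#'   baselineRate,traceNoise visual motor response trace parameters;
#'   \code{traceNoise} is "poisson" or "none"
#' @seealso [simConfig()] for the validated constructor
#' @export
setClass("SimConfig", representation(
  seed = "integer",
  nChromosomes = "integer",
  nGenes = "integer",
  transcriptsPerGene = "integer",
  nProbesPerProbeset = "integer",
  nProbesets = "integer",
  groups = "data.frame",
  fracDE = "numeric",
  log2fcDE = "numeric",
  noiseSD = "numeric",
  fracSplice = "numeric",
  fracLowSignal = "numeric",
  nTerms = "integer",
  spikedPathwaySize = "integer",
  spikedPathwayDEFraction = "numeric",
  locusCount = "integer",
  nLarvae = "integer",
  settleMinutes = "integer",
  phaseMinutes = "integer",
  nCycles = "integer",
  burstAmplitude = "numeric",
  baselineRate = "numeric",
  traceNoise = "character"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  fr <- c(fracDE = object@fracDE, fracSplice = object@fracSplice,
          fracLowSignal = object@fracLowSignal,
          spikedPathwayDEFraction = object@spikedPathwayDEFraction)
  bad <- names(fr)[fr < 0 | fr > 1 | is.na(fr)]
  if (length(bad))
    msg <- c(msg, paste0("fractions must lie in [0,1]: ", paste(bad, collapse = ", ")))
  cnt <- c(nChromosomes = object@nChromosomes, nGenes = object@nGenes,
           nProbesPerProbeset = object@nProbesPerProbeset,
           nProbesets = object@nProbesets, nTerms = object@nTerms,
           spikedPathwaySize = object@spikedPathwaySize,
           locusCount = object@locusCount, nLarvae = object@nLarvae,
           settleMinutes = object@settleMinutes,
           phaseMinutes = object@phaseMinutes, nCycles = object@nCycles)
  bad <- names(cnt)[cnt < 1 | is.na(cnt)]
  if (length(bad))
    msg <- c(msg, paste0("counts must be >= 1: ", paste(bad, collapse = ", ")))
  if (length(object@transcriptsPerGene) != 2 ||
      any(object@transcriptsPerGene < 1) ||
      object@transcriptsPerGene[1] > object@transcriptsPerGene[2])
    msg <- c(msg, "transcriptsPerGene must be an increasing integer pair >= 1")
  if (is.na(object@noiseSD) || object@noiseSD < 0)
    msg <- c(msg, "noiseSD must be >= 0")
  if (!all(c("stage", "n") %in% names(object@groups)))
    msg <- c(msg, "groups needs columns stage and n")
  else if (any(object@groups$n < 2))
    msg <- c(msg, "each group needs >= 2 replicates (variance undefined below 2)")
  if (object@spikedPathwaySize > object@nGenes)
    msg <- c(msg, "spikedPathwaySize cannot exceed nGenes")
  if (!object@traceNoise %in% c("poisson", "none"))
    msg <- c(msg, "traceNoise must be 'poisson' or 'none'")
  if (object@baselineRate < 0 || object@burstAmplitude < 0)
    msg <- c(msg, "baselineRate and burstAmplitude must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Create a simulation configuration
#'
#' Defaults reproduce the study conditions the generator emulates: three
#' developmental stages (3, 4, 5 dpf) with three biological replicates each,
#' 11 probes per probe set, 2,000 probe sets of which 7.5% carry a true
#' |log2 fold change| of 1.5 between 5 and 3 dpf under log2 noise of sd 0.35,
#' a spiked 30-gene pathway with half its members differentially expressed,
#' and a locomotor protocol of 30 min settling plus four 20-min light ON/OFF
#' cycles.
#'
#' @param seed master seed (integer)
#' @param nChromosomes,nGenes,transcriptsPerGene,nProbesPerProbeset,nProbesets
#'   genomic and array layout (see [SimConfig-class])
#' @param groups data.frame of stage labels and replicate counts
#' @param fracDE,log2fcDE,noiseSD,fracSplice,fracLowSignal intensity model
#' @param nTerms,spikedPathwaySize,spikedPathwayDEFraction,locusCount
#'   functional-annotation generator
#' @param nLarvae,settleMinutes,phaseMinutes,nCycles,burstAmplitude,baselineRate,traceNoise
#'   behaviour-trace generator
#' @return a validated \linkS4class{SimConfig}
#' @examples
#' cfg <- simConfig(seed = 1, nGenes = 20)
#' simSeed(cfg)
#' @export
simConfig <- function(seed = 1L,
                      nChromosomes = 5L,
                      nGenes = 120L,
                      transcriptsPerGene = c(1L, 3L),
                      nProbesPerProbeset = 11L,
                      nProbesets = 2000L,
                      groups = data.frame(stage = c("3", "4", "5"), n = 3L),
                      fracDE = 0.075,
                      log2fcDE = 1.5,
                      noiseSD = 0.35,
                      fracSplice = 0.25,
                      fracLowSignal = 0.1,
                      nTerms = 50L,
                      spikedPathwaySize = 30L,
                      spikedPathwayDEFraction = 0.5,
                      locusCount = 12L,
                      nLarvae = 12L,
                      settleMinutes = 30L,
                      phaseMinutes = 20L,
                      nCycles = 4L,
                      burstAmplitude = 0.9,
                      baselineRate = 0.1,
                      traceNoise = "poisson") {
  groups$stage <- as.character(groups$stage)
  groups$n <- as.integer(groups$n)
  new("SimConfig",
      seed = as.integer(seed),
      nChromosomes = as.integer(nChromosomes),
      nGenes = as.integer(nGenes),
      transcriptsPerGene = as.integer(transcriptsPerGene),
      nProbesPerProbeset = as.integer(nProbesPerProbeset),
      nProbesets = as.integer(nProbesets),
      groups = groups,
      fracDE = fracDE, log2fcDE = log2fcDE, noiseSD = noiseSD,
      fracSplice = fracSplice, fracLowSignal = fracLowSignal,
      nTerms = as.integer(nTerms),
      spikedPathwaySize = as.integer(spikedPathwaySize),
      spikedPathwayDEFraction = spikedPathwayDEFraction,
      locusCount = as.integer(locusCount),
      nLarvae = as.integer(nLarvae),
      settleMinutes = as.integer(settleMinutes),
      phaseMinutes = as.integer(phaseMinutes),
      nCycles = as.integer(nCycles),
      burstAmplitude = burstAmplitude,
      baselineRate = baselineRate,
      traceNoise = traceNoise)
}

#' @describeIn simConfig accessor for the master seed
#' @param object,x a \code{SimConfig}
#' @export
simSeed <- function(object) object@seed

#' @describeIn simConfig accessor for the stage/replicate design
#' @export
simGroups <- function(object) object@groups

setMethod("show", "SimConfig", function(object) {
  g <- object@groups
  cat("SimConfig (seed ", object@seed, ")\n",
      "  genome: ", object@nGenes, " genes on ", object@nChromosomes,
      " chromosomes, ", object@transcriptsPerGene[1], "-",
      object@transcriptsPerGene[2], " transcripts/gene\n",
      "  array:  ", object@nProbesets, " probe sets x ",
      object@nProbesPerProbeset, " probes\n",
      "  design: ", paste(sprintf("%s dpf x%d", g$stage, g$n), collapse = ", "), "\n",
      "  effects: fracDE=", object@fracDE, " |log2FC|=", object@log2fcDE,
      " noiseSD=", object@noiseSD, "\n", sep = "")
})

#' Empirical-Bayes variance prior
#'
#' The scaled inverse-chi-square prior for gene-wise residual variances:
#' \code{d0} prior degrees of freedom (possibly infinite when the observed
#' variances show no excess dispersion) and prior variance \code{s0sq}.
#'
#' @slot d0 prior degrees of freedom, in (0, Inf]
#' @slot s0sq prior variance, > 0
#' @seealso [fitVariancePrior()]
#' @export
setClass("VariancePrior", representation(d0 = "numeric", s0sq = "numeric"))

setValidity("VariancePrior", function(object) {
  msg <- character()
  if (length(object@d0) != 1 || is.na(object@d0) || object@d0 <= 0)
    msg <- c(msg, "d0 must be a single value > 0 (Inf allowed)")
  if (length(object@s0sq) != 1 || is.na(object@s0sq) || object@s0sq <= 0)
    msg <- c(msg, "s0sq must be a single value > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a variance prior directly
#'
#' Mostly useful for the shrinkage-free limit \code{d0 = 0} is not allowed by
#' the class (the prior must carry positive df); pass \code{d0} close to zero
#' or use [moderatedTTest()] with \code{prior = NULL} for the ordinary pooled
#' t-test.
#'
#' @param d0 prior degrees of freedom (> 0 or Inf)
#' @param s0sq prior variance (> 0)
#' @return a \linkS4class{VariancePrior}
#' @export
variancePrior <- function(d0, s0sq) new("VariancePrior", d0 = d0, s0sq = s0sq)

#' @describeIn variancePrior prior degrees of freedom
#' @param object a \code{VariancePrior}
#' @export
priorDf <- function(object) object@d0

#' @describeIn variancePrior prior variance
#' @export
priorVar <- function(object) object@s0sq

setMethod("show", "VariancePrior", function(object) {
  cat("VariancePrior: d0 =", format(object@d0, digits = 4),
      ", s0^2 =", format(object@s0sq, digits = 4), "\n")
})
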