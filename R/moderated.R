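#' Invert the trigamma function
#'
#' Newton iteration on \code{trigamma(x) = y}, used by the variance-prior
#' moment estimator. Monotone decreasing, so the iteration converges from
#' the standard starting value.
#'
#' @param y positive values
#' @return x with trigamma(x) = y
#' @keywords internal
trigammaInverse <- function(y) {
  out <- rep(NA_real_, length(y))
  out[y > 1e7] <- 1 / sqrt(y[y > 1e7])
  out[y < 1e-6] <- 1 / y[y < 1e-6]
  todo <- which(is.na(out) & !is.na(y))
  x <- 0.5 + 1 / y[todo]
  for (iter in seq_len(50)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y[todo]) / psigamma(x, deriv = 2)
    x <- x + dif
    if (max(abs(dif / x)) < 1e-10) break
  }
  out[todo] <- x
  out
}

#' Estimate the empirical-Bayes variance prior
#'
#' Fits the scaled inverse-chi-square prior for residual variances by
#' moment matching on the log scale: with \eqn{z_g = \log s^2_g} and
#' residual df \eqn{d_g}, the centred values
#' \eqn{e_g = z_g - \psi(d_g/2) + \log(d_g/2)} have mean
#' \eqn{\log s_0^2 + \psi(d_0/2) - \log(d_0/2)} and excess variance
#' \eqn{\psi'(d_0/2)} beyond \eqn{\psi'(d_g/2)}. When the observed variance
#' of \eqn{e} does not exceed its theoretical minimum the prior df is
#' infinite and every posterior variance shrinks to the common value
#' \eqn{s_0^2 = \exp(\bar e)}.
#'
#' @param s2 per-row residual variances (values below 1e-10 are floored
#'   with a warning)
#' @param df residual degrees of freedom, scalar or per-row (>= 1)
#' @return a \linkS4class{VariancePrior}
#' @examples
#' fitVariancePrior(rchisq(100, 4) / 4, df = 4)
#' @export
fitVariancePrior <- function(s2, df) {
  if (length(s2) < 2) stop("need at least 2 residual variances")
  if (all(s2 == 0)) stop("all residual variances are zero; data degenerate")
  if (any(s2 < 1e-10)) {
    warning(sum(s2 < 1e-10), " near-zero variance(s) floored at 1e-10")
    s2 <- pmax(s2, 1e-10)
  }
  df <- rep_len(df, length(s2))
  if (any(df < 1)) stop("residual df must be >= 1")
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  excess <- var(e) - mean(trigamma(df / 2))
  if (is.na(excess) || excess <= 0)
    return(variancePrior(d0 = Inf, s0sq = exp(emean)))
  d0 <- 2 * trigammaInverse(excess)
  variancePrior(d0 = d0,
                s0sq = exp(emean + digamma(d0 / 2) - log(d0 / 2)))
}

#' Moderated two-sample t-test between developmental stages
#'
#' For every row, the log2 fold change is the difference of group means
#' (first listed stage minus second, default 5 dpf minus 3 dpf); the pooled
#' residual variance with \eqn{d_g = n_1 + n_2 - 2} df is shrunk toward the
#' prior, \eqn{\tilde s^2 = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g)}, and the
#' moderated t \eqn{= \mathrm{log2fc} / (\tilde s \sqrt{1/n_1 + 1/n_2})} is
#' referred to a t distribution on \eqn{d_0 + d_g} df (normal when
#' \eqn{d_0 = \infty}). With \code{prior = NULL} (\eqn{d_0 = 0}) this is
#' exactly the ordinary pooled two-sample t-test.
#'
#' @param se log2 SummarizedExperiment with stage metadata
#' @param stages length-2 character: (test stage, reference stage)
#' @param prior a \linkS4class{VariancePrior}, or NULL for no shrinkage
#' @return data.frame: probeset_id, one \code{mean_<stage>} column per stage
#'   present, log2fc, s2, t, df, p
#' @export
moderatedTTest <- function(se, stages = c("5", "3"), prior = NULL) {
  if (!signalIsLog2(se)) stop("moderatedTTest expects log2 values")
  st <- sampleStages(se)
  if (!all(stages %in% st))
    stop("stages absent from the data: ",
         paste(setdiff(stages, st), collapse = ", "))
  m <- signalValues(se)
  i1 <- which(st == stages[1]); i2 <- which(st == stages[2])
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2 || n2 < 2) stop("each compared group needs >= 2 replicates")
  mean1 <- rowMeans(m[, i1, drop = FALSE])
  mean2 <- rowMeans(m[, i2, drop = FALSE])
  ss1 <- rowSums((m[, i1, drop = FALSE] - mean1)^2)
  ss2 <- rowSums((m[, i2, drop = FALSE] - mean2)^2)
  dg <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / dg
  log2fc <- mean1 - mean2
  if (is.null(prior)) {
    d0 <- 0; s0 <- 0
  } else {
    stopifnot(is(prior, "VariancePrior"))
    d0 <- priorDf(prior); s0 <- priorVar(prior)
  }
  s2post <- if (is.infinite(d0)) rep(s0, length(s2))
            else (d0 * s0 + dg * s2) / (d0 + dg)
  tstat <- log2fc / sqrt(s2post * (1 / n1 + 1 / n2))
  dfTot <- d0 + dg
  p <- if (is.infinite(dfTot)) 2 * pnorm(-abs(tstat))
       else 2 * pt(-abs(tstat), df = dfTot)
  p[log2fc == 0] <- 1  # zero fold change is never evidence (0/0 guarded)
  tstat[log2fc == 0] <- 0
  res <- data.frame(probeset_id = rownames(m), stringsAsFactors = FALSE)
  for (s in unique(st))
    res[[paste0("mean_", s)]] <-
      rowMeans(m[, st == s, drop = FALSE])
  res$log2fc <- log2fc
  res$s2 <- s2
  res$t <- tstat
  res$df <- dfTot
  res$p <- p
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment:
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, capped at 1 and mapped back
#' to the input order.
#'
#' @param p p-values in [0, 1]
#' @return adjusted q-values in input order
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  p.adjust(p, method = "BH")
}

#' Call differential expression status
#'
#' A row is \code{up} iff q < \code{qCut} and linear fold change
#' \eqn{2^{\mathrm{log2fc}} \ge} \code{fcUp}; \code{down} iff q < \code{qCut}
#' and fold change \eqn{\le} \code{fcDown}; otherwise \code{ns}. Both the
#' significance and the fold-change condition are required jointly, and the
#' fold-change thresholds are interpreted on the linear scale exactly as
#' given (1.5 and 0.67 are deliberately asymmetric).
#'
#' @param results data.frame with columns log2fc and q
#' @param qCut adjusted-p threshold (default 0.05)
#' @param fcUp,fcDown linear fold-change thresholds (defaults 1.5 and 0.67)
#' @return \code{results} with a \code{status} column
#' @export
selectDE <- function(results, qCut = 0.05, fcUp = 1.5, fcDown = 0.67) {
  if (fcUp <= 1) stop("fcUp must be > 1")
  if (fcDown >= 1) stop("fcDown must be < 1")
  fc <- 2^results$log2fc
  status <- rep("ns", nrow(results))
  status[results$q < qCut & fc >= fcUp] <- "up"
  status[results$q < qCut & fc <= fcDown] <- "down"
  results$status <- status
  results
}

#' Run the probe-set-level differential expression stage
#'
#' Convenience wrapper: fit the variance prior on the filtered matrix, run
#' the moderated t-test for the requested contrast, adjust by
#' Benjamini-Hochberg and call status.
#'
#' @inheritParams moderatedTTest
#' @inheritParams selectDE
#' @return annotated results data.frame (with q and status)
#' @export
runModeratedDE <- function(se, stages = c("5", "3"), qCut = 0.05,
                           fcUp = 1.5, fcDown = 0.67) {
  st <- sampleStages(se)
  i1 <- which(st == stages[1]); i2 <- which(st == stages[2])
  m <- signalValues(se)
  dg <- length(i1) + length(i2) - 2
  mean1 <- rowMeans(m[, i1, drop = FALSE])
  mean2 <- rowMeans(m[, i2, drop = FALSE])
  s2 <- (rowSums((m[, i1, drop = FALSE] - mean1)^2) +
         rowSums((m[, i2, drop = FALSE] - mean2)^2)) / dg
  prior <- if (length(s2) >= 2) fitVariancePrior(s2, dg) else NULL
  res <- moderatedTTest(se, stages, prior)
  res$q <- bhAdjust(res$p)
  selectDE(res, qCut, fcUp, fcDown)
}

#' Splicing-Index-gated gene-level aggregation
#'
#' For each gene, the Splicing Index of probe set i is its log2 fold change
#' minus the gene's central (default median) probe-set log2 fold change.
#' Genes whose indices all lie within the gate \eqn{[-1, 1]} are aggregated:
#' their probe-set log2 expressions are averaged per sample and the
#' moderated test is re-run on the gene-level matrix, with q-values
#' recomputed by Benjamini-Hochberg over the gene-level set. Genes with any
#' index beyond the gate are flagged as candidate alternative splicing and
#' their probe sets reported separately. Single-probe-set genes have index 0
#' and are never flagged.
#'
#' @param se filtered log2 probe-set-level SummarizedExperiment
#' @param results probe-set DE table from [runModeratedDE()]
#' @param geneMap data.frame (probeset_id, gene_id)
#' @param stages contrast, as in [moderatedTTest()]
#' @param siGate gate half-width (default 1)
#' @param center "median" (default) or "mean" centring of the index
#' @param qCut,fcUp,fcDown status thresholds for the gene-level calls
#' @return list with \code{summary} (gene_id, n_probesets, si
#'   (semicolon-joined), splice_flag), \code{geneResults} (gene-level DE
#'   table for unflagged genes) and \code{splicedProbeSets} (probe-set rows
#'   of flagged genes)
#' @export
splicingIndexAggregate <- function(se, results, geneMap,
                                   stages = c("5", "3"), siGate = 1,
                                   center = c("median", "mean"),
                                   qCut = 0.05, fcUp = 1.5, fcDown = 0.67) {
  center <- match.arg(center)
  centerFun <- if (center == "median") median else mean
  gene <- geneMap$gene_id[match(results$probeset_id, geneMap$probeset_id)]
  if (anyNA(gene))
    stop("gene mapping missing for some probe sets")
  m <- signalValues(se)[results$probeset_id, , drop = FALSE]
  byGene <- split(seq_len(nrow(results)), gene)
  if (any(lengths(byGene) == 0)) stop("gene with zero probe sets")
  summary <- vector("list", length(byGene))
  agg <- list()
  flagged <- character()
  for (i in seq_along(byGene)) {
    g <- names(byGene)[i]
    idx <- byGene[[i]]
    fc <- results$log2fc[idx]
    si <- fc - centerFun(fc)
    flag <- any(abs(si) > siGate)
    summary[[i]] <- data.frame(
      gene_id = g, n_probesets = length(idx),
      si = paste(formatC(si, digits = 6, format = "g"), collapse = ";"),
      splice_flag = flag, stringsAsFactors = FALSE)
    if (flag) flagged <- c(flagged, g)
    else agg[[g]] <- colMeans(m[idx, , drop = FALSE])
  }
  summary <- do.call(rbind, summary)
  geneResults <- NULL
  if (length(agg)) {
    gm <- do.call(rbind, agg)
    gse <- signalMatrix(gm, as.data.frame(SummarizedExperiment::colData(se)),
                        log2 = TRUE)
    geneResults <- runModeratedDE(gse, stages, qCut, fcUp, fcDown)
    names(geneResults)[names(geneResults) == "probeset_id"] <- "gene_id"
  }
  spliced <- results[gene %in% flagged, , drop = FALSE]
  spliced$gene_id <- gene[gene %in% flagged]
  list(summary = summary, geneResults = geneResults,
       splicedProbeSets = spliced)
}
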