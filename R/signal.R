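#' Build a signal matrix
#'
#' Wraps an intensity matrix and its sample metadata in a
#' \link[SummarizedExperiment]{SummarizedExperiment} with a \code{log2}
#' flag in the metadata; all expression stages operate on this container.
#'
#' @param values numeric matrix, rows = probes or probe sets, columns =
#'   samples (no missing values)
#' @param samples data.frame with columns sample_id, stage, replicate;
#'   matched to the matrix columns by sample_id
#' @param log2 TRUE if values are already log2-transformed
#' @return a SummarizedExperiment with assay \code{exprs}
#' @export
signalMatrix <- function(values, samples, log2 = FALSE) {
  if (anyNA(values)) stop("signal matrix must not contain missing values")
  stopifnot(all(c("sample_id", "stage", "replicate") %in% names(samples)))
  m <- match(colnames(values), samples$sample_id)
  if (anyNA(m)) stop("sample metadata missing for: ",
                     paste(colnames(values)[is.na(m)], collapse = ", "))
  samples <- samples[m, , drop = FALSE]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values),
    colData = S4Vectors::DataFrame(samples, row.names = samples$sample_id))
  S4Vectors::metadata(se)$log2 <- log2
  se
}

#' Read a signal matrix from TSV files
#'
#' @param intensityPath TSV, first column probe ids, remaining columns one
#'   per sample (linear-scale intensities)
#' @param samplesPath TSV with columns sample_id, stage, replicate
#' @return a SummarizedExperiment as from [signalMatrix()]
#' @export
readSignalMatrix <- function(intensityPath, samplesPath) {
  tab <- readTsv(intensityPath)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  samples <- readTsv(samplesPath)
  samples$stage <- as.character(samples$stage)
  signalMatrix(m, samples, log2 = FALSE)
}

#' @rdname signalMatrix
#' @param se a SummarizedExperiment built by [signalMatrix()]
#' @export
signalValues <- function(se) SummarizedExperiment::assay(se, "exprs")

#' @rdname signalMatrix
#' @export
signalIsLog2 <- function(se) isTRUE(S4Vectors::metadata(se)$log2)

#' @rdname signalMatrix
#' @export
sampleStages <- function(se)
  as.character(SummarizedExperiment::colData(se)$stage)

#' Quantile-normalize a signal matrix
#'
#' Log2-transforms linear intensities and maps each column's sorted values
#' onto the mean sorted profile across columns; tied values within a column
#' receive the mean of their destination quantiles. After normalization
#' every column has an identical sorted value multiset, and re-applying the
#' transform is a no-op.
#'
#' @param se linear-scale SummarizedExperiment from [signalMatrix()]
#' @return log2 quantile-normalized SummarizedExperiment
#' @export
quantileNormalize <- function(se) {
  m <- signalValues(se)
  if (signalIsLog2(se)) stop("quantileNormalize expects linear intensities")
  bad <- which(m <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-positive intensity at row '%s', sample '%s'",
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
  norm <- limma::normalizeQuantiles(log2(m), ties = TRUE)
  dimnames(norm) <- dimnames(m)
  out <- signalMatrix(norm, as.data.frame(SummarizedExperiment::colData(se)),
                      log2 = TRUE)
  out
}

#' Summarize probe-level signal into probe-set expression
#'
#' Fits an additive two-way model to each probe set's probes-by-samples
#' log2 sub-matrix by median polish (at most 10 sweeps, tolerance 1e-6) and
#' reports the overall plus per-sample column effects, the RMA-style robust
#' summary that cancels probe-specific affinity offsets.
#'
#' @param se log2 probe-level SummarizedExperiment
#' @param probeMap data.frame (probe_id, probeset_id); every listed probe
#'   must be present, each in exactly one probe set
#' @param geneMap optional data.frame (probeset_id, gene_id) stored in the
#'   rowData of the result
#' @return probe-set-level log2 SummarizedExperiment, rows sorted by id
#' @export
summarizeProbeSets <- function(se, probeMap, geneMap = NULL) {
  if (!signalIsLog2(se)) stop("summarizeProbeSets expects log2 values")
  if (anyDuplicated(probeMap$probe_id))
    stop("a probe may belong to only one probe set")
  m <- signalValues(se)
  missing <- setdiff(probeMap$probe_id, rownames(m))
  if (length(missing))
    stop("probes absent from the matrix: ", paste(head(missing), collapse = ", "))
  ids <- sort(unique(probeMap$probeset_id))
  out <- matrix(NA_real_, length(ids), ncol(m),
                dimnames = list(ids, colnames(m)))
  byPs <- split(probeMap$probe_id, probeMap$probeset_id)
  for (ps in ids) {
    sub <- m[byPs[[ps]], , drop = FALSE]
    if (nrow(sub) == 0) stop("probe set with zero probes: ", ps)
    if (nrow(sub) == 1) {
      out[ps, ] <- sub[1, ]
    } else {
      # the 10-sweep cap is deliberate; the non-convergence warning is not
      mp <- suppressWarnings(
        medpolish(sub, maxiter = 10, eps = 1e-6, trace.iter = FALSE))
      out[ps, ] <- mp$overall + mp$col
    }
  }
  res <- signalMatrix(out, as.data.frame(SummarizedExperiment::colData(se)),
                      log2 = TRUE)
  if (!is.null(geneMap))
    SummarizedExperiment::rowData(res)$gene_id <-
      geneMap$gene_id[match(ids, geneMap$probeset_id)]
  res
}

#' Remove probe sets never detected above the signal floor
#'
#' A row is removed iff its maximal log2 intensity over all samples is
#' strictly below the threshold (default 6): rows reaching the floor in at
#' least one sample are kept.
#'
#' @param se log2 probe-set-level SummarizedExperiment
#' @param threshold log2 signal floor (default 6)
#' @return filtered SummarizedExperiment; removed row ids in
#'   \code{metadata(.)$removed}
#' @export
lowSignalFilter <- function(se, threshold = 6) {
  if (!signalIsLog2(se)) stop("lowSignalFilter expects log2 values")
  m <- signalValues(se)
  keep <- apply(m, 1, max) >= threshold
  out <- se[keep, ]
  S4Vectors::metadata(out)$removed <- rownames(m)[!keep]
  out
}
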