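#' Hierarchical clustering of samples on correlation distance
#'
#' Rows are z-scored (mean 0, sd 1; zero-variance rows are dropped and
#' reported), pairwise sample distance is 1 minus the Pearson correlation,
#' and samples are agglomerated by average linkage (UPGMA).
#'
#' @param se log2 SummarizedExperiment with >= 2 samples
#' @return list with \code{hclust} (the stats::hclust tree), \code{order}
#'   (sample ids in dendrogram order) and \code{dropped} (zero-variance row
#'   ids)
#' @export
hierarchicalClusterSamples <- function(se) {
  m <- signalValues(se)
  if (ncol(m) < 2) stop("need at least 2 samples to cluster")
  sds <- apply(m, 1, sd)
  dropped <- rownames(m)[sds == 0]
  if (length(dropped))
    message(length(dropped), " zero-variance row(s) dropped before z-scoring")
  m <- m[sds > 0, , drop = FALSE]
  z <- (m - rowMeans(m)) / apply(m, 1, sd)
  d <- as.dist(1 - cor(z))
  hc <- hclust(d, method = "average")
  list(hclust = hc, order = hc$labels[hc$order], dropped = dropped)
}

#' Write a dendrogram as Newick
#'
#' @param hc an \code{hclust} object (e.g. from
#'   [hierarchicalClusterSamples()])
#' @param path output file
#' @return the path, invisibly
#' @export
writeDendrogramNewick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
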