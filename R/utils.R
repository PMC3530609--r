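#' @importFrom methods new validObject is slotNames
#' @importFrom stats median p.adjust phyper pt pnorm rnorm rpois runif t.test
#'   wilcox.test cor hclust as.dist medpolish var sd setNames
#' @importFrom utils read.delim write.table head read.csv write.csv modifyList
NULL

# Run code under a temporary RNG state; the caller's stream is untouched.
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# One RNG stream per output family, all derived from the master seed, so
# regenerating one file family does not perturb the others.
familySeed <- function(seed, family) {
  offsets <- c(annotation = 101L, probes = 211L, expression = 307L,
               functional = 401L, behavior = 503L, pipeline = 601L)
  if (!family %in% names(offsets))
    stop("unknown RNG family: ", family)
  (as.integer(seed) %% 1000000L) * 1000L + offsets[[family]]
}

# Deterministic TSV writer: fixed quoting, ordering left to callers, no
# row names, 15 significant digits so reruns are byte-identical.
writeTsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 15, format = "g"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

readTsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
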