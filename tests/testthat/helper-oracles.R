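# Independent oracles used by the property and acceptance tests. Each is a
# deliberately naive implementation kept separate from the package code
# paths it checks.

# Step-up BH by direct min-over-suffix evaluation.
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m))
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

# Hypergeometric upper tail by direct mass summation.
hyperOracle <- function(k, K, n, N) {
  x <- k:min(K, n)
  sum(choose(K, x) * choose(N - K, n - x)) / choose(N, n)
}

# All-pairs overlap + union-find connected components over an exon table.
# Returns the partition as a sorted character vector of comma-joined
# member sets.
bruteClusters <- function(exons, ignoreStrand = FALSE) {
  ids <- sort(unique(exons$transcript_id))
  byTx <- split(exons, exons$transcript_id)[ids]
  parent <- seq_along(ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (a in seq_along(ids)) for (b in seq_len(a - 1L)) {
    ta <- byTx[[a]]; tb <- byTx[[b]]
    if (ta$chrom[1] != tb$chrom[1]) next
    if (!ignoreStrand && ta$strand[1] != tb$strand[1]) next
    hit <- FALSE
    for (i in seq_len(nrow(ta))) {
      if (any(ta$start[i] < tb$end & tb$start < ta$end[i])) { hit <- TRUE; break }
    }
    if (hit) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[ra] <- rb
    }
  }
  root <- vapply(seq_along(ids), find, 1L)
  sort(vapply(split(ids, root), function(s)
    paste(sort(s), collapse = ","), ""))
}

clusterPartition <- function(clustering) {
  sort(vapply(split(clustering$map$transcript_id, clustering$map$gene_id),
              function(s) paste(sort(s), collapse = ","), ""))
}

# Naive O(n^3) UPGMA: cluster distances recomputed as means of the original
# pairwise distances. Returns merge heights in merge order.
upgmaOracle <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    bestD <- Inf; bi <- bj <- NA
    for (i in seq_along(clusters)) for (j in seq_len(i - 1L)) {
      dd <- mean(d[clusters[[i]], clusters[[j]]])
      if (dd < bestD) { bestD <- dd; bi <- i; bj <- j }
    }
    heights <- c(heights, bestD)
    merged <- c(clusters[[bi]], clusters[[bj]])
    clusters <- clusters[-c(bi, bj)]
    clusters[[length(clusters) + 1L]] <- merged
  }
  heights
}

# Two-way median polish, coded from the algorithm description.
medpolishOracle <- function(x, maxiter = 10, eps = 1e-6) {
  z <- x
  t <- 0
  r <- numeric(nrow(x)); cc <- numeric(ncol(x))
  oldsum <- 0
  for (iter in seq_len(maxiter)) {
    rdelta <- apply(z, 1, median)
    z <- z - rdelta
    r <- r + rdelta
    delta <- median(cc)
    cc <- cc - delta
    t <- t + delta
    cdelta <- apply(z, 2, median)
    z <- sweep(z, 2, cdelta)
    cc <- cc + cdelta
    delta <- median(r)
    r <- r - delta
    t <- t + delta
    newsum <- sum(abs(z))
    if (newsum == 0 || abs(newsum - oldsum) < eps * newsum) break
    oldsum <- newsum
  }
  list(overall = t, row = r, col = cc)
}

# Exact two-sided Wilcoxon rank-sum p by full enumeration (no ties).
wilcoxEnum <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- combn(n1 + n2, n1)
  allRanks <- rank(seq_len(n1 + n2))
  us <- apply(sets, 2, function(s) sum(allRanks[s]) - n1 * (n1 + 1) / 2)
  if (u <= n1 * n2 / 2) min(1, 2 * mean(us <= u))
  else min(1, 2 * mean(us >= u))
}

# All permutations of 1..n (recursive).
allPerms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- allPerms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

# Small random exon tables for clustering property tests.
randomExonTable <- function(nTx, seed) {
  set.seed(seed)
  data.frame(
    transcript_id = sprintf("t%03d", seq_len(nTx)),
    chrom = sample(paste0("chr", 1:3), nTx, replace = TRUE),
    strand = sample(c("+", "-"), nTx, replace = TRUE),
    start = sample(1:2000, nTx, replace = TRUE),
    end = 0, stringsAsFactors = FALSE) -> ex
  ex$end <- ex$start + sample(50:400, nTx, replace = TRUE)
  ex
}
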