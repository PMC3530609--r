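test_that("hypergeometric enrichment p-values match hand calculations", {
  cat1 <- annotationCatalog(c("T1", "T2", "Tall"), c("t1", "t2", "all"),
                            c("KEGG", "KEGG", "GO_BP"),
                            list(letters[1:5], letters[6:10], letters[1:20]))
  res <- fisherEnrichment(letters[1:5], letters[1:20], cat1)
  p <- setNames(res$p, res$term_id)
  expect_equal(unname(p["T1"]), 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(unname(p["T2"]), 1)           # k = 0: upper tail from zero
  expect_equal(unname(p["Tall"]), 1)         # term covers the universe
  expect_equal(res$k[res$term_id == "Tall"], 5)
  expect_error(fisherEnrichment(c("zzz"), letters[1:20], cat1), "subset")
})

test_that("enrichment equals exhaustive mass summation and is monotone in n", {
  set.seed(12)
  for (i in 1:40) {
    N <- sample(10:60, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 hyperOracle(k, K, n, N), tolerance = 1e-12)
  }
  # growing the DE list with k fixed never decreases p
  N <- 50; K <- 10; k <- 3
  ps <- vapply(k:40, function(n) phyper(k - 1, K, N - K, n, lower.tail = FALSE), 1)
  expect_true(all(diff(ps) >= -1e-15))
})

test_that("q-values are adjusted within namespace and sorted by significance", {
  cat2 <- annotationCatalog(
    paste0("T", 1:4), paste0("t", 1:4), c("KEGG", "KEGG", "GO_BP", "GO_BP"),
    list(letters[1:5], letters[1:6], letters[1:5], letters[7:11]))
  res <- fisherEnrichment(letters[1:5], letters[1:20], cat2)
  for (ns in unique(res$namespace)) {
    sub <- res[res$namespace == ns, ]
    expect_equal(sub$q, bhOracle(sub$p)[order(order(sub$q, sub$p))],
                 tolerance = 1e-12)
  }
  expect_true(all(diff(res$q) >= 0))
})

test_that("the spiked pathway is recovered as the top enriched term", {
  genes <- sprintf("g%04d", 1:3000)
  cfg <- simConfig(seed = 23, nTerms = 50, spikedPathwaySize = 30,
                   spikedPathwayDEFraction = 0.5)
  de <- withr::with_seed(23, sample(genes, 300))
  fun <- simulateFunctionalAnnotation(cfg, genes, de)
  res <- fisherEnrichment(de, genes, fun$zfCatalog)
  expect_equal(res$term_id[1], "KEGG:SPIKE")
  expect_lt(res$q[1], 0.05)
  # spiked membership honours the configured DE fraction
  expect_equal(sum(fun$truth$spikedMembers %in% de), 15)
})

test_that("category counts use set semantics per gene and direction", {
  cat3 <- annotationCatalog(
    c("T1", "T2", "T3"), c("x", "y", "z"), c("GO_BP", "GO_BP", "GO_BP"),
    list(c("g1", "g2"), c("g1", "g3"), "g4"))
  cmap <- c(T1 = "vision", T2 = "vision", T3 = "stress")
  out <- goCategorySummary(deUp = c("g1", "g4"), deDown = "g9",
                           catalog = cat3, categoryMap = cmap)
  up <- out[out$direction == "up", ]
  expect_equal(up$count[up$category == "vision"], 1)   # g1 once, not twice
  expect_equal(up$count[up$category == "stress"], 1)
  down <- out[out$direction == "down", ]
  expect_equal(down$count[down$category == "other"], 1)  # unannotated g9
  zero <- goCategorySummary(character(), character(), cat3, cmap)
  expect_true(all(zero$count == 0))
})

test_that("cytoband ranges resolve to spanning intervals", {
  cb <- rbind(
    data.frame(chrom = "chr6", start = c(0, 100, 200, 300, 400),
               end = c(100, 200, 300, 400, 500),
               band = c("p12", "q14.1", "q14.3", "q16.1", "q16.2")),
    data.frame(chrom = "chrX", start = c(0, 50, 500, 600),
               end = c(50, 100, 600, 700),
               band = c("p22.1", "p11", "q27", "q28")))
  r <- suppressWarnings(
    resolveCytobands(c("6q14-q16.2", "Xp22", "Xq28-qter", "Xq26-q27", "17q"),
                     cb))
  expect_equal(r[r$locus == "6q14-q16.2", c("start", "end")],
               data.frame(start = 100, end = 500), ignore_attr = TRUE)
  expect_equal(r[r$locus == "Xp22", c("start", "end")],
               data.frame(start = 0, end = 50), ignore_attr = TRUE)
  expect_equal(r[r$locus == "Xq28-qter", c("start", "end")],
               data.frame(start = 600, end = 700), ignore_attr = TRUE)
  expect_true(is.na(r$start[r$locus == "Xq26-q27"]))  # q26 not in table
  expect_true(is.na(r$start[r$locus == "17q"]))       # chromosome missing
  expect_warning(resolveCytobands("6q99", cb), "unresolvable")
})

test_that("disease candidate mapping follows the any-overlap rule", {
  coords <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                       start = c(100, 900, 100), end = c(200, 1100, 200),
                       gene = c("H1", "H2", "H3"))
  map <- c(z1 = "H1", z2 = "H2", z3 = "H3")
  loci <- data.frame(disease = c("inside", "straddle", "elsewhere"),
                     omim_id = 1:3, chrom = c("chr1", "chr1", "chr3"),
                     start = c(0, 1000, 0), end = c(500, 2000, 5000))
  res <- diseaseLocusCandidates(c("z1", "z2", "z3"), map, coords, loci)
  expect_equal(res$gene_id[res$disease == "inside"], "z1")
  expect_equal(res$gene_id[res$disease == "straddle"], "z2")  # partial overlap
  expect_false("elsewhere" %in% res$disease)                  # wrong chrom
  # invariant to input order
  res2 <- diseaseLocusCandidates(c("z3", "z2", "z1"), map, coords,
                                 loci[c(3, 1, 2), ])
  expect_identical(res, res2)
  # loci without coordinates are skipped with a warning
  lociNA <- rbind(loci, data.frame(disease = "nocoord", omim_id = 4,
                                   chrom = NA, start = NA, end = NA))
  expect_warning(res3 <- diseaseLocusCandidates("z1", map, coords, lociNA),
                 "skipped")
  expect_equal(res3$gene_id, "z1")
})

test_that("GMT files round-trip with namespace metadata", {
  cat1 <- annotationCatalog(c("A", "B"), c("alpha", "beta"),
                            c("KEGG", "GO_MF"), list(c("g2", "g1"), "g3"))
  f <- withr::local_tempfile(fileext = ".gmt")
  writeGMT(cat1, f)
  back <- readGMT(f)
  expect_identical(catalogTerms(back), catalogTerms(cat1))
  expect_identical(catalogGenes(back), catalogGenes(cat1))
  expect_error(readGMT(withr::local_tempfile(lines = "onlyonefield")),
               "malformed")
  # member translation collapses duplicates and drops empty terms
  tr <- mapCatalogGenes(cat1, c(g1 = "G", g2 = "G"))
  expect_equal(catalogGenes(tr)[["A"]], "G")
})
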