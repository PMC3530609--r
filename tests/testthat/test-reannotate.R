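exonRow <- function(id, chrom, strand, start, end)
  data.frame(transcript_id = id, chrom = chrom, strand = strand,
             start = start, end = end, stringsAsFactors = FALSE)

test_that("transcripts chain into genes through transitive exon overlap", {
  ex <- rbind(exonRow("T1", "chr1", "+", 100, 200),
              exonRow("T2", "chr1", "+", 150, 250),
              exonRow("T3", "chr1", "+", 240, 300),
              exonRow("T4", "chr1", "-", 100, 200))
  cl <- clusterTranscripts(ex)
  expect_identical(unname(clusterPartition(cl)), c("T1,T2,T3", "T4"))
  # antisense overlap connects when strand is ignored
  cl2 <- clusterTranscripts(ex, ignoreStrand = TRUE)
  expect_identical(unname(clusterPartition(cl2)), "T1,T2,T3,T4")
  # different chromosomes never overlap
  ex2 <- rbind(exonRow("T1", "chr1", "+", 100, 200),
               exonRow("T5", "chr2", "+", 100, 200))
  expect_equal(nrow(clusterTranscripts(ex2)$clusters), 2)
  # singleton
  expect_equal(nrow(clusterTranscripts(exonRow("T9", "chr3", "+", 5, 9))$clusters), 1)
})

test_that("clustering validates input and partitions it deterministically", {
  expect_equal(nrow(clusterTranscripts(
    exonRow(character(), character(), character(), integer(), integer()))$clusters), 0)
  bad <- rbind(exonRow("T1", "chr1", "+", 100, 200),
               exonRow("T1", "chr2", "+", 100, 200))
  expect_error(clusterTranscripts(bad), "duplicate transcript_id")
  expect_error(clusterTranscripts(exonRow("T1", "chr1", "+", 200, 100)),
               "start < end")
  # permutation invariance and partition property on random instances
  for (s in 1:10) {
    ex <- randomExonTable(30, seed = 100 + s)
    cl <- clusterTranscripts(ex)
    expect_equal(nrow(cl$map), 30)        # partition: every transcript once
    expect_false(anyDuplicated(cl$map$transcript_id) > 0)
    perm <- ex[sample(nrow(ex)), ]
    expect_identical(clusterTranscripts(perm)$clusters, cl$clusters)
  }
})

test_that("clustering matches the brute-force connected-components oracle", {
  for (s in 1:30) {
    ex <- randomExonTable(sample(5:60, 1), seed = 200 + s)
    expect_identical(unname(clusterPartition(clusterTranscripts(ex))),
                     unname(bruteClusters(ex)), info = paste("seed", s))
    expect_identical(unname(clusterPartition(clusterTranscripts(ex, TRUE))),
                     unname(bruteClusters(ex, TRUE)))
  }
})

mkAlign <- function(probe, chrom, start, mism = 0, hits = 1, len = 25) {
  data.frame(qseqid = probe, chrom = chrom, pident = 100 * (len - mism) / len,
             length = len, mismatch = mism, sstart = start + 1, send = start + len,
             strand = "+", hit_count = hits, stringsAsFactors = FALSE)
}

test_that("probe filtering retains only perfect, unique, fully exonic, single-gene probes", {
  ex <- rbind(exonRow("T1", "chr1", "+", 1000, 1200),
              exonRow("T2", "chr1", "+", 1100, 1300),
              exonRow("T9", "chr2", "+", 1000, 1200))
  cl <- clusterTranscripts(ex)
  al <- rbind(mkAlign("pClean", "chr1", 1120),          # inside T1 and T2
              mkAlign("pOnlyT1", "chr1", 1010),         # inside T1 only
              mkAlign("pMism", "chr1", 1120, mism = 1),
              rbind(mkAlign("pMulti", "chr1", 1120, hits = 2),
                    mkAlign("pMulti", "chr2", 1010, hits = 2)),
              mkAlign("pSpan", "chr1", 1290),           # crosses T2 exon end
              mkAlign("pIntergenic", "chr1", 5000))
  res <- filterProbeAlignments(al, ex, cl)
  expect_setequal(res$assignments$probe_id, c("pClean", "pOnlyT1"))
  expect_equal(res$assignments$transcripts[res$assignments$probe_id == "pClean"],
               "T1,T2")
  expect_equal(res$assignments$transcripts[res$assignments$probe_id == "pOnlyT1"],
               "T1")
  lg <- setNames(res$log$reason, res$log$probe_id)
  expect_equal(unname(lg["pMism"]), "mismatch")
  expect_equal(unname(lg["pMulti"]), "multi_hit")
  expect_equal(unname(lg["pSpan"]), "outside_cds")
  expect_equal(unname(lg["pIntergenic"]), "outside_cds")
  expect_error(filterProbeAlignments(mkAlign("p", "chrX", 10), ex, cl),
               "unknown chromosome")
})

test_that("probe sets group by exact covered-transcript set with a size floor", {
  asn <- data.frame(
    probe_id = sprintf("p%02d", 1:16),
    gene_id = c(rep("G1", 14), "G2", "G2"),
    transcripts = c(rep("T1,T2", 11), rep("T1", 3), "T5", "T5"),
    stringsAsFactors = FALSE)
  ps <- buildProbeSets(asn, minProbes = 3)
  expect_equal(nrow(ps$probeSets), 2)  # G1 x2 groups kept, G2 group dropped
  expect_setequal(ps$probeSets$covered_transcripts, c("T1,T2", "T1"))
  expect_equal(sort(ps$probeSets$n_probes), c(3, 11))
  expect_equal(ps$dropped$n_probes, 2)
  expect_error(buildProbeSets(asn, minProbes = 0), "minProbes")
  # monotonicity: raising the floor never increases the number of probe sets
  set.seed(42)
  rnd <- data.frame(probe_id = sprintf("q%03d", 1:120),
                    gene_id = sample(sprintf("G%d", 1:8), 120, TRUE),
                    transcripts = sample(c("A", "A,B", "B"), 120, TRUE))
  counts <- vapply(1:6, function(k) nrow(buildProbeSets(rnd, k)$probeSets), 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("homolog filtering applies the inclusive 30/30 rule and best-hit tie-breaks", {
  hit <- function(q, s, pid, alen, qlen, bs, ev)
    data.frame(query_id = q, subject_id = s, pct_identity = pid,
               align_length = alen, query_length = qlen, bitscore = bs,
               evalue = ev, stringsAsFactors = FALSE)
  hits <- rbind(
    hit("g1", "hA", 30.0, 300, 1000, 200, 1e-20),   # exactly at both bounds
    hit("g2", "hB", 29.9, 900, 1000, 500, 1e-50),   # identity below
    hit("g3", "hC", 80, 299, 1000, 500, 1e-50),     # length below
    hit("g4", "hHi", 50, 500, 1000, 180, 1e-10),
    hit("g4", "hLo", 50, 500, 1000, 120, 1e-30),
    hit("g5", "hEv1", 50, 500, 1000, 150, 1e-30),
    hit("g5", "hEv2", 50, 500, 1000, 150, 1e-10),
    hit("g6", "hX", 50, 500, 1000, 150, 1e-10),
    hit("g6", "hY", 50, 500, 1000, 150, 1e-10))
  best <- filterHomologHits(hits)
  m <- setNames(best$subject_id, best$query_id)
  expect_equal(unname(m["g1"]), "hA")
  expect_false(any(c("g2", "g3") %in% names(m)))
  expect_equal(unname(m["g4"]), "hHi")   # highest bitscore wins
  expect_equal(unname(m["g5"]), "hEv1")  # lower e-value breaks ties
  expect_equal(unname(m["g6"]), "hX")    # then lexicographic subject
  expect_false(anyDuplicated(best$query_id) > 0)
  expect_true(all(best$pct_identity >= 30 &
                    10 * best$align_length >= 3 * best$query_length))
  expect_error(filterHomologHits(hit("g", "h", 50, 10, 0, 1, 1)),
               "query_length")
})

test_that("annotation combination unions zebrafish and transferred human terms", {
  zf <- annotationCatalog(c("GO:A", "GO:B"), c("a", "b"), c("GO_BP", "GO_BP"),
                          list(c("g1", "g2"), "g3"))
  hu <- annotationCatalog(c("GO:A", "HU:only"), c("a-human", "human only"),
                          c("GO_BP", "KEGG"),
                          list("h2", c("h1", "h9")))
  map <- c(g1 = "h1", g2 = "h2")
  comb <- combineAnnotations(zf, hu, map)
  cg <- catalogGenes(comb)
  expect_setequal(cg[["GO:A"]], c("g1", "g2"))  # union dedupes g2
  expect_setequal(cg[["HU:only"]], "g1")        # transferred via homolog
  expect_setequal(cg[["GO:B"]], "g3")           # no homolog: unchanged
  # human metadata wins for terms defined on both sides
  tm <- catalogTerms(comb)
  expect_equal(tm$term_name[tm$term_id == "GO:A"], "a-human")
  expect_warning(
    combineAnnotations(zf, hu, c(gX = "h1"), universe = c("g1", "g2", "g3")),
    "unknown gene")
})
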