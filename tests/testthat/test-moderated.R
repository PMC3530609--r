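mkSe <- function(m, stages) {
  sam <- data.frame(sample_id = colnames(m), stage = stages,
                    replicate = as.integer(ave(seq_along(stages),
                                               stages, FUN = seq_along)))
  signalMatrix(m, sam, log2 = TRUE)
}

test_that("zero-dispersion variances give an infinite-df prior", {
  d <- 4
  s2 <- rep(0.2, 50)
  pr <- fitVariancePrior(s2, d)
  expect_equal(priorDf(pr), Inf)
  expect_equal(priorVar(pr), 0.2 * exp(-digamma(d / 2) + log(d / 2)))
  # dispersed variances give a finite positive prior df
  pr2 <- fitVariancePrior(c(0.01, 0.01, 1, 1, 5), 4)
  expect_true(is.finite(priorDf(pr2)) && priorDf(pr2) > 0)
  expect_error(fitVariancePrior(c(0, 0, 0), 4), "zero")
  expect_error(fitVariancePrior(0.5, 4), "at least 2")
})

test_that("prior estimation recovers known hyperparameters and matches limma", {
  set.seed(31)
  d0 <- 4; s0 <- 0.04; dg <- 4; n <- 5000
  sigma2 <- s0 * d0 / rchisq(n, d0)          # scaled inverse chi-square
  s2 <- sigma2 * rchisq(n, dg) / dg
  pr <- fitVariancePrior(s2, dg)
  expect_lt(abs(priorDf(pr) - d0) / d0, 0.15)
  expect_lt(abs(priorVar(pr) - s0) / s0, 0.15)
  fd <- limma::fitFDist(s2, df1 = dg)
  expect_equal(priorDf(pr), fd$df2, tolerance = 1e-6)
  expect_equal(priorVar(pr), fd$scale, tolerance = 1e-6)
})

test_that("shrinkage-free moderated t reproduces the pooled two-sample t", {
  m <- rbind(x = c(1, 2, 3, 3, 4, 5))
  colnames(m) <- paste0("s", 1:6)
  se <- mkSe(m, c("3", "3", "3", "5", "5", "5"))
  res <- moderatedTTest(se, c("5", "3"), prior = NULL)
  expect_equal(res$log2fc, 2)
  expect_equal(res$s2, 1)
  expect_equal(res$t, 2 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(res$df, 4)
  expect_equal(res$p, 2 * pt(-sqrt(6), 4), tolerance = 1e-10)
  expect_equal(res$p, 0.0705, tolerance = 1e-3)
  tt <- t.test(c(3, 4, 5), c(1, 2, 3), var.equal = TRUE)
  expect_equal(res$p, tt$p.value, tolerance = 1e-12)
  # equal group means: t = 0, p = 1
  m0 <- rbind(x = c(1, 2, 3, 1, 2, 3))
  colnames(m0) <- paste0("s", 1:6)
  r0 <- moderatedTTest(mkSe(m0, c("3", "3", "3", "5", "5", "5")), c("5", "3"))
  expect_equal(r0$t, 0); expect_equal(r0$p, 1)
  # label swap flips t and keeps p
  sw <- moderatedTTest(se, c("3", "5"), prior = NULL)
  expect_equal(sw$t, -res$t); expect_equal(sw$p, res$p)
  expect_error(moderatedTTest(se[, 1:3], c("5", "3")), "absent")
})

test_that("the full moderated pipeline agrees with an independent limma fit", {
  set.seed(77)
  m <- matrix(rnorm(200 * 6, 8, 1), 200, 6,
              dimnames = list(sprintf("ps%03d", 1:200), paste0("s", 1:6)))
  stages <- c("3", "3", "3", "5", "5", "5")
  se <- mkSe(m, stages)
  res <- runModeratedDE(se)
  design <- cbind(1, stages == "5")
  fit <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(res$log2fc, unname(fit$coefficients[, 2]), tolerance = 1e-10)
  expect_equal(res$t, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(res$p, unname(fit$p.value[, 2]), tolerance = 1e-8)
  expect_equal(res$q, unname(p.adjust(fit$p.value[, 2], "BH")),
               tolerance = 1e-8)
  # moderated |t| grows with |log2fc| at fixed variance
  ord <- order(abs(res$log2fc))
  sameVar <- moderatedTTest(se, prior = variancePrior(1e6, mean(res$s2)))
  expect_true(all(diff(abs(sameVar$t[ord])) >= -1e-12))
})

test_that("BH adjustment matches the hand-derived step-up example", {
  expect_equal(bhAdjust(c(0.01, 0.04, 0.03, 0.005)),
               c(0.02, 0.04, 0.04, 0.02))
  expect_equal(bhAdjust(0.37), 0.37)
  expect_equal(bhAdjust(c(1, 1)), c(1, 1))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(5)
  for (i in 1:20) {
    p <- round(runif(sample(1:12, 1)), 3)
    expect_equal(bhAdjust(p), bhOracle(p), info = paste("case", i))
  }
})

test_that("DE status needs both the q cut and the asymmetric fold bounds", {
  res <- data.frame(log2fc = c(log2(1.5), log2(1.4), log2(3), log2(0.67),
                               log2(0.7), 0),
                    q = c(0.001, 0.001, 0.06, 0.001, 0.001, 0.001))
  out <- selectDE(res)
  expect_equal(out$status, c("up", "ns", "ns", "down", "ns", "ns"))
  expect_error(selectDE(res, fcUp = 0.9), "fcUp")
  expect_error(selectDE(res, fcDown = 1.2), "fcDown")
})

test_that("the splicing index gates aggregation at |SI| > 1", {
  stages <- c("3", "3", "3", "5", "5", "5")
  base <- c(8, 8, 8, 8, 8, 8)
  mk <- function(fc) base + c(0, 0, 0, fc, fc, fc)
  jit <- matrix(rnorm(5 * 6, 0, 1e-3), 5, 6)
  m <- rbind(ga_1 = mk(2), ga_2 = mk(1.5),      # si +/-0.25: aggregate
             gb_1 = mk(3), gb_2 = mk(0.5),      # si +/-1.25: flag
             gc_1 = mk(1)) + jit                # single probe set
  colnames(m) <- paste0("s", 1:6)
  se <- mkSe(m, stages)
  res <- runModeratedDE(se)
  gm <- data.frame(probeset_id = rownames(m),
                   gene_id = sub("_.*", "", rownames(m)))
  agg <- splicingIndexAggregate(se, res, gm)
  s <- agg$summary
  expect_equal(s$splice_flag[s$gene_id == "ga"], FALSE)
  expect_equal(s$splice_flag[s$gene_id == "gb"], TRUE)
  expect_equal(s$splice_flag[s$gene_id == "gc"], FALSE)
  siOf <- function(g) as.numeric(strsplit(s$si[s$gene_id == g], ";")[[1]])
  expect_equal(sort(siOf("ga")), c(-0.25, 0.25), tolerance = 1e-2)
  expect_equal(sort(siOf("gb")), c(-1.25, 1.25), tolerance = 1e-2)
  expect_equal(siOf("gc"), 0)
  # aggregated gene-level fold change is the mean of its probe sets
  gr <- agg$geneResults
  expect_equal(gr$log2fc[gr$gene_id == "ga"], 1.75, tolerance = 1e-2)
  # single-probe-set gene aggregates to the probe set itself
  expect_equal(gr$log2fc[gr$gene_id == "gc"],
               res$log2fc[res$probeset_id == "gc_1"], tolerance = 1e-12)
  # flagged gene's probe sets are reported separately
  expect_setequal(agg$splicedProbeSets$probeset_id, c("gb_1", "gb_2"))
})

test_that("splice gate recovers exactly the truth-flagged genes at low noise", {
  cfg <- simConfig(seed = 19, nProbesets = 300, noiseSD = 0.1,
                   fracLowSignal = 0)
  ex <- simulateExpression(cfg)
  # simulated arrays share one intensity scale, so the gate is evaluated on
  # plain log2 summaries; quantile normalization is exercised elsewhere
  se <- signalMatrix(log2(ex$intensity), ex$samples, log2 = TRUE)
  pse <- summarizeProbeSets(se, ex$probes)
  res <- runModeratedDE(pse)
  gm <- ex$truthProbesets[, c("probeset_id", "gene_id")]
  agg <- splicingIndexAggregate(pse, res, gm)
  truth <- ex$truthGenes
  merged <- merge(agg$summary, truth, by = "gene_id")
  expect_equal(merged$splice_flag.x, merged$splice_flag.y)
})
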