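flatTrace <- function(n = 4000, level = 0.1, settleOn = 1800, phase = 600) {
  states <- c("ON", rep(c("OFF", "ON"), 2))
  light <- rep(states, c(settleOn, rep(phase, 4)))[1:n]
  data.frame(larva_id = "L1", second = 0:(n - 1), activity = level,
             light_state = light, stringsAsFactors = FALSE)
}

test_that("sub-second activity integrates into conserving 1-second bins", {
  raw <- data.frame(time = c(0.0, 0.5, 1.0, 1.5),
                    activity = c(0.2, 0.2, 0.3, 0.1),
                    light_state = c("ON", "ON", "ON", "OFF"))
  out <- binActivity(raw)
  expect_equal(out$activity, c(0.4, 0.4))
  expect_equal(out$light_state, c("ON", "ON"))  # tie falls to bin start
  # 1 Hz input is the identity
  hz <- data.frame(time = 0:5, activity = 1:6, light_state = "ON")
  expect_equal(binActivity(hz)$activity, 1:6)
  # 10 Hz trace: binned total equals raw total
  set.seed(3)
  raw10 <- data.frame(time = seq(0, 59.9, by = 0.1),
                      activity = rexp(600), light_state = "OFF")
  expect_equal(sum(binActivity(raw10)$activity), sum(raw10$activity))
  expect_error(binActivity(data.frame(time = -1, activity = 1,
                                      light_state = "ON")), "negative")
})

test_that("peak extraction recovers flat traces and injected bursts", {
  tr <- flatTrace()
  s <- vmrPeaks(tr)
  expect_equal(s$on_peak, 0.1)
  expect_equal(s$off_peak, 0.1)
  expect_equal(s$norm_on, 1.0)
  expect_equal(s$norm_off, 1.0)
  # single injected ON burst of 0.9 over baseline 0.1
  tr2 <- flatTrace()
  onStart <- 1800 + 600  # first ON transition after settling
  tr2$activity[tr2$second == onStart] <- 0.9
  s2 <- vmrPeaks(tr2)
  expect_equal(s2$off_peak, 0.1)
  expect_equal(s2$norm_off, 1.0)
  # two ON transitions: peaks 0.9 and 0.1 average to 0.5
  expect_equal(s2$on_peak, 0.5)
  expect_equal(s2$norm_on, 5.0)
  # bursts at both ON transitions with amplitudes 0.8 and 1.0
  tr3 <- flatTrace()
  tr3$activity[tr3$second == onStart] <- 0.8
  tr3$activity[tr3$second == onStart + 1200] <- 1.0
  expect_equal(vmrPeaks(tr3)$on_peak, 0.9)
  expect_error(vmrPeaks(flatTrace(n = 1700)), "no light transitions")
})

test_that("peak extraction is translation- and scale-invariant", {
  tr <- flatTrace()
  tr$activity[tr$second == 2400] <- 0.9
  base <- vmrPeaks(tr)
  shift <- tr
  shift$second <- shift$second + 500
  shifted <- vmrPeaks(shift, settle = 1800 + 500)
  expect_equal(shifted[, c("on_peak", "off_peak", "norm_on", "norm_off")],
               base[, c("on_peak", "off_peak", "norm_on", "norm_off")])
  scaled <- tr
  scaled$activity <- scaled$activity * 7
  sc <- vmrPeaks(scaled)
  expect_equal(sc$on_peak, 7 * base$on_peak)
  expect_equal(sc$norm_on, base$norm_on)
  expect_equal(sc$norm_off, base$norm_off)
})

test_that("zero baselines are excluded from normalization, not made infinite", {
  tr <- flatTrace(level = 0)
  tr$activity[tr$second == 2400] <- 0.9
  s <- vmrPeaks(tr)
  expect_true(is.na(s$norm_on))
  expect_true(s$n_zero_baseline > 0)
})

test_that("group comparisons match exact Wilcoxon enumeration and Bonferroni", {
  d <- data.frame(larva_id = paste0("L", 1:6),
                  treatment = rep(c("ctrl", "drug"), each = 3),
                  norm_on = c(1, 2, 3, 4, 5, 6),
                  norm_off = c(6, 5, 4, 3, 2, 1))
  out <- groupCompare(d, metrics = c("norm_on", "norm_off"))
  expect_equal(out$p, c(0.1, 0.1))            # 2 / choose(6, 3)
  expect_equal(out$p_bonf, pmin(1, out$p * 2))
  expect_equal(out$direction, c("lower", "higher"))
  # identical groups: p = 1
  dEq <- data.frame(treatment = rep(c("a", "b"), each = 3),
                    norm_on = rep(c(1, 2, 3), 2))
  expect_equal(groupCompare(dEq, "norm_on")$p, 1)
  # exact test matches full enumeration for assorted small groups
  set.seed(8)
  for (i in 1:15) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    v <- sample(100, n1 + n2)  # distinct values: no ties
    dd <- data.frame(treatment = rep(c("a", "b"), c(n1, n2)), norm_on = v)
    expect_equal(groupCompare(dd, "norm_on")$p,
                 wilcoxEnum(v[1:n1], v[-(1:n1)]), tolerance = 1e-12,
                 info = paste("case", i))
  }
  # Welch variant needs two values per group
  expect_error(groupCompare(data.frame(treatment = c("a", "a", "b"),
                                       norm_on = c(1, 2, 3)),
                            "norm_on", method = "welch_t"), ">= 2")
  expect_equal(groupCompare(d, "norm_on", method = "welch_t")$p,
               t.test(1:3, 4:6)$p.value)
})

test_that("washout recovery reports direction and exact identity null", {
  pre <- data.frame(larva_id = paste0("L", 1:5), norm_on = c(2, 2.1, 1.9, 2, 2))
  post <- data.frame(larva_id = paste0("L", 1:5), norm_on = c(9, 9.2, 8.8, 9, 9.1))
  out <- recoveryCompare(pre, post, metrics = "norm_on")
  expect_equal(out$direction, "increase")
  expect_lt(out$p, 0.05)
  same <- recoveryCompare(pre, pre, metrics = "norm_on", paired = TRUE)
  expect_equal(same$p, 1)
  expect_equal(same$direction, "none")
  expect_error(recoveryCompare(pre, pre[0, ], metrics = "norm_on"), "nonempty")
})

test_that("simulated traces feed through the summary stage exactly", {
  cfg <- simConfig(seed = 41, nLarvae = 3, traceNoise = "none",
                   burstAmplitude = 0.9, baselineRate = 0.1)
  beh <- simulateBehaviorTraces(cfg)
  s <- vmrSummaries(beh$traces, settle = beh$protocol$settle_s)
  expect_equal(nrow(s), 3)
  expect_equal(s$on_peak, rep(0.9, 3))
  expect_equal(s$off_peak, rep(0.9, 3))
  expect_equal(s$norm_on, rep(9, 3))
  expect_equal(s$norm_off, rep(9, 3))
  expect_equal(s$n_on, rep(4, 3))
  expect_equal(s$n_off, rep(4, 3))
})
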