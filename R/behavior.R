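#' Integrate raw activity into 1-second bins
#'
#' Sums sub-second activity samples into whole-second bins (bin t covers
#' [t, t+1)) and downsamples the light-state channel by within-bin majority
#' (ties resolved toward the state at the bin start). Already 1 Hz input
#' passes through unchanged, and total activity is conserved.
#'
#' @param raw data.frame with columns time (seconds, nondecreasing,
#'   nonnegative), activity and light_state; optionally larva_id and
#'   treatment, which are carried through (binning is per larva)
#' @param bin bin width in seconds (default 1)
#' @return data.frame: (larva_id, treatment,) second, activity, light_state
#' @export
binActivity <- function(raw, bin = 1) {
  if (any(raw$time < 0)) stop("negative timestamps are not allowed")
  binOne <- function(d) {
    if (is.unsorted(d$time)) stop("timestamps must be nondecreasing")
    sec <- floor(d$time / bin) * bin
    act <- tapply(d$activity, sec, sum)
    light <- tapply(d$light_state, sec, function(s) {
      tab <- table(s)
      cand <- names(tab)[tab == max(tab)]
      if (length(cand) == 1) cand else s[1]
    })
    data.frame(second = as.numeric(names(act)),
               activity = as.numeric(act),
               light_state = as.character(light),
               stringsAsFactors = FALSE)
  }
  if ("larva_id" %in% names(raw)) {
    parts <- lapply(split(raw, raw$larva_id), function(d) {
      out <- binOne(d)
      out <- cbind(larva_id = d$larva_id[1], out, stringsAsFactors = FALSE)
      if ("treatment" %in% names(d)) out$treatment <- d$treatment[1]
      out
    })
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    out
  } else binOne(raw)
}

#' Extract and normalize visual motor response peaks
#'
#' Finds every light transition after the settling period; for each, the
#' peak is the maximal 1-s bin within \code{peakWindow} seconds after the
#' transition (the transition second included) and the baseline is the mean
#' activity over the \code{baseWindow} seconds before it. ON and OFF peaks
#' are averaged across that type's transitions (the study protocol yields
#' duplicate responses per type), and the normalized response is the mean
#' over transitions of peak / baseline — the fold increase in locomotor
#' activity after the light change. Transitions with a zero baseline are
#' excluded from the normalized value (reported as missing if none remain)
#' and counted.
#'
#' @param trace data.frame for one larva: second, activity, light_state
#'   (and optionally larva_id, treatment)
#' @param settle settling duration in seconds excluded from analysis
#'   (default 1800)
#' @param peakWindow,baseWindow window lengths in seconds (defaults 30)
#' @param peakStat "max" (default, the maximal bin) or "mean" (windowed
#'   mean)
#' @return one-row data.frame: larva_id, treatment, on_peak, off_peak,
#'   base_pre_on, base_pre_off, norm_on, norm_off, n_on, n_off,
#'   n_zero_baseline
#' @export
vmrPeaks <- function(trace, settle = 1800, peakWindow = 30, baseWindow = 30,
                     peakStat = c("max", "mean")) {
  peakStat <- match.arg(peakStat)
  stopifnot(all(c("second", "activity", "light_state") %in% names(trace)))
  if (any(trace$activity < 0)) stop("activity must be nonnegative")
  trace <- trace[order(trace$second), ]
  s <- trace$second
  ls <- trace$light_state
  trans <- which(ls[-1] != ls[-length(ls)]) + 1L  # first index of new state
  trans <- trans[s[trans] >= settle]
  if (!length(trans)) stop("no light transitions after the settling period")
  perTrans <- lapply(trans, function(i) {
    t0 <- s[i]
    pk <- trace$activity[s >= t0 & s < t0 + peakWindow]
    bs <- trace$activity[s >= t0 - baseWindow & s < t0]
    peak <- if (peakStat == "max") max(pk) else mean(pk)
    base <- if (length(bs)) mean(bs) else NA_real_
    data.frame(type = ls[i], peak = peak, base = base)
  })
  pt <- do.call(rbind, perTrans)
  one <- function(type) {
    d <- pt[pt$type == type, , drop = FALSE]
    if (!nrow(d)) return(c(peak = NA, base = NA, norm = NA, n = 0, zero = 0))
    ok <- !is.na(d$base) & d$base > 0
    c(peak = mean(d$peak), base = mean(d$base),
      norm = if (any(ok)) mean(d$peak[ok] / d$base[ok]) else NA_real_,
      n = nrow(d), zero = sum(!ok))
  }
  on <- one("ON"); off <- one("OFF")
  data.frame(larva_id = trace$larva_id[1] %||% NA_character_,
             treatment = if ("treatment" %in% names(trace))
               trace$treatment[1] else NA_character_,
             on_peak = on[["peak"]], off_peak = off[["peak"]],
             base_pre_on = on[["base"]], base_pre_off = off[["base"]],
             norm_on = on[["norm"]], norm_off = off[["norm"]],
             n_on = on[["n"]], n_off = off[["n"]],
             n_zero_baseline = on[["zero"]] + off[["zero"]],
             stringsAsFactors = FALSE)
}

#' Summarize all larvae of a trace table
#'
#' Applies [vmrPeaks()] per larva.
#'
#' @param traces data.frame with larva_id plus the [vmrPeaks()] columns
#' @inheritParams vmrPeaks
#' @return data.frame of one [vmrPeaks()] row per larva
#' @export
vmrSummaries <- function(traces, settle = 1800, peakWindow = 30,
                         baseWindow = 30, peakStat = "max") {
  out <- do.call(rbind, lapply(split(traces, traces$larva_id), vmrPeaks,
                               settle = settle, peakWindow = peakWindow,
                               baseWindow = baseWindow, peakStat = peakStat))
  rownames(out) <- NULL
  out
}

#' Compare treatment groups on VMR metrics
#'
#' Two-sided Wilcoxon rank-sum (exact null when the combined sample is at
#' most 20 without ties, normal approximation with tie correction
#' otherwise) or Welch two-sample t-test per metric, with Bonferroni
#' adjustment across the comparisons in the report. Missing metric values
#' (e.g. zero-baseline larvae) are dropped and counted.
#'
#' @param summaries data.frame of per-larva summaries with a grouping column
#' @param metrics metric column names to compare (each is one comparison)
#' @param group name of the grouping column (must have exactly 2 levels)
#' @param method "wilcoxon" (default) or "welch_t"
#' @return data.frame: metric, method, n1, n2, estimate1, estimate2,
#'   direction, p, p_bonf
#' @export
groupCompare <- function(summaries, metrics = c("norm_on", "norm_off"),
                         group = "treatment",
                         method = c("wilcoxon", "welch_t")) {
  method <- match.arg(method)
  g <- as.character(summaries[[group]])
  lev <- sort(unique(g))
  if (length(lev) != 2) stop("grouping column must have exactly 2 levels")
  m <- length(metrics)
  rows <- lapply(metrics, function(met) {
    x <- summaries[[met]][g == lev[1]]; x <- x[!is.na(x)]
    y <- summaries[[met]][g == lev[2]]; y <- y[!is.na(y)]
    if (!length(x) || !length(y)) stop("a group is empty for metric ", met)
    if (method == "welch_t") {
      if (length(x) < 2 || length(y) < 2)
        stop("welch_t needs >= 2 values per group")
      p <- t.test(x, y, var.equal = FALSE)$p.value
    } else {
      exact <- (length(x) + length(y)) <= 20 &&
        !anyDuplicated(c(x, y))
      p <- suppressWarnings(wilcox.test(x, y, exact = exact,
                                        correct = !exact)$p.value)
    }
    e1 <- median(x); e2 <- median(y)
    data.frame(metric = met, method = method,
               n1 = length(x), n2 = length(y),
               estimate1 = e1, estimate2 = e2,
               direction = if (e1 > e2) "higher" else if (e1 < e2) "lower"
                           else "equal",
               p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_bonf <- pmin(1, res$p * m)
  res
}

#' Compare pre-treatment and washed-out VMR summaries
#'
#' Applies the [groupCompare()] statistics to the pre vs post-washout
#' summaries (unpaired by default; \code{paired = TRUE} uses the paired
#' signed-rank / paired t variant on larvae present in both sets) and
#' reports the direction of change of each metric.
#'
#' @param pre,post data.frames of per-larva summaries
#' @param metrics metric columns to compare
#' @param method "wilcoxon" or "welch_t"
#' @param paired logical design flag
#' @return data.frame: metric, method, direction ("increase"/"decrease"/
#'   "none" for post relative to pre), p, p_bonf
#' @export
recoveryCompare <- function(pre, post, metrics = c("norm_on", "norm_off"),
                            method = c("wilcoxon", "welch_t"),
                            paired = FALSE) {
  method <- match.arg(method)
  if (!nrow(pre) || !nrow(post)) stop("both pre and post must be nonempty")
  m <- length(metrics)
  rows <- lapply(metrics, function(met) {
    if (paired) {
      common <- intersect(pre$larva_id, post$larva_id)
      x <- pre[[met]][match(common, pre$larva_id)]
      y <- post[[met]][match(common, post$larva_id)]
      ok <- !is.na(x) & !is.na(y); x <- x[ok]; y <- y[ok]
      if (!length(x)) stop("no paired observations for metric ", met)
      d <- y - x
      p <- if (method == "welch_t") t.test(y, x, paired = TRUE)$p.value
           else if (all(d == 0)) 1
           else suppressWarnings(
             wilcox.test(y, x, paired = TRUE,
                         exact = length(d) <= 20 &&
                           !anyDuplicated(abs(d[d != 0])))$p.value)
    } else {
      x <- pre[[met]]; x <- x[!is.na(x)]
      y <- post[[met]]; y <- y[!is.na(y)]
      p <- if (method == "welch_t") t.test(y, x, var.equal = FALSE)$p.value
           else suppressWarnings(
             wilcox.test(y, x,
                         exact = (length(x) + length(y)) <= 20 &&
                           !anyDuplicated(c(x, y)))$p.value)
    }
    delta <- mean(y) - mean(x)
    data.frame(metric = met, method = method,
               direction = if (delta > 0) "increase"
                           else if (delta < 0) "decrease" else "none",
               p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_bonf <- pmin(1, res$p * m)
  res
}
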