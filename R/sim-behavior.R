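#' Simulate visual motor response activity traces
#'
#' Per-larva 1 Hz locomotor traces under the standard protocol: a settling
#' period with lights on (default 30 min), then alternating 20-min light
#' OFF / light ON phases (default four cycles, giving four OFF and four ON
#' transitions). Baseline activity is Poisson with mean \code{baselineRate}
#' per second (or a constant \code{baselineRate} in the deterministic
#' \code{traceNoise = "none"} limit); the first second after every light
#' transition is set to \code{burstAmplitude} (when positive), emulating the
#' startle burst whose recovery the peak extractor is tested against.
#'
#' @param config a \linkS4class{SimConfig}
#' @return list with \code{traces} (data.frame: larva_id, treatment, second,
#'   activity, light_state), \code{protocol} (list: settle_s, phase_s,
#'   n_cycles) and \code{truth} (data.frame: larva_id, transition_type,
#'   second, amplitude)
#' @export
simulateBehaviorTraces <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  settle <- config@settleMinutes * 60L
  phase <- config@phaseMinutes * 60L
  states <- c("ON", rep(c("OFF", "ON"), config@nCycles))
  durs <- c(settle, rep(phase, 2L * config@nCycles))
  light <- rep(states, durs)
  n <- length(light)
  transIdx <- settle + phase * seq(0L, 2L * config@nCycles - 1L)  # 0-based s
  transType <- rep(c("OFF", "ON"), config@nCycles)
  withSeed(familySeed(config@seed, "behavior"), {
    traces <- vector("list", config@nLarvae)
    truth <- vector("list", config@nLarvae)
    for (i in seq_len(config@nLarvae)) {
      act <- if (config@traceNoise == "poisson")
        as.numeric(rpois(n, config@baselineRate))
      else rep(config@baselineRate, n)
      if (config@burstAmplitude > 0)
        act[transIdx + 1L] <- config@burstAmplitude
      lid <- sprintf("larva%02d", i)
      traces[[i]] <- data.frame(larva_id = lid, treatment = "control",
                                second = seq_len(n) - 1L, activity = act,
                                light_state = light, stringsAsFactors = FALSE)
      truth[[i]] <- data.frame(larva_id = lid, transition_type = transType,
                               second = transIdx,
                               amplitude = config@burstAmplitude,
                               stringsAsFactors = FALSE)
    }
    list(traces = do.call(rbind, traces),
         protocol = list(settle_s = settle, phase_s = phase,
                         n_cycles = config@nCycles),
         truth = do.call(rbind, truth))
  })
}
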