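#' Genotype-level rhythmicity call
#'
#' A genotype (its population-averaged periodogram) is called rhythmic —
#' labelled `"strong"` — when the periodogram has exactly one peak with
#' period between 16 and 32 h and that peak's power exceeds the p = 0.05
#' randomization significance line. Any other configuration (no in-window
#' peak, several peaks, or a sub-threshold peak) is `"arrhythmic"`; there is
#' no weak class at genotype level.
#'
#' @param pg a [Periodogram-class] carrying significance lines.
#' @param window period window in hours (default `c(16, 32)`).
#' @param level significance level whose line gates the call (default 0.05).
#' @param prominenceFrac peak prominence convention, see [findPeaks()].
#' @param subject label stored in the call.
#' @return a [RhythmCall-class].
#' @export
classifyGenotype <- function(pg, window = c(16, 32), level = 0.05,
                             prominenceFrac = 0.2, subject = "genotype") {
  stopIfNot1(length(pg@sigLines) > 0,
             "periodogram carries no significance lines")
  key <- as.character(level)
  stopIfNot1(key %in% names(pg@sigLines),
             "no significance line at level %s", key)
  pk <- findPeaks(pg, window, prominenceFrac)
  if (nrow(pk) == 0)
    return(arrhythmicCall(subject, "no in-window peak"))
  if (nrow(pk) > 1)
    return(arrhythmicCall(subject, "multiple peaks"))
  if (pk$power[1] <= pg@sigLines[[key]])
    return(arrhythmicCall(subject, sprintf("peak below the %s line", key)))
  est <- estimatePeriod(pg, window, prominenceFrac)
  new("RhythmCall", subject = subject, label = "strong",
      periodH = est$period_h, uncertaintyH = est$uncertainty_h,
      peakPower = est$power,
      ruleTrace = sprintf("single in-window peak above the %s line", key))
}

arrhythmicCall <- function(subject, trace) {
  new("RhythmCall", subject = subject, label = "arrhythmic",
      periodH = NA_real_, uncertaintyH = NA_real_, peakPower = NA_real_,
      ruleTrace = trace)
}

#' Individual-fly rhythmicity call
#'
#' A fly is `"strong"` if its own periodogram passes the genotype rule (one
#' peak in 16-32 h above the fly's own 0.05 shuffle line). Failing that, it
#' is `"weak"` if the periodogram shows exactly one peak with period between
#' 18 and 32 h and power larger than `weakPowerCutoff` (0.2 on the variance
#' normalization scale). Otherwise it is `"arrhythmic"`. Strong takes
#' precedence: a significant 17-h peak is strong even though 17 h lies
#' outside the weak window.
#'
#' @param pg the fly's [Periodogram-class], with its own significance lines.
#' @param strongWindow period window for the strong rule (default
#'   `c(16, 32)`).
#' @param weakWindow period window for the weak rule (default `c(18, 32)`).
#' @param weakPowerCutoff minimum power for a weak call (default 0.2).
#' @param level,prominenceFrac as in [classifyGenotype()].
#' @param subject label stored in the call (e.g. the fly id).
#' @return a [RhythmCall-class].
#' @export
classifyIndividual <- function(pg, strongWindow = c(16, 32),
                               weakWindow = c(18, 32),
                               weakPowerCutoff = 0.2, level = 0.05,
                               prominenceFrac = 0.2, subject = "fly") {
  strong <- classifyGenotype(pg, strongWindow, level, prominenceFrac, subject)
  if (strong@label == "strong") return(strong)
  pk <- findPeaks(pg, weakWindow, prominenceFrac)
  if (nrow(pk) == 1 && pk$power[1] > weakPowerCutoff) {
    est <- estimatePeriod(pg, weakWindow, prominenceFrac)
    return(new("RhythmCall", subject = subject, label = "weak",
               periodH = est$period_h, uncertaintyH = est$uncertainty_h,
               peakPower = est$power,
               ruleTrace = sprintf(
                 "single weak-window peak with power %.2f > %.2f",
                 pk$power[1], weakPowerCutoff)))
  }
  arrhythmicCall(subject, paste0("strong rule: ", strong@ruleTrace,
                                 "; weak rule not met"))
}

#' Fraction of rhythmic individuals
#'
#' Rhythmic = strong + weak; arrhythmic flies count only toward the total.
#'
#' @param calls list of [RhythmCall-class] objects (>= 1).
#' @return named numeric: `n_rhythmic`, `n_total`, `fraction`.
#' @examples
#' # 14 rhythmic of 20 -> 0.70
#' @export
percentRhythmic <- function(calls) {
  stopIfNot1(is.list(calls) && length(calls) >= 1, "need at least one call")
  labels <- vapply(calls, callLabel, "")
  nR <- sum(labels %in% c("strong", "weak"))
  c(n_rhythmic = nR, n_total = length(labels),
    fraction = nR / length(labels))
}
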