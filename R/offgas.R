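#' Molar volume of an ideal gas at 0 degC and 1 atm, mL/mmol
#' @export
MOLAR_VOLUME <- 22.414

#' Infer bioreactor outflow from the inert-gas balance
#'
#' Argon is inert, so its molar flow through the reactor is conserved:
#' `F_out = F_in * y_Ar,in / y_Ar,out`. This is the standard inversion that
#' turns measured off-gas mole fractions into molar outflow rates.
#'
#' @param inlet a [GasStream-class] feed (must contain Ar).
#' @param outletFractions named numeric off-gas mole fractions (must contain
#'   a positive Ar fraction).
#' @return Outflow in mL/min at reference conditions.
#' @examples
#' feed <- gasStream(72, c(CO = 0.5, H2 = 0.2, CO2 = 0.2, Ar = 0.1))
#' inferOutflow(feed, c(CO = 0.45, H2 = 0.15, CO2 = 0.275, Ar = 0.125))
#' @export
inferOutflow <- function(inlet, outletFractions) {
  yin <- inlet@fractions["Ar"]
  if (is.na(yin) || yin <= 0) stop("feed gas has no Ar: inert balance impossible")
  yout <- outletFractions["Ar"]
  if (is.na(yout) || yout <= 0) stop("inert species absent from off-gas")
  unname(inlet@flow * yin / yout)
}

#' Specific gas uptake or production rate from in/out molar flows
#'
#' `q = |F_in*y_in - F_out*y_out| * 60 / (molarVolume * volume * biomass)`,
#' in mmol/gDCW/h. The role is labelled `"uptake"` when the inflow exceeds
#' the outflow and `"production"` otherwise.
#'
#' @param inlet,outlet [GasStream-class] feed and off-gas streams (the outlet
#'   flow is typically obtained with [inferOutflow()]).
#' @param species species name present in the streams' fractions.
#' @param biomass gDCW/L (> 0).
#' @param volume working volume, L (> 0).
#' @param molarVolume mL/mmol, default [MOLAR_VOLUME].
#' @return list with `q` (positive magnitude) and `role`.
#' @export
specificGasRate <- function(inlet, outlet, species, biomass, volume,
                            molarVolume = MOLAR_VOLUME) {
  if (biomass <= 0) stop("biomass must be positive")
  if (volume <= 0) stop("volume must be positive")
  yin <- inlet@fractions[species]; yin[is.na(yin)] <- 0
  yout <- outlet@fractions[species]; yout[is.na(yout)] <- 0
  net <- inlet@flow * yin - outlet@flow * yout   # mL/min, + = consumed
  q <- abs(net) * 60 / (molarVolume * volume * biomass)
  list(q = unname(q), role = unname(ifelse(net > 0, "uptake", "production")))
}

#' Ethanol stripping rate from the off-gas
#'
#' Volatile ethanol leaves with the off-gas; its molar outflow normalised by
#' biomass gives a specific rate that must be added to the liquid-phase
#' ethanol production rate before carbon balancing (no ethanol enters with
#' the feed, so the inflow term is zero).
#'
#' @inheritParams specificGasRate
#' @param outlet a [GasStream-class]; a missing or zero ethanol fraction
#'   gives 0.
#' @return q_EtOH,gas in mmol/gDCW/h (production).
#' @export
ethanolStrippingRate <- function(outlet, biomass, volume,
                                 molarVolume = MOLAR_VOLUME) {
  if (biomass <= 0) stop("biomass must be positive")
  if (volume <= 0) stop("volume must be positive")
  y <- outlet@fractions["ethanol"]
  if (is.na(y)) y <- 0
  unname(outlet@flow * y * 60 / (molarVolume * volume * biomass))
}

#' Average an off-gas trace over its steady-state window
#'
#' Takes the final `window` hours of a trace, averages the mole fractions per
#' species, and flags the window stable when every species' coefficient of
#' variation is at or below `cvThreshold`. The default window of four
#' residence times reflects the usual practice of accepting a chemostat
#' steady state only after several working volumes of stable readings.
#'
#' @param trace data.frame with columns `time_h`, `species`, `mole_fraction`.
#' @param window hours to average over (counted back from the last sample).
#' @param cvThreshold per-species coefficient-of-variation limit.
#' @return list with `fractions` (named means), `cv` (named CVs) and
#'   `stable` (logical).
#' @export
steadyStateWindow <- function(trace, window = NULL, cvThreshold = 0.02) {
  if (nrow(trace) == 0) stop("empty off-gas trace")
  tmax <- max(trace$time_h)
  if (is.null(window)) window <- tmax - min(trace$time_h)
  keep <- trace$time_h >= tmax - window - 1e-9
  tr <- trace[keep, ]
  sp <- split(tr$mole_fraction, tr$species)
  fr <- vapply(sp, mean, numeric(1))
  cv <- vapply(sp, function(x)
    if (mean(x) == 0) 0 else stats::sd(x) / mean(x), numeric(1))
  cv[is.na(cv)] <- 0
  list(fractions = fr, cv = cv, stable = all(cv <= cvThreshold))
}

#' Specific rates for all measured gas species of one replicate
#'
#' Convenience wrapper: averages the trace, infers the outflow by the Ar
#' balance, and computes the specific rate and role of every measured gas
#' plus the ethanol stripping rate.
#'
#' @param inlet feed [GasStream-class].
#' @param trace off-gas trace data.frame (see [steadyStateWindow()]).
#' @param biomass gDCW/L; @param volume L.
#' @param window,cvThreshold passed to [steadyStateWindow()].
#' @param molarVolume mL/mmol.
#' @return list with `q` (named magnitudes for CO, H2, CO2), `role`,
#'   `ethanolStripping`, `outflow`, `stable`.
#' @export
offgasRates <- function(inlet, trace, biomass, volume = 0.75,
                        window = NULL, cvThreshold = 0.02,
                        molarVolume = MOLAR_VOLUME) {
  win <- steadyStateWindow(trace, window, cvThreshold)
  # renormalise the measured fractions over the monitored species; the
  # inert-balance products F_out * y_i are invariant under joint rescaling
  fr <- win$fractions / sum(win$fractions)
  fout <- inferOutflow(inlet, fr)
  outlet <- gasStream(fout, fr)
  species <- intersect(c("CO", "H2", "CO2"), names(win$fractions))
  q <- numeric(0); role <- character(0)
  for (s in species) {
    r <- specificGasRate(inlet, outlet, s, biomass, volume, molarVolume)
    q[s] <- r$q; role[s] <- r$role
  }
  list(q = q, role = role,
       ethanolStripping = ethanolStrippingRate(outlet, biomass, volume,
                                               molarVolume),
       outflow = fout, stable = win$stable)
}
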