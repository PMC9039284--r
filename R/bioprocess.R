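#' Carbon counts of the balanced species
#'
#' Carbon atoms per mole of each compound entering the C-mol balance, plus
#' the biomass carbon content parameter (C-mol per gDCW; default 0.0417,
#' i.e. 24 g biomass per C-mol for a generic CH1.8O0.5N0.2 composition).
#'
#' @param biomassCarbon C-mol per gDCW.
#' @return Named list with `counts` (atoms per mole) and `biomassCarbon`.
#' @export
speciesCarbon <- function(biomassCarbon = 0.0417) {
  list(counts = c(CO = 1, CO2 = 1, acetate = 2, ethanol = 2, BDO = 4,
                  cysteine = 3),
       biomassCarbon = biomassCarbon)
}

#' Biomass concentration from optical density
#'
#' `X = K * OD600` with the OD-to-dry-cell-weight correlation coefficient
#' K = 0.23 gDCW/L per OD unit (strain-specific calibration).
#'
#' @param od600 optical density at 600 nm (>= 0).
#' @param k correlation coefficient, gDCW/L per OD unit.
#' @return Biomass concentration, gDCW/L.
#' @examples
#' biomassFromOD(6.87)   # 1.58 gDCW/L
#' @export
biomassFromOD <- function(od600, k = 0.23) {
  if (any(od600 < 0)) stop("negative OD")
  k * od600
}

#' Liquid-phase specific production rate at steady state
#'
#' In a chemostat at steady state a dissolved product at concentration `c`
#' (mM) leaves with the liquid outflow, so `q = (D/24) * c / X` in
#' mmol/gDCW/h (D in 1/day). For ethanol the gas-stripped flux measured by
#' [ethanolStrippingRate()] is added back so `q` is the total production rate.
#'
#' @param conc concentration in broth, mM.
#' @param dilution dilution rate, 1/day (> 0).
#' @param biomass gDCW/L (> 0).
#' @param strippedQ gas-stripped specific rate to add, mmol/gDCW/h
#'   (only meaningful for ethanol; default 0).
#' @return q in mmol/gDCW/h.
#' @examples
#' liquidSpecificRate(48, 2.4, 1.5)   # 3.2
#' @export
liquidSpecificRate <- function(conc, dilution, biomass, strippedQ = 0) {
  if (dilution <= 0) stop("dilution must be positive")
  if (biomass <= 0) stop("biomass must be positive")
  (dilution / 24) * conc / biomass + strippedQ
}

#' Dissolved-CO2 outflow rate in the liquid phase
#'
#' Dissolved CO2 follows Henry's law, `CO2* = K_H * pCO2`, and carries a
#' bicarbonate fraction `HCO3- = CO2* * 10^(pH - pKa1)`. The total soluble
#' CO2 exits with the liquid outflow at `(D/24) * c_total / X`. At the
#' cultivation pH of ~5 the bicarbonate correction is minor
#' (10^(5 - 6.30) ~ 5% of CO2*).
#'
#' @param pH broth pH (0 < pH < 14).
#' @param temperatureC broth temperature, degC (documentation only; the
#'   default constants are 37 degC values).
#' @param pCO2 CO2 partial pressure over the broth, atm.
#' @param dilution 1/day; @param biomass gDCW/L.
#' @param kH Henry constant, M/atm (default 0.0246 at 37 degC).
#' @param pKa1 first carbonic-acid pKa (default 6.30 at 37 degC).
#' @return q_CO2,liquid in mmol/gDCW/h.
#' @examples
#' dissolvedCO2Rate(5, 37, 0.2, 2.4, 1.5)   # ~0.34
#' @export
dissolvedCO2Rate <- function(pH, temperatureC = 37, pCO2, dilution, biomass,
                             kH = 0.0246, pKa1 = 6.30) {
  if (pH <= 0 || pH >= 14) stop("pH must lie in (0, 14)")
  cstar <- kH * pCO2                      # M
  ctot_mM <- cstar * (1 + 10^(pH - pKa1)) * 1000
  liquidSpecificRate(ctot_mM, dilution, biomass)
}

#' C-mol carbon balance of one steady state
#'
#' Distributes substrate carbon (CO, plus cysteine when fed) over the growth
#' products acetate, ethanol, 2,3-butanediol, CO2 and biomass, as C-mol
#' fractions of the total C-mol substrate uptake. The biomass term is
#' `(mu/24) * biomassCarbon * 1000` mmol C/gDCW/h. Recovery is the summed
#' product fraction in percent; `normalised` rescales the fractions to sum to
#' exactly 100% so carbon distributions are comparable across conditions.
#'
#' @param panel a [RatePanel-class] whose rates already include the
#'   stripping-corrected ethanol rate and (if desired) the dissolved-CO2
#'   term added to the CO2 production rate.
#' @param qCysteine cysteine uptake, mmol/gDCW/h (default 0).
#' @param carbon list from [speciesCarbon()].
#' @return A [CarbonBalance-class].
#' @export
carbonBalance <- function(panel, qCysteine = 0, carbon = speciesCarbon()) {
  cnt <- carbon$counts
  upt <- panel@q[panel@role[names(panel@q)] == "uptake"]
  denom <- sum(upt[intersect(names(upt), "CO")] * cnt["CO"]) +
    qCysteine * cnt["cysteine"]
  if (!is.finite(denom) || denom <= 0)
    stop("zero substrate carbon uptake: balance undefined")
  prod <- panel@q[panel@role[names(panel@q)] == "production"]
  prods <- intersect(c("acetate", "ethanol", "BDO", "CO2"), names(prod))
  fr <- setNames(prod[prods] * cnt[prods] / denom, prods)
  fr["biomass"] <- (panel@mu / 24) * carbon$biomassCarbon * 1000 / denom
  rec <- sum(fr) * 100
  new("CarbonBalance", fractions = fr, recovery = rec,
      normalised = fr / sum(fr) * 100)
}

#' Molar acetate-to-ethanol product ratio
#'
#' @param qAcetate,qEthanol specific rates, mmol/gDCW/h; `qEthanol` must be
#'   positive.
#' @return qAcetate / qEthanol.
#' @export
productRatio <- function(qAcetate, qEthanol) {
  if (qEthanol <= 0) stop("undefined ratio: ethanol rate is zero")
  qAcetate / qEthanol
}

#' Fold changes of specific rates between the extreme growth rates
#'
#' For a set of replicate [RatePanel-class] objects spanning two or more mu
#' levels, computes the ratio of condition means, highest mu over lowest mu,
#' per species. `fold_rounded` carries the one-decimal presentation used when
#' quoting rate fold-changes.
#'
#' @param panels list of [RatePanel-class] objects (replicates at their mu).
#' @return data.frame with species, low/high mu means, fold and
#'   fold_rounded; a zero denominator is flagged (`fold = NA`,
#'   `flag = "zero-denominator"`).
#' @export
foldChangeTable <- function(panels) {
  mus <- vapply(panels, function(p) p@mu, numeric(1))
  if (length(unique(round(mus, 6))) < 2) stop("need >= 2 mu levels")
  lo <- min(mus); hi <- max(mus)
  species <- Reduce(union, lapply(panels, function(p) names(p@q)))
  mean_at <- function(mu0, s) {
    v <- vapply(panels[abs(mus - mu0) < 1e-9],
                function(p) unname(p@q[s]), numeric(1))
    mean(v, na.rm = TRUE)
  }
  out <- do.call(rbind, lapply(species, function(s) {
    mlo <- mean_at(lo, s); mhi <- mean_at(hi, s)
    fold <- if (!is.finite(mlo) || mlo == 0) NA_real_ else mhi / mlo
    data.frame(species = s, low_mu = lo, high_mu = hi,
               low_mean = mlo, high_mean = mhi, fold = fold,
               fold_rounded = round(fold, 1),
               flag = if (is.na(fold)) "zero-denominator" else "",
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Mean and SD of replicate rate panels
#'
#' Condition summary across bioreplicates: per-species mean +- SD of the
#' specific rates, mean mu and mean biomass, computed on per-replicate
#' results.
#'
#' @param panels list of [RatePanel-class] replicates of one condition.
#' @return list with `panel` (a mean [RatePanel-class]) and `summary`
#'   (data.frame species, mean, sd, role).
#' @export
summariseReplicates <- function(panels) {
  species <- Reduce(union, lapply(panels, function(p) names(p@q)))
  qm <- vapply(species, function(s)
    mean(vapply(panels, function(p) unname(p@q[s]), numeric(1))), numeric(1))
  qs <- vapply(species, function(s)
    stats::sd(vapply(panels, function(p) unname(p@q[s]), numeric(1))),
    numeric(1))
  role <- panels[[1]]@role[species]
  mu <- mean(vapply(panels, function(p) p@mu, numeric(1)))
  X <- mean(vapply(panels, function(p) p@biomass, numeric(1)))
  list(panel = ratePanel(mu, qm, role, biomass = X,
                         volume = panels[[1]]@volume),
       summary = data.frame(species = species, mean = unname(qm),
                            sd = unname(qs), role = unname(role)))
}
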