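#' @import methods
#' @importFrom stats rnorm runif rnbinom sd setNames quantile
NULL

GAS_SPECIES <- c("CO", "H2", "CO2", "ethanol", "Ar")
PRODUCT_SPECIES <- c("acetate", "ethanol", "BDO")
RATE_SPECIES <- c("CO", "H2", "CO2", "acetate", "ethanol", "BDO")

#' GasStream: a gas flow with its molar composition
#'
#' Represents either a feed gas or a measured off-gas stream of a chemostat
#' bioreactor: a volumetric flow (mL/min at 0 degC / 1 atm reference) and the
#' mole fraction of each measured species (CO, H2, CO2, ethanol, Ar). Argon is
#' the inert internal standard used for outflow inference, so any stream meant
#' for an inert-gas balance must carry a positive Ar fraction.
#'
#' @slot flow numeric(1), volumetric flow in mL/min at reference conditions.
#' @slot fractions named numeric, mole fraction per species; non-negative and
#'   summing to at most 1 (unmeasured balance species may make up the rest).
#' @export
setClass("GasStream",
  representation(flow = "numeric", fractions = "numeric"))

setValidity("GasStream", function(object) {
  msg <- NULL
  if (length(object@flow) != 1L || !is.finite(object@flow) || object@flow < 0)
    msg <- c(msg, "flow must be a single non-negative finite number")
  fr <- object@fractions
  if (is.null(names(fr)) || any(!nzchar(names(fr))))
    msg <- c(msg, "fractions must be named by species")
  if (any(!is.finite(fr)) || any(fr < -1e-12))
    msg <- c(msg, "fractions must be finite and non-negative")
  if (sum(fr) > 1 + 1e-9)
    msg <- c(msg, "fractions sum above 1")
  if (is.null(msg)) TRUE else msg
})

#' Construct a GasStream
#'
#' @param flow volumetric flow, mL/min at reference conditions.
#' @param fractions named numeric vector of mole fractions.
#' @return A [GasStream-class] object.
#' @examples
#' gasStream(50, c(CO = 0.6, Ar = 0.4))
#' @export
gasStream <- function(flow, fractions) {
  new("GasStream", flow = as.numeric(flow), fractions = fractions)
}

setMethod("show", "GasStream", function(object) {
  cat("GasStream:", format(object@flow), "mL/min\n")
  print(round(object@fractions, 4))
})

#' RatePanel: biomass-specific rates of one steady state
#'
#' Holds the specific rates q (mmol/gDCW/h) of one replicate or one
#' condition-average steady state, together with the specific growth rate.
#' Rates are stored as positive magnitudes with a role label per species
#' ("uptake" or "production") to avoid silent sign errors when a species
#' switches between consumption and production across conditions.
#'
#' @slot mu numeric(1), specific growth rate, 1/day.
#' @slot q named numeric, rate magnitudes in mmol/gDCW/h.
#' @slot role named character, "uptake" or "production" per species in `q`.
#' @slot biomass numeric(1), steady-state biomass concentration, gDCW/L.
#' @slot volume numeric(1), working volume, L.
#' @export
setClass("RatePanel",
  representation(mu = "numeric", q = "numeric", role = "character",
                 biomass = "numeric", volume = "numeric"))

setValidity("RatePanel", function(object) {
  msg <- NULL
  if (!all(is.finite(object@q)))
    msg <- c(msg, "rates must be finite")
  if (any(object@q < -1e-9))
    msg <- c(msg, "rates are stored as positive magnitudes")
  if (!identical(sort(names(object@q)), sort(names(object@role))))
    msg <- c(msg, "q and role must cover the same species")
  if (!all(object@role %in% c("uptake", "production")))
    msg <- c(msg, "roles must be 'uptake' or 'production'")
  if (length(object@mu) != 1L || !is.finite(object@mu) || object@mu <= 0)
    msg <- c(msg, "mu must be a single positive number (steady state)")
  if (is.null(msg)) TRUE else msg
})

#' Construct a RatePanel
#'
#' @param mu specific growth rate, 1/day.
#' @param q named numeric of rate magnitudes (mmol/gDCW/h).
#' @param role named character of "uptake"/"production" per species; defaults
#'   to uptake for CO and H2, production otherwise.
#' @param biomass biomass concentration, gDCW/L.
#' @param volume working volume, L.
#' @return A [RatePanel-class] object.
#' @examples
#' ratePanel(mu = 1.02, q = c(CO = 32, CO2 = 24), biomass = 1.58)
#' @export
ratePanel <- function(mu, q, role = NULL, biomass = NA_real_, volume = 0.75) {
  if (is.null(role)) {
    role <- ifelse(names(q) %in% c("CO", "H2"), "uptake", "production")
    names(role) <- names(q)
  }
  new("RatePanel", mu = as.numeric(mu), q = q, role = role,
      biomass = as.numeric(biomass), volume = as.numeric(volume))
}

setMethod("show", "RatePanel", function(object) {
  cat(sprintf("RatePanel: mu = %.3g /day, X = %.3g gDCW/L\n",
              object@mu, object@biomass))
  df <- data.frame(q = round(object@q, 3), role = object@role[names(object@q)])
  print(df)
})

#' CarbonBalance: C-mol distribution of substrate carbon over products
#'
#' @slot fractions named numeric, C-mol fraction of total substrate carbon
#'   uptake recovered in each product (acetate, ethanol, BDO, CO2, biomass).
#' @slot recovery numeric(1), percent of substrate C-mol recovered in products.
#' @slot normalised named numeric, fractions rescaled to sum to exactly 100.
#' @export
setClass("CarbonBalance",
  representation(fractions = "numeric", recovery = "numeric",
                 normalised = "numeric"))

setValidity("CarbonBalance", function(object) {
  msg <- NULL
  if (any(object@fractions < -1e-9))
    msg <- c(msg, "fractions must be non-negative")
  if (abs(sum(object@normalised) - 100) > 1e-6)
    msg <- c(msg, "normalised fractions must sum to 100")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "CarbonBalance", function(object) {
  cat(sprintf("CarbonBalance: recovery %.1f%%\n", object@recovery))
  print(round(object@normalised, 2))
})

#' CoreModel: stoichiometric model of core acetogen metabolism
#'
#' A compact constraint-based model (~30 reactions) of the Wood-Ljungdahl
#' pathway and associated redox/energy metabolism of a CO/H2-fermenting
#' acetogen. Rows of `S` are metabolites, columns are reactions. Every
#' internal (non-exchange, non-biomass) reaction is carbon- and
#' electron-balanced by construction, which [buildCoreModel()] verifies.
#'
#' @slot S numeric matrix, stoichiometric coefficients (negative = consumed).
#' @slot lb,ub numeric, flux bounds per reaction, mmol/gDCW/h.
#' @slot metabolites data.frame with columns id, carbon (atoms per mole),
#'   degree (degree of reduction, electrons per mole), compartment.
#' @slot reactions data.frame with columns id, name, equation, type
#'   ("internal", "exchange", "biomass").
#' @export
setClass("CoreModel",
  representation(S = "matrix", lb = "numeric", ub = "numeric",
                 metabolites = "data.frame", reactions = "data.frame"))

setValidity("CoreModel", function(object) {
  msg <- NULL
  if (nrow(object@S) != nrow(object@metabolites))
    msg <- c(msg, "S rows must match metabolites")
  if (ncol(object@S) != nrow(object@reactions))
    msg <- c(msg, "S columns must match reactions")
  if (length(object@lb) != ncol(object@S) || length(object@ub) != ncol(object@S))
    msg <- c(msg, "bounds must match reaction count")
  if (any(object@lb > object@ub))
    msg <- c(msg, "lower bounds exceed upper bounds")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "CoreModel", function(object) {
  cat(sprintf("CoreModel: %d metabolites x %d reactions (%d exchanges)\n",
              nrow(object@S), ncol(object@S),
              sum(object@reactions$type == "exchange")))
})

#' FluxSolution: result of one FBA optimisation
#'
#' @slot fluxes named numeric, flux per reaction (mmol/gDCW/h; biomass in 1/h).
#' @slot objectiveValue numeric(1).
#' @slot status character(1): "optimal", "infeasible" or "unbounded".
#' @slot derived list of derived statistics (see [derivedStatistics()]).
#' @export
setClass("FluxSolution",
  representation(fluxes = "numeric", objectiveValue = "numeric",
                 status = "character", derived = "list"))

setMethod("show", "FluxSolution", function(object) {
  cat(sprintf("FluxSolution: status %s, objective %.4g\n",
              object@status, object@objectiveValue))
  if (length(object@derived))
    cat("  derived:", paste(names(object@derived), collapse = ", "), "\n")
})

#' TruePhysiology: ground-truth steady-state physiology of one condition
#'
#' The generator's own record of what a simulated chemostat condition truly
#' does: specific rates, carbon split, maintenance ATP and biomass level.
#' Its invariant is exact carbon closure (product C-mol fractions sum to 1).
#'
#' @slot mu numeric(1), 1/day.
#' @slot q named numeric, specific rate magnitudes, mmol/gDCW/h
#'   (CO, H2 = uptake; CO2, acetate, ethanol, BDO = production).
#' @slot productCarbonFractions named numeric over
#'   acetate/ethanol/BDO/CO2/biomass, summing to 1.
#' @slot maintenanceATP numeric(1), mmol ATP/gDCW/h.
#' @slot biomassConc numeric(1), gDCW/L.
#' @export
setClass("TruePhysiology",
  representation(mu = "numeric", q = "numeric",
                 productCarbonFractions = "numeric",
                 maintenanceATP = "numeric", biomassConc = "numeric"))

setValidity("TruePhysiology", function(object) {
  msg <- NULL
  if (abs(sum(object@productCarbonFractions) - 1) > 1e-9)
    msg <- c(msg, "product carbon fractions must sum to 1")
  if (any(object@q < 0)) msg <- c(msg, "rates must be non-negative magnitudes")
  if (object@mu <= 0) msg <- c(msg, "mu must be positive")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "TruePhysiology", function(object) {
  cat(sprintf("TruePhysiology: mu %.3g /day, maintenance %.3g mmol ATP/gDCW/h\n",
              object@mu, object@maintenanceATP))
  print(round(object@q, 3))
})
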