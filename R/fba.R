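.SPECIES_EXCHANGE <- c(CO = "EX_co", H2 = "EX_h2", CO2 = "EX_co2",
                       acetate = "EX_ac", ethanol = "EX_etoh", BDO = "EX_bdo")

# assemble constraint matrices from a model plus extra linear constraints
.lpFromModel <- function(model, extraConstraints) {
  n <- ncol(model@S)
  Aeq <- model@S; beq <- rep(0, nrow(model@S))
  Ale <- NULL; ble <- NULL
  for (ec in extraConstraints) {
    row <- rep(0, n)
    idx <- match(names(ec$coef), model@reactions$id)
    if (anyNA(idx)) stop("constraint names unknown reaction: ",
                         paste(names(ec$coef)[is.na(idx)], collapse = ", "))
    row[idx] <- ec$coef
    if (ec$dir == "==") {
      Aeq <- rbind(Aeq, row); beq <- c(beq, ec$rhs)
    } else if (ec$dir == "<=") {
      Ale <- rbind(Ale, row); ble <- c(ble, ec$rhs)
    } else if (ec$dir == ">=") {
      Ale <- rbind(Ale, -row); ble <- c(ble, -ec$rhs)
    } else stop("constraint dir must be '<=', '>=' or '=='")
  }
  list(Aeq = Aeq, beq = beq, Ale = Ale, ble = ble)
}

#' Flux balance analysis on a core model
#'
#' Solves max (or min) of a single reaction flux subject to steady state
#' (S v = 0), the model's flux bounds, and optional extra linear constraints.
#' Among alternative optima a secondary minimisation of the total flux
#' sum(|v|) is applied so the returned flux vector is reproducible.
#'
#' @param model a [CoreModel-class].
#' @param objective reaction id to optimise.
#' @param direction `"max"` (default) or `"min"`.
#' @param extraConstraints list of constraints, each a list with elements
#'   `coef` (named numeric over reaction ids), `dir` (`"<="`, `">="`, `"=="`)
#'   and `rhs` (scalar).
#' @param minimiseTotal apply the secondary sum(|v|) minimisation (default TRUE).
#' @return A [FluxSolution-class]; `status` is `"optimal"`, `"infeasible"` or
#'   `"unbounded"` - never a silent failure.
#' @examples
#' mod <- buildCoreModel()
#' mod <- setBounds(mod, "EX_co", lb = -1, ub = -1)
#' sol <- fba(mod, "EX_ac")
#' solverStatus(sol)
#' @export
fba <- function(model, objective, direction = c("max", "min"),
                extraConstraints = list(), minimiseTotal = TRUE) {
  direction <- match.arg(direction)
  oi <- match(objective, model@reactions$id)
  if (is.na(oi)) stop("objective names no existing reaction: ", objective)
  n <- ncol(model@S)
  obj <- rep(0, n); obj[oi] <- 1
  cm <- .lpFromModel(model, extraConstraints)
  res <- .solveLP(obj, cm$Aeq, cm$beq, model@lb, model@ub,
                  Ale = cm$Ale, ble = cm$ble,
                  maximize = direction == "max")
  if (res$status != "optimal")
    return(new("FluxSolution", fluxes = setNames(rep(NA_real_, n),
                                                 model@reactions$id),
               objectiveValue = NA_real_, status = res$status,
               derived = list()))
  v <- res$v
  if (minimiseTotal) {
    v2 <- .minimiseTotalFlux(obj, cm$Aeq, cm$beq, model@lb, model@ub,
                             zstar = res$objective,
                             maximize = direction == "max",
                             Ale = cm$Ale, ble = cm$ble)
    if (!is.null(v2)) v <- v2
  }
  resid <- max(abs(model@S %*% v))
  if (resid > 1e-6)
    warning("steady-state residual ", format(resid), " above tolerance")
  new("FluxSolution", fluxes = setNames(v, model@reactions$id),
      objectiveValue = res$objective, status = "optimal", derived = list())
}

# measured rate -> signed exchange flux (uptake negative, production positive)
.signedExchange <- function(panel) {
  sgn <- ifelse(panel@role[names(panel@q)] == "uptake", -1, 1)
  setNames(sgn * panel@q, names(panel@q))
}

#' Estimate intracellular fluxes and maintenance ATP from measured rates
#'
#' Implements flux estimation for one steady state: every measured exchange
#' flux (gas and liquid specific rates) and the growth rate are fixed to their
#' measured values within a relative tolerance band, and the ATP-maintenance
#' flux is maximised (maximisation of ATP dissipation). The maintenance
#' estimate is the optimal `ATPM` flux.
#'
#' @param model a [CoreModel-class].
#' @param panel a [RatePanel-class] with `mu` (1/day) and specific rates
#'   (mmol/gDCW/h).
#' @param tolerance relative half-width of the band around each measured flux
#'   (default 0.02). Needed because measured rates never close mass balances
#'   exactly.
#' @param qCysteine cysteine uptake, mmol/gDCW/h (default 0).
#' @return A [FluxSolution-class] with `derived$maintenance_atp` plus the
#'   statistics of [derivedStatistics()].
#' @export
estimateFluxes <- function(model, panel, tolerance = 0.02, qCysteine = 0) {
  ex <- .signedExchange(panel)
  targets <- c(setNames(ex[names(.SPECIES_EXCHANGE)], .SPECIES_EXCHANGE),
               EX_cys = -abs(qCysteine),
               EX_biomass = panel@mu / 24)
  targets <- targets[!is.na(targets)]
  for (id in names(targets)) {
    x <- targets[[id]]
    band <- abs(x) * tolerance
    model <- setBounds(model, id, lb = x - band, ub = x + band)
  }
  sol <- fba(model, "ATPM", "max")
  if (sol@status != "optimal")
    stop("flux estimation ", sol@status, " at tolerance ", tolerance,
         ": measured rates likely leave a carbon/electron recovery gap; ",
         "check the carbon balance or widen the tolerance")
  sol@derived <- c(list(maintenance_atp = unname(sol@fluxes["ATPM"])),
                   derivedStatistics(sol, model))
  sol
}

#' Predict the optimal growth phenotype from substrate uptake rates
#'
#' Fixes substrate uptake (CO, H2, cysteine) and the maintenance-ATP flux,
#' then maximises biomass yield. With `coupling = TRUE` the prediction is
#' additionally constrained by zeroing CO2 reduction through the
#' NADPH-consuming FdhA (`rxn00103_c0 = 0`) and fixing the ratio between
#' direct H2-dependent CO2 reduction (`rxn08518_c0`) and electron-bifurcating
#' Fd_red/NADPH generation (`leq000001`) to the experiment's qH2/qCO ratio.
#'
#' @param model a [CoreModel-class].
#' @param uptakes named numeric with elements `CO`, `H2` (and optionally
#'   `cysteine`), uptake magnitudes in mmol/gDCW/h.
#' @param maintenanceATP fixed maintenance flux, mmol/gDCW/h.
#' @param coupling logical, apply the H2-coupling constraints.
#' @param couplingRatio ratio r in `rxn08518_c0 = r * leq000001`; default
#'   `uptakes["H2"] / uptakes["CO"]`.
#' @return A [FluxSolution-class]; `derived` holds predicted `mu` (1/day) and
#'   product secretion rates.
#' @export
predictPhenotype <- function(model, uptakes, maintenanceATP,
                             coupling = TRUE, couplingRatio = NULL) {
  qco <- unname(uptakes["CO"]); qh2 <- unname(uptakes["H2"])
  if (is.na(qh2)) qh2 <- 0
  qcys <- if ("cysteine" %in% names(uptakes)) unname(uptakes["cysteine"]) else 0
  if (any(c(qco, qh2, qcys) < 0)) stop("uptakes must be non-negative magnitudes")
  # uptakes are availability ceilings (standard FBA convention): the optimum
  # may leave substrate unused when a coupling constraint restricts its use
  model <- setBounds(model, "EX_co", lb = -qco, ub = 0)
  model <- setBounds(model, "EX_h2", lb = -qh2, ub = 0)
  model <- setBounds(model, "EX_cys", lb = -qcys, ub = 0)
  model <- setBounds(model, "ATPM", lb = maintenanceATP, ub = maintenanceATP)
  # products export-only in prediction mode
  model <- setBounds(model, c("EX_ac", "EX_etoh", "EX_bdo", "EX_co2"), lb = 0)
  extra <- list()
  if (coupling) {
    if (is.null(couplingRatio))
      couplingRatio <- if (qco > 0) qh2 / qco else 0
    model <- setBounds(model, "rxn00103_c0", lb = 0, ub = 0)
    extra <- list(list(coef = c(rxn08518_c0 = 1, leq000001 = -couplingRatio),
                       dir = "==", rhs = 0))
  }
  sol <- fba(model, "EX_biomass", "max", extraConstraints = extra)
  if (sol@status == "optimal")
    sol@derived <- list(
      mu = unname(sol@fluxes["EX_biomass"]) * 24,
      q_acetate = unname(sol@fluxes["EX_ac"]),
      q_ethanol = unname(sol@fluxes["EX_etoh"]),
      q_BDO = unname(sol@fluxes["EX_bdo"]),
      co_used = -unname(sol@fluxes["EX_co"]),
      h2_used = -unname(sol@fluxes["EX_h2"]),
      coupling = coupling)
  sol
}

#' Theoretical CO2 dissipation for a sole product
#'
#' Stoichiometric ceiling analysis: at fixed substrate feed (CO alone, or CO
#' and H2 at a given molar ratio), all products except the chosen one and CO2
#' are closed, biomass formation is off, and the product flux is maximised.
#' Returns the fraction of consumed substrate carbon emitted as CO2.
#'
#' @param model a [CoreModel-class].
#' @param feedRatio CO:H2 molar uptake ratio; `Inf` means pure CO.
#' @param soleProduct `"ethanol"` or `"acetate"`.
#' @return list with `co2_fraction` (0-1), `co2_percent`, the product yield
#'   per CO, and the [FluxSolution-class].
#' @examples
#' mod <- buildCoreModel()
#' theoreticalCO2Loss(mod, Inf, "ethanol")$co2_percent   # ~66.7
#' @export
theoreticalCO2Loss <- function(model, feedRatio = Inf,
                               soleProduct = c("ethanol", "acetate")) {
  soleProduct <- match.arg(soleProduct)
  if (feedRatio < 0) stop("feedRatio must be >= 0 (Inf = pure CO)")
  qco <- 1
  qh2 <- if (is.infinite(feedRatio)) 0 else qco / feedRatio
  model <- setBounds(model, "EX_co", lb = -qco, ub = -qco)
  model <- setBounds(model, "EX_h2", lb = -qh2, ub = -qh2)
  model <- setBounds(model, "EX_cys", lb = 0, ub = 0)
  model <- setBounds(model, "EX_biomass", lb = 0, ub = 0)
  closed <- setdiff(c("EX_ac", "EX_etoh", "EX_bdo"),
                    if (soleProduct == "ethanol") "EX_etoh" else "EX_ac")
  model <- setBounds(model, closed, lb = 0, ub = 0)
  model <- setBounds(model, "EX_co2", lb = 0)
  target <- if (soleProduct == "ethanol") "EX_etoh" else "EX_ac"
  sol <- fba(model, target, "max")
  if (sol@status != "optimal")
    return(list(co2_fraction = NA_real_, co2_percent = NA_real_,
                product_per_co = NA_real_, solution = sol))
  frac <- unname(sol@fluxes["EX_co2"] / qco)
  list(co2_fraction = frac, co2_percent = 100 * frac,
       product_per_co = unname(sol@fluxes[target]) / qco, solution = sol)
}

#' Derived redox and energy statistics of a flux solution
#'
#' * `fdred_from_co_fraction`: share of total ferredoxin reduction carried by
#'   CO oxidation (CODH) relative to all Fd-reducing fluxes (CODH, MTHFR, Hyt).
#' * `atpase_to_ack_ratio`: ratio of the two ATP-producing fluxes, ATP
#'   synthase over acetate kinase.
#' * `maintenance_fraction_of_total_atp`: maintenance flux over total ATP
#'   production (ACK + ATPase).
#' * `wlp_flux`: methyl-branch/ACS flux into acetyl-CoA.
#'
#' Ratios with a zero denominator are returned as `NA` with a `"undefined"`
#' note rather than propagating NaN.
#'
#' @param sol an optimal [FluxSolution-class].
#' @param model the [CoreModel-class] it was solved on.
#' @return Named list of statistics.
#' @export
derivedStatistics <- function(sol, model) {
  if (sol@status != "optimal") stop("solution is not optimal")
  v <- sol@fluxes
  fdProd <- sum(v[c("CODH", "MTHFR", "leq000001")])
  atpProd <- sum(v[c("ACK", "ATPS")])
  ratio <- function(num, den) if (abs(den) < 1e-12) NA_real_ else num / den
  out <- list(
    fdred_from_co_fraction = ratio(unname(v["CODH"]), fdProd),
    atpase_to_ack_ratio = ratio(unname(v["ATPS"]), unname(v["ACK"])),
    maintenance_fraction_of_total_atp = ratio(unname(v["ATPM"]), atpProd),
    wlp_flux = unname(v["ACS"]))
  und <- names(out)[vapply(out, is.na, logical(1))]
  if (length(und)) out$undefined <- und
  out
}
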