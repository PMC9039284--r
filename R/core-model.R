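#' Default core-model parameters
#'
#' Biomass composition and cofactor choices for the core acetogen network.
#' The biomass pseudo-reaction drains acetyl-CoA and pyruvate as lumped
#' carbon precursors (2*15 + 3*3.9 = 41.7 mmol C per gDCW, i.e. 0.0417
#' C-mol/gDCW), plus ATP and NADPH. The ATP requirement (85 mmol/gDCW)
#' bundles polymerisation and anabolic costs and was calibrated once against
#' the reference steady states (see the methods vignette); NADPH demand is a
#' generic bacterial value. ADH and BDH default to NADPH (primary-secondary
#' alcohol dehydrogenase); set `"nadh"` to switch cofactor.
#'
#' @return Named list of parameters accepted by [buildCoreModel()].
#' @export
coreModelParams <- function() {
  list(
    biomassAcetylCoA = 15,    # mmol acetyl-CoA per gDCW
    biomassPyruvate  = 3.9,   # mmol pyruvate per gDCW
    biomassATP       = 85,    # mmol ATP per gDCW (growth-associated)
    biomassNADPH     = 12,    # mmol NADPH per gDCW
    adhCofactor      = "nadph",
    bdhCofactor      = "nadph"
  )
}

# metabolite table: carbon atoms and degree of reduction (electrons/mole,
# reference species CO2/H2O/H+/NH3/H2S at zero). THF carriers count only the
# bound C1 unit.
.coreMetabolites <- function(params) {
  m <- function(id, carbon, degree, comp = "cytosol")
    data.frame(id = id, carbon = carbon, degree = degree, compartment = comp,
               stringsAsFactors = FALSE)
  bioC <- 2 * params$biomassAcetylCoA + 3 * params$biomassPyruvate
  bioE <- 8 * params$biomassAcetylCoA + 10 * params$biomassPyruvate +
    2 * params$biomassNADPH
  rbind(
    m("co", 1, 2), m("co2", 1, 0), m("h2", 0, 2), m("h2o", 0, 0), m("h", 0, 0),
    m("formate", 1, 2), m("thf", 0, 0), m("fthf", 1, 2), m("mlthf", 1, 4),
    m("methf", 1, 6), m("coa", 0, 0), m("accoa", 2, 8), m("actp", 2, 8),
    m("pi", 0, 0), m("ac", 2, 8), m("acald", 2, 10), m("etoh", 2, 12),
    m("pyr", 3, 10), m("alac", 5, 20), m("actn", 4, 20), m("bdo", 4, 22),
    m("atp", 0, 0), m("adp", 0, 0), m("nad", 0, 0), m("nadh", 0, 2),
    m("nadp", 0, 0), m("nadph", 0, 2), m("fdox", 0, 0), m("fdred", 0, 2),
    m("cys", 3, 10), m("nh3", 0, 0), m("h2s", 0, 0),
    m("biomass_m", bioC, bioE),
    m("h_e", 0, 0, "extracellular")
  )
}

.coreReactions <- function(params) {
  nadx <- function(cof) if (cof == "nadph") c("nadph", "nadp") else c("nadh", "nad")
  adh <- nadx(params$adhCofactor)
  bdh <- nadx(params$bdhCofactor)
  r <- list(
    CODH = list(c(co = -1, h2o = -1, fdox = -1, co2 = 1, fdred = 1, h = 2),
                "CO dehydrogenase"),
    rxn00103_c0 = list(c(co2 = -1, nadph = -1, formate = 1, nadp = 1),
                       "formate dehydrogenase (NADPH, FdhA)"),
    rxn08518_c0 = list(c(co2 = -1, h2 = -1, formate = 1, h = 1),
                       "formate-H2 lyase (HytA-E/FdhA)"),
    leq000001 = list(c(h2 = -2, fdox = -1, nadp = -1, fdred = 1, nadph = 1, h = 1),
                     "electron-bifurcating hydrogenase (Hyt)"),
    FTHFS = list(c(formate = -1, thf = -1, atp = -1, fthf = 1, adp = 1, pi = 1),
                 "formyl-THF synthetase"),
    MTHFD = list(c(fthf = -1, nadph = -1, h = -1, mlthf = 1, nadp = 1, h2o = 1),
                 "methenyl-THF cyclohydrolase/dehydrogenase (lumped)"),
    MTHFR = list(c(mlthf = -1, nadh = -2, fdox = -1, methf = 1, nad = 2, fdred = 1),
                 "methylene-THF reductase (NADH, Fd-reducing)"),
    ACS = list(c(methf = -1, co = -1, coa = -1, accoa = 1, thf = 1),
               "acetyl-CoA synthase/CODH complex"),
    PTA = list(c(accoa = -1, pi = -1, actp = 1, coa = 1),
               "phosphotransacetylase"),
    ACK = list(c(actp = -1, adp = -1, ac = 1, atp = 1), "acetate kinase"),
    AOR = list(c(ac = -1, fdred = -1, h = -2, acald = 1, fdox = 1, h2o = 1),
               "aldehyde:Fd oxidoreductase"),
    ADH = list(setNames(c(-1, -1, -1, 1, 1),
                        c("acald", adh[1], "h", "etoh", adh[2])),
               "alcohol dehydrogenase"),
    ADHE = list(c(accoa = -1, nadh = -2, h = -2, etoh = 1, coa = 1, nad = 2),
                "bifunctional aldehyde/alcohol dehydrogenase"),
    PFOR = list(c(accoa = -1, co2 = -1, fdred = -1, h = -1, pyr = 1, coa = 1,
                  fdox = 1),
                "pyruvate:Fd oxidoreductase (carboxylating)"),
    ALS = list(c(pyr = -2, h = -1, alac = 1, co2 = 1), "acetolactate synthase"),
    ALDC = list(c(alac = -1, actn = 1, co2 = 1), "acetolactate decarboxylase"),
    BDH = list(setNames(c(-1, -1, -1, 1, 1),
                        c("actn", bdh[1], "h", "bdo", bdh[2])),
               "2,3-butanediol dehydrogenase"),
    RNF = list(c(fdred = -1, nad = -1, h = -3, fdox = 1, nadh = 1, h_e = 2),
               "Rnf complex (2 H+ translocated per Fd_red)"),
    ATPS = list(c(adp = -1, pi = -1, h_e = -4, atp = 1, h2o = 1, h = 3),
                "ATP synthase (4 H+/ATP)"),
    NFN = list(c(fdred = -1, nadh = -1, nadp = -2, h = -1, fdox = 1, nad = 1,
                 nadph = 2),
               "Nfn transhydrogenase"),
    ATPM = list(c(atp = -1, h2o = -1, adp = 1, pi = 1, h = 1),
                "ATP maintenance (non-growth-associated)"),
    CYSD = list(c(cys = -1, h2o = -1, pyr = 1, nh3 = 1, h2s = 1),
                "cysteine desulfhydrase")
  )
  bio <- c(accoa = -params$biomassAcetylCoA, pyr = -params$biomassPyruvate,
           atp = -params$biomassATP, nadph = -params$biomassNADPH,
           h2o = -params$biomassATP,
           biomass_m = 1, coa = params$biomassAcetylCoA,
           adp = params$biomassATP, pi = params$biomassATP,
           nadp = params$biomassNADPH, h = params$biomassATP)
  r$BIOMASS <- list(bio, "biomass pseudo-reaction (1/h)")
  r
}

.coreExchanges <- function() {
  # id, metabolite, lb, ub; positive flux = export
  ex <- rbind(
    data.frame(id = "EX_co",      met = "co",        lb = -1000, ub = 1000),
    data.frame(id = "EX_h2",      met = "h2",        lb = -1000, ub = 1000),
    data.frame(id = "EX_co2",     met = "co2",       lb = -1000, ub = 1000),
    data.frame(id = "EX_ac",      met = "ac",        lb = -1000, ub = 1000),
    data.frame(id = "EX_etoh",    met = "etoh",      lb = -1000, ub = 1000),
    data.frame(id = "EX_bdo",     met = "bdo",       lb = -1000, ub = 1000),
    data.frame(id = "EX_cys",     met = "cys",       lb = -1000, ub = 0),
    data.frame(id = "EX_biomass", met = "biomass_m", lb = 0,     ub = 1000),
    data.frame(id = "EX_h2o",     met = "h2o",       lb = -1000, ub = 1000),
    data.frame(id = "EX_h",       met = "h",         lb = -1000, ub = 1000),
    data.frame(id = "EX_nh3",     met = "nh3",       lb = -1000, ub = 1000),
    data.frame(id = "EX_h2s",     met = "h2s",       lb = -1000, ub = 1000)
  )
  ex
}

.formatEquation <- function(coef) {
  lhs <- coef[coef < 0]; rhs <- coef[coef > 0]
  term <- function(x) paste(ifelse(abs(x) == 1, names(x),
                                   paste(abs(x), names(x))), collapse = " + ")
  paste(term(lhs), "->", term(rhs))
}

#' Build the core acetogen stoichiometric model
#'
#' Constructs a ~35-reaction constraint-based model of CO/H2 fermentation in
#' an acetogen: CO oxidation (CODH), the methyl branch of the Wood-Ljungdahl
#' pathway with its two CO2-reduction entries (NADPH-dependent FdhA,
#' `rxn00103_c0`, and the H2-dependent formate-H2 lyase, `rxn08518_c0`),
#' the electron-bifurcating hydrogenase (`leq000001`), acetyl-CoA synthase,
#' acetate/ethanol/2,3-butanediol formation (PTA/ACK, AOR, ADH, ADHE,
#' ALS/ALDC/BDH), the Rnf/ATPase energy-conservation couple (2 H+ per Fd_red,
#' 4 H+ per ATP), the Nfn transhydrogenase, an ATP-maintenance drain and a
#' biomass pseudo-reaction. Internal reactions are irreversible in their
#' physiological direction.
#'
#' Every internal reaction is checked for carbon and electron
#' (degree-of-reduction) balance at build time; an imbalance is a
#' construction error naming the reaction.
#'
#' @param params list as returned by [coreModelParams()].
#' @return A [CoreModel-class].
#' @examples
#' mod <- buildCoreModel()
#' reactionIds(mod)
#' @export
buildCoreModel <- function(params = coreModelParams()) {
  mets <- .coreMetabolites(params)
  rxns <- .coreReactions(params)
  exch <- .coreExchanges()

  nr <- length(rxns) + nrow(exch)
  S <- matrix(0, nrow(mets), nr,
              dimnames = list(mets$id, c(names(rxns), exch$id)))
  for (i in seq_along(rxns)) {
    coef <- rxns[[i]][[1]]
    stopifnot(all(names(coef) %in% mets$id))
    S[names(coef), i] <- coef
  }
  for (j in seq_len(nrow(exch)))
    S[exch$met[j], length(rxns) + j] <- -1

  type <- c(ifelse(names(rxns) == "BIOMASS", "biomass", "internal"),
            rep("exchange", nrow(exch)))
  lb <- c(rep(0, length(rxns)), exch$lb)
  ub <- c(rep(1000, length(rxns)), exch$ub)

  eqn <- c(vapply(rxns, function(x) .formatEquation(x[[1]]), character(1)),
           paste(exch$met, "->"))
  rtab <- data.frame(id = colnames(S),
                     name = c(vapply(rxns, `[[`, character(1), 2), exch$id),
                     equation = eqn, type = type, stringsAsFactors = FALSE)

  # carbon and electron balance of every internal reaction
  for (j in which(rtab$type == "internal")) {
    cbal <- sum(S[, j] * mets$carbon)
    ebal <- sum(S[, j] * mets$degree)
    if (abs(cbal) > 1e-9)
      stop("carbon imbalance in reaction ", rtab$id[j], " (", cbal, ")")
    if (abs(ebal) > 1e-9)
      stop("electron imbalance in reaction ", rtab$id[j], " (", ebal, ")")
  }

  new("CoreModel", S = S, lb = lb, ub = ub, metabolites = mets,
      reactions = rtab)
}

#' Set flux bounds on a model
#'
#' @param model a [CoreModel-class].
#' @param id reaction id(s).
#' @param lb,ub new bounds (recycled); NA leaves a bound unchanged.
#' @return The modified model.
#' @export
setBounds <- function(model, id, lb = NA, ub = NA) {
  idx <- match(id, model@reactions$id)
  if (anyNA(idx)) stop("unknown reaction id: ",
                       paste(id[is.na(idx)], collapse = ", "))
  lb <- rep_len(lb, length(idx)); ub <- rep_len(ub, length(idx))
  model@lb[idx] <- ifelse(is.na(lb), model@lb[idx], lb)
  model@ub[idx] <- ifelse(is.na(ub), model@ub[idx], ub)
  validObject(model)
  model
}

#' Serialise a model as a reaction table
#'
#' Writes a TSV with one row per reaction: id, name, equation, type, lb, ub.
#'
#' @param model a [CoreModel-class].
#' @param path output file.
#' @return Invisibly, the written data.frame.
#' @export
writeModelTSV <- function(model, path) {
  df <- cbind(model@reactions, lb = model@lb, ub = model@ub)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
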