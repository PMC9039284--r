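#' Default steady-state condition grid
#'
#' The study design the simulator reproduces: 23 steady-state chemostats,
#' two feed gases (CO: 60% CO / 40% Ar at 50 or 72 mL/min; syngas: 50% CO,
#' 20% H2, 20% CO2, 10% Ar) at three dilution rates (~1.0, ~2.0, ~2.8 1/day)
#' with 4/3/3 and 6/3/4 bioreplicates and similar steady-state biomass
#' concentrations. Working volume 0.75 L.
#'
#' @return data.frame with one row per gas x dilution condition and a
#'   `feed` list-column of mole fractions.
#' @export
defaultConditionGrid <- function() {
  co_feed <- c(CO = 0.6, H2 = 0, CO2 = 0, ethanol = 0, Ar = 0.4)
  sg_feed <- c(CO = 0.5, H2 = 0.2, CO2 = 0.2, ethanol = 0, Ar = 0.1)
  g <- data.frame(
    gas = rep(c("CO", "syngas"), each = 3),
    flow = c(50, 72, 72, 50, 72, 72),
    agitation = c(690, 815, 1175, 675, 800, 1160),
    dilution = c(1.02, 2.03, 2.79, 1.01, 2.01, 2.79),
    biomass = c(1.58, 1.65, 1.65, 1.59, 1.57, 1.43),
    nReplicates = c(4, 3, 3, 6, 3, 4),
    volume = 0.75,
    stringsAsFactors = FALSE)
  g$feed <- rep(list(co_feed, sg_feed), each = 3)
  stopifnot(all(vapply(g$feed, sum, numeric(1)) - 1 < 1e-9))
  g
}

# physiology targets per grid row: CO uptake, H2 uptake, molar acetate/ethanol
# ratio and BDO rate chosen once to track the reference study's magnitudes
# (rates rising ~2-3x over the mu range, acetate/ethanol falling, BDO up on
# syngas); everything else follows from carbon/electron closure.
.defaultPhysiologyTargets <- function() {
  data.frame(
    gas = rep(c("CO", "syngas"), each = 3),
    dilution = c(1.02, 2.03, 2.79, 1.01, 2.01, 2.79),
    qCO = c(32, 50, 70, 25, 48, 73),
    qH2 = c(0, 0, 0, 7, 21, 21),
    aceEtohRatio = c(1.5, 1.1, 0.9, 1.8, 1.0, 0.6),
    qBDO = c(0.10, 0.12, 0.15, 0.094, 0.24, 0.66),
    stringsAsFactors = FALSE)
}

#' Ground-truth physiology from carbon/electron closure
#'
#' Builds a fully self-consistent steady-state physiology. The free inputs
#' are mu (1/day), the substrate uptake rates qCO and qH2, the molar
#' acetate/ethanol ratio and the 2,3-butanediol rate. The remaining rates
#' are then forced: the degree-of-reduction (electron) balance fixes the
#' total acetate + ethanol output, and the carbon balance fixes q_CO2, so
#' the product C-mol fractions sum to exactly 1.
#'
#' Maintenance ATP is computed by closed-form cofactor bookkeeping of the
#' core network (CODH/methyl-branch/ACS fluxes, Fd/NADH/NADPH balances, Rnf
#' 2H+/Fd_red, ATPase 4H+/ATP, full AOR ethanol route, and - under
#' maximal ATP dissipation - NADPH-dependent CO2 reduction). This hand
#' derivation is independent of the LP solver and serves as ground truth
#' for flux-estimation recovery tests.
#'
#' @param gas `"CO"` or `"syngas"` (bookkeeping only; H2 routing follows qH2).
#' @param mu 1/day; @param qCO,qH2 uptake magnitudes, mmol/gDCW/h.
#' @param aceEtohRatio molar acetate/ethanol ratio.
#' @param qBDO 2,3-butanediol rate, mmol/gDCW/h.
#' @param biomassConc gDCW/L.
#' @param params core-model parameters, [coreModelParams()].
#' @return A [TruePhysiology-class].
#' @examples
#' truePhysiology("CO", mu = 1.02, qCO = 32, qH2 = 0, aceEtohRatio = 1.5,
#'                qBDO = 0.1, biomassConc = 1.58)
#' @export
truePhysiology <- function(gas, mu, qCO, qH2 = 0, aceEtohRatio = 1.5,
                           qBDO = 0.1, biomassConc = 1.6,
                           params = coreModelParams()) {
  b <- mu / 24                                   # biomass flux, 1/h
  bioC <- 2 * params$biomassAcetylCoA + 3 * params$biomassPyruvate
  bioE <- 8 * params$biomassAcetylCoA + 10 * params$biomassPyruvate +
    2 * params$biomassNADPH
  # electron balance fixes acetate + ethanol output
  E <- 2 * qCO + 2 * qH2 - 22 * qBDO - bioE * b
  qEtoh <- E / (12 + 8 * aceEtohRatio)
  qAce <- aceEtohRatio * qEtoh
  if (qEtoh <= 0) stop("infeasible physiology: no electrons left for ethanol")
  # carbon balance fixes CO2
  qCO2 <- qCO - 2 * (qAce + qEtoh) - 4 * qBDO - bioC * b
  if (qCO2 <= 0) stop("infeasible physiology: negative CO2 production")

  # cofactor bookkeeping (all fluxes mmol/gDCW/h)
  p <- params$biomassPyruvate * b + 2 * qBDO        # PFOR
  k <- qAce + qEtoh                                 # ACK (full AOR route)
  m <- params$biomassAcetylCoA * b + p + k          # methyl branch / ACS
  h <- qH2 / 2                                      # Hyt
  n <- (2 * m + qEtoh + qBDO + params$biomassNADPH * b - h) / 2   # Nfn
  r <- 2 * m + n                                    # Rnf
  cdh <- qCO - m                                    # CODH
  if (cdh < 0) stop("infeasible physiology: CO uptake below WLP demand")
  if (n < 0) stop("infeasible physiology: Nfn flux negative")
  # ferredoxin closure must follow from the electron balance
  fdGap <- (cdh + m + h) - (qEtoh + p + r + n)
  stopifnot(abs(fdGap) < 1e-8)
  M <- k + r / 2 - m - params$biomassATP * b
  if (M < 0) stop("infeasible physiology: negative maintenance ATP")

  q <- c(CO = qCO, H2 = qH2, CO2 = qCO2, acetate = qAce, ethanol = qEtoh,
         BDO = qBDO)
  fr <- c(acetate = 2 * qAce, ethanol = 2 * qEtoh, BDO = 4 * qBDO,
          CO2 = qCO2, biomass = bioC * b) / qCO
  new("TruePhysiology", mu = mu, q = q, productCarbonFractions = fr,
      maintenanceATP = M, biomassConc = biomassConc)
}

#' Forward-simulate an off-gas trace for one replicate
#'
#' Applies the species mole balances that off-gas analysis later inverts:
#' outflow molar rate = inflow - consumption + production for every species,
#' argon conserved, mole fractions renormalised over the measured species.
#' A configurable fraction of produced ethanol is stripped to the gas phase.
#' Multiplicative Gaussian noise (relative SD `noiseSd`) is applied per
#' species and timepoint; at `noiseSd = 0` the trace satisfies the balances
#' exactly.
#'
#' @param phys a [TruePhysiology-class].
#' @param feed named feed mole fractions (CO, H2, CO2, ethanol, Ar).
#' @param flow feed flow, mL/min; @param volume working volume, L.
#' @param strippedFraction fraction of produced ethanol leaving via off-gas
#'   (default 0.05).
#' @param noiseSd relative SD of measurement noise (default 0).
#' @param nTimepoints samples in the trace; @param dt hours between samples.
#' @param molarVolume mL/mmol.
#' @return list with `trace` (data.frame time_h, species, mole_fraction),
#'   `outflow` (mL/min), `outletFractions` (noise-free) and `strippedQ`.
#' @export
simulateOffgas <- function(phys, feed, flow, volume = 0.75,
                           strippedFraction = 0.05, noiseSd = 0,
                           nTimepoints = 25, dt = 0.5,
                           molarVolume = MOLAR_VOLUME) {
  if (flow <= 0) stop("feed flow must be positive")
  if (is.na(feed["Ar"]) || feed["Ar"] <= 0)
    stop("feed must contain Ar for the inert balance")
  X <- phys@biomassConc
  nin <- flow * feed[GAS_SPECIES] / molarVolume          # mmol/min
  names(nin) <- GAS_SPECIES
  nin[is.na(nin)] <- 0
  gXV <- X * volume / 60                                 # gDCW * h/min
  delta <- c(CO = -phys@q[["CO"]], H2 = -phys@q[["H2"]],
             CO2 = phys@q[["CO2"]],
             ethanol = strippedFraction * phys@q[["ethanol"]],
             Ar = 0) * gXV
  nout <- nin + delta
  bad <- names(nout)[nout < -1e-12]
  if (length(bad))
    stop("infeasible physiology: computed negative outflow for ",
         paste(bad, collapse = ", "))
  fout <- sum(nout) * molarVolume
  yout <- nout / sum(nout)

  times <- seq(0, by = dt, length.out = nTimepoints)
  tr <- expand.grid(time_h = times, species = GAS_SPECIES,
                    stringsAsFactors = FALSE)
  tr$mole_fraction <- yout[tr$species]
  if (noiseSd > 0)
    tr$mole_fraction <- tr$mole_fraction *
      (1 + stats::rnorm(nrow(tr), 0, noiseSd))
  list(trace = tr, outflow = unname(fout), outletFractions = yout,
       strippedQ = unname(strippedFraction * phys@q[["ethanol"]]))
}

#' Simulate broth chemistry and optical density for one replicate
#'
#' Steady-state CSTR relation: a product at specific rate q accumulates to
#' `c = q * X / (D/24)` mM. Only the non-stripped share of ethanol appears
#' in the broth. OD600 is biomass over the OD-DCW coefficient (0.23).
#' Multiplicative Gaussian noise models HPLC/OD measurement error.
#'
#' @param phys a [TruePhysiology-class]; @param dilution 1/day.
#' @param strippedFraction share of ethanol lost to off-gas.
#' @param noiseSd relative SD; @param nOD OD timepoints.
#' @param k OD-DCW coefficient, gDCW/L per OD.
#' @return list with `broth` (data.frame compound, conc_mM) and `od`
#'   (numeric vector).
#' @export
simulateBrothOD <- function(phys, dilution, strippedFraction = 0.05,
                            noiseSd = 0, nOD = 5, k = 0.23) {
  if (dilution <= 0) stop("dilution must be positive")
  X <- phys@biomassConc
  Dh <- dilution / 24
  qliq <- c(acetate = phys@q[["acetate"]],
            ethanol = (1 - strippedFraction) * phys@q[["ethanol"]],
            BDO = phys@q[["BDO"]])
  conc <- qliq * X / Dh
  if (noiseSd > 0) conc <- conc * (1 + stats::rnorm(length(conc), 0, noiseSd))
  od <- rep(X / k, nOD)
  if (noiseSd > 0) od <- od * (1 + stats::rnorm(nOD, 0, noiseSd))
  list(broth = data.frame(compound = names(qliq), conc_mM = unname(conc),
                          stringsAsFactors = FALSE),
       od = od)
}

#' Default configuration of the RNA-seq count simulator
#'
#' @return list of tuning parameters for [simulateCounts()]: numbers of
#'   slope-up/down genes shared between gases, gas-divergent genes, the
#'   range of planted log2 effects across the full mu range, NB dispersion,
#'   library-size range (reads) and baseline log2-CPM range.
#' @export
degConfig <- function() {
  list(nUp = 100, nDown = 100, nDiverge = 50,
       lfcRange = c(1.5, 3), dispersion = 0.01,
       libSizeRange = c(5.6e6, 9.3e6), baseLogCpmRange = c(3, 9))
}

#' Simulate an RNA-seq count matrix with mu-dependent expression
#'
#' Gene classes: `flat` (no mu dependence), `up`/`down` (log2 expression
#' linear in mu with the same slope on both gases - the tight-control truth),
#' and `diverge` (different slopes per gas). Planted slopes are drawn so the
#' full-range fold change is `2^lfc` with `lfc` uniform in `lfcRange`.
#' Counts are negative binomial with the configured dispersion; library
#' sizes are uniform on `libSizeRange` (the typical depth of a bacterial
#' RNA-seq run, 5.6-9.3 million reads).
#'
#' @param nGenes >= 100 genes.
#' @param design data.frame with columns `sample`, `gas`, `mu`, `replicate`;
#'   needs >= 2 mu levels and >= 2 replicates per condition.
#' @param config list from [degConfig()].
#' @param seed integer seed.
#' @return list with `counts` (genes x samples integer matrix),
#'   `geneLengths` (bp), `libSizes`, and `truth` (data.frame gene, class,
#'   slope_CO, slope_syngas, lfc_full_range).
#' @export
simulateCounts <- function(nGenes = 2000, design, config = degConfig(),
                           seed = 1) {
  if (nGenes < 100) stop("nGenes must be >= 100")
  if (length(unique(design$mu)) < 2) stop("design needs >= 2 mu levels")
  tab <- table(design$gas, design$mu)
  if (any(tab[tab > 0] < 2)) stop("design needs >= 2 replicates per condition")
  set.seed(seed)
  genes <- sprintf("gene%04d", seq_len(nGenes))
  nU <- config$nUp; nD <- config$nDown; nV <- config$nDiverge
  if (nU + nD + nV > nGenes) stop("more planted genes than genes")
  class <- c(rep("up", nU), rep("down", nD), rep("diverge", nV),
             rep("flat", nGenes - nU - nD - nV))
  murange <- diff(range(design$mu))
  lfc <- stats::runif(nGenes, config$lfcRange[1], config$lfcRange[2])
  sl <- lfc / murange
  slopeCO <- ifelse(class == "up", sl, ifelse(class == "down", -sl, 0))
  # divergent genes: opposite-sign slopes on the two gases
  dv <- class == "diverge"
  slopeCO[dv] <- sl[dv]
  slopeSG <- slopeCO
  slopeSG[dv] <- -sl[dv]

  base <- stats::runif(nGenes, config$baseLogCpmRange[1],
                       config$baseLogCpmRange[2])
  libs <- stats::runif(nrow(design), config$libSizeRange[1],
                       config$libSizeRange[2])
  counts <- matrix(0L, nGenes, nrow(design),
                   dimnames = list(genes, design$sample))
  for (j in seq_len(nrow(design))) {
    slope <- if (design$gas[j] == "CO") slopeCO else slopeSG
    logrel <- base + slope * (design$mu[j] - min(design$mu))
    p <- 2^logrel; p <- p / sum(p)
    counts[, j] <- stats::rnbinom(nGenes, mu = p * libs[j],
                                  size = 1 / config$dispersion)
  }
  truth <- data.frame(gene = genes, class = class, slope_CO = slopeCO,
                      slope_syngas = slopeSG, lfc_full_range = lfc,
                      stringsAsFactors = FALSE)
  list(counts = counts,
       geneLengths = setNames(round(stats::runif(nGenes, 300, 3000)), genes),
       libSizes = setNames(round(libs), design$sample), truth = truth)
}

#' Simulate GO and COG annotation tables with a known enriched subset
#'
#' Mock functional annotation: `nTerms` GO-like terms with sizes uniform in
#' `sizeRange`; `nEnriched` of them draw a configurable share of their genes
#' from the planted slope genes, so enrichment analysis has a known answer.
#' COG letters are assigned uniformly at random.
#'
#' @param truth the truth table from [simulateCounts()].
#' @param nTerms,nEnriched,sizeRange,enrichedShare tuning parameters.
#' @param seed integer seed.
#' @return list with `go` (data.frame gene_id, term_id), `cog` (gene_id,
#'   COG_letter), and `enrichedTerms` (character).
#' @export
simulateAnnotations <- function(truth, nTerms = 50, nEnriched = 5,
                                sizeRange = c(5, 200), enrichedShare = 0.6,
                                seed = 1) {
  set.seed(seed + 7)
  genes <- truth$gene
  slope_genes <- truth$gene[truth$class %in% c("up", "down")]
  terms <- sprintf("GO:%07d", seq_len(nTerms))
  enriched <- terms[seq_len(nEnriched)]
  rows <- lapply(seq_len(nTerms), function(i) {
    size <- round(stats::runif(1, sizeRange[1], sizeRange[2]))
    size <- min(size, length(genes))
    if (terms[i] %in% enriched) {
      nsl <- min(round(enrichedShare * size), length(slope_genes))
      g <- c(sample(slope_genes, nsl),
             sample(setdiff(genes, slope_genes), size - nsl))
    } else g <- sample(genes, size)
    data.frame(gene_id = g, term_id = terms[i], stringsAsFactors = FALSE)
  })
  cog <- data.frame(gene_id = genes,
                    COG_letter = sample(strsplit("CEFGHJKLMNOPSTUV", "")[[1]],
                                        length(genes), replace = TRUE),
                    stringsAsFactors = FALSE)
  list(go = do.call(rbind, rows), cog = cog, enrichedTerms = enriched)
}

#' Simulate a complete chemostat study with ground truth
#'
#' Runs the full forward model over a condition grid: per-replicate off-gas
#' traces, broth chemistry, OD series, an RNA-seq count matrix over the gas
#' x mu design (3 replicates per condition by default) with annotations,
#' plus the [TruePhysiology-class] of every condition. Identical seeds give
#' identical datasets.
#'
#' @param grid condition grid, [defaultConditionGrid()].
#' @param targets physiology targets per grid row (gas, dilution, qCO, qH2,
#'   aceEtohRatio, qBDO).
#' @param noiseSd relative measurement noise (default 0.02; set 0 for exact
#'   round-trip checks).
#' @param strippedFraction ethanol stripping fraction.
#' @param nGenes genes in the count matrix; @param rnaReplicates RNA-seq
#'   replicates per condition.
#' @param countConfig list from [degConfig()].
#' @param seed integer seed.
#' @return list of class `ChemostatStudy`: `grid`, `offgas` (per-replicate
#'   traces), `broth`, `od`, `se` (a
#'   [SummarizedExperiment::SummarizedExperiment] of counts with gas/mu/
#'   replicate colData and gene lengths in rowData), `annotations`, `truth`.
#' @export
#' @importFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors DataFrame
simulateChemostatStudy <- function(grid = defaultConditionGrid(),
                                   targets = .defaultPhysiologyTargets(),
                                   noiseSd = 0.02, strippedFraction = 0.05,
                                   nGenes = 2000, rnaReplicates = 3,
                                   countConfig = degConfig(), seed = 1) {
  set.seed(seed)
  offgas <- list(); broth <- list(); od <- list(); phys <- list()
  for (i in seq_len(nrow(grid))) {
    tg <- targets[targets$gas == grid$gas[i] &
                    abs(targets$dilution - grid$dilution[i]) < 1e-9, ]
    stopifnot(nrow(tg) == 1)
    ph <- truePhysiology(grid$gas[i], mu = grid$dilution[i], qCO = tg$qCO,
                         qH2 = tg$qH2, aceEtohRatio = tg$aceEtohRatio,
                         qBDO = tg$qBDO, biomassConc = grid$biomass[i])
    cond <- paste0(grid$gas[i], "_D", grid$dilution[i])
    phys[[cond]] <- ph
    for (rep in seq_len(grid$nReplicates[i])) {
      id <- paste0(cond, "_r", rep)
      og <- simulateOffgas(ph, grid$feed[[i]], grid$flow[i], grid$volume[i],
                           strippedFraction, noiseSd)
      og$trace$replicate_id <- id
      og$trace$condition <- cond
      bo <- simulateBrothOD(ph, grid$dilution[i], strippedFraction, noiseSd)
      bo$broth$replicate_id <- id
      bo$broth$condition <- cond
      offgas[[id]] <- og$trace
      broth[[id]] <- bo$broth
      od[[id]] <- bo$od
    }
  }

  design <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    data.frame(gas = grid$gas[i], mu = grid$dilution[i],
               replicate = seq_len(rnaReplicates), stringsAsFactors = FALSE)
  }))
  design$sample <- sprintf("%s_D%g_s%d", design$gas, design$mu,
                           design$replicate)
  cnt <- simulateCounts(nGenes, design, countConfig, seed = seed + 1)
  ann <- simulateAnnotations(cnt$truth, seed = seed)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = cnt$counts),
    colData = S4Vectors::DataFrame(design, row.names = design$sample),
    rowData = S4Vectors::DataFrame(length_bp = cnt$geneLengths))

  structure(list(grid = grid,
                 offgas = do.call(rbind, offgas),
                 broth = do.call(rbind, broth),
                 od = od, se = se, annotations = ann,
                 truth = list(physiology = phys, genes = cnt$truth,
                              enrichedTerms = ann$enrichedTerms,
                              strippedFraction = strippedFraction),
                 noiseSd = noiseSd, seed = seed),
            class = "ChemostatStudy")
}

#' @export
print.ChemostatStudy <- function(x, ...) {
  cat(sprintf("ChemostatStudy: %d conditions, %d replicate traces, %d genes x %d RNA samples (seed %d)\n",
              nrow(x$grid), length(unique(x$offgas$replicate_id)),
              nrow(x$se), ncol(x$se), x$seed))
  invisible(x)
}
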