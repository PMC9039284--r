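#' Default pipeline configuration
#'
#' All analysis thresholds live here, never hard-coded in stage logic:
#' OD-DCW coefficient K = 0.23, DEG thresholds FC > 1.5 / q < 0.05,
#' expression filter > 10 RPKM in >= 2 samples, FBA measurement tolerance,
#' noise level and ethanol-stripping fraction of the simulator, and the
#' global seed.
#'
#' @param seed global seed; @param outdir output directory.
#' @return Nested named list; serialisable to/from YAML with
#'   [writeConfig()] / [readConfig()].
#' @export
defaultConfig <- function(seed = 1, outdir = "acetoflux_out") {
  list(
    seed = seed,
    outdir = outdir,
    simulate = list(enabled = TRUE, noise_sd = 0.02,
                    stripped_fraction = 0.05, n_genes = 2000,
                    rna_replicates = 3),
    bioprocess = list(od_dcw_k = 0.23, biomass_carbon = 0.0417,
                      q_cysteine = 0, henry_kH = 0.0246, pKa1 = 6.30),
    offgas = list(molar_volume = 22.414, cv_threshold = 0.02),
    fba = list(tolerance = 0.02),
    transcriptomics = list(fc_threshold = 1.5, q_threshold = 0.05,
                           rpkm_threshold = 10, rpkm_min_samples = 2,
                           slope_alpha = 0.05)
  )
}

#' Read / write a pipeline configuration
#'
#' @param path YAML file.
#' @param config configuration list.
#' @return `readConfig`: the validated configuration list.
#' @export
readConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  validateConfig(cfg)
  cfg
}

#' @rdname readConfig
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Validate a configuration before any stage runs
#'
#' @param config configuration list.
#' @return Invisibly TRUE; otherwise an error naming the offending key.
#' @export
validateConfig <- function(config) {
  need <- c("seed", "outdir", "simulate", "bioprocess", "offgas", "fba",
            "transcriptomics")
  miss <- setdiff(need, names(config))
  if (length(miss)) stop("config error: missing keys ",
                         paste(miss, collapse = ", "))
  tc <- config$transcriptomics
  if (tc$fc_threshold <= 1) stop("config error: fc_threshold must exceed 1")
  if (tc$q_threshold <= 0 || tc$q_threshold >= 1)
    stop("config error: q_threshold must lie in (0, 1)")
  if (config$bioprocess$od_dcw_k <= 0) stop("config error: od_dcw_k <= 0")
  if (config$simulate$noise_sd < 0) stop("config error: negative noise_sd")
  invisible(TRUE)
}

# replicate trace + broth -> RatePanel (the inversion the simulator's
# forward model is built to satisfy)
.replicatePanel <- function(study, id, cfg) {
  gr <- study$grid
  cond <- unique(study$offgas$condition[study$offgas$replicate_id == id])
  i <- which(paste0(gr$gas, "_D", gr$dilution) == cond)
  inlet <- gasStream(gr$flow[i], gr$feed[[i]])
  trace <- study$offgas[study$offgas$replicate_id == id,
                        c("time_h", "species", "mole_fraction")]
  X <- biomassFromOD(mean(study$od[[id]]), cfg$bioprocess$od_dcw_k)
  og <- offgasRates(inlet, trace, X, gr$volume[i],
                    cvThreshold = cfg$offgas$cv_threshold,
                    molarVolume = cfg$offgas$molar_volume)
  broth <- study$broth[study$broth$replicate_id == id, ]
  conc <- setNames(broth$conc_mM, broth$compound)
  D <- gr$dilution[i]
  q <- c(og$q,
         acetate = liquidSpecificRate(conc[["acetate"]], D, X),
         ethanol = liquidSpecificRate(conc[["ethanol"]], D, X,
                                      strippedQ = og$ethanolStripping),
         BDO = liquidSpecificRate(conc[["BDO"]], D, X))
  role <- c(og$role, acetate = "production", ethanol = "production",
            BDO = "production")
  # a gas species absent from the feed and not produced shows ~0 flux; drop
  # H2 on CO gas to keep panels tidy
  if (gr$gas[i] == "CO" && "H2" %in% names(q) && q[["H2"]] < 1e-9) {
    q <- q[names(q) != "H2"]; role <- role[names(role) != "H2"]
  }
  ratePanel(D, q, role, biomass = X, volume = gr$volume[i])
}

#' Run the full pipeline
#'
#' Stages in dependency order: simulate (forward model with ground truth) ->
#' rates (off-gas inversion + liquid rates per replicate, condition
#' mean +- SD) -> balance (C-mol carbon balances, product ratios, rate fold
#' changes) -> fluxes (maintenance-ATP estimation and derived statistics per
#' condition; theoretical CO2 dissipation) -> transcriptome (RPKM filter,
#' within-gas DEG calling, overlaps, clustering, enrichment, tight-control
#' genes) -> report. Outputs are written under `config$outdir`; a failure
#' aborts naming the stage. One global seed makes the run deterministic.
#'
#' @param config list from [defaultConfig()] or [readConfig()].
#' @return A report list (class `acetofluxReport`) with per-stage summaries
#'   and provenance.
#' @export
runPipeline <- function(config = defaultConfig()) {
  validateConfig(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- "simulate"
  report <- list()
  tryCatch({
    sim <- config$simulate
    study <- simulateChemostatStudy(noiseSd = sim$noise_sd,
                                    strippedFraction = sim$stripped_fraction,
                                    nGenes = sim$n_genes,
                                    rnaReplicates = sim$rna_replicates,
                                    seed = config$seed)
    writeStudyTables(study, file.path(config$outdir, "simulated"))

    stage <- "rates"
    ids <- unique(study$offgas$replicate_id)
    panels <- lapply(setNames(ids, ids), function(id)
      .replicatePanel(study, id, config))
    conds <- unique(study$offgas$condition)
    condPanels <- lapply(setNames(conds, conds), function(cd) {
      reps <- ids[vapply(ids, function(id)
        unique(study$offgas$condition[study$offgas$replicate_id == id]) == cd,
        logical(1))]
      summariseReplicates(panels[reps])
    })
    rateTab <- do.call(rbind, lapply(conds, function(cd)
      cbind(condition = cd, condPanels[[cd]]$summary)))
    utils::write.table(rateTab, file.path(config$outdir, "rates_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$rates <- rateTab

    stage <- "balance"
    balances <- lapply(condPanels, function(cp)
      carbonBalance(cp$panel, config$bioprocess$q_cysteine,
                    speciesCarbon(config$bioprocess$biomass_carbon)))
    balTab <- do.call(rbind, lapply(names(balances), function(cd) {
      nb <- normalisedFractions(balances[[cd]])
      data.frame(condition = cd, product = names(nb),
                 normalised_pct = unname(nb),
                 recovery_pct = recovery(balances[[cd]]))
    }))
    utils::write.table(balTab, file.path(config$outdir, "carbon_balance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$carbon_balance <- balTab
    report$product_ratio <- vapply(condPanels, function(cp)
      productRatio(cp$panel@q[["acetate"]], cp$panel@q[["ethanol"]]),
      numeric(1))
    byGas <- split(panels, vapply(names(panels), function(id)
      sub("_D.*", "", id), character(1)))
    report$fold_changes <- lapply(byGas, foldChangeTable)

    stage <- "fluxes"
    model <- buildCoreModel()
    flux <- lapply(condPanels, function(cp)
      tryCatch(estimateFluxes(model, cp$panel,
                              tolerance = config$fba$tolerance)@derived,
               error = function(e) list(error = conditionMessage(e))))
    report$fluxes <- flux
    report$theoretical_co2 <- c(
      ethanol_pure_CO = theoreticalCO2Loss(model, Inf, "ethanol")$co2_percent,
      ethanol_CO_H2_2 = theoreticalCO2Loss(model, 2, "ethanol")$co2_percent)

    stage <- "transcriptome"
    tc <- config$transcriptomics
    counts <- SummarizedExperiment::assay(study$se, "counts")
    meta <- as.data.frame(SummarizedExperiment::colData(study$se))
    lens <- SummarizedExperiment::rowData(study$se)$length_bp
    rp <- rpkm(counts, lens)
    expressed <- filterExpressed(rp, tc$rpkm_threshold, tc$rpkm_min_samples)
    degs <- degCallAll(counts[expressed, ], meta,
                       librarySizes = colSums(counts),
                       fcThreshold = tc$fc_threshold,
                       qThreshold = tc$q_threshold)
    degSets <- lapply(degs, function(d) d$gene[d$is_deg])
    allDegs <- Reduce(union, degSets)
    report$deg_counts <- vapply(degSets, length, integer(1))
    report$total_degs <- length(allDegs)
    hiCmp <- grep(":2.79v1", names(degSets), value = TRUE)
    if (length(hiCmp) == 2)
      report$deg_overlap_high_mu <- overlapCounts(degSets[hiCmp])
    if (length(allDegs) >= 2) {
      profiles <- t(apply(log2(cpm(counts[allDegs, , drop = FALSE]) + 0.5), 1,
                          function(x) tapply(x, paste(meta$gas, meta$mu), mean)))
      cl <- clusterProfiles(profiles)
      report$clusters <- list(k = cl$k, sizes = table(cl$assignments))
      enr <- enrichment(allDegs, study$annotations$go, expressed)
      report$enrichment <- utils::head(enr, 10)
    }
    ts <- tightControlSelection(counts[expressed, ], meta, degs,
                                librarySizes = colSums(counts),
                                alpha = tc$slope_alpha)
    report$tight_control <- ts
    report$n_tight_control <- sum(ts$retained)
    utils::write.table(ts, file.path(config$outdir, "tight_control.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "report"
    report$provenance <- list(seed = config$seed,
                              package_version = as.character(
                                utils::packageVersion("acetoflux")),
                              n_conditions = length(conds),
                              config = config)
    payload <- jsonlite::toJSON(.reportPayload(report), auto_unbox = TRUE,
                                digits = 10, pretty = TRUE)
    writeLines(payload, file.path(config$outdir, "report.json"))
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  class(report) <- "acetofluxReport"
  report
}

# JSON-serialisable subset of the report (drop large tables kept on disk)
.reportPayload <- function(report) {
  list(rates = report$rates,
       carbon_balance = report$carbon_balance,
       product_ratio = as.list(report$product_ratio),
       fold_changes = lapply(report$fold_changes, function(df)
         df[, c("species", "fold")]),
       fluxes = report$fluxes,
       theoretical_co2 = as.list(report$theoretical_co2),
       deg_counts = as.list(report$deg_counts),
       total_degs = report$total_degs,
       clusters = if (!is.null(report$clusters))
         list(k = report$clusters$k) else NULL,
       n_tight_control = report$n_tight_control,
       provenance = report$provenance[c("seed", "package_version",
                                        "n_conditions")])
}

#' @export
print.acetofluxReport <- function(x, ...) {
  cat("acetoflux pipeline report\n")
  cat(sprintf("  conditions: %d, seed %d\n",
              x$provenance$n_conditions, x$provenance$seed))
  cat(sprintf("  total DEGs: %d; tight-control genes: %d\n",
              x$total_degs, x$n_tight_control))
  cat(sprintf("  theoretical CO2 loss (ethanol): %.1f%% (pure CO), %.1f%% (CO:H2 = 2)\n",
              x$theoretical_co2[["ethanol_pure_CO"]],
              x$theoretical_co2[["ethanol_CO_H2_2"]]))
  invisible(x)
}

#' Write the simulated study as plain-text tables
#'
#' Off-gas traces, broth/OD, counts, gene lengths, annotations and the
#' ground truth (JSON), matching the package's external interfaces.
#'
#' @param study a `ChemostatStudy`; @param dir output directory.
#' @return Invisibly, the directory.
#' @export
writeStudyTables <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(study$offgas, file.path(dir, "offgas_traces.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.table(study$broth, file.path(dir, "broth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  od <- data.frame(replicate_id = rep(names(study$od),
                                      lengths(study$od)),
                   od600 = unlist(study$od, use.names = FALSE))
  utils::write.table(od, file.path(dir, "od600.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  counts <- SummarizedExperiment::assay(study$se, "counts")
  utils::write.table(data.frame(gene_id = rownames(counts), counts,
                                check.names = FALSE),
                     file.path(dir, "counts.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  lens <- SummarizedExperiment::rowData(study$se)$length_bp
  utils::write.table(data.frame(gene_id = rownames(counts), length_bp = lens),
                     file.path(dir, "gene_lengths.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(study$annotations$go, file.path(dir, "annotation_go.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$annotations$cog, file.path(dir, "annotation_cog.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- list(
    physiology = lapply(study$truth$physiology, function(ph) list(
      mu = ph@mu, q = as.list(ph@q),
      carbon_fractions = as.list(ph@productCarbonFractions),
      maintenance_atp = ph@maintenanceATP, biomass = ph@biomassConc)),
    enriched_terms = study$truth$enrichedTerms,
    stripped_fraction = study$truth$strippedFraction)
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = 10,
                              pretty = TRUE),
             file.path(dir, "truth.json"))
  invisible(dir)
}
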