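#' RPKM from counts, gene lengths and library sizes
#'
#' `rpkm = counts * 1e9 / (librarySize * length_bp)`.
#'
#' @param counts genes x samples matrix of non-negative integers.
#' @param geneLengths bp per gene (> 0), recycled across samples.
#' @param librarySizes total mapped reads per sample (> 0); defaults to the
#'   column sums of `counts`.
#' @return Matrix of RPKM values, same dimensions as `counts`.
#' @examples
#' rpkm(matrix(100), geneLengths = 1000, librarySizes = 1e6)   # 100
#' @export
rpkm <- function(counts, geneLengths, librarySizes = colSums(counts)) {
  if (any(geneLengths <= 0)) stop("gene lengths must be positive")
  if (any(librarySizes <= 0)) stop("zero library size")
  counts * 1e9 / outer(geneLengths, librarySizes)
}

#' Counts per million
#' @inheritParams rpkm
#' @return CPM matrix.
#' @export
cpm <- function(counts, librarySizes = colSums(counts)) {
  if (any(librarySizes <= 0)) stop("zero library size")
  sweep(counts, 2, librarySizes / 1e6, "/")
}

#' Filter to expressed genes
#'
#' Keeps genes with RPKM strictly above `threshold` in at least `minSamples`
#' samples (the expression filter applied before differential testing).
#' Idempotent: filtering a filtered matrix changes nothing.
#'
#' @param rpkmMatrix genes x samples RPKM matrix.
#' @param threshold RPKM cutoff (strict >, default 10).
#' @param minSamples minimum samples above threshold (default 2).
#' @return Character vector of retained gene names (or indices when unnamed).
#' @export
filterExpressed <- function(rpkmMatrix, threshold = 10, minSamples = 2) {
  keep <- rowSums(rpkmMatrix > threshold) >= minSamples
  if (is.null(rownames(rpkmMatrix))) which(keep) else rownames(rpkmMatrix)[keep]
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order.
#' @export
bhFdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes for one within-gas comparison
#'
#' Per-gene Welch t-test on log2(CPM + 0.5) between two mu levels of the
#' same gas mix, Benjamini-Hochberg adjustment across the tested genes, and
#' the DEG flag `|FC| > fcThreshold & q < qThreshold`. Fold change is the
#' ratio of group geometric means on the CPM scale. Comparisons across gas
#' mixes are refused: the design compares mu levels within one gas only.
#'
#' @param counts genes x samples count matrix (already expression-filtered).
#' @param meta data.frame with per-sample `gas` and `mu` (rows = columns of
#'   `counts`).
#' @param gas gas mix of the comparison.
#' @param muA,muB the two mu levels (the fold change is B over A).
#' @param librarySizes per-sample totals; default column sums.
#' @param fcThreshold,qThreshold DEG thresholds (defaults 1.5 and 0.05).
#' @return data.frame per gene: log2 fold-change, raw p, q, is_deg.
#' @export
degCall <- function(counts, meta, gas, muA, muB,
                    librarySizes = colSums(counts),
                    fcThreshold = 1.5, qThreshold = 0.05) {
  if (length(unique(meta$gas[meta$mu %in% c(muA, muB)])) > 1 &&
      missing(gas))
    stop("specify the gas mix")
  if (!all(c(muA, muB) %in% meta$mu[meta$gas == gas]))
    stop("cross-gas or missing-mu comparison requested: mu levels are only ",
         "compared within one gas mix")
  selA <- meta$gas == gas & abs(meta$mu - muA) < 1e-9
  selB <- meta$gas == gas & abs(meta$mu - muB) < 1e-9
  if (sum(selA) < 2 || sum(selB) < 2) stop("need >= 2 replicates per side")
  lc <- log2(cpm(counts, librarySizes) + 0.5)
  A <- lc[, selA, drop = FALSE]; B <- lc[, selB, drop = FALSE]
  n <- nrow(lc)
  pv <- numeric(n); lfc <- numeric(n)
  for (i in seq_len(n)) {
    a <- A[i, ]; b <- B[i, ]
    lfc[i] <- mean(b) - mean(a)
    pv[i] <- if (stats::sd(a) == 0 && stats::sd(b) == 0) 1 else
      tryCatch(stats::t.test(b, a)$p.value, error = function(e) 1)
  }
  q <- bhFdr(pv)
  out <- data.frame(gene = rownames(counts), log2fc = lfc, p = pv, q = q,
                    is_deg = abs(lfc) > log2(fcThreshold) & q < qThreshold,
                    stringsAsFactors = FALSE)
  attr(out, "comparison") <- sprintf("%s: mu %g vs %g", gas, muB, muA)
  out
}

#' All within-gas mu comparisons of a design
#'
#' Runs [degCall()] for every mu pair within each gas (for three mu levels:
#' 2.0 vs 1.0, 2.8 vs 1.0, 2.8 vs 2.0, per gas).
#'
#' @inheritParams degCall
#' @return Named list of DEG tables, names like `"CO:2.79v1.02"`.
#' @export
degCallAll <- function(counts, meta, librarySizes = colSums(counts),
                       fcThreshold = 1.5, qThreshold = 0.05) {
  out <- list()
  for (g in unique(meta$gas)) {
    mus <- sort(unique(meta$mu[meta$gas == g]))
    for (i in seq_along(mus)) for (j in seq_along(mus)) {
      if (j <= i) next
      nm <- sprintf("%s:%gv%g", g, mus[j], mus[i])
      out[[nm]] <- degCall(counts, meta, g, mus[i], mus[j], librarySizes,
                           fcThreshold, qThreshold)
    }
  }
  out
}

#' Venn region counts for 2-3 DEG sets
#'
#' @param degSets named list of character vectors (gene ids).
#' @return Named integer vector of exact region cardinalities; region names
#'   join the member sets with `&` (e.g. `"A&B"` is in A and B but not in
#'   any other set).
#' @export
overlapCounts <- function(degSets) {
  k <- length(degSets)
  if (k < 2 || k > 3) stop("2 or 3 sets supported")
  universe <- Reduce(union, degSets)
  member <- vapply(degSets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL, names(degSets)))
  key <- apply(member, 1, function(m) paste(names(degSets)[m], collapse = "&"))
  regions <- unlist(lapply(seq_len(k), function(n)
    utils::combn(names(degSets), n, paste, collapse = "&")))
  out <- setNames(integer(length(regions)), regions)
  tb <- table(key)
  out[names(tb)] <- as.integer(tb)
  out
}

# Lance-Williams Ward.D2 agglomeration is delegated to stats::hclust; the
# brute-force O(n^3) oracle lives in the test suite.

#' Cluster mu-dependent expression profiles
#'
#' Row-z-scores the profile matrix (constant rows are excluded with a
#' warning), clusters with Ward.D2 on Euclidean distance, and chooses the
#' cluster count at the sharpest relative drop in dendrogram merge height:
#' cutting between merge heights H_j > H_(j+1) (sorted descending) where
#' `(H_j - H_(j+1)) / H_j` is largest yields j+1 clusters; ties take the
#' smaller count.
#'
#' @param profiles genes x conditions matrix (e.g. mean log2 CPM per
#'   condition for DEGs).
#' @param maxClusters largest cluster count considered (default 12).
#' @param k force a cluster count instead of the elbow choice.
#' @return list with `hclust`, `k`, `assignments` (named), `heights`,
#'   `excluded` (constant rows).
#' @export
clusterProfiles <- function(profiles, maxClusters = 12, k = NULL) {
  if (nrow(profiles) < 2) stop("need >= 2 profiles")
  rsd <- apply(profiles, 1, stats::sd)
  excluded <- rownames(profiles)[rsd == 0]
  if (length(excluded)) {
    warning(length(excluded), " constant (zero-variance) profiles excluded")
    profiles <- profiles[rsd > 0, , drop = FALSE]
  }
  if (nrow(profiles) < 2)
    return(list(hclust = NULL, k = 1,
                assignments = setNames(rep(1, nrow(profiles)),
                                       rownames(profiles)),
                heights = numeric(0), excluded = excluded))
  z <- t(scale(t(profiles)))
  hc <- stats::hclust(stats::dist(z), method = "ward.D2")
  H <- sort(hc$height, decreasing = TRUE)
  if (max(H) < 1e-12) {
    kk <- 1
  } else if (is.null(k)) {
    jmax <- min(maxClusters - 1, length(H) - 1)
    drops <- (H[seq_len(jmax)] - H[seq_len(jmax) + 1]) / H[seq_len(jmax)]
    kk <- which.max(drops) + 1       # which.max takes the first (smaller k) tie
  } else kk <- k
  list(hclust = hc, k = kk,
       assignments = stats::cutree(hc, kk),
       heights = H, excluded = excluded)
}

#' Term over-representation by Fisher's exact test
#'
#' One-sided (enrichment direction) Fisher's exact test per term on the
#' 2x2 table of gene-set membership vs term annotation over the universe,
#' with Benjamini-Hochberg adjustment across terms. Terms with no annotated
#' gene in the universe are skipped.
#'
#' @param geneSet character vector, must be a subset of `universe`.
#' @param annotation data.frame with columns `gene_id`, `term_id` (GO terms,
#'   COG letters, or any categorical labels).
#' @param universe character vector of all eligible genes.
#' @param qThreshold significance label threshold (default 0.05).
#' @return data.frame per term: counts, odds ratio, Fisher p, q, significant.
#' @export
enrichment <- function(geneSet, annotation, universe, qThreshold = 0.05) {
  if (length(universe) == 0) stop("empty universe")
  if (!all(geneSet %in% universe)) stop("geneSet must be a subset of universe")
  ann <- annotation[annotation$gene_id %in% universe, ]
  terms <- unique(ann$term_id)
  res <- lapply(terms, function(tm) {
    tg <- unique(ann$gene_id[ann$term_id == tm])
    a <- sum(geneSet %in% tg)                       # in set, in term
    b <- length(geneSet) - a                        # in set, not term
    cc <- length(tg) - a                            # out of set, in term
    d <- length(universe) - length(geneSet) - cc
    p <- stats::phyper(a - 1, a + cc, b + d, a + b, lower.tail = FALSE)
    or <- if (b * cc == 0) Inf else (a * d) / (b * cc)
    data.frame(term_id = tm, set_in_term = a, set_total = length(geneSet),
               term_size = a + cc, universe = length(universe),
               odds_ratio = or, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bhFdr(out$p)
  out$significant <- out$q < qThreshold
  out[order(out$p), ]
}

# OLS slope of log2 expression vs mu with its standard error
.slopeFit <- function(y, mu) {
  fit <- stats::lm(y ~ mu)
  s <- summary(fit)$coefficients
  c(slope = unname(s["mu", "Estimate"]), se = unname(s["mu", "Std. Error"]),
    df = fit$df.residual)
}

#' Select genes with tightly mu-controlled expression on both gases
#'
#' Three steps. (1) Keep genes that are DEGs in both consecutive
#' comparisons (mid vs low mu AND high vs mid mu) on both gases, with a
#' consistent monotone direction (all four fold-changes up, or all down).
#' (2) Per gas, fit the ordinary least-squares slope of log2(CPM + 0.5)
#' against mu. (3) Compare the two slopes with a t-test
#' (`t = (b1 - b2) / sqrt(se1^2 + se2^2)`, Welch-Satterthwaite df). By
#' default genes whose slopes are statistically indistinguishable
#' (p >= `alpha`) are retained - the "same expression trend on both gases"
#' reading; `polarity = "different"` flips to the literal p < alpha rule.
#'
#' @param counts genes x samples counts (expression-filtered).
#' @param meta per-sample `gas` and `mu`; both gases need >= 3 mu levels.
#' @param degTables list from [degCallAll()].
#' @param librarySizes per-sample totals.
#' @param alpha slope-test level (default 0.05).
#' @param polarity `"equal"` (retain p >= alpha, default) or `"different"`.
#' @return data.frame per candidate gene: slopes, SEs, t, p, retained.
#' @export
tightControlSelection <- function(counts, meta, degTables,
                                  librarySizes = colSums(counts),
                                  alpha = 0.05,
                                  polarity = c("equal", "different")) {
  polarity <- match.arg(polarity)
  gases <- sort(unique(meta$gas))
  if (length(gases) != 2) stop("exactly two gas mixes expected")
  for (g in gases)
    if (length(unique(meta$mu[meta$gas == g])) < 3)
      stop("missing mu level: both gases need >= 3 mu levels")

  # step 1: monotone DEGs on both gases (both consecutive comparisons)
  consec <- function(g) {
    mus <- sort(unique(meta$mu[meta$gas == g]))
    lo <- sprintf("%s:%gv%g", g, mus[2], mus[1])
    hi <- sprintf("%s:%gv%g", g, mus[3], mus[2])
    if (!all(c(lo, hi) %in% names(degTables)))
      stop("degTables must contain the consecutive within-gas comparisons")
    list(lo = degTables[[lo]], hi = degTables[[hi]])
  }
  keep <- NULL
  dir <- list()
  for (g in gases) {
    cc <- consec(g)
    both <- cc$lo$is_deg & cc$hi$is_deg &
      sign(cc$lo$log2fc) == sign(cc$hi$log2fc)
    dir[[g]] <- sign(cc$lo$log2fc)
    gk <- cc$lo$gene[both]
    keep <- if (is.null(keep)) gk else intersect(keep, gk)
  }
  g1 <- degTables[[1]]$gene
  same_dir <- dir[[gases[1]]] == dir[[gases[2]]]
  keep <- intersect(keep, g1[same_dir])
  if (!length(keep))
    return(data.frame(gene = character(0), slope_1 = numeric(0),
                      slope_2 = numeric(0), t = numeric(0), p = numeric(0),
                      retained = logical(0)))

  # steps 2-3: per-gas slopes and the slope-equality t-test
  lc <- log2(cpm(counts, librarySizes) + 0.5)
  res <- lapply(keep, function(gene) {
    f <- lapply(gases, function(g) {
      sel <- meta$gas == g
      .slopeFit(lc[gene, sel], meta$mu[sel])
    })
    b1 <- f[[1]]["slope"]; b2 <- f[[2]]["slope"]
    se2 <- f[[1]]["se"]^2 + f[[2]]["se"]^2
    t <- (b1 - b2) / sqrt(se2)
    df <- se2^2 / (f[[1]]["se"]^4 / f[[1]]["df"] + f[[2]]["se"]^4 / f[[2]]["df"])
    p <- 2 * stats::pt(-abs(t), df)
    data.frame(gene = gene, slope_1 = unname(b1), slope_2 = unname(b2),
               se_1 = unname(f[[1]]["se"]), se_2 = unname(f[[2]]["se"]),
               t = unname(t), p = unname(p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$retained <- if (polarity == "equal") out$p >= alpha else out$p < alpha
  names(out)[names(out) == "slope_1"] <- paste0("slope_", gases[1])
  names(out)[names(out) == "slope_2"] <- paste0("slope_", gases[2])
  out
}
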