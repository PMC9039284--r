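test_that("RPKM follows its definition and scales linearly", {
  expect_equal(rpkm(matrix(0), 1000, 1e6)[1, 1], 0)
  expect_equal(rpkm(matrix(100), 1000, 1e6)[1, 1], 100)
  expect_equal(rpkm(matrix(50), 500, 5e6)[1, 1], 20)
  m <- matrix(rpois(60, 50), 10, 6)
  r1 <- rpkm(m, rep(1000, 10), rep(2e6, 6))
  expect_equal(rpkm(2 * m, rep(1000, 10), rep(2e6, 6)), 2 * r1)
  expect_equal(rpkm(m, rep(2000, 10), rep(2e6, 6)), r1 / 2)
  expect_equal(rpkm(m, rep(1000, 10), rep(4e6, 6)), r1 / 2)
  expect_error(rpkm(m, rep(1000, 10), rep(0, 6)), "library")
  expect_error(rpkm(m, rep(0, 10), rep(1e6, 6)), "length")
})

test_that("expression filtering is strict and idempotent", {
  rp <- rbind(at_threshold = rep(10, 4),
              two_samples = c(11, 11, 0, 0),
              one_huge = c(1e6, 0, 0, 0),
              expressed = c(50, 60, 70, 80))
  kept <- filterExpressed(rp)
  expect_identical(kept, c("two_samples", "expressed"))
  expect_identical(filterExpressed(rp[kept, ]), kept)
})

test_that("BH adjustment matches the brute-force step-up definition", {
  expect_equal(bhFdr(0.03), 0.03)
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(5)
  for (rep in 1:1000) {
    p <- runif(sample(1:50, 1))^sample(c(1, 2, 4), 1)
    expect_equal(bhFdr(p), bhOracle(p), tolerance = 1e-12)
  }
  expect_error(bhFdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the DEG caller controls false positives and finds planted effects", {
  grid <- defaultConditionGrid()
  design <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i)
    data.frame(gas = grid$gas[i], mu = grid$dilution[i], replicate = 1:3)))
  design$sample <- sprintf("%s_D%g_s%d", design$gas, design$mu,
                           design$replicate)

  # global null: all slopes zero
  nullCfg <- degConfig()
  nullCfg$nUp <- 0; nullCfg$nDown <- 0; nullCfg$nDiverge <- 0
  cn <- simulateCounts(1000, design, nullCfg, seed = 21)
  dn <- degCall(cn$counts, design, "CO", 1.02, 2.79, cn$libSizes)
  expect_lte(mean(dn$is_deg), 0.01)

  # planted effects: recall and precision at the default thresholds
  cp <- simulateCounts(2000, design, seed = 22)
  rp <- rpkm(cp$counts, cp$geneLengths, cp$libSizes)
  keep <- filterExpressed(rp)
  d <- degCall(cp$counts[keep, ], design, "syngas", 1.01, 2.79, cp$libSizes)
  truth <- cp$truth[match(d$gene, cp$truth$gene), ]
  planted <- truth$class %in% c("up", "down", "diverge")
  recall <- sum(d$is_deg & planted) / sum(planted)
  precision <- sum(d$is_deg & planted) / sum(d$is_deg)
  expect_gte(recall, 0.8)
  expect_gte(precision, 0.9)
  # q-values dominate raw p-values; flags follow the thresholds exactly
  expect_true(all(d$q >= d$p - 1e-12))
  expect_identical(d$is_deg, abs(d$log2fc) > log2(1.5) & d$q < 0.05)
  # planted direction is recovered
  up_called <- d$gene[d$is_deg & d$log2fc > 0]
  expect_gt(mean(truth$class[match(up_called, truth$gene)] == "up"), 0.45)

  expect_error(degCall(cp$counts, design, "CO", 1.01, 2.79), "within one gas")
  comparisons <- degCallAll(cp$counts[keep, ], design, cp$libSizes)
  expect_equal(length(comparisons), 6)   # three mu pairs per gas
})

test_that("Venn region counts are exact for two and three sets", {
  expect_equal(unname(overlapCounts(list(A = "a", B = "b"))), c(1, 1, 0))
  ov <- overlapCounts(list(A = c("a", "b", "c"), B = c("b", "c", "d")))
  expect_equal(unname(ov["A&B"]), 2)
  expect_equal(unname(ov["A"]), 1)
  three <- overlapCounts(list(X = c("a", "b", "c", "g"),
                              Y = c("b", "c", "d", "g"),
                              Z = c("c", "e", "g")))
  expect_equal(unname(three["X&Y&Z"]), 2)      # c and g
  expect_equal(unname(three["X&Y"]), 1)        # b
  expect_equal(sum(three), length(unique(c("a","b","c","d","e","g"))))
  expect_error(overlapCounts(list(A = "a")), "2 or 3")
})

test_that("Ward.D2 clustering matches the brute-force agglomeration oracle", {
  set.seed(8)
  X <- rbind(matrix(rnorm(30 * 4, 0), 30, 4),
             matrix(rnorm(20 * 4, 6), 20, 4))
  oracle_h <- wardD2Oracle(X)
  hc <- stats::hclust(dist(X), method = "ward.D2")
  expect_equal(sort(hc$height), sort(oracle_h), tolerance = 1e-8)

  # two blobs with opposite profile shapes (z-scoring removes level, so the
  # groups must differ in shape): the elbow picks 2 and recovers membership
  shape <- c(-1, -1, 1, 1)
  X <- rbind(matrix(rnorm(30 * 4, 0, 0.4), 30, 4, byrow = TRUE) +
               matrix(3 * shape, 30, 4, byrow = TRUE),
             matrix(rnorm(20 * 4, 0, 0.4), 20, 4, byrow = TRUE) +
               matrix(-3 * shape, 20, 4, byrow = TRUE))
  rownames(X) <- paste0("g", 1:50)
  cl <- clusterProfiles(X)
  expect_equal(cl$k, 2)
  truth <- rep(1:2, c(30, 20))
  tab <- table(cl$assignments, truth)
  expect_equal(sum(apply(tab, 1, max)), 50)

  # identical profiles collapse to one cluster
  same <- matrix(rep(c(1, 2, 3, 4), each = 6), 6, 4)
  rownames(same) <- paste0("s", 1:6)
  expect_warning(res <- clusterProfiles(rbind(same, flat = c(5, 5, 5, 5))),
                 "constant")
  expect_equal(res$k, 1)
})

test_that("Fisher enrichment equals the hypergeometric tail oracle", {
  # the whole universe as the query can enrich nothing
  ann <- data.frame(gene_id = paste0("g", 1:50),
                    term_id = rep(c("T1", "T2"), 25))
  uni <- paste0("g", 1:50)
  e0 <- enrichment(uni, ann, uni)
  expect_true(all(e0$p == 1))

  # direct tail-sum comparison on a specified 2x2 table:
  # set 100 genes, 10 in term; universe 1000, term size 20
  set.seed(13)
  uni <- paste0("g", 1:1000)
  term <- c(paste0("g", 1:10), paste0("g", 101:110))       # 20 genes
  gset <- c(paste0("g", 1:10), paste0("g", 201:290))       # 100 genes
  ann2 <- data.frame(gene_id = term, term_id = "TX")
  e1 <- enrichment(gset, ann2, uni)
  expect_equal(e1$p, hyperTailOracle(10, 20, 1000, 100), tolerance = 1e-10)

  # randomised tables against the oracle
  for (i in 1:25) {
    N <- sample(200:800, 1)
    uni <- paste0("u", seq_len(N))
    tsize <- sample(5:80, 1); ssize <- sample(20:120, 1)
    term <- sample(uni, tsize)
    gset <- sample(uni, ssize)
    a <- sum(gset %in% term)
    e <- enrichment(gset, data.frame(gene_id = term, term_id = "T"), uni)
    expect_equal(e$p, hyperTailOracle(a, tsize, N, ssize), tolerance = 1e-10)
  }
  expect_error(enrichment("g1", ann, character(0)), "universe")
})

test_that("known enriched annotation terms are detected on synthetic truth", {
  # large universe so slope genes are a small background fraction
  grid <- defaultConditionGrid()
  design <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i)
    data.frame(gas = grid$gas[i], mu = grid$dilution[i], replicate = 1:2)))
  design$sample <- sprintf("%s_D%g_s%d", design$gas, design$mu,
                           design$replicate)
  cnt <- simulateCounts(2000, design, seed = 17)
  ann <- simulateAnnotations(cnt$truth, nTerms = 40, nEnriched = 5,
                             sizeRange = c(30, 150), enrichedShare = 0.7,
                             seed = 17)
  slope_genes <- cnt$truth$gene[cnt$truth$class %in% c("up", "down")]
  e <- enrichment(slope_genes, ann$go, cnt$truth$gene)
  called <- e$term_id[e$significant]
  expect_true(all(ann$enrichedTerms %in% called))
  # non-enriched terms stay mostly quiet
  expect_lte(sum(!(called %in% ann$enrichedTerms)), 2)
})

test_that("tight-control selection keeps equal slopes and drops divergent ones", {
  grid <- defaultConditionGrid()
  design <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i)
    data.frame(gas = grid$gas[i], mu = grid$dilution[i], replicate = 1:3)))
  design$sample <- sprintf("%s_D%g_s%d", design$gas, design$mu,
                           design$replicate)
  # identical slopes on both gases and no divergent genes (divergent genes
  # shift the CPM normalisation differently per gas, which the slope test
  # rightly detects at very low noise)
  cfg <- degConfig()
  cfg$dispersion <- 0.002      # low noise so step 1 passes for planted genes
  cfg$lfcRange <- c(2.5, 3.5)
  cfg$nDiverge <- 0
  cnt <- simulateCounts(600, design, cfg, seed = 31)
  degs <- degCallAll(cnt$counts, design, cnt$libSizes)
  ts <- tightControlSelection(cnt$counts, design, degs, cnt$libSizes)
  truth <- cnt$truth[match(ts$gene, cnt$truth$gene), ]
  expect_false(any(truth$class == "flat"))
  # genes planted with identical slopes on both gases are mostly retained
  expect_gt(mean(ts$retained), 0.8)

  # gas-divergent genes never reach the slope test (excluded at step 1)
  cfg2 <- degConfig(); cfg2$dispersion <- 0.002; cfg2$lfcRange <- c(2.5, 3.5)
  cnt2 <- simulateCounts(600, design, cfg2, seed = 32)
  degs2 <- degCallAll(cnt2$counts, design, cnt2$libSizes)
  ts_dv <- tightControlSelection(cnt2$counts, design, degs2, cnt2$libSizes)
  truth2 <- cnt2$truth[match(ts_dv$gene, cnt2$truth$gene), ]
  expect_false(any(truth2$class == "diverge"))

  # the slope t-statistic equals a brute-force two-regression computation
  lc <- log2(cpm(cnt$counts, cnt$libSizes) + 0.5)
  set.seed(41)
  for (gene in sample(rownames(lc), 100)) {
    stats <- lapply(c("CO", "syngas"), function(g) {
      sel <- design$gas == g
      x <- design$mu[sel]; y <- lc[gene, sel]
      b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
      a <- mean(y) - b * mean(x)
      res <- y - a - b * x
      se <- sqrt(sum(res^2) / (length(x) - 2) / sum((x - mean(x))^2))
      c(b = b, se = se)
    })
    tt <- (stats[[1]]["b"] - stats[[2]]["b"]) /
      sqrt(stats[[1]]["se"]^2 + stats[[2]]["se"]^2)
    f1 <- acetoflux:::.slopeFit(lc[gene, design$gas == "CO"],
                                design$mu[design$gas == "CO"])
    f2 <- acetoflux:::.slopeFit(lc[gene, design$gas == "syngas"],
                                design$mu[design$gas == "syngas"])
    tpkg <- (f1["slope"] - f2["slope"]) / sqrt(f1["se"]^2 + f2["se"]^2)
    expect_equal(unname(tpkg), unname(tt), tolerance = 1e-10)
  }

  # requesting the literal polarity flips the retained set
  ts2 <- tightControlSelection(cnt$counts, design, degs, cnt$libSizes,
                               polarity = "different")
  expect_identical(ts2$retained, !ts$retained)

  # a missing mu level is a design error
  sub <- design$gas == "syngas" & design$mu < 2.5
  expect_error(tightControlSelection(cnt$counts[, !(design$gas == "syngas" &
                                                      design$mu > 2.5)],
                                     design[!(design$gas == "syngas" &
                                                design$mu > 2.5), ], degs),
               "mu level")
})
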