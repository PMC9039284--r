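# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Brute-force LP oracle: enumerate all basic solutions (vertices) of
# max obj'v s.t. S v = 0, lb <= v <= ub, by fixing every subset of n - rank
# variables at a bound and solving the remaining square system.
enumerateVerticesLP <- function(S, lb, ub, obj) {
  n <- ncol(S)
  r <- qr(S)$rank
  k <- n - r
  best <- -Inf; bestv <- NULL
  fix_sets <- utils::combn(n, k, simplify = FALSE)
  for (fs in fix_sets) {
    grid <- expand.grid(rep(list(c(1, 2)), k))
    for (gi in seq_len(nrow(grid))) {
      v <- rep(NA_real_, n)
      v[fs] <- ifelse(unlist(grid[gi, ]) == 1, lb[fs], ub[fs])
      if (any(!is.finite(v[fs]))) next
      freeIdx <- setdiff(seq_len(n), fs)
      A <- S[, freeIdx, drop = FALSE]
      b <- -S[, fs, drop = FALSE] %*% v[fs]
      sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
      if (is.null(sol)) next
      if (max(abs(A %*% sol - b)) > 1e-8) next
      v[freeIdx] <- sol
      if (any(v < lb - 1e-8) || any(v > ub + 1e-8)) next
      z <- sum(obj * v)
      if (z > best + 1e-12) { best <- z; bestv <- v }
    }
  }
  list(objective = best, v = bestv)
}

# Brute-force Ward.D2 agglomeration via the Lance-Williams update on squared
# Euclidean distances; returns merge heights in order.
wardD2Oracle <- function(X) {
  n <- nrow(X)
  D2 <- as.matrix(stats::dist(X))^2
  active <- seq_len(n)
  sizes <- rep(1, n)
  heights <- numeric(0)
  repeat {
    if (length(active) < 2) break
    best <- Inf; bi <- bj <- NA
    for (a in seq_along(active)) for (b in seq_along(active)) {
      if (b <= a) next
      i <- active[a]; j <- active[b]
      if (D2[i, j] < best) { best <- D2[i, j]; bi <- i; bj <- j }
    }
    heights <- c(heights, sqrt(best))
    # merge bj into bi with the Lance-Williams Ward.D2 update
    ni <- sizes[bi]; nj <- sizes[bj]
    for (k in active) {
      if (k == bi || k == bj) next
      nk <- sizes[k]
      D2[bi, k] <- D2[k, bi] <-
        ((ni + nk) * D2[bi, k] + (nj + nk) * D2[bj, k] - nk * D2[bi, bj]) /
        (ni + nj + nk)
    }
    sizes[bi] <- ni + nj
    active <- setdiff(active, bj)
  }
  heights
}

# Hypergeometric right-tail by direct summation of dhyper mass.
hyperTailOracle <- function(a, termSize, universeSize, setSize) {
  sum(stats::dhyper(a:min(termSize, setSize), termSize,
                    universeSize - termSize, setSize))
}

# BH step-up by its definition: q_i = min_{j >= i} m * p_(j) / j.
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- rev(cummin(rev(m * ps / seq_len(m))))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# shared small synthetic study (built once per test session)
.studyCache <- new.env()
cachedStudy <- function(noise = 0, seed = 11) {
  key <- paste0("s", noise, "_", seed)
  if (is.null(.studyCache[[key]]))
    .studyCache[[key]] <- simulateChemostatStudy(noiseSd = noise,
                                                 nGenes = 500, seed = seed)
  .studyCache[[key]]
}

# printed condition-mean rate panels of the reference study (mmol/gDCW/h),
# used as inputs for the worked fold-change examples
printedPanels <- function() {
  list(
    co_lo = ratePanel(1.02, c(CO = 32, CO2 = 24), biomass = 1.58),
    co_hi = ratePanel(2.79, c(CO = 70, CO2 = 43), biomass = 1.65),
    sg_lo = ratePanel(1.01, c(CO = 25, H2 = 7, CO2 = 10), biomass = 1.59),
    sg_hi = ratePanel(2.79, c(CO = 73, H2 = 21, CO2 = 34), biomass = 1.43))
}
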