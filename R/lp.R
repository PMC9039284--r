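# Internal linear-programming layer.
#
# Solves  max/min  c'v   s.t.  Aeq v = beq,  Ale v <= ble,  lb <= v <= ub.
# The solver is a dense two-phase primal simplex with Bland's anti-cycling
# rule, written for the small (<= ~100 variable) LPs that core-model FBA
# produces; it is cross-checked against a brute-force vertex-enumeration
# oracle in the test suite. Effectively unbounded variables are capped at
# .LP_BIG; a solution touching the cap is reported as "unbounded".

.LP_BIG <- 1e5
.LP_TOL <- 1e-8

# two-phase simplex on standard form: max/min c'x, A x = b, x >= 0, b >= 0.
# Bland's rule (smallest-index entering and leaving) guarantees termination.
.simplexCore <- function(A, b, cc, maximize, maxit = 20000L) {
  m <- nrow(A); n <- ncol(A)
  if (!maximize) cc <- -cc
  sgn <- ifelse(b < 0, -1, 1)
  A <- A * sgn; b <- b * sgn

  T <- cbind(A, diag(m), b)            # artificials appended
  basis <- n + seq_len(m)
  ncols <- n + m

  runPhase <- function(T, basis, cost, active) {
    for (it in seq_len(maxit)) {
      cB <- cost[basis]
      # reduced costs r_j = c_j - cB' T_j  (tableau rows are basis-reduced)
      r <- cost[active] - as.numeric(crossprod(cB, T[, active, drop = FALSE]))
      ent_rel <- which(r > .LP_TOL)
      if (!length(ent_rel)) return(list(T = T, basis = basis, optimal = TRUE))
      j <- active[min(ent_rel)]        # Bland: smallest index
      col <- T[, j]
      pos <- which(col > .LP_TOL)
      if (!length(pos)) return(list(T = T, basis = basis, optimal = FALSE))
      ratio <- T[pos, ncols + 1L] / col[pos]
      rmin <- min(ratio)
      cand <- pos[ratio <= rmin + .LP_TOL]
      i <- cand[which.min(basis[cand])] # Bland on the leaving variable
      piv <- T[i, j]
      T[i, ] <- T[i, ] / piv
      for (k in seq_len(m)) if (k != i && abs(T[k, j]) > 0)
        T[k, ] <- T[k, ] - T[k, j] * T[i, ]
      basis[i] <- j
      T[, basis] <- 0; T[cbind(seq_len(m), basis)] <- 1  # keep basis clean
    }
    stop("simplex iteration limit reached")
  }

  # phase 1: maximise -sum(artificials)
  cost1 <- c(rep(0, n), rep(-1, m))
  # reduce tableau so the artificial basis columns are identity (they are)
  ph1 <- runPhase(T, basis, cost1, seq_len(ncols))
  obj1 <- sum(cost1[ph1$basis] * ph1$T[, ncols + 1L])
  if (obj1 < -1e-6) return(list(status = "infeasible"))
  T <- ph1$T; basis <- ph1$basis
  # drive artificials out of the basis where possible
  for (i in which(basis > n)) {
    row <- T[i, seq_len(n)]
    j <- which(abs(row) > .LP_TOL)
    if (length(j)) {
      j <- j[1]
      T[i, ] <- T[i, ] / T[i, j]
      for (k in seq_len(m)) if (k != i && abs(T[k, j]) > 0)
        T[k, ] <- T[k, ] - T[k, j] * T[i, ]
      basis[i] <- j
    }
    # a zero row: redundant constraint, harmless with the artificial at 0
  }

  # phase 2: only structural columns may enter
  cost2 <- c(cc, rep(0, m))
  ph2 <- runPhase(T, basis, cost2, seq_len(n))
  if (!ph2$optimal) return(list(status = "unbounded"))
  x <- numeric(n)
  sel <- ph2$basis <= n
  x[ph2$basis[sel]] <- ph2$T[sel, ncols + 1L]
  list(status = "optimal", x = x)
}

.solveLP <- function(obj, Aeq, beq, lb, ub, Ale = NULL, ble = NULL,
                     maximize = TRUE) {
  n <- length(obj)
  stopifnot(ncol(Aeq) == n, length(lb) == n, length(ub) == n)
  lbw <- pmax(lb, -.LP_BIG)
  ubw <- pmin(ub, .LP_BIG)
  if (any(lbw > ubw + 1e-12)) return(list(status = "infeasible"))

  # eliminate variables fixed by their bounds
  fixed <- (ubw - lbw) < 1e-12
  vfix <- lbw
  free <- which(!fixed)
  checkFull <- function(v) {
    max(abs(Aeq %*% v - beq)) < 1e-6 &&
      (is.null(Ale) || all(Ale %*% v <= ble + 1e-6))
  }
  if (!length(free)) {
    v <- vfix
    return(if (checkFull(v))
      list(status = "optimal", v = v, objective = sum(obj * v))
      else list(status = "infeasible"))
  }
  beqF <- as.numeric(beq - Aeq[, fixed, drop = FALSE] %*% vfix[fixed])
  AeqF <- Aeq[, free, drop = FALSE]
  bleF <- if (!is.null(Ale))
    as.numeric(ble - Ale[, fixed, drop = FALSE] %*% vfix[fixed]) else NULL
  AleF <- if (!is.null(Ale)) Ale[, free, drop = FALSE] else NULL

  # drop linearly dependent equality rows (conserved moieties); their
  # consistency is re-checked on the returned solution
  qrA <- qr(t(AeqF))
  keep <- sort(qrA$pivot[seq_len(qrA$rank)])
  AeqR <- AeqF[keep, , drop = FALSE]
  beqR <- beqF[keep]

  # shift to x >= 0 and add upper bounds / inequalities as slack rows
  nf <- length(free)
  shift <- lbw[free]
  width <- ubw[free] - shift
  Aub <- diag(nf); bub <- width
  if (!is.null(AleF)) {
    Aub <- rbind(Aub, AleF)
    bub <- c(bub, as.numeric(bleF - AleF %*% shift))
  }
  mU <- nrow(Aub); mE <- nrow(AeqR)
  A <- rbind(cbind(AeqR, matrix(0, mE, mU)),
             cbind(Aub, diag(mU)))
  b <- c(as.numeric(beqR - AeqR %*% shift), bub)
  cc <- c(obj[free], rep(0, mU))

  res <- .simplexCore(A, b, cc, maximize)
  if (res$status != "optimal") return(res)
  v <- numeric(n)
  v[fixed] <- vfix[fixed]
  v[free] <- shift + res$x[seq_len(nf)]
  if (!checkFull(v)) return(list(status = "infeasible"))
  at_cap <- (abs(v) >= .LP_BIG * (1 - 1e-6)) & (lb < -.LP_BIG | ub > .LP_BIG)
  if (any(at_cap)) return(list(status = "unbounded"))
  list(status = "optimal", v = v, objective = sum(obj * v))
}

# Secondary minimisation of sum(|v|) among optima: lock the achieved
# objective, split v into v+ - v- and minimise the sum of parts.
.minimiseTotalFlux <- function(obj, Aeq, beq, lb, ub, zstar, maximize,
                               Ale = NULL, ble = NULL) {
  n <- length(obj)
  lb2 <- rep(0, 2 * n)
  ub2 <- c(pmin(pmax(ub, 0), .LP_BIG), pmin(pmax(-lb, 0), .LP_BIG))
  Aeq2 <- cbind(Aeq, -Aeq)
  beq2 <- beq
  Aeq2 <- rbind(Aeq2, c(obj, -obj))
  beq2 <- c(beq2, zstar)
  Ale2 <- if (!is.null(Ale)) cbind(Ale, -Ale) else NULL
  ble2 <- ble
  # boxes not containing 0 are not captured by the split caps alone
  for (j in which(lb > 0)) {
    row <- rep(0, 2 * n); row[j] <- -1; row[n + j] <- 1
    Ale2 <- rbind(Ale2, row); ble2 <- c(ble2, -lb[j])
  }
  for (j in which(ub < 0)) {
    row <- rep(0, 2 * n); row[j] <- 1; row[n + j] <- -1
    Ale2 <- rbind(Ale2, row); ble2 <- c(ble2, ub[j])
  }
  res <- .solveLP(rep(1, 2 * n), Aeq2, beq2, lb2, ub2,
                  Ale = Ale2, ble = ble2, maximize = FALSE)
  if (res$status != "optimal") return(NULL)
  res$v[seq_len(n)] - res$v[n + seq_len(n)]
}
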