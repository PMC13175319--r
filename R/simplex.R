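# Dense two-phase simplex for flux-balance problems.
#
# Solves  max/min c'v  subject to  S v = 0,  lb <= v <= ub.
# Variables are shifted/reflected/split so every working variable is
# non-negative; finite upper bounds become explicit slack rows; phase 1
# drives artificials on the equality rows to zero. Bland's rule is used for
# both the entering and the leaving choice, so the method terminates on
# degenerate bases and is fully deterministic for a fixed model ordering.
#
# Tolerances: pivot/entering 1e-9, phase-1 feasibility 1e-7.

lp_solve_bounded <- function(S, lb, ub, objective_coefs, maximize = TRUE,
                             tol = 1e-9, feas_tol = 1e-7) {
  m <- nrow(S)
  n <- ncol(S)
  stopifnot(length(lb) == n, length(ub) == n, length(objective_coefs) == n)
  if (any(lb > ub)) {
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  }
  cc <- if (maximize) objective_coefs else -objective_coefs

  # --- transform to y >= 0 -------------------------------------------------
  cols <- list(); costs <- numeric(0); dvec <- numeric(0)
  # map[[j]]: list(kind, idx) to reconstruct x from y
  vmap <- vector("list", n)
  offset <- numeric(n)
  for (j in seq_len(n)) {
    if (is.finite(lb[j])) {
      cols[[length(cols) + 1]] <- S[, j]
      costs <- c(costs, cc[j])
      dvec <- c(dvec, ub[j] - lb[j])
      offset[j] <- lb[j]
      vmap[[j]] <- list(kind = "shift", idx = length(cols))
    } else if (is.finite(ub[j])) {
      cols[[length(cols) + 1]] <- -S[, j]
      costs <- c(costs, -cc[j])
      dvec <- c(dvec, Inf)
      offset[j] <- ub[j]
      vmap[[j]] <- list(kind = "reflect", idx = length(cols))
    } else {
      cols[[length(cols) + 1]] <- S[, j]
      costs <- c(costs, cc[j])
      dvec <- c(dvec, Inf)
      cols[[length(cols) + 1]] <- -S[, j]
      costs <- c(costs, -cc[j])
      dvec <- c(dvec, Inf)
      offset[j] <- 0
      vmap[[j]] <- list(kind = "split", idx = c(length(cols) - 1L, length(cols)))
    }
  }
  A <- do.call(cbind, cols)
  n1 <- ncol(A)
  b <- as.numeric(-S %*% offset)

  bounded <- which(is.finite(dvec))
  k <- length(bounded)

  # tableau: rows = m equality + k bound rows
  # columns = y (n1) | slack (k) | artificial (m) | RHS
  ncols <- n1 + k + m + 1L
  Tb <- matrix(0, nrow = m + k, ncol = ncols)
  Tb[seq_len(m), seq_len(n1)] <- A
  Tb[seq_len(m), ncols] <- b
  # flip equality rows to non-negative RHS
  neg <- which(Tb[seq_len(m), ncols] < 0)
  if (length(neg) > 0) Tb[neg, ] <- -Tb[neg, ]
  for (i in seq_len(k)) {
    Tb[m + i, bounded[i]] <- 1
    Tb[m + i, n1 + i] <- 1
    Tb[m + i, ncols] <- dvec[bounded[i]]
  }
  for (i in seq_len(m)) Tb[i, n1 + k + i] <- 1
  basis <- c(n1 + k + seq_len(m),             # artificials on equality rows
             n1 + seq_len(k))                 # slacks on bound rows
  art_cols <- n1 + k + seq_len(m)

  run_simplex <- function(Tb, basis, red, allowed) {
    rhs_col <- ncol(Tb)
    repeat {
      enter_candidates <- allowed[red[allowed] < -tol]
      if (length(enter_candidates) == 0) {
        return(list(Tb = Tb, basis = basis, red = red, status = "optimal"))
      }
      q <- min(enter_candidates)                       # Bland: smallest index
      colq <- Tb[, q]
      pos <- which(colq > tol)
      if (length(pos) == 0) {
        return(list(Tb = Tb, basis = basis, red = red, status = "unbounded"))
      }
      ratios <- Tb[pos, rhs_col] / colq[pos]
      best <- min(ratios)
      ties <- pos[ratios <= best + tol * (1 + abs(best))]
      p <- ties[which.min(basis[ties])]                # Bland on leaving var
      # pivot
      pivrow <- Tb[p, ] / Tb[p, q]
      Tb <- Tb - outer(Tb[, q], pivrow)
      Tb[p, ] <- pivrow
      red <- red - red[q] * pivrow
      basis[p] <- q
    }
  }

  # --- phase 1: minimize sum of artificials --------------------------------
  red1 <- numeric(ncols)
  red1[art_cols] <- 1
  for (i in which(basis %in% art_cols)) red1 <- red1 - Tb[i, ]
  allowed1 <- seq_len(n1 + k)          # artificials never re-enter
  res <- run_simplex(Tb, basis, red1, allowed1)
  Tb <- res$Tb; basis <- res$basis
  phase1_obj <- -res$red[ncols]
  if (phase1_obj > feas_tol) {
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  }
  # purge residual artificials from the basis
  art_rows <- which(basis %in% art_cols)
  drop_rows <- integer(0)
  for (p in art_rows) {
    cand <- which(abs(Tb[p, seq_len(n1 + k)]) > tol)
    if (length(cand) == 0) {
      drop_rows <- c(drop_rows, p)      # redundant constraint
    } else {
      q <- min(cand)
      pivrow <- Tb[p, ] / Tb[p, q]
      Tb <- Tb - outer(Tb[, q], pivrow)
      Tb[p, ] <- pivrow
      basis[p] <- q
    }
  }
  if (length(drop_rows) > 0) {
    Tb <- Tb[-drop_rows, , drop = FALSE]
    basis <- basis[-drop_rows]
  }
  # delete artificial columns
  keep_cols <- c(seq_len(n1 + k), ncols)
  Tb <- Tb[, keep_cols, drop = FALSE]
  ncols2 <- ncol(Tb)

  # --- phase 2: minimize -c'y ----------------------------------------------
  red2 <- numeric(ncols2)
  red2[seq_len(n1)] <- -costs
  for (i in seq_along(basis)) {
    cb <- if (basis[i] <= n1) -costs[basis[i]] else 0
    if (cb != 0) red2 <- red2 - cb * Tb[i, ]
  }
  res <- run_simplex(Tb, basis, red2, seq_len(n1 + k))
  if (res$status == "unbounded") {
    return(list(status = "unbounded", x = NULL, objective = NA_real_))
  }
  Tb <- res$Tb; basis <- res$basis

  yv <- numeric(n1 + k)
  yv[basis] <- Tb[, ncol(Tb)]
  x <- numeric(n)
  for (j in seq_len(n)) {
    mp <- vmap[[j]]
    x[j] <- switch(mp$kind,
      shift = offset[j] + yv[mp$idx],
      reflect = offset[j] - yv[mp$idx],
      split = yv[mp$idx[1]] - yv[mp$idx[2]]
    )
  }
  # clip tiny excursions beyond the (original) bounds
  x <- pmin(pmax(x, lb - 1e-9), ub + 1e-9)
  list(status = "optimal", x = x,
       objective = sum(objective_coefs * x))
}
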