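#' Solve a flux-balance problem
#'
#' Flux balance analysis (FBA) predicts steady-state metabolic fluxes by
#' linear programming: maximize (or minimize) the flux through an objective
#' reaction subject to the steady-state constraint `S v = 0` and the flux
#' bounds `lb <= v <= ub`. The solver is a deterministic two-phase simplex
#' (Bland's rule), so a fixed model ordering always yields the same optimal
#' vertex. FBA optima are generically non-unique; assert biological claims
#' through [flux_variability()] ranges rather than the particular vertex
#' returned.
#'
#' @param model A `constraint_model`.
#' @param objective Reaction id to optimize; defaults to the model objective.
#' @param sense `"max"` (default) or `"min"`.
#' @param bound_overrides Optional named list `list(rxn = c(lb, ub), ...)`
#'   applied before solving (the model itself is untouched).
#' @return A `flux_solution`: list with `status` (`"optimal"`,
#'   `"infeasible"`, `"unbounded"`), `objective_value`, `fluxes` (named
#'   vector, mmol/gDW/h), and `residual` (max |S v|).
#' @examples
#' model <- build_mini_core()
#' sol <- solve_fba(model)
#' sol$objective_value
#' @export
solve_fba <- function(model, objective = NULL, sense = c("max", "min"),
                      bound_overrides = NULL) {
  sense <- match.arg(sense)
  if (!is.null(bound_overrides)) {
    model <- apply_bound_overrides(model, bound_overrides)
  }
  objective <- objective %||% model$objective
  if (is.na(objective) || !objective %in% model$reactions$id) {
    abort(paste0("objective reaction '", objective, "' not in model"))
  }
  S <- stoichiometric_matrix(model)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  cc <- as.numeric(model$reactions$id == objective)
  res <- lp_solve_bounded(S, lb, ub, cc, maximize = (sense == "max"))
  if (res$status != "optimal") {
    return(new_flux_solution(res$status, NA_real_, NULL, NA_real_,
                             objective, sense, model$id))
  }
  fluxes <- setNames(res$x, model$reactions$id)
  residual <- max(abs(S %*% res$x))
  new_flux_solution("optimal", res$objective, fluxes, residual,
                    objective, sense, model$id)
}

new_flux_solution <- function(status, objective_value, fluxes, residual,
                              objective, sense, model_id) {
  structure(
    list(status = status, objective_value = objective_value, fluxes = fluxes,
         residual = residual, objective = objective, sense = sense,
         model_id = model_id),
    class = "flux_solution"
  )
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> ", x$sense, " ", x$objective, " on ", x$model_id,
      "\n", sep = "")
  cat("  status: ", x$status, sep = "")
  if (x$status == "optimal") {
    cat("  objective: ", format(x$objective_value, digits = 6),
        "  max|S.v|: ", format(x$residual, digits = 3), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Flux variability at (a fraction of) the optimum
#'
#' For each reaction, computes the minimum and maximum flux attainable while
#' the objective is held at least at `fraction` times its optimum (with
#' relative slack 1e-6 to avoid cutting off the optimal face numerically).
#' This resolves the degeneracy of FBA optima: a claim such as "no flux
#' toward l-fuculose production" is asserted as an FVA range of (0, 0), not
#' as a property of one optimal vertex. `fraction = 0` reproduces the
#' unconstrained bounds-feasible ranges.
#'
#' @inheritParams solve_fba
#' @param fraction Number in \[0, 1\]: required share of the optimal objective.
#' @param reactions Reaction ids to range over (default: all).
#' @return A tibble with columns `reaction`, `fva_min`, `fva_max`.
#' @export
flux_variability <- function(model, objective = NULL, fraction = 1,
                             reactions = NULL, bound_overrides = NULL) {
  if (fraction < 0 || fraction > 1) abort("`fraction` must be in [0, 1]")
  if (!is.null(bound_overrides)) {
    model <- apply_bound_overrides(model, bound_overrides)
  }
  objective <- objective %||% model$objective
  base <- solve_fba(model, objective = objective)
  if (base$status != "optimal") {
    abort(paste0("flux_variability: base problem is ", base$status),
          class = "fucflux_infeasible")
  }
  if (fraction > 0) {
    opt <- base$objective_value
    threshold <- fraction * opt - 1e-6 * abs(opt)
    i <- match(objective, model$reactions$id)
    model$reactions$lower_bound[i] <-
      max(model$reactions$lower_bound[i], threshold)
  }
  targets <- reactions %||% model$reactions$id
  unknown <- setdiff(targets, model$reactions$id)
  if (length(unknown) > 0) {
    abort(paste0("unknown reaction(s): ", paste(unknown, collapse = ", ")))
  }
  rows <- lapply(targets, function(r) {
    lo <- solve_fba(model, objective = r, sense = "min")
    hi <- solve_fba(model, objective = r, sense = "max")
    if (lo$status != "optimal" || hi$status != "optimal") {
      abort(paste0("flux_variability: subproblem for '", r, "' is ",
                   lo$status), class = "fucflux_infeasible")
    }
    tibble::tibble(reaction = r,
                   fva_min = lo$objective_value,
                   fva_max = hi$objective_value)
  })
  dplyr::bind_rows(rows)
}

#' Exhaustive LP oracle for small networks
#'
#' Independently computes the optimal FBA objective by enumerating every
#' basic solution of the bounded linear program: each choice of rank(S)
#' basic columns with the remaining fluxes pinned at either bound. Any
#' bounded feasible LP attains its optimum at such a vertex, so the best
#' feasible enumerated objective equals the true optimum. Exponential in the
#' reaction count, hence refused above `max_reactions`; intended as a
#' cross-check for the simplex on toy networks.
#'
#' @inheritParams solve_fba
#' @param max_reactions Refusal threshold on the model size (default 12).
#' @return List with `status` (`"optimal"` or `"infeasible"`) and
#'   `objective_value`.
#' @export
enumerate_vertices_oracle <- function(model, objective = NULL,
                                      sense = c("max", "min"),
                                      max_reactions = 12) {
  sense <- match.arg(sense)
  n <- nrow(model$reactions)
  if (n > max_reactions) {
    abort(paste0("oracle refused: model has ", n, " reactions (cap ",
                 max_reactions, ")"))
  }
  objective <- objective %||% model$objective
  S <- stoichiometric_matrix(model)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  if (any(!is.finite(lb)) || any(!is.finite(ub))) {
    abort("oracle requires finite bounds")
  }
  cc <- as.numeric(model$reactions$id == objective)
  r <- qr(S)$rank
  best <- if (sense == "max") -Inf else Inf
  better <- if (sense == "max") function(a, b) a > b else function(a, b) a < b
  found <- FALSE

  basic_sets <- if (r == 0) list(integer(0)) else
    asplit(combn(n, r), 2)
  for (B in basic_sets) {
    B <- as.integer(B)
    N <- setdiff(seq_len(n), B)
    if (length(B) > 0) {
      qrB <- qr(S[, B, drop = FALSE])
      if (qrB$rank < length(B)) next
    }
    # every nonbasic flux at one of its bounds
    if (length(N) > 0) {
      grid <- as.matrix(expand.grid(lapply(N, function(j) c(lb[j], ub[j]))))
      VN <- t(grid)                                   # |N| x ncombo
    } else {
      VN <- matrix(0, nrow = 0, ncol = 1)
    }
    ncombo <- ncol(VN)
    if (length(B) > 0) {
      rhs <- if (length(N) > 0) -S[, N, drop = FALSE] %*% VN else
        matrix(0, nrow = nrow(S), ncol = ncombo)
      VB <- qr.coef(qrB, rhs)
      VB[is.na(VB)] <- 0
      resid <- S[, B, drop = FALSE] %*% VB - rhs
      ok <- colSums(abs(resid)) <= 1e-7 &
        colSums(VB < lb[B] - 1e-9 | VB > ub[B] + 1e-9) == 0
    } else {
      VB <- matrix(0, nrow = 0, ncol = ncombo)
      ok <- colSums(abs(if (length(N) > 0) S[, N, drop = FALSE] %*% VN else
        matrix(0, nrow(S), ncombo))) <= 1e-7
    }
    if (!any(ok)) next
    obj <- (if (length(B) > 0) as.numeric(cc[B] %*% VB) else 0) +
      (if (length(N) > 0) as.numeric(cc[N] %*% VN) else 0)
    obj <- obj[ok]
    found <- TRUE
    cand <- if (sense == "max") max(obj) else min(obj)
    if (better(cand, best)) best <- cand
  }
  if (!found) {
    list(status = "infeasible", objective_value = NA_real_)
  } else {
    list(status = "optimal", objective_value = best)
  }
}
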