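#' Tidy a flux solution
#'
#' @param x A `flux_solution`.
#' @param ... Unused.
#' @return A tibble with columns `reaction` and `flux` (mmol/gDW/h), empty
#'   when the problem was infeasible or unbounded.
#' @export
tidy.flux_solution <- function(x, ...) {
  if (x$status != "optimal") {
    return(tibble::tibble(reaction = character(), flux = numeric()))
  }
  tibble::tibble(reaction = names(x$fluxes), flux = unname(x$fluxes))
}

#' One-row summary of a flux solution
#'
#' @param x A `flux_solution`.
#' @param ... Unused.
#' @return A one-row tibble: `status`, `objective`, `sense`,
#'   `objective_value`, `residual`, `n_reactions`.
#' @export
glance.flux_solution <- function(x, ...) {
  tibble::tibble(
    status = x$status, objective = x$objective, sense = x$sense,
    objective_value = x$objective_value, residual = x$residual,
    n_reactions = if (is.null(x$fluxes)) NA_integer_ else length(x$fluxes)
  )
}
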