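#' Read a fermentation time-course CSV
#'
#' Reads time-course fermentation tables with columns (case-insensitive)
#' `time` (h), `od600`, `glucose` (g/L), `acetate` (g/L), `lad` (mM),
#' `pdo` (mM), `fuculose` (mg/L). `ND` (not detected, e.g. loss during
#' derivatization) and blank cells parse as missing values — never as zero.
#' Unknown columns raise a warning and are dropped. Not every column must be
#' present, but `time` is required, must be strictly increasing, and
#' concentrations must be non-negative where observed.
#'
#' @param file Path to a CSV file.
#' @return A validated timecourse tibble (class `fuc_timecourse`), rows in
#'   time order.
#' @export
read_timecourse <- function(file) {
  raw <- readr::read_csv(file, na = c("", "NA", "ND", "nd"),
                         show_col_types = FALSE)
  as_timecourse(raw)
}

#' Validate a data frame as a fermentation time course
#'
#' @param x A data frame with a `time` column and any of `od600`, `glucose`,
#'   `acetate`, `lad`, `pdo`, `fuculose` (names matched case-insensitively).
#' @return A `fuc_timecourse` tibble.
#' @export
as_timecourse <- function(x) {
  known <- c("time", "od600", "glucose", "acetate", "lad", "pdo", "fuculose")
  x <- tibble::as_tibble(x)
  names(x) <- tolower(names(x))
  extra <- setdiff(names(x), known)
  if (length(extra) > 0) {
    warn(paste0("ignoring unknown column(s): ", paste(extra, collapse = ", ")))
    x <- x[, intersect(names(x), known)]
  }
  if (!"time" %in% names(x)) abort("timecourse needs a `time` column")
  if (nrow(x) < 2) abort("timecourse needs at least two time points")
  if (any(is.na(x$time))) abort("`time` must not contain missing values")
  if (any(diff(x$time) <= 0)) abort("`time` must be strictly increasing")
  for (col in setdiff(intersect(known, names(x)), "time")) {
    v <- x[[col]]
    if (any(v < 0, na.rm = TRUE)) {
      abort(paste0("negative values in column `", col, "`"))
    }
  }
  class(x) <- unique(c("fuc_timecourse", class(x)))
  x
}

#' Summarize a fermentation time course
#'
#' Derives the product metrics of a fuculose fermentation:
#'
#' * `max_titer` — the maximum observed l-fuculose concentration (mg/L) and
#'   the time it was reached (`t_max`); the maximum, not the endpoint, so a
#'   late-phase decline does not hide the best titer (endpoint mode
#'   available via `titer`);
#' * `lad_consumed` — first observed LAD minus minimum observed LAD (mM);
#' * `molar_yield_pct` — `100 * (max_titer / 164.16) / lad_consumed`, the
#'   percentage of consumed lactaldehyde converted to l-fuculose on a molar
#'   basis (MW l-fuculose 164.16 g/mol, MW lactaldehyde 74.08 g/mol);
#' * `fold_vs_reference` — [fold_improvement()] over `reference_titer` when
#'   one is supplied.
#'
#' Missing values (`ND`) are excluded from every max/min, never imputed.
#'
#' @param tc A timecourse tibble ([read_timecourse()],
#'   [simulate_timecourse()], or [as_timecourse()]).
#' @param reference_titer Optional benchmark titer (mg/L) for the fold
#'   improvement.
#' @param titer `"max"` (default) or `"endpoint"` (last observed value).
#' @return A one-row tibble: `max_titer`, `t_max`, `lad_consumed`,
#'   `molar_yield_pct`, `fold_vs_reference`.
#' @examples
#' tc <- simulate_timecourse(fermentation_params(yield = 0.068, sigma = 0))
#' summarize_fermentation(tc)$molar_yield_pct  # 6.8
#' @export
summarize_fermentation <- function(tc, reference_titer = NULL,
                                   titer = c("max", "endpoint")) {
  titer <- match.arg(titer)
  tc <- as_timecourse(tc)
  for (col in c("fuculose", "lad")) {
    if (!col %in% names(tc) || all(is.na(tc[[col]]))) {
      abort(paste0("timecourse has no observed `", col, "` values"))
    }
  }
  fcl <- tc$fuculose
  if (titer == "max") {
    max_titer <- max(fcl, na.rm = TRUE)
    t_max <- tc$time[which(fcl == max_titer)[1]]
  } else {
    i <- max(which(!is.na(fcl)))
    max_titer <- fcl[i]
    t_max <- tc$time[i]
  }
  lad_obs <- tc$lad[!is.na(tc$lad)]
  lad_consumed <- lad_obs[1] - min(lad_obs)
  molar_yield_pct <- if (lad_consumed > 0) {
    100 * (max_titer / MW_FUCULOSE) / lad_consumed
  } else if (max_titer == 0) {
    0
  } else {
    NA_real_
  }
  tibble::tibble(
    max_titer = max_titer, t_max = t_max, lad_consumed = lad_consumed,
    molar_yield_pct = molar_yield_pct,
    fold_vs_reference = if (is.null(reference_titer)) NA_real_ else
      fold_improvement(max_titer, reference_titer)
  )
}

#' Fold improvement of a titer over a reference
#'
#' Plain ratio `titer / reference_titer`, reported to 3 significant figures
#' (scale-invariant: common rescaling of both titers leaves it unchanged).
#' The engineered Fuc 4 strain at 50.25 mg/L against the earlier microbial
#' benchmark of 1.55 mg/L gives 32.4.
#'
#' @param titer Titer, mg/L (vectorized).
#' @param reference_titer Reference titer, mg/L (> 0).
#' @return Dimensionless ratio, 3 significant figures.
#' @examples
#' fold_improvement(50.25, 1.55)  # 32.4
#' @export
fold_improvement <- function(titer, reference_titer) {
  if (any(reference_titer <= 0)) abort("`reference_titer` must be > 0")
  signif(titer / reference_titer, 3)
}
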