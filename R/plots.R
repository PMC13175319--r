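#' Plot a campaign table
#'
#' For gridded campaigns (oxygen sweep, substrate scan) plots maximal
#' growth and maximal l-fuculose secretion against the magnitude of the
#' control uptake bound; for the strain series, a bar chart of maximal
#' fuculose per strain with growth overlaid.
#'
#' @param object A campaign tibble from [oxygen_sweep()],
#'   [substrate_ratio_scan()] or [strain_series()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fuc_campaign <- function(object, ...) {
  control <- attr(object, "control")
  if (identical(control, "strain")) {
    df <- tidyr::pivot_longer(
      dplyr::select(object, "strain", "max_growth", "max_fuculose"),
      c("max_growth", "max_fuculose"),
      names_to = "quantity", values_to = "value")
    return(
      ggplot2::ggplot(df, ggplot2::aes(
        x = factor(.data$strain, levels = unique(object$strain)),
        y = .data$value, fill = .data$quantity)) +
        ggplot2::geom_col(position = "dodge") +
        ggplot2::labs(x = NULL, y = "flux (mmol/gDW/h)", fill = NULL) +
        ggplot2::theme_minimal()
    )
  }
  if (identical(control, "scenario")) {
    df <- dplyr::filter(object, !is.na(.data$reaction))
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$reaction, y = .data$flux,
                                       fill = .data$scenario)) +
        ggplot2::geom_col(position = "dodge") +
        ggplot2::coord_flip() +
        ggplot2::labs(x = NULL, y = "flux (mmol/gDW/h)", fill = NULL) +
        ggplot2::theme_minimal()
    )
  }
  df <- tidyr::pivot_longer(
    dplyr::mutate(object, uptake = abs(.data[[control]])),
    c("max_growth", "max_fuculose"),
    names_to = "quantity", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$uptake, y = .data$value,
                                   colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = paste0("|", control, "| (mmol/gDW/h)"),
                  y = "flux (mmol/gDW/h)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a fermentation time course
#'
#' Faceted view of the measured series (OD600, glucose, acetate, LAD,
#' 1,2-PDO, l-fuculose) against time.
#'
#' @param object A `fuc_timecourse` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fuc_timecourse <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object), -"time",
                            names_to = "series", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = NULL) +
    ggplot2::theme_minimal()
}
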