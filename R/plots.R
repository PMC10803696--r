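#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_contour labs
#'   scale_x_log10 autoplot facet_wrap
NULL

#' Plot time-activity curves
#'
#' @param result A `pbrpk_result`.
#' @param organs Organs to show (default: tumor and the organs at risk
#'   present in the model).
#' @param log_time Log-scale the time axis.
#' @return A ggplot.
#' @export
plot_tac <- function(result, organs = NULL, log_time = FALSE) {
  present <- unique(result$graph$compartments$organ)
  organs <- organs %||%
    intersect(c("tumor", "kidneys", "salivary_glands", "vein"), present)
  df <- purrr::map_dfr(organs, function(org) activity_tac(result, org))
  p <- ggplot(df, aes(x = .data$time, y = .data$activity,
                      colour = .data$organ)) +
    geom_line() +
    labs(x = "time (min)", y = "activity (nmol/min)", colour = NULL)
  if (log_time) p <- p + scale_x_log10()
  p
}

#' Plot iso-dose contours of a dose grid
#'
#' @param grid A [dose_grid()].
#' @param levels Contour levels (Gy); default deciles of the dose range.
#' @return A ggplot of the (hot, cold) plane with iso-dose lines.
#' @export
plot_isodose <- function(grid, levels = NULL) {
  stopifnot(inherits(grid, "dose_grid"))
  rng <- range(grid$dose)
  levels <- levels %||% (rng[1] + diff(rng) * seq(0.1, 0.9, by = 0.1))
  df <- tidyr::expand_grid(hot = grid$hot, cold = grid$cold)
  df$dose <- as.vector(t(grid$dose))
  ggplot(df, aes(x = .data$hot, y = .data$cold, z = .data$dose)) +
    geom_contour(breaks = levels, colour = "steelblue") +
    labs(x = "injected hot (nmol)", y = "injected cold (nmol)",
         title = paste("iso-dose contours:", grid$organ))
}

#' @method autoplot twist_profile
#' @export
autoplot.twist_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$level, y = .data$twist_deg)) +
    geom_line() + geom_point() +
    labs(x = "iso-dose level (Gy)", y = "twist (degrees)",
         title = unique(object$organ))
}

#' @method autoplot ef_curve
#' @export
autoplot.ef_curve <- function(object, ...) {
  ggplot(dplyr::filter(object, is.finite(.data$kd_alb)),
         aes(x = .data$kd_alb, y = .data$ef, colour = .data$oar)) +
    geom_line() + geom_point() + scale_x_log10() +
    labs(x = "albumin K_D (nmol/L)", y = "enhancement factor",
         colour = "organ at risk")
}

#' Plot MRDC against a patient covariate
#'
#' @param mrdc A table of `mrdc_result` rows with a `density` or
#'   `volume_ml` column (as produced by [run_injection_study()]).
#' @param x Covariate column name (default `"density"`).
#' @return A ggplot.
#' @export
plot_mrdc <- function(mrdc, x = "density") {
  ggplot(mrdc, aes(x = .data[[x]], y = .data$mrdc, colour = .data$organ)) +
    geom_line() + geom_point() +
    labs(x = x, y = "maximum relative dose change")
}

#' Plot blood residence time against albumin affinity
#'
#' @param brt Tibble with `kd_alb` and `brt_min` (from
#'   [run_albumin_study()]).
#' @return A ggplot.
#' @export
plot_brt <- function(brt) {
  ggplot(dplyr::filter(brt, is.finite(.data$kd_alb)),
         aes(x = .data$kd_alb, y = .data$brt_min)) +
    geom_line() + geom_point() + scale_x_log10() +
    labs(x = "albumin K_D (nmol/L)", y = "blood residence time (min)")
}
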