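AVOGADRO <- 6.02214076e23

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Time-activity curve of an organ
#'
#' The activity attributed to an organ at time t is `lambda_phys` times the
#' total hot-moiety amount (free, receptor-bound, internalized and
#' albumin-complexed hot ligand) over all compartments of the organ.
#' Activity is carried in nmol/min (decays per minute expressed in nmol);
#' dosimetry converts to absolute decay counts, and ratios such as the
#' blood residence time are unit-independent.
#'
#' @param result A `pbrpk_result`.
#' @param organ Organ label present in the model.
#' @return A `pbrpk_tac` tibble with columns `organ`, `time` (min) and
#'   `activity` (nmol/min), carrying `lambda_phys` as an attribute.
#' @export
activity_tac <- function(result, organ) {
  stopifnot(inherits(result, "pbrpk_result"))
  if (!organ %in% result$graph$compartments$organ) {
    abort(paste0("unknown organ: ", organ), class = "pbrpk_error_reference")
  }
  lambda <- unname(result$graph$parameters["lambda_phys"])
  if (is.na(lambda)) {
    abort("graph has no `lambda_phys` parameter",
          class = "pbrpk_error_validation")
  }
  hot <- moiety_totals(result, "hot", organ = organ)
  out <- tibble(organ = organ, time = as.numeric(result$times),
                activity = lambda * hot)
  attr(out, "lambda_phys") <- lambda
  class(out) <- c("pbrpk_tac", class(out))
  out
}

#' Time-integrated activity of a TAC
#'
#' Trapezoidal integration of the activity over `[0, t_end]`, plus (by
#' default) an analytic exponential tail beyond `t_end` that assumes the
#' terminal activity decays purely physically:
#' `A(t_end) / lambda_phys`.
#'
#' @param tac A `pbrpk_tac` from [activity_tac()], or any data frame with
#'   `time` and `activity` columns.
#' @param t_end Upper integration limit in minutes (default: last time
#'   point of the curve).
#' @param tail Add the analytic post-`t_end` tail (default `TRUE`; requires
#'   a `lambda_phys` attribute or argument).
#' @param lambda_phys Decay constant used for the tail; defaults to the
#'   curve's attribute.
#' @return Time-integrated activity in activity-minutes (nmol).
#' @export
time_integrated_activity <- function(tac, t_end = max(tac$time), tail = TRUE,
                                     lambda_phys = attr(tac, "lambda_phys")) {
  if (t_end > max(tac$time) + 1e-9) {
    abort("t_end beyond the simulated range", class = "pbrpk_error_validation")
  }
  keep <- tac$time <= t_end + 1e-12
  tt <- tac$time[keep]
  aa <- tac$activity[keep]
  if (abs(tt[length(tt)] - t_end) > 1e-9) {
    aa <- c(aa, stats::approx(tac$time, tac$activity, xout = t_end)$y)
    tt <- c(tt, t_end)
  }
  tia <- trapz(tt, aa)
  if (tail) {
    if (is.null(lambda_phys) || !is.finite(lambda_phys) || lambda_phys <= 0) {
      abort("tail extrapolation requires a positive lambda_phys",
            class = "pbrpk_error_validation")
    }
    tia <- tia + aa[length(aa)] / lambda_phys
  }
  tia
}

#' Absorbed dose from a time-integrated activity
#'
#' Local-deposition (self-dose) model: the absorbed dose is the number of
#' decays in the organ times the mean energy deposited per decay, divided
#' by the organ mass.
#'
#' @param tia Time-integrated activity in nmol (activity carried as
#'   nmol/min, see [activity_tac()]).
#' @param organ_mass_kg Organ mass in kg (> 0).
#' @param mean_energy_per_decay Mean energy deposited locally per decay, J.
#' @return Absorbed dose in Gy.
#' @export
absorbed_dose <- function(tia, organ_mass_kg,
                          mean_energy_per_decay = 2.369e-14) {
  if (organ_mass_kg <= 0) {
    abort("organ mass must be > 0", class = "pbrpk_error_validation")
  }
  decays <- tia * 1e-9 * AVOGADRO
  decays * mean_energy_per_decay / organ_mass_kg
}

organ_mass_kg <- function(result, organ, density) {
  cp <- result$graph$compartments
  sum(cp$volume[cp$organ == organ]) * density
}

#' Per-organ dose report
#'
#' Computes, for each requested organ, the time-integrated activity (with
#' exponential tail), the organ mass (sum of the organ's compartment
#' volumes times the soft-tissue density) and the absorbed dose.
#'
#' @param result A `pbrpk_result`.
#' @param organs Organ labels; default: every organ in the model except the
#'   excreta compartment.
#' @param t_end Integration limit, minutes; defaults to the simulated
#'   horizon.
#' @param mean_energy_per_decay,density Dosimetry constants; default to the
#'   values stored in the graph parameters (falling back to Lu-177 beta
#'   energy and 1.04 kg/L soft tissue).
#' @return A tibble (class `dose_report`) with columns `organ`, `tia`,
#'   `mass_kg`, `dose_gy`, with the constants attached as attributes.
#' @export
dose_report <- function(result, organs = NULL, t_end = max(result$times),
                        mean_energy_per_decay = NULL, density = NULL) {
  stopifnot(inherits(result, "pbrpk_result"))
  pars <- result$graph$parameters
  delta <- mean_energy_per_decay %||%
    unname(pars["mean_energy_per_decay"])
  if (is.na(delta)) delta <- 2.369e-14
  dens <- density %||% unname(pars["tissue_density"])
  if (is.na(dens)) dens <- 1.04
  all_organs <- unique(result$graph$compartments$organ)
  organs <- organs %||% setdiff(all_organs, "excreta")
  missing <- setdiff(organs, all_organs)
  if (length(missing)) {
    abort(paste0("unknown organs: ", paste(missing, collapse = ", ")),
          class = "pbrpk_error_reference")
  }
  out <- purrr::map_dfr(organs, function(org) {
    tac <- activity_tac(result, org)
    tia <- time_integrated_activity(tac, t_end = t_end)
    mass <- organ_mass_kg(result, org, dens)
    tibble(organ = org, tia = tia, mass_kg = mass,
           dose_gy = absorbed_dose(tia, mass, delta))
  })
  attr(out, "mean_energy_per_decay") <- delta
  attr(out, "density") <- dens
  attr(out, "t_end") <- t_end
  class(out) <- c("dose_report", class(out))
  out
}

#' Blood residence time
#'
#' Time-integrated activity of the venous blood pool divided by the
#' injected activity: `BRT = integral(A_vein) / (lambda_phys * H_0)` with
#' `H_0` the total injected hot amount. The arbitrary activity unit cancels
#' in the ratio.
#'
#' @param result A `pbrpk_result` whose schedule injected hot ligand into a
#'   venous blood pool.
#' @param t_end Integration limit, minutes.
#' @param tail Include the analytic decay tail (default `TRUE`).
#' @return Blood residence time in minutes.
#' @export
blood_residence_time <- function(result, t_end = max(result$times),
                                 tail = TRUE) {
  stopifnot(inherits(result, "pbrpk_result"))
  if (!"vein" %in% result$graph$compartments$organ) {
    abort("model has no venous blood pool organ `vein`",
          class = "pbrpk_error_reference")
  }
  h0 <- result$schedule$hot_total
  if (h0 <= 0) {
    abort("injected hot amount is zero; BRT undefined",
          class = "pbrpk_error_validation")
  }
  tac <- activity_tac(result, "vein")
  lambda <- attr(tac, "lambda_phys")
  tia <- time_integrated_activity(tac, t_end = t_end, tail = tail)
  tia / (lambda * h0)
}
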