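#' Construct a dose grid over the (hot, cold) injection plane
#'
#' @param hot Strictly increasing injected hot amounts, nmol.
#' @param cold Strictly increasing injected cold amounts, nmol.
#' @param dose Matrix of doses (Gy), `length(hot)` rows by `length(cold)`
#'   columns; non-negative.
#' @param organ Organ label.
#' @return A `dose_grid` object.
#' @export
dose_grid <- function(hot, cold, dose, organ = "organ") {
  if (any(diff(hot) <= 0) || any(diff(cold) <= 0)) {
    abort("dose grid axes must be strictly increasing",
          class = "pbrpk_error_validation")
  }
  dose <- as.matrix(dose)
  if (!all(dim(dose) == c(length(hot), length(cold)))) {
    abort("dose matrix must be hot x cold", class = "pbrpk_error_validation")
  }
  if (any(dose < 0)) {
    abort("doses must be non-negative", class = "pbrpk_error_validation")
  }
  structure(list(hot = hot, cold = cold, dose = dose, organ = organ),
            class = "dose_grid")
}

#' Extract iso-dose contours from a dose grid
#'
#' Marching-squares contour extraction (linear interpolation on cell
#' edges) on the rectilinear sweep grid; for each level the longest
#' connected polyline is returned. Levels outside the dose range are
#' skipped with a warning.
#'
#' @param grid A [dose_grid()].
#' @param levels Iso-dose levels in Gy.
#' @return A list of `isodose_contour` objects (`level`, tibble of
#'   `hot`/`cold` points, and the grid axis ranges used for
#'   standardization).
#' @export
extract_isodose_contours <- function(grid, levels) {
  stopifnot(inherits(grid, "dose_grid"))
  rng <- range(grid$dose)
  out <- list()
  for (lv in levels) {
    if (lv <= rng[1] || lv >= rng[2]) {
      warn(paste0("iso-dose level ", signif(lv, 6),
                  " outside the dose range; skipped"))
      next
    }
    segs <- grDevices::contourLines(x = grid$hot, y = grid$cold,
                                    z = grid$dose, levels = lv)
    if (!length(segs)) {
      warn(paste0("no contour found at level ", signif(lv, 6)))
      next
    }
    # longest connected polyline, by arc length on standardized axes
    lens <- vapply(segs, function(s) {
      dx <- diff(s$x) / diff(range(grid$hot))
      dy <- diff(s$y) / diff(range(grid$cold))
      sum(sqrt(dx^2 + dy^2))
    }, numeric(1))
    s <- segs[[which.max(lens)]]
    out[[length(out) + 1L]] <- structure(
      list(level = lv, points = tibble(hot = s$x, cold = s$y),
           hot_range = range(grid$hot), cold_range = range(grid$cold)),
      class = "isodose_contour"
    )
  }
  out
}

#' Fit a straight line to an iso-dose contour
#'
#' Orthogonal (total-least-squares) fit of the contour polyline after
#' standardizing both axes by their sweep ranges, so the angle does not
#' depend on the units or spans of the axes. Neither axis is a response
#' variable, hence the orthogonal rather than ordinary regression.
#'
#' @param contour An `isodose_contour`, or any data frame with `hot` and
#'   `cold` columns.
#' @param hot_range,cold_range Axis ranges used for standardization;
#'   default to the ranges carried by the contour.
#' @return Direction angle of the fitted line in degrees, in `[0, 180)`;
#'   90 degrees is a vertical contour (no hot/cold competition).
#' @export
fit_contour_line <- function(contour, hot_range = NULL, cold_range = NULL) {
  pts <- if (inherits(contour, "isodose_contour")) contour$points else
    as_tibble(contour)
  hot_range <- hot_range %||% contour$hot_range %||% range(pts$hot)
  cold_range <- cold_range %||% contour$cold_range %||% range(pts$cold)
  if (nrow(pts) < 2L) {
    abort("contour has fewer than 2 points", class = "pbrpk_error_validation")
  }
  x <- (pts$hot - hot_range[1]) / diff(hot_range)
  y <- (pts$cold - cold_range[1]) / diff(cold_range)
  m <- cbind(x - mean(x), y - mean(y))
  sv <- svd(m)
  v <- sv$v[, 1]
  ang <- atan2(v[2], v[1]) * 180 / pi
  ang <- ang %% 180
  ang
}

#' Iso-dose twist profile of a dose grid
#'
#' The twist of an iso-dose level is the absolute angle between the
#' straight line fitted to its contour and the line fitted to the contour
#' of the lowest usable dose level (the reference, which by construction
#' has twist 0), folded into `[0, 90]` degrees. Growing twist with dose
#' level indicates receptor-saturation-driven nonlinearity between
#' injected amounts and delivered dose.
#'
#' @param grid A [dose_grid()].
#' @param levels Iso-dose levels (Gy); default: nine interior deciles of
#'   the grid's dose range.
#' @return A `twist_profile` tibble: `organ`, `level`, `angle_deg`,
#'   `twist_deg`, sorted by level.
#' @export
compute_twist <- function(grid, levels = NULL) {
  stopifnot(inherits(grid, "dose_grid"))
  rng <- range(grid$dose)
  levels <- levels %||% (rng[1] + diff(rng) * seq(0.1, 0.9, by = 0.1))
  contours <- extract_isodose_contours(grid, sort(levels))
  if (length(contours) < 2L) {
    abort("fewer than 2 iso-dose contours extractable",
          class = "pbrpk_error_validation")
  }
  angles <- vapply(contours, fit_contour_line, numeric(1))
  lvls <- vapply(contours, function(ct) ct$level, numeric(1))
  ref <- angles[which.min(lvls)]
  twist <- abs(angles - ref)
  twist <- pmin(twist, 180 - twist)
  out <- tibble(organ = grid$organ, level = lvls, angle_deg = angles,
                twist_deg = twist) |>
    dplyr::arrange(.data$level)
  class(out) <- c("twist_profile", class(out))
  out
}

#' Maximum relative dose change over an injection-schedule sweep
#'
#' `MRDC = (Dose(n*, tau*) - Dose_baseline) / Dose_baseline`, where
#' `(n*, tau*)` is the schedule maximizing the organ dose over the sweep
#' and the baseline is the single-bolus dose. Ties are broken toward the
#' smallest `n`, then the smallest `tau`. Because organ dose and
#' time-integrated activity differ only by a multiplicative constant, the
#' maximum relative TIA change is identical.
#'
#' @param dose_table Data frame with columns `n`, `tau`, `dose`.
#' @param baseline Single-bolus dose (Gy), > 0.
#' @param organ Organ label carried through to the result.
#' @return An `mrdc_result` tibble: `organ`, `baseline_dose`, `n_star`,
#'   `tau_star`, `best_dose`, `mrdc`.
#' @export
compute_mrdc <- function(dose_table, baseline, organ = "organ") {
  if (!all(c("n", "tau", "dose") %in% names(dose_table)) ||
      nrow(dose_table) == 0L) {
    abort("dose_table must have rows and columns n, tau, dose",
          class = "pbrpk_error_validation")
  }
  if (!is.finite(baseline) || baseline <= 0) {
    abort("baseline dose must be > 0", class = "pbrpk_error_validation")
  }
  ord <- order(-dose_table$dose, dose_table$n, dose_table$tau)
  best <- dose_table[ord[1], ]
  out <- tibble(organ = organ, baseline_dose = baseline,
                n_star = best$n, tau_star = best$tau, best_dose = best$dose,
                mrdc = (best$dose - baseline) / baseline)
  class(out) <- c("mrdc_result", class(out))
  out
}

#' Enhancement factor curve over an albumin-affinity sweep
#'
#' `EF(K_D_alb) = [TumorDose(K_D_alb) / OARDose(K_D_alb)] /
#' [TumorDose(Inf) / OARDose(Inf)]`: the tumor-to-organ-at-risk dose ratio
#' at a given albumin binding affinity, normalized by the same ratio with
#' albumin binding disabled. `EF = 1` at `K_D_alb = Inf` by construction;
#' values above 1 mean albumin binding delivers differentially more dose
#' to the tumor.
#'
#' @param kd_alb Albumin dissociation constants, nmol/L.
#' @param tumor_doses,oar_doses Doses (Gy) at each `kd_alb`, same order.
#' @param tumor_base,oar_base Baseline doses at `K_D_alb = Inf` (> 0).
#' @param oar Label of the organ at risk.
#' @return An `ef_curve` tibble: `oar`, `kd_alb`, `tumor_dose`, `oar_dose`,
#'   `ef`.
#' @export
compute_ef <- function(kd_alb, tumor_doses, oar_doses, tumor_base, oar_base,
                       oar = "oar") {
  if (length(kd_alb) != length(tumor_doses) ||
      length(kd_alb) != length(oar_doses)) {
    abort("kd_alb, tumor_doses and oar_doses must have equal length",
          class = "pbrpk_error_validation")
  }
  if (tumor_base <= 0 || oar_base <= 0) {
    abort("baseline doses must be > 0", class = "pbrpk_error_validation")
  }
  if (any(oar_doses <= 0)) {
    abort("organ-at-risk doses must be > 0", class = "pbrpk_error_validation")
  }
  out <- tibble(
    oar = oar, kd_alb = kd_alb,
    tumor_dose = tumor_doses, oar_dose = oar_doses,
    ef = (tumor_doses / oar_doses) / (tumor_base / oar_base)
  )
  class(out) <- c("ef_curve", class(out))
  out
}
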