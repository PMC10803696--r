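#' Specify a simulation study
#'
#' Bundles the parameter grids, organs to report and solver settings for
#' one of the three study pipelines. Defaults reproduce the studied
#' sweeps: hot/cold competition (hot 5–100 nmol, cold 25–800 nmol, tumor
#' receptor density 10–890 nmol/L and tumor volume 40–2100 mL, 10 linear
#' samples each); injection fractionation (1–10 boluses, 10–1000 min
#' apart, totals fixed at 10 nmol hot / 100 nmol cold, densities 43–342
#' nmol/L); albumin affinity (20 log-spaced dissociation constants in
#' 5–1e5 nmol/L plus the binding-disabled baseline).
#'
#' @param kind `"hotcold"`, `"injection"` or `"albumin"`.
#' @param hot,cold Injected amounts grids (nmol) for the hot/cold study,
#'   or scalar totals for the other studies.
#' @param volumes_ml,densities Tumor volume (mL) and receptor density
#'   (nmol/L) grids.
#' @param n_values,tau_values Bolus count and inter-bolus interval (min)
#'   grids for the injection study.
#' @param kd_values Albumin dissociation constant grid (nmol/L) for the
#'   albumin study; the `Inf` baseline is always added.
#' @param injection_coefficient Inert labeled parameter echoed with
#'   injection-study output; it does not influence the simulation.
#' @param organs Organs to report.
#' @param base Population parameters ([default_parameters()]).
#' @param settings [solver_settings()].
#' @return A `study_spec` object.
#' @export
study_spec <- function(kind = c("hotcold", "injection", "albumin"),
                       hot = NULL, cold = NULL,
                       volumes_ml = NULL, densities = NULL,
                       n_values = NULL, tau_values = NULL,
                       kd_values = NULL,
                       injection_coefficient = 1:6,
                       organs = c("tumor", "kidneys", "salivary_glands"),
                       base = default_parameters(),
                       settings = solver_settings()) {
  kind <- match.arg(kind)
  spec <- switch(kind,
    hotcold = list(
      hot = hot %||% seq(5, 100, length.out = 10),
      cold = cold %||% seq(25, 800, length.out = 10),
      volumes_ml = volumes_ml %||% seq(40, 2100, length.out = 10),
      densities = densities %||% seq(10, 890, length.out = 10)
    ),
    injection = list(
      hot = hot %||% 10, cold = cold %||% 100,
      n_values = as.integer(n_values %||% 1:10),
      tau_values = tau_values %||% c(10, 50, 100, 200, 300, 400, 500, 750,
                                     1000),
      volumes_ml = volumes_ml %||% seq(40, 2100, length.out = 10),
      densities = densities %||% seq(43, 342, length.out = 10),
      injection_coefficient = injection_coefficient
    ),
    albumin = list(
      hot = hot %||% 10, cold = cold %||% 100,
      kd_values = kd_values %||%
        exp(seq(log(5), log(1e5), length.out = 20)),
      volumes_ml = volumes_ml %||% 20,
      densities = densities %||% 40
    )
  )
  structure(c(list(kind = kind, organs = organs, base = base,
                   settings = settings), spec),
            class = "study_spec")
}

#' @export
print.study_spec <- function(x, ...) {
  cat("<study_spec>", x$kind, "\n")
  grids <- intersect(names(x), c("hot", "cold", "volumes_ml", "densities",
                                 "n_values", "tau_values", "kd_values"))
  for (gname in grids) {
    cat("  ", gname, ": ", length(x[[gname]]), " value(s)\n", sep = "")
  }
  invisible(x)
}

subsample_keep_ends <- function(x, factor) {
  n <- length(x)
  m <- ceiling(n / factor)
  if (m <= 1L) return(x[1])
  idx <- unique(round(seq(1, n, length.out = m)))
  x[idx]
}

#' Reduce a study's grids for desk-scale runs
#'
#' Subsamples every swept grid to `ceiling(size/factor)` points, always
#' keeping the endpoints (a single remaining point is the lower endpoint).
#' The study structure is unchanged.
#'
#' @param spec A [study_spec()].
#' @param factor Integer >= 1; 1 is the identity.
#' @export
scale_grid <- function(spec, factor) {
  stopifnot(inherits(spec, "study_spec"))
  if (factor < 1 || factor != round(factor)) {
    abort("scale factor must be an integer >= 1",
          class = "pbrpk_error_validation")
  }
  for (gname in intersect(names(spec),
                          c("hot", "cold", "volumes_ml", "densities",
                            "n_values", "tau_values", "kd_values"))) {
    if (length(spec[[gname]]) > 1L) {
      spec[[gname]] <- subsample_keep_ends(spec[[gname]], factor)
    }
  }
  spec
}

# dose per organ for one simulation, as a narrow tibble
organ_doses <- function(result, organs) {
  rep_ <- dose_report(result, organs = organs)
  tibble(organ = rep_$organ, tia = rep_$tia, dose_gy = rep_$dose_gy)
}

#' Run the hot/cold ligand competition study
#'
#' For every virtual patient (tumor volume x receptor density) and every
#' (hot, cold) injection pair: a single bolus is simulated and the
#' absorbed dose per reported organ computed. Iso-dose twist profiles are
#' derived per patient and organ from the resulting dose grids.
#'
#' @param spec A `study_spec` of kind `"hotcold"`.
#' @return A `pbrpk_study`: `results` (long tibble of doses per grid
#'   point) and `twist` (twist profiles per patient and organ).
#' @export
run_hotcold_study <- function(spec) {
  stopifnot(inherits(spec, "study_spec"), spec$kind == "hotcold")
  grid <- tidyr::expand_grid(volume_ml = spec$volumes_ml,
                             density = spec$densities)
  results <- purrr::pmap_dfr(grid, function(volume_ml, density) {
    patient <- suppressWarnings(
      make_virtual_patient(spec$base, volume_ml, density))
    graph <- build_pbrpk_model(patient, model_options(albumin_enabled = FALSE))
    inj <- tidyr::expand_grid(hot = spec$hot, cold = spec$cold)
    purrr::pmap_dfr(inj, function(hot, cold) {
      res <- simulate_model(graph, injection_schedule(hot, cold),
                            spec$settings)
      organ_doses(res, spec$organs) |>
        dplyr::mutate(volume_ml = volume_ml, density = density,
                      hot = hot, cold = cold, .before = 1)
    })
  })
  twist <- results |>
    dplyr::group_by(.data$volume_ml, .data$density, .data$organ) |>
    dplyr::group_modify(function(df, key) {
      dg <- dose_grid(
        hot = sort(unique(df$hot)), cold = sort(unique(df$cold)),
        dose = df |>
          dplyr::arrange(.data$cold, .data$hot) |>
          dplyr::pull(.data$dose_gy) |>
          matrix(nrow = length(unique(df$hot))),
        organ = key$organ
      )
      tw <- tryCatch(compute_twist(dg), error = function(e) NULL)
      if (is.null(tw)) tibble() else dplyr::select(tw, -"organ")
    }) |>
    dplyr::ungroup()
  new_study("hotcold", spec, results, twist = twist)
}

#' Run the injection-fractionation study
#'
#' For every virtual patient and every (number of boluses n, inter-bolus
#' interval tau): the fixed totals are split equally over the boluses and
#' the dose per reported organ computed. The maximum relative dose change
#' (MRDC) per patient and organ is taken over the swept schedules against
#' the single-bolus baseline (which is part of the searched set via
#' n = 1).
#'
#' @param spec A `study_spec` of kind `"injection"`.
#' @return A `pbrpk_study`: `results` and `mrdc`.
#' @export
run_injection_study <- function(spec) {
  stopifnot(inherits(spec, "study_spec"), spec$kind == "injection")
  grid <- tidyr::expand_grid(volume_ml = spec$volumes_ml,
                             density = spec$densities)
  results <- purrr::pmap_dfr(grid, function(volume_ml, density) {
    patient <- suppressWarnings(
      make_virtual_patient(spec$base, volume_ml, density))
    graph <- build_pbrpk_model(patient, model_options(albumin_enabled = FALSE))
    # the single-bolus run does not depend on tau: simulate once, echo per tau
    single <- simulate_model(graph, injection_schedule(spec$hot, spec$cold),
                             spec$settings)
    single_doses <- organ_doses(single, spec$organs)
    purrr::pmap_dfr(tidyr::expand_grid(n = spec$n_values,
                                       tau = spec$tau_values),
                    function(n, tau) {
      doses <- if (n == 1L) single_doses else {
        res <- simulate_model(
          graph, injection_schedule(spec$hot, spec$cold, n = n, tau = tau),
          spec$settings)
        organ_doses(res, spec$organs)
      }
      doses |>
        dplyr::mutate(volume_ml = volume_ml, density = density,
                      n = n, tau = tau, .before = 1)
    })
  })
  mrdc <- results |>
    dplyr::group_by(.data$volume_ml, .data$density, .data$organ) |>
    dplyr::group_modify(function(df, key) {
      base <- df$dose_gy[df$n == 1L][1]
      compute_mrdc(
        tibble(n = df$n, tau = df$tau, dose = df$dose_gy),
        baseline = base, organ = key$organ
      ) |> dplyr::select(-"organ")
    }) |>
    dplyr::ungroup()
  new_study("injection", spec, results, mrdc = mrdc)
}

#' Run the albumin-affinity study
#'
#' Sweeps the albumin dissociation constant `K_D_alb` over the study specification's
#' log-spaced grid plus the binding-disabled baseline (`K_D_alb = Inf`),
#' simulating the albumin-enabled model for a fixed injection (10 nmol
#' hot, 100 nmol cold by default). Reports per-organ doses, the blood
#' residence time per affinity, and the enhancement factor of the tumor
#' versus each non-tumor reported organ.
#'
#' @param spec A `study_spec` of kind `"albumin"`.
#' @return A `pbrpk_study`: `results`, `brt` and `ef`.
#' @export
run_albumin_study <- function(spec) {
  stopifnot(inherits(spec, "study_spec"), spec$kind == "albumin")
  kds <- c(sort(spec$kd_values, decreasing = TRUE), Inf)
  kds <- unique(kds)
  patient0 <- suppressWarnings(
    make_virtual_patient(spec$base, spec$volumes_ml[1], spec$densities[1]))
  runs <- purrr::map(kds, function(kd) {
    base <- patient0$base
    base$K_D_alb <- kd
    patient <- make_virtual_patient(base, patient0$tumor_volume_ml,
                                    patient0$receptor_density)
    graph <- build_pbrpk_model(patient, model_options(albumin_enabled = TRUE))
    res <- simulate_model(graph,
                          injection_schedule(spec$hot, spec$cold),
                          spec$settings)
    list(kd = kd, doses = organ_doses(res, spec$organs),
         brt = blood_residence_time(res))
  })
  results <- purrr::map_dfr(runs, function(r) {
    r$doses |> dplyr::mutate(kd_alb = r$kd, .before = 1)
  })
  brt <- tibble(kd_alb = kds,
                brt_min = vapply(runs, function(r) r$brt, numeric(1)))
  oars <- setdiff(spec$organs, "tumor")
  base_doses <- results |> dplyr::filter(is.infinite(.data$kd_alb))
  tumor_base <- base_doses$dose_gy[base_doses$organ == "tumor"]
  ef <- purrr::map_dfr(oars, function(oar) {
    sub <- results |> dplyr::filter(.data$organ %in% c("tumor", oar)) |>
      tidyr::pivot_wider(id_cols = "kd_alb", names_from = "organ",
                         values_from = "dose_gy")
    compute_ef(sub$kd_alb, sub$tumor, sub[[oar]],
               tumor_base, base_doses$dose_gy[base_doses$organ == oar],
               oar = oar)
  })
  new_study("albumin", spec, results, brt = brt, ef = ef)
}

new_study <- function(kind, spec, results, ...) {
  structure(list(kind = kind, spec = spec, results = results, ...),
            class = "pbrpk_study")
}

#' @export
print.pbrpk_study <- function(x, ...) {
  cat("<pbrpk_study>", x$kind, "-", nrow(x$results), "dose rows\n")
  invisible(x)
}

#' @method tidy pbrpk_study
#' @export
tidy.pbrpk_study <- function(x, ...) as_tibble(x$results)

#' @method glance pbrpk_study
#' @export
glance.pbrpk_study <- function(x, ...) {
  tibble(kind = x$kind, n_rows = nrow(x$results),
         n_organs = length(unique(x$results$organ)),
         max_dose_gy = max(x$results$dose_gy))
}

#' Write a study's tables and run manifest to a directory
#'
#' Emits the long-form result table and every derived metric table as
#' tab-separated files, plus a YAML manifest echoing the study grids and
#' solver settings.
#'
#' @param study A `pbrpk_study`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
export_study <- function(study, dir) {
  stopifnot(inherits(study, "pbrpk_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  tables <- c(list(results = study$results),
              study[setdiff(names(study), c("kind", "spec", "results"))])
  for (nm in names(tables)) {
    if (!is.data.frame(tables[[nm]])) next
    p <- file.path(dir, paste0(study$kind, "_", nm, ".tsv"))
    utils::write.table(tables[[nm]], p, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    paths <- c(paths, p)
  }
  spec <- study$spec
  manifest <- list(
    kind = study$kind,
    organs = spec$organs,
    grids = lapply(spec[intersect(names(spec),
                                  c("hot", "cold", "volumes_ml", "densities",
                                    "n_values", "tau_values", "kd_values",
                                    "injection_coefficient"))],
                   function(v) unname(as.numeric(v))),
    solver = list(rtol = spec$settings$rtol, atol = spec$settings$atol,
                  t_end = spec$settings$t_end),
    package_version = as.character(utils::packageVersion("pbrpk"))
  )
  mp <- file.path(dir, paste0(study$kind, "_manifest.yaml"))
  yaml::write_yaml(manifest, mp)
  invisible(c(paths, mp))
}
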