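#' Define a multi-bolus injection schedule
#'
#' A schedule is characterized by the total injected hot (radiolabeled) and
#' cold (unlabeled) ligand amounts, the number of boluses `n`, and the
#' inter-bolus interval `tau`; boluses occur at times `0, tau, ..., (n-1) tau`
#' minutes. By default the totals are split equally across boluses; explicit
#' per-bolus amounts may be given instead.
#'
#' @param hot_total Total injected hot ligand, nmol.
#' @param cold_total Total injected cold ligand, nmol.
#' @param n Number of boluses (integer >= 1).
#' @param tau Inter-bolus interval, minutes (>= 0).
#' @param hot_per_bolus,cold_per_bolus Optional numeric vectors of length `n`
#'   overriding the equal split; must sum to the respective totals.
#' @return An `injection_schedule` object.
#' @export
injection_schedule <- function(hot_total = 10, cold_total = 100,
                               n = 1L, tau = 0,
                               hot_per_bolus = NULL, cold_per_bolus = NULL) {
  n <- as.integer(n)
  if (n < 1L) abort("number of injections must be >= 1",
                    class = "pbrpk_error_validation")
  if (tau < 0) abort("inter-bolus interval must be >= 0",
                     class = "pbrpk_error_validation")
  if (hot_total < 0 || cold_total < 0) {
    abort("injected amounts must be >= 0", class = "pbrpk_error_validation")
  }
  hp <- hot_per_bolus %||% rep(hot_total / n, n)
  cp <- cold_per_bolus %||% rep(cold_total / n, n)
  if (length(hp) != n || length(cp) != n) {
    abort("per-bolus amount vectors must have length n",
          class = "pbrpk_error_validation")
  }
  if (abs(sum(hp) - hot_total) > 1e-9 * max(1, hot_total) ||
      abs(sum(cp) - cold_total) > 1e-9 * max(1, cold_total)) {
    abort("per-bolus amounts must sum to the stated totals",
          class = "pbrpk_error_validation")
  }
  structure(
    list(hot_total = hot_total, cold_total = cold_total, n = n, tau = tau,
         times = (seq_len(n) - 1) * tau, hot_per_bolus = hp,
         cold_per_bolus = cp),
    class = "injection_schedule"
  )
}

#' Solver settings for the stiff ODE integration
#'
#' @param rtol Relative tolerance (default 1e-8).
#' @param atol Absolute tolerance in nmol (default 1e-12).
#' @param t_end Simulation horizon in minutes (default 50,000, about 5.2
#'   half-lives of Lu-177).
#' @param grid Optional explicit output time grid (minutes). When `NULL`, a
#'   composite grid is used: minute resolution over the first hour, then
#'   log-spaced points out to `t_end` (plus all bolus times).
#' @export
solver_settings <- function(rtol = 1e-8, atol = 1e-12, t_end = 50000,
                            grid = NULL) {
  if (rtol <= 0 || atol <= 0) abort("tolerances must be > 0",
                                    class = "pbrpk_error_validation")
  if (t_end <= 0) abort("t_end must be > 0", class = "pbrpk_error_validation")
  structure(list(rtol = rtol, atol = atol, t_end = t_end, grid = grid),
            class = "solver_settings")
}

default_output_grid <- function(t_end, bolus_times = 0) {
  early <- seq(0, min(60, t_end), by = 1)
  late <- exp(seq(log(max(1, min(60, t_end))), log(t_end), length.out = 400))
  grid <- sort(unique(c(0, early, late, t_end,
                        bolus_times[bolus_times <= t_end])))
  grid[grid <= t_end]
}

#' Assemble the ODE right-hand side of a reaction graph
#'
#' Compiles the graph into a derivative evaluator `d(state)/dt =
#' S %*% rates(state)`. All unimolecular and transport reactions are folded
#' into a constant linear operator; bimolecular mass-action reactions are
#' evaluated separately, so both the right-hand side and its analytic
#' Jacobian are cheap dense linear-algebra operations.
#'
#' @inheritParams add_compartment
#' @return A list with elements `rhs(t, y, parms)` and `jac(t, y, parms)`
#'   (deSolve calling convention), `species` (state ordering) and the
#'   internal operator pieces.
#' @export
assemble_rhs <- function(graph) {
  stop_if_invalid(graph)
  sp <- graph$species$id
  ns <- length(sp)
  vol <- stats::setNames(graph$compartments$volume, graph$compartments$id)
  comp <- stats::setNames(graph$species$compartment, graph$species$id)
  rx <- graph$reactions
  S <- stoichiometry_matrix(graph)

  L <- matrix(0, ns, ns, dimnames = list(sp, sp))
  bi_i1 <- integer(0); bi_i2 <- integer(0); bi_c <- numeric(0)
  bi_cols <- integer(0)

  for (j in seq_len(nrow(rx))) {
    r <- rx$reactants[[j]]
    k <- rx$rate_constant[j]
    total <- sum(r)
    if (rx$form[j] != "mass_action") {
      src <- names(r)[1]
      i <- match(src, sp)
      L[, i] <- L[, i] + S[, j] * (k / vol[comp[src]])
    } else if (total == 1) {
      src <- names(r)[1]
      i <- match(src, sp)
      vr <- vol[rx$volume_refs[[j]][1]]
      L[, i] <- L[, i] + S[, j] * (k * vr / vol[comp[src]])
    } else if (total == 2) {
      vr <- vol[rx$volume_refs[[j]][1]]
      if (length(r) == 2L) {
        s1 <- names(r)[1]; s2 <- names(r)[2]
        cc <- k * vr / (vol[comp[s1]] * vol[comp[s2]])
        bi_i1 <- c(bi_i1, match(s1, sp)); bi_i2 <- c(bi_i2, match(s2, sp))
      } else {
        s1 <- names(r)[1]
        cc <- k * vr / vol[comp[s1]]^2
        bi_i1 <- c(bi_i1, match(s1, sp)); bi_i2 <- c(bi_i2, match(s1, sp))
      }
      bi_c <- c(bi_c, cc)
      bi_cols <- c(bi_cols, j)
    } else {
      abort("mass-action reactions of order > 2 are not supported",
            class = "pbrpk_error_validation")
    }
  }
  nb <- length(bi_c)
  S_bi <- if (nb) S[, bi_cols, drop = FALSE] else matrix(0, ns, 0)
  storage.mode(S_bi) <- "double"

  rhs <- function(t, y, parms) {
    dy <- L %*% y
    if (nb) dy <- dy + S_bi %*% (bi_c * y[bi_i1] * y[bi_i2])
    list(as.numeric(dy))
  }
  jac <- function(t, y, parms) {
    if (!nb) return(L)
    Rb <- matrix(0, nb, ns)
    ix1 <- cbind(seq_len(nb), bi_i1)
    ix2 <- cbind(seq_len(nb), bi_i2)
    Rb[ix1] <- Rb[ix1] + bi_c * y[bi_i2]
    Rb[ix2] <- Rb[ix2] + bi_c * y[bi_i1]
    L + S_bi %*% Rb
  }
  list(rhs = rhs, jac = jac, species = sp, linear = L, S_bi = S_bi,
       bi = list(i1 = bi_i1, i2 = bi_i2, coef = bi_c))
}

# locate the venous free hot/cold ligand species used as bolus targets
bolus_targets <- function(graph) {
  sp <- graph$species
  cp <- graph$compartments
  pool <- cp$id[cp$subspace == "blood_pool" &
                  grepl("vein|venous", cp$organ, ignore.case = TRUE)]
  if (!length(pool)) pool <- cp$id[cp$subspace == "blood_pool"]
  hot <- sp$id[sp$kind == "hot_ligand" & sp$compartment %in% pool]
  cold <- sp$id[sp$kind == "cold_ligand" & sp$compartment %in% pool]
  if (!length(hot)) hot <- sp$id[sp$kind == "hot_ligand"]
  if (!length(cold)) cold <- sp$id[sp$kind == "cold_ligand"]
  list(hot = hot[1], cold = cold[1])
}

#' Simulate a reaction graph under an injection schedule
#'
#' Integrates the stiff mass-action system with `deSolve::lsoda` using the
#' analytic Jacobian from [assemble_rhs()]. Boluses are applied as
#' discontinuous additions to the venous free hot/cold ligand amounts; the
#' integrator restarts cleanly at each bolus time (the first bolus, at t =
#' 0, is folded into the initial state).
#'
#' @inheritParams add_compartment
#' @param schedule An [injection_schedule()].
#' @param settings A [solver_settings()].
#' @return A `pbrpk_result` with the output time grid (`times`, minutes), the
#'   amounts matrix (`amounts`, time by species, nmol), the graph, schedule
#'   and settings echoes, and solver diagnostics.
#' @export
simulate_model <- function(graph, schedule = injection_schedule(),
                           settings = solver_settings()) {
  stop_if_invalid(graph)
  if (settings$t_end <= max(schedule$times)) {
    abort("t_end must exceed the last bolus time",
          class = "pbrpk_error_validation")
  }
  sys <- assemble_rhs(graph)
  y0 <- stats::setNames(graph$species$initial_amount, sys$species)
  tg <- bolus_targets(graph)
  if ((schedule$hot_total > 0 && is.na(tg$hot)) ||
      (schedule$cold_total > 0 && is.na(tg$cold))) {
    abort("graph has no venous hot/cold ligand species to inject into",
          class = "pbrpk_error_reference")
  }
  # first bolus at t = 0 goes straight into the initial state
  if (!is.na(tg$hot)) y0[tg$hot] <- y0[tg$hot] + schedule$hot_per_bolus[1]
  if (!is.na(tg$cold)) y0[tg$cold] <- y0[tg$cold] + schedule$cold_per_bolus[1]

  times <- settings$grid %||%
    default_output_grid(settings$t_end, schedule$times)
  times <- sort(unique(c(0, times)))

  events <- NULL
  if (schedule$n > 1L) {
    later <- seq(2L, schedule$n)
    ed <- data.frame(
      var = rep(c(tg$hot, tg$cold), each = length(later)),
      time = rep(schedule$times[later], 2L),
      value = c(schedule$hot_per_bolus[later], schedule$cold_per_bolus[later]),
      method = "add",
      stringsAsFactors = FALSE
    )
    ed <- ed[ed$value != 0, , drop = FALSE]
    ed <- ed[order(ed$time, ed$var), , drop = FALSE]
    if (nrow(ed)) events <- list(data = ed)
    times <- sort(unique(c(times, schedule$times)))
  }

  out <- deSolve::ode(
    y = y0, times = times, func = sys$rhs, parms = NULL,
    method = "lsoda", jacfunc = sys$jac, jactype = "fullusr",
    rtol = settings$rtol, atol = settings$atol,
    events = events, maxsteps = 50000
  )
  diagn <- attr(out, "istate")
  if (attr(out, "istate")[1] < 0) {
    abort(paste0("ODE solver failed near t = ",
                 max(out[, "time"], na.rm = TRUE), " min"),
          class = "pbrpk_error_solver")
  }
  amounts <- out[, -1, drop = FALSE]
  clamp <- 1e3 * settings$atol
  if (min(amounts) < -clamp) {
    abort(paste0("negative state beyond tolerance: min = ", min(amounts)),
          class = "pbrpk_error_solver")
  }
  amounts[amounts < 0] <- 0
  structure(
    list(times = out[, "time"], amounts = amounts, graph = graph,
         schedule = schedule, settings = settings, diagnostics = diagn),
    class = "pbrpk_result"
  )
}

#' @export
print.pbrpk_result <- function(x, ...) {
  cat("<pbrpk_result>\n")
  cat("  time points:", length(x$times), " (0 to",
      max(x$times), "min)\n")
  cat("  species:    ", ncol(x$amounts), "\n")
  cat("  schedule:   ", x$schedule$n, "bolus(es),",
      x$schedule$hot_total, "nmol hot /", x$schedule$cold_total,
      "nmol cold\n")
  invisible(x)
}

#' Tidy a simulation result into a long tibble
#'
#' @param x A `pbrpk_result`.
#' @param ... Unused.
#' @return A tibble with columns `time`, `organ`, `compartment`, `subspace`,
#'   `species`, `kind`, `amount` (nmol).
#' @method tidy pbrpk_result
#' @export
tidy.pbrpk_result <- function(x, ...) {
  sp <- x$graph$species
  cp <- x$graph$compartments
  long <- as_tibble(x$amounts) |>
    dplyr::mutate(time = x$times, .before = 1) |>
    tidyr::pivot_longer(-"time", names_to = "species", values_to = "amount")
  meta <- sp |>
    dplyr::left_join(cp, by = c(compartment = "id")) |>
    dplyr::select(species = "id", "compartment", "subspace", "organ", "kind")
  dplyr::left_join(long, meta, by = "species") |>
    dplyr::select("time", "organ", "compartment", "subspace", "species",
                  "kind", "amount")
}

#' One-line summary of a simulation result
#' @inheritParams tidy.pbrpk_result
#' @method glance pbrpk_result
#' @export
glance.pbrpk_result <- function(x, ...) {
  tibble(
    n_species = ncol(x$amounts),
    n_times = length(x$times),
    t_end = max(x$times),
    n_bolus = x$schedule$n,
    hot_total = x$schedule$hot_total,
    cold_total = x$schedule$cold_total,
    total_final = sum(x$amounts[nrow(x$amounts), ])
  )
}

#' Resample a simulation result onto a new time grid
#'
#' Linear (hence monotone-preserving) interpolation of every species
#' trajectory; endpoints are reproduced exactly.
#'
#' @param result A `pbrpk_result`.
#' @param grid New time grid, minutes, within the simulated range.
#' @export
resample <- function(result, grid) {
  stopifnot(inherits(result, "pbrpk_result"))
  if (any(grid < min(result$times) - 1e-12) ||
      any(grid > max(result$times) + 1e-12)) {
    abort("resampling grid outside the simulated time range",
          class = "pbrpk_error_validation")
  }
  grid <- sort(grid)
  new_amounts <- apply(result$amounts, 2, function(a) {
    stats::approx(result$times, a, xout = grid, rule = 1)$y
  })
  if (length(grid) == 1L) {
    new_amounts <- matrix(new_amounts, nrow = 1,
                          dimnames = list(NULL, colnames(result$amounts)))
  }
  result$times <- grid
  result$amounts <- new_amounts
  result
}

#' Sum species amounts by moiety over time
#'
#' Helper used by the conservation audits: returns, per output time, the
#' total amount of a labeled moiety. Moieties: `"ligand"` counts every hot
#' and cold form (free, receptor-bound, internalized, albumin-complexed,
#' excreted); `"albumin"` counts free albumin and both complexes;
#' `"receptor"` counts free and occupied receptors; `"hot"` counts all
#' hot-labeled forms.
#'
#' @param result A `pbrpk_result`.
#' @param moiety One of `"ligand"`, `"albumin"`, `"receptor"`, `"hot"`.
#' @param organ Optional organ filter (used for per-organ receptor audits).
#' @return Numeric vector, one total per output time.
#' @export
moiety_totals <- function(result, moiety = c("ligand", "albumin", "receptor",
                                             "hot"),
                          organ = NULL) {
  moiety <- match.arg(moiety)
  kinds <- switch(moiety,
    ligand = c("hot_ligand", "cold_ligand", "hot_bound", "cold_bound",
               "hot_internal", "cold_internal", "hot_albumin_complex",
               "cold_albumin_complex"),
    albumin = c("albumin", "hot_albumin_complex", "cold_albumin_complex"),
    receptor = c("receptor", "hot_bound", "cold_bound"),
    hot = c("hot_ligand", "hot_bound", "hot_internal", "hot_albumin_complex")
  )
  sp <- result$graph$species
  keep <- sp$kind %in% kinds
  if (!is.null(organ)) {
    cp <- result$graph$compartments
    comps <- cp$id[cp$organ == organ]
    keep <- keep & sp$compartment %in% comps
  }
  ids <- sp$id[keep]
  if (!length(ids)) return(rep(0, length(result$times)))
  rowSums(result$amounts[, ids, drop = FALSE])
}
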